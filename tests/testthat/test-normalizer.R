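test_that("lexicon expansion adds seeds, synonyms, children and colloquials", {
  fx <- generate_lexicon_fixture(tempfile("lex"))
  lex <- fx$lexicon
  # the ingrown-toenail child sits under the nail-changes seed
  child <- lex[lex$concept_id == "C0027343", ]
  expect_gte(nrow(child), 1)
  expect_true(all(child$group_id == "nail changes"))
  expect_true(all(child$seed_concept_id == "C0027339"))
  expect_true(all(child$source == "child"))
  # synonyms carried over
  expect_true("Xerosis" %in% lex$name[lex$group_id == "xerosis"])
  # colloquial phrases attached to their group
  expect_true("itching like crazy" %in% lex$name[lex$group_id == "pruritus"])
  # (name, concept_id) unique
  expect_false(anyDuplicated(lex[c("name", "concept_id")]) > 0)
})

test_that("child expansion obeys the expand_children flag", {
  fx <- generate_lexicon_fixture(tempfile("lex"))
  seeds_off <- fx$seeds
  seeds_off$expand_children <- FALSE
  lex_off <- expand_lexicon(seeds_off, fx$ontology, fx$colloquial)
  expect_false("C0027343" %in% lex_off$concept_id)
  expect_false("C0263531" %in% lex_off$concept_id)
})

test_that("a bare seed with no synonyms/children/colloquial yields one entry", {
  ont <- tibble::tibble(concept_id = "C9999999",
                        preferred_name = "Solitary finding",
                        synonyms = list(character()), parents = list(character()))
  seeds <- tibble::tibble(concept_id = "C9999999", group_id = "solo",
                          expand_children = TRUE)
  lex <- expand_lexicon(seeds, ont, colloquial = NULL)
  expect_equal(nrow(lex), 1L)
  expect_equal(lex$source, "seed")
})

test_that("unknown seed concepts and cyclic ontologies are rejected", {
  fx <- generate_lexicon_fixture(tempfile("lex"))
  bad_seed <- tibble::tibble(concept_id = "C0000000", group_id = "x",
                             expand_children = FALSE)
  expect_error(expand_lexicon(bad_seed, fx$ontology),
               class = "adrsignal_unknown_seed")
  cyc <- tibble::tibble(concept_id = c("A", "B"),
                        preferred_name = c("a", "b"),
                        synonyms = list(character(), character()),
                        parents = list("B", "A"))
  expect_error(adrsignal:::validate_ontology(cyc),
               class = "adrsignal_ontology_error")
})

test_that("the worked colloquial mention resolves to Peeling of nails (C0263531)", {
  idx <- small_lexicon_index()
  hit <- normalize_mention("finger nails have been peeling", idx)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$concept_id, "C0263531")
  expect_equal(hit$group_id, "nail changes")
  expect_equal(hit$rank, 1L)
})

test_that("every lexicon entry self-resolves to its own concept at rank 1", {
  fx <- generate_lexicon_fixture(tempfile("lex"))
  idx <- build_concept_index(fx$lexicon)
  hits <- purrr::map(fx$lexicon$name, normalize_mention, index = idx)
  expect_true(all(purrr::map_int(hits, nrow) == 1L))
  expect_equal(purrr::map_chr(hits, "concept_id"), fx$lexicon$concept_id)
})

test_that("returned matches stay within the configured target groups", {
  idx <- small_lexicon_index()
  mentions <- c("bad rash", "skin is peeling", "cannot sweat", "acne got worse")
  for (m in mentions) {
    hit <- normalize_mention(m, idx)
    if (nrow(hit) == 1) {
      expect_true(hit$group_id %in% default_target_groups())
    }
  }
})

test_that("gibberish and empty mentions return no match", {
  idx <- small_lexicon_index()
  expect_equal(nrow(normalize_mention("zzqq blargh", idx)), 0L)
  expect_equal(nrow(normalize_mention("", idx)), 0L)
  expect_equal(nrow(normalize_mention("   ", idx)), 0L)
})

test_that("index build is invariant to entry order and deduplicates", {
  fx <- generate_lexicon_fixture(tempfile("lex"))
  lex <- fx$lexicon
  idx1 <- build_concept_index(lex)
  idx2 <- build_concept_index(lex[rev(seq_len(nrow(lex))), ])
  idx3 <- build_concept_index(dplyr::bind_rows(lex, lex[1:3, ]))
  queries <- c("nail peeling", "dry skin", "itchy skin", "blisters")
  for (q in queries) {
    expect_identical(concept_candidates(q, idx1), concept_candidates(q, idx2))
    expect_identical(concept_candidates(q, idx1), concept_candidates(q, idx3))
  }
  expect_error(build_concept_index(lex[0, ]),
               class = "adrsignal_empty_lexicon")
})

test_that("adding an unrelated entry never changes an exact-match top hit", {
  fx <- generate_lexicon_fixture(tempfile("lex"))
  idx1 <- build_concept_index(fx$lexicon)
  unrelated <- tibble::tibble(name = "quixotic zymurgy finding",
                              concept_id = "C7777777",
                              seed_concept_id = "C7777777",
                              group_id = "rash", source = "seed")
  idx2 <- build_concept_index(dplyr::bind_rows(fx$lexicon, unrelated))
  for (q in fx$lexicon$name) {
    expect_equal(normalize_mention(q, idx1)$concept_id,
                 normalize_mention(q, idx2)$concept_id)
  }
})

test_that("normalize_mentions maps ADR spans only and memoises surfaces", {
  idx <- small_lexicon_index()
  spans <- tibble::tibble(
    post_id = c("p1", "p1", "p2"),
    char_start = c(0L, 10L, 0L), char_end = c(4L, 14L, 4L),
    label = c("ADR", "IND", "ADR"),
    surface = c("dry skin", "psoriasis", "dry skin")
  )
  out <- normalize_mentions(spans, idx)
  expect_equal(out$group_id, c("xerosis", NA, "xerosis"))
  expect_true(is.na(out$concept_id[2]))
})
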