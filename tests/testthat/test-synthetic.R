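test_that("corpus generation is byte-identical under a fixed seed", {
  cfg <- gen_config(n_users = 200, seed = 42)
  b1 <- generate_corpus(cfg)
  b2 <- generate_corpus(cfg)
  expect_identical(b1, b2)
  b3 <- generate_corpus(gen_config(n_users = 200, seed = 43))
  expect_false(identical(b1$posts$body, b3$posts$body))
})

test_that("zero emission probabilities produce zero reaction spans and pairs", {
  cfg <- gen_config(n_users = 150, background_emission = 0,
                    indication_rate = 0, seed = 7)
  b <- generate_corpus(cfg)
  expect_equal(nrow(b$spans), 0L)
  expect_equal(nrow(b$pairs), 0L)
  expect_true(all(nzchar(b$posts$body)))
})

test_that("gold spans sit verbatim at their offsets and pairs are witnessed", {
  b <- generate_corpus(gen_config(n_users = 250, seed = 11))
  body_of <- setNames(b$posts$body, b$posts$post_id)
  expect_true(all(substring(body_of[b$spans$post_id],
                            b$spans$char_start + 1,
                            b$spans$char_end) == b$spans$surface))
  # every gold pair has a drug mention and an ADR span in the same post
  m <- compile_drug_matcher(b$aliases$alias)
  adr_posts <- unique(b$spans$post_id[b$spans$label == "ADR"])
  set.seed(1)
  for (i in sample(nrow(b$pairs), min(50, nrow(b$pairs)))) {
    p <- b$pairs[i, ]
    expect_true(p$post_id %in% adr_posts)
    expect_gte(nrow(match_drug(m, body_of[[p$post_id]])), 1)
  }
})

test_that("planted pair frequency matches its generative rate within 3 sigma", {
  p_emit <- 0.3
  cfg <- gen_config(
    n_users = 1000, posts_per_user_mean = 3,
    drugs = tibble::tibble(drug_id = c("erlotinib", "metformin"),
                           role = c("target", "comparison"),
                           mention_prob = 0.2, brand = NA_character_),
    background_emission = 0.01,
    planted = tibble::tibble(drug_id = "erlotinib", group_id = "hypohidrosis",
                             emission_prob = p_emit),
    seed = 99)
  b <- generate_corpus(cfg)
  n_hit <- dplyr::n_distinct(
    b$pairs$user_id[b$pairs$drug_id == "erlotinib" &
                      b$pairs$group_id == "hypohidrosis"])
  # per-user inclusion probability under the generative model
  q <- 0.2 * (1 - (1 - p_emit) * (1 - 0.2 * 0.01))
  p_user <- 1 - exp(-3 * q)
  expect_lt(abs(n_hit - 1000 * p_user), 3 * sqrt(1000 * p_user * (1 - p_user)))
})

test_that("expected PRR is exactly 1 for an exchangeable two-drug configuration", {
  cfg <- gen_config(
    n_users = 100,
    drugs = tibble::tibble(drug_id = c("a", "b"),
                           role = c("target", "comparison"),
                           mention_prob = 0.1, brand = NA_character_),
    background_emission = 0.05, seed = 1)
  for (g in default_target_groups()) {
    expect_equal(expected_prr(cfg, "a", g), 1.0, tolerance = 1e-12)
  }
})

test_that("expected PRR rises strictly with the planted emission rate", {
  # strict monotonicity holds over the operating range of emission rates;
  # at extreme rates the planted pair also inflates the drug's any-reaction
  # denominator and the unique-user expectation saturates
  prrs <- purrr::map_dbl(c(0.02, 0.05, 0.1, 0.2), function(p) {
    cfg <- gen_config(
      planted = tibble::tibble(drug_id = "erlotinib",
                               group_id = "hypohidrosis",
                               emission_prob = p), seed = 1)
    expected_prr(cfg, "erlotinib", "hypohidrosis")
  })
  expect_true(all(diff(prrs) > 0))
})

test_that("gold-bypass user counts equal brute-force enumeration of the bundle", {
  b <- generate_corpus(gen_config(n_users = 300, seed = 5))
  comp <- b$config$drugs$drug_id[b$config$drugs$role == "comparison"]
  cts <- aggregate_counts(b$pairs, "erlotinib", comp,
                          groups = default_target_groups())
  for (g in default_target_groups()) {
    row <- cts[cts$group_id == g, ]
    expect_equal(row$n_dr, length(unique(
      b$pairs$user_id[b$pairs$drug_id == "erlotinib" &
                        b$pairs$group_id == g])))
    expect_equal(row$n_notd_r, length(unique(
      b$pairs$user_id[b$pairs$drug_id %in% comp & b$pairs$group_id == g])))
  }
  expect_equal(cts$n_d[1], length(unique(
    b$pairs$user_id[b$pairs$drug_id == "erlotinib"])))
  expect_equal(cts$n_notd[1], length(unique(
    b$pairs$user_id[b$pairs$drug_id != "erlotinib"])))
})

test_that("lexicon fixture files round-trip through the normalizer", {
  dir <- tempfile("lexfix")
  fx <- generate_lexicon_fixture(dir)
  expect_true(all(file.exists(unlist(fx$paths))))
  lex <- read_lexicon(fx$paths$lexicon)
  expect_equal(nrow(lex), nrow(fx$lexicon))
  idx <- build_concept_index(lex)
  hit <- normalize_mention("nail peeling", idx)
  expect_equal(hit$concept_id, "C0263531")
  # one-group minimal fixture is still valid
  fx1 <- generate_lexicon_fixture(tempfile("lex1"),
                                  groups = default_group_specs()[1])
  expect_gte(nrow(fx1$lexicon), 1L)
  expect_equal(unique(fx1$lexicon$group_id), "rash")
})

test_that("invalid generator probabilities are rejected", {
  expect_error(gen_config(background_emission = 1.2),
               class = "adrsignal_invalid_probability")
  expect_error(gen_config(colloquial_rate = -0.1),
               class = "adrsignal_invalid_probability")
  expect_error(gen_config(posts_per_user_mean = 0),
               class = "adrsignal_bad_argument")
})
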