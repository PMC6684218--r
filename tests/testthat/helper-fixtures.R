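# Small in-code fixtures shared across the suite.

tiny_posts <- function() {
  tibble::tibble(
    post_id = c("p1", "p2", "p3", "p4", "p5", "p6", "p7", "p8", "p9", "p10"),
    user_id = c("u1", "u1", "u2", "u3", "u4", "u5", "u6", "u7", "u8", "u9"),
    created_at = as.Date("2010-01-01") + seq(0, 90, by = 10),
    body = c(
      "Started Tarceva today and feeling nervous.",
      "the rash is getting worse every day.",
      "erlotinib gave me a bad rash on my face.",
      "hope everyone is doing well this week.",
      "my doctor put me on erlotinib after the scan.",
      "nothing about drugs here at all.",
      "erlotinibx is not a real drug name.",
      "tarceva then more tarceva discussion.",
      "we are staying positive.",
      "metformin works fine for me."
    )
  )
}

write_tiny_posts_jsonl <- function(path = tempfile(fileext = ".jsonl")) {
  write_posts(tiny_posts(), path, format = "jsonl")
  path
}

small_lexicon_index <- local({
  idx <- NULL
  function() {
    if (is.null(idx)) {
      fx <- generate_lexicon_fixture(tempfile("lex"))
      idx <<- build_concept_index(fx$lexicon)
    }
    idx
  }
})

# deterministic tiny tagging setup reused by tagger tests
tiny_ner_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- gen_config(
        n_users = 120, posts_per_user_mean = 2,
        drugs = tibble::tibble(
          drug_id = c("erlotinib", "metformin", "lisinopril"),
          role = c("target", "comparison", "comparison"),
          mention_prob = 0.4, brand = c("Tarceva", NA, NA)),
        background_emission = 0.15, indication_rate = 0.3, seed = 13)
      cache <<- generate_corpus(cfg)
    }
    cache
  }
})
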