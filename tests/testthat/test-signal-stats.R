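pair_rec <- function(drug, group, user, post = NULL, date = "2010-06-01") {
  if (is.null(post)) post <- paste0("p", seq_along(drug))
  tibble::tibble(drug_id = drug, group_id = group, user_id = user,
                 post_id = post, date = as.Date(date))
}

test_that("contingency counts deduplicate by user and match brute-force enumeration", {
  # one user posting the same pair three times counts once
  rec <- pair_rec(rep("d1", 3), rep("rash", 3), rep("u1", 3),
                  post = c("a", "b", "c"))
  cts <- aggregate_counts(rec, "d1", comparison_drugs = "d2")
  expect_equal(cts$n_dr, 1L)
  expect_equal(cts$n_d, 1L)
  expect_equal(cts$n_notd_r, 0L)
  expect_equal(cts$n_notd, 0L)

  # 12-record fixture across 3 drugs vs exhaustive set-cardinality oracle
  rec <- pair_rec(
    drug = c("d1", "d1", "d1", "d1", "d2", "d2", "d2", "d3", "d3", "d1",
             "d2", "d3"),
    group = c("rash", "rash", "acne", "rash", "rash", "acne", "rash", "rash",
              "acne", "acne", "rash", "rash"),
    user = c("u1", "u2", "u1", "u2", "u3", "u1", "u4", "u5", "u2", "u6",
             "u1", "u1")
  )
  cts <- aggregate_counts(rec, "d1", comparison_drugs = c("d2", "d3"),
                          groups = c("rash", "acne"))
  oracle <- function(g) {
    list(
      n_dr = length(unique(rec$user_id[rec$drug_id == "d1" &
                                         rec$group_id == g])),
      n_d = length(unique(rec$user_id[rec$drug_id == "d1"])),
      n_notd_r = length(unique(rec$user_id[rec$drug_id %in% c("d2", "d3") &
                                             rec$group_id == g])),
      n_notd = length(unique(rec$user_id[rec$drug_id != "d1"]))
    )
  }
  for (g in c("rash", "acne")) {
    o <- oracle(g)
    row <- cts[cts$group_id == g, ]
    expect_equal(row$n_dr, o$n_dr)
    expect_equal(row$n_d, o$n_d)
    expect_equal(row$n_notd_r, o$n_notd_r)
    expect_equal(row$n_notd, o$n_notd)
  }
  expect_error(aggregate_counts(rec, "d1", comparison_drugs = c("d1", "d2")),
               class = "adrsignal_overlapping_sets")
})

test_that("PRR follows the printed formula with its degenerate-case conventions", {
  cts <- tibble::tibble(n_dr = c(10L, 20L, 5L, 0L),
                        n_d = c(100L, 50L, 50L, 50L),
                        n_notd_r = c(10L, 30L, 0L, 0L),
                        n_notd = c(100L, 300L, 300L, 300L))
  prr <- compute_prr(cts)$prr
  expect_equal(prr[1], 1.0)       # symmetric table
  expect_equal(prr[2], 4.0)       # (20/50)/(30/300)
  expect_identical(prr[3], Inf)   # zero comparator with cases
  expect_equal(prr[4], 0)         # no cases
  expect_error(compute_prr(tibble::tibble(n_dr = 0L, n_d = 0L,
                                          n_notd_r = 1L, n_notd = 10L)),
               class = "adrsignal_undefined_prr")
  expect_error(compute_prr(tibble::tibble(n_dr = 5L, n_d = 3L,
                                          n_notd_r = 1L, n_notd = 10L)),
               class = "adrsignal_invalid_counts")
  # Haldane correction resolves the zero comparator finitely
  h <- compute_prr(cts[3, ], haldane = TRUE)$prr
  expect_true(is.finite(h))
  expect_equal(h, (5.5 / 50.5) / (0.5 / 300.5))
})

test_that("PRR strictly increases in n_dr with other counts fixed", {
  base <- tibble::tibble(n_dr = 1:40, n_d = 50L, n_notd_r = 7L, n_notd = 300L)
  prr <- compute_prr(base)$prr
  expect_true(all(diff(prr) > 0))
})

test_that("negative-control construction is product minus known minus manual", {
  ctl <- suppressMessages(build_negative_controls(
    c("d1", "d2"), c("g1", "g2"),
    known = tibble::tibble(drug_id = "d1", group_id = "g1", relation = "adr")))
  expect_equal(nrow(ctl), 3L)
  card <- attr(ctl, "cardinalities")
  expect_equal(unname(card), c(4L, 3L, 3L))

  expect_warning(suppressMessages(build_negative_controls(
    c("a", "b", "c"), c("x", "y", "z"),
    manual_exclusions = tidyr::expand_grid(drug_id = c("a", "b", "c"),
                                           group_id = c("x", "y", "z")) |>
      dplyr::mutate(reason = "syndromic"))),
    "empty")

  expect_error(suppressMessages(build_negative_controls(
    "d1", "g1",
    manual_exclusions = tibble::tibble(drug_id = "d9", group_id = "g1",
                                       reason = "coprescription"))),
    class = "adrsignal_bad_argument")
})

test_that("threshold calibration interpolates order statistics", {
  expect_equal(calibrate_threshold((1:100) / 100, percentile = 95), 0.9505)
  expect_equal(calibrate_threshold(rep(0.3, 25)), 0.3)
  expect_error(calibrate_threshold(c(0.1, 0.2, 0.3, 0.4), min_n = 10),
               class = "adrsignal_calibration_error")
  expect_warning(th <- calibrate_threshold(c((1:20) / 20, Inf)),
                 "infinite")
  expect_lte(th, 1)
  expect_error(suppressWarnings(calibrate_threshold(c(Inf, Inf))),
               class = "adrsignal_calibration_error")
  # the interpolated order statistic leaves at most one extra value above
  set.seed(5)
  for (i in 1:10) {
    x <- rexp(57)
    th <- calibrate_threshold(x, percentile = 95)
    expect_lte(mean(x > th), 0.05 + 1 / length(x))
  }
})

test_that("flagging uses strict inequality over both criteria", {
  res <- tibble::tibble(drug_id = "d", group_id = c("a", "b", "c"),
                        prr = c(1.90, 1.0, 0.5))
  fl <- flag_signals(res, threshold = 0.82)
  expect_equal(fl$flagged, c(TRUE, FALSE, FALSE))
  expect_equal(fl$flagged_fixed, c(TRUE, FALSE, FALSE))
  expect_equal(fl$flagged_calibrated, c(TRUE, TRUE, FALSE))
  expect_error(flag_signals(res, threshold = Inf),
               class = "adrsignal_bad_argument")
  g <- glance(fl)
  expect_equal(g$n_flagged, 1L)
  expect_equal(g$n_pairs, 3L)
})

test_that("pair records join corpus posts with normalized mentions", {
  posts <- tiny_posts()
  corpus <- build_drug_corpus(posts,
                              compile_drug_matcher(c("erlotinib", "tarceva")),
                              "erlotinib")
  spans <- tibble::tibble(
    post_id = c("p1", "p3", "p4"),   # p4 not in the drug corpus
    char_start = 0L, char_end = 4L, label = "ADR",
    surface = "rash", concept_id = "C0015230", concept_name = "Rash",
    group_id = "rash", norm_score = 1
  )
  rec <- extract_pair_records(corpus, spans)
  expect_setequal(rec$post_id, c("p1", "p3"))
  path <- tempfile(fileext = ".tsv")
  write_pair_records(rec, path)
  expect_equal(read_pair_records(path), rec)
  expect_true(all(rec$drug_id == "erlotinib"))
  expect_equal(rec$date, posts$created_at[match(rec$post_id, posts$post_id)])
})
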