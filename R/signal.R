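#' Build drug–ADR pair records from a corpus and normalized mentions
#'
#' Joins a per-drug corpus with the normalized ADR mentions found in its
#' posts: one record per (post, ADR group), carrying the posting user and
#' date. A post mentioning several drugs contributes a record to every drug
#' corpus it belongs to.
#'
#' @param corpus A `drug_corpus` (posts with `drug_id`).
#' @param spans Normalized span tibble from [normalize_mentions()] (needs
#'   `post_id`, `group_id`); rows with `NA` `group_id` are dropped.
#' @return Pair-record tibble: `drug_id`, `group_id`, `user_id`, `post_id`,
#'   `date`.
#' @export
extract_pair_records <- function(corpus, spans) {
  hits <- spans |>
    dplyr::filter(!is.na(.data$group_id)) |>
    dplyr::distinct(.data$post_id, .data$group_id)
  corpus |>
    tibble::as_tibble() |>
    dplyr::inner_join(hits, by = "post_id") |>
    dplyr::transmute(drug_id = .data$drug_id, group_id = .data$group_id,
                     user_id = .data$user_id, post_id = .data$post_id,
                     date = .data$created_at)
}

#' Aggregate unique-user contingency counts for a drug
#'
#' For drug `D` and each reaction group `R`, computes the four counts of the
#' proportional reporting ratio from pair records, deduplicating by user:
#' `n_dr` unique users reporting both `D` and `R`; `n_d` unique users
#' reporting any reaction group with `D`; `n_notd_r` unique users reporting
#' `R` with a comparison drug (excluding `D`); `n_notd` unique users
#' reporting at least one reaction with any drug except `D`.
#'
#' @param records Pair-record tibble covering all drugs and all extracted
#'   reaction groups (see [extract_pair_records()]).
#' @param drug Target drug (or drug-class) id `D`.
#' @param comparison_drugs Character vector of comparison drug ids; must not
#'   contain `drug`.
#' @param groups Reaction groups to report; default all groups seen with
#'   `drug`.
#' @return Tibble with one row per group: `drug_id`, `group_id`, `n_dr`,
#'   `n_d`, `n_notd_r`, `n_notd`.
#' @export
aggregate_counts <- function(records, drug, comparison_drugs, groups = NULL) {
  if (drug %in% comparison_drugs) {
    stop_adr(sprintf("Target drug `%s` must not be in the comparison set.",
                     drug),
             "adrsignal_overlapping_sets")
  }
  d_rec <- records[records$drug_id == drug, ]
  groups <- groups %||% sort(unique(d_rec$group_id))
  comp_rec <- records[records$drug_id %in% comparison_drugs, ]
  n_d <- dplyr::n_distinct(d_rec$user_id)
  n_notd <- dplyr::n_distinct(records$user_id[records$drug_id != drug])
  purrr::map(groups, function(g) {
    tibble::tibble(
      drug_id = drug, group_id = g,
      n_dr = dplyr::n_distinct(d_rec$user_id[d_rec$group_id == g]),
      n_d = n_d,
      n_notd_r = dplyr::n_distinct(comp_rec$user_id[comp_rec$group_id == g]),
      n_notd = n_notd
    )
  }) |> dplyr::bind_rows()
}

#' Compute the proportional reporting ratio
#'
#' `PRR = (n_dr / n_d) / (n_notd_r / n_notd)`: the proportion of a drug's
#' reporting users that report the reaction, relative to the same proportion
#' among comparison drugs. Degenerate cases: a zero comparator
#' (`n_notd_r = 0`) with `n_dr > 0` yields `Inf` (reported, never silently
#' flagged); `n_dr = 0` yields 0; `n_d = 0` or `n_notd = 0` is an error
#' because the ratio is undefined. An optional Haldane-style continuity
#' correction adds 0.5 to all four counts (off by default; the uncorrected
#' formula is the reference behaviour).
#'
#' @param counts Contingency tibble from [aggregate_counts()] (columns `n_dr`,
#'   `n_d`, `n_notd_r`, `n_notd`).
#' @param haldane Apply the +0.5 continuity correction? Default `FALSE`.
#' @return `counts` with an added `prr` column.
#' @export
compute_prr <- function(counts, haldane = FALSE) {
  with(counts, {
    if (any(n_dr > n_d) || any(n_notd_r > n_notd) ||
        any(c(n_dr, n_d, n_notd_r, n_notd) < 0)) {
      stop_adr("Invalid contingency counts (need 0 <= n_dr <= n_d, 0 <= n_notd_r <= n_notd).",
               "adrsignal_invalid_counts")
    }
  })
  a <- counts$n_dr; b <- counts$n_d
  c_ <- counts$n_notd_r; d <- counts$n_notd
  if (isTRUE(haldane)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  if (any(b == 0) || any(d == 0)) {
    stop_adr("PRR undefined: n_d and n_notd must be positive.",
             "adrsignal_undefined_prr")
  }
  prr <- ifelse(a == 0, 0, ifelse(c_ == 0, Inf, (a / b) / (c_ / d)))
  dplyr::mutate(counts, prr = prr)
}

#' Construct the negative-control pair set
#'
#' Pairs every comparison drug with every target reaction group, then removes
#' pairs with a known association (adverse reaction or indication) and pairs
#' excluded by manual review for confounding (co-prescription or syndromic
#' co-occurrence). The three cardinalities — candidates, after known-pair
#' removal, final — are attached as the `"cardinalities"` attribute and
#' reported via message.
#'
#' @param comparison_drugs Character vector of comparison drug ids.
#' @param target_groups Character vector of reaction group ids.
#' @param known Known-association tibble: `drug_id`, `group_id`, `relation`
#'   (`"adr"` or `"indication"`).
#' @param manual_exclusions Optional tibble: `drug_id`, `group_id`, `reason`
#'   (`"coprescription"` or `"syndromic"`).
#' @return Tibble of control pairs (`drug_id`, `group_id`) with attribute
#'   `cardinalities` = c(candidates, after_known, final).
#' @export
build_negative_controls <- function(comparison_drugs, target_groups,
                                    known = NULL, manual_exclusions = NULL) {
  if (length(comparison_drugs) == 0 || length(target_groups) == 0) {
    stop_adr("Comparison drugs and target groups must be non-empty.",
             "adrsignal_bad_argument")
  }
  pairs <- tidyr::expand_grid(drug_id = unique(comparison_drugs),
                              group_id = unique(target_groups))
  n_cand <- nrow(pairs)
  if (!is.null(known) && nrow(known) > 0) {
    if (!all(known$relation %in% c("adr", "indication"))) {
      stop_adr("Known-association relation must be 'adr' or 'indication'.",
               "adrsignal_bad_argument")
    }
    pairs <- dplyr::anti_join(pairs, known, by = c("drug_id", "group_id"))
  }
  n_after_known <- nrow(pairs)
  if (!is.null(manual_exclusions) && nrow(manual_exclusions) > 0) {
    if (!all(manual_exclusions$reason %in% c("coprescription", "syndromic"))) {
      stop_adr("Manual-exclusion reason must be 'coprescription' or 'syndromic'.",
               "adrsignal_bad_argument")
    }
    full <- tidyr::expand_grid(drug_id = unique(comparison_drugs),
                               group_id = unique(target_groups))
    stray <- dplyr::anti_join(manual_exclusions, full,
                              by = c("drug_id", "group_id"))
    if (nrow(stray) > 0) {
      stop_adr(sprintf("Manual exclusion (%s, %s) is not a candidate pair.",
                       stray$drug_id[1], stray$group_id[1]),
               "adrsignal_bad_argument")
    }
    pairs <- dplyr::anti_join(pairs, manual_exclusions,
                              by = c("drug_id", "group_id"))
  }
  n_final <- nrow(pairs)
  if (n_final == 0) {
    rlang::warn("All candidate pairs were excluded; negative-control set is empty.")
  }
  rlang::inform(sprintf(
    "Negative controls: %d candidate pairs, %d after known-association removal, %d final.",
    n_cand, n_after_known, n_final))
  attr(pairs, "cardinalities") <- c(candidates = n_cand,
                                    after_known = n_after_known,
                                    final = n_final)
  pairs
}

#' Calibrate the signal threshold from negative-control PRRs
#'
#' Returns the empirical `percentile`-th percentile (linear interpolation
#' between closest order statistics) of the finite control PRR values, so
#' that close to `percentile`% of control values lie at or below the
#' threshold (interpolation can leave at most one value more than the
#' nominal fraction above it). Infinite values are excluded with a warning.
#'
#' @param control_prrs Numeric vector of PRR values for negative-control
#'   pairs.
#' @param percentile Percentile in (0, 100]; default 95.
#' @param min_n Minimum number of finite control values required (default 10).
#' @return The calibrated threshold (scalar).
#' @export
calibrate_threshold <- function(control_prrs, percentile = 95, min_n = 10L) {
  finite <- control_prrs[is.finite(control_prrs)]
  if (length(finite) < length(control_prrs)) {
    rlang::warn(sprintf("%d infinite control PRR value(s) excluded from calibration.",
                        length(control_prrs) - length(finite)))
  }
  if (length(finite) == 0) {
    stop_adr("No finite control PRR values to calibrate on.",
             "adrsignal_calibration_error")
  }
  if (length(finite) < min_n) {
    stop_adr(sprintf("Need >= %d finite control PRR values, got %d.",
                     min_n, length(finite)),
             "adrsignal_calibration_error")
  }
  unname(stats::quantile(finite, probs = percentile / 100, type = 7))
}

#' Flag signals against calibrated and fixed thresholds
#'
#' A pair is flagged when its PRR strictly exceeds `max(threshold,
#' fixed_rule)`; both criteria are also recorded separately.
#'
#' @param results Tibble with a `prr` column (e.g. from [compute_prr()]).
#' @param threshold Calibrated threshold (finite).
#' @param fixed_rule Fixed-rule threshold; default 1.0 (the conventional
#'   PRR > 1 rule).
#' @return `results` with added columns `threshold`, `flagged_calibrated`,
#'   `flagged_fixed`, `flagged`, carrying class `adr_signal_tbl`.
#' @export
flag_signals <- function(results, threshold, fixed_rule = 1.0) {
  if (!is.finite(threshold)) {
    stop_adr("`threshold` must be finite.", "adrsignal_bad_argument")
  }
  out <- results |>
    dplyr::mutate(
      threshold = threshold,
      flagged_calibrated = .data$prr > threshold,
      flagged_fixed = .data$prr > fixed_rule,
      flagged = .data$prr > max(threshold, fixed_rule)
    )
  class(out) <- c("adr_signal_tbl", class(tibble::tibble()))
  out
}
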