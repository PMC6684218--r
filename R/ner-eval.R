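#' Evaluate predicted entity spans against a gold standard
#'
#' Micro-averaged precision, recall and F-measure, pooling true/false
#' positives and false negatives over all posts. In `strict` mode a predicted
#' span is a true positive iff its `char_start`, `char_end` and `label` all
#' equal a gold span's; in `overlap` mode labels must match and spans must
#' share at least one character, with one-to-one greedy matching by descending
#' overlap length (ties by earlier gold start, then earlier predicted start).
#'
#' @param predicted,gold Span tibbles (`post_id`, `char_start`, `char_end`,
#'   `label`).
#' @param mode `"strict"` (default) or `"overlap"`.
#' @param post_ids Optional known post-id universe; spans referencing other
#'   posts raise an error.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_measure`.
#' @export
evaluate_ner <- function(predicted, gold, mode = c("strict", "overlap"),
                         post_ids = NULL) {
  mode <- match.arg(mode)
  if (!is.null(post_ids)) {
    bad <- setdiff(c(predicted$post_id, gold$post_id), post_ids)
    if (length(bad) > 0) {
      stop_adr(sprintf("Span references unknown post_id: %s", bad[1]),
               "adrsignal_unknown_post")
    }
  }
  tp <- 0L
  if (mode == "strict") {
    key <- function(d) paste(d$post_id, d$char_start, d$char_end, d$label,
                             sep = "\r")
    pk <- key(predicted); gk <- key(gold)
    # multiset intersection
    tp <- sum(pmin(table(factor(pk, levels = unique(c(pk, gk)))),
                   table(factor(gk, levels = unique(c(pk, gk))))))
  } else {
    if (nrow(predicted) > 0 && nrow(gold) > 0) {
      cand <- dplyr::inner_join(
        dplyr::mutate(predicted, .p = dplyr::row_number()),
        dplyr::mutate(gold, .g = dplyr::row_number()),
        by = c("post_id", "label"), suffix = c("_p", "_g"),
        relationship = "many-to-many"
      ) |>
        dplyr::mutate(overlap = pmin(.data$char_end_p, .data$char_end_g) -
                        pmax(.data$char_start_p, .data$char_start_g)) |>
        dplyr::filter(.data$overlap > 0) |>
        dplyr::arrange(dplyr::desc(.data$overlap), .data$char_start_g,
                       .data$char_start_p)
      used_p <- logical(nrow(predicted)); used_g <- logical(nrow(gold))
      for (i in seq_len(nrow(cand))) {
        p <- cand$.p[i]; g <- cand$.g[i]
        if (!used_p[p] && !used_g[g]) {
          used_p[p] <- TRUE; used_g[g] <- TRUE; tp <- tp + 1L
        }
      }
    }
  }
  fp <- nrow(predicted) - tp
  fn <- nrow(gold) - tp
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble::tibble(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), precision = precision, recall = recall,
                 f_measure = f)
}

#' Inter-annotator agreement as micro-averaged F
#'
#' Treats annotator B's spans as the gold standard and scores annotator A's
#' against them.
#'
#' @param annotations_a,annotations_b Span tibbles over the same posts.
#' @inheritParams evaluate_ner
#' @return The micro-averaged F-measure (scalar).
#' @export
annotator_agreement <- function(annotations_a, annotations_b,
                                mode = c("strict", "overlap")) {
  evaluate_ner(annotations_a, annotations_b, mode = mode)$f_measure
}
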