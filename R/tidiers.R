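#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   geom_step geom_vline geom_histogram labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Tidy a flagged signal table
#'
#' @param x An `adr_signal_tbl` from [flag_signals()].
#' @param ... Unused.
#' @return A plain tibble, one row per drug–reaction pair.
#' @export
tidy.adr_signal_tbl <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summarise a flagged signal table
#'
#' @param x An `adr_signal_tbl`.
#' @param ... Unused.
#' @return One-row tibble: `n_pairs`, `n_flagged`, `n_flagged_fixed`,
#'   `threshold`, `max_prr`.
#' @export
glance.adr_signal_tbl <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_flagged = sum(x$flagged),
    n_flagged_fixed = sum(x$flagged_fixed),
    threshold = x$threshold[1] %||% NA_real_,
    max_prr = if (nrow(x)) max(x$prr) else NA_real_
  )
}

#' Tidy a trained tagger
#'
#' @param x An `adr_tagger`.
#' @param ... Unused.
#' @return Tibble of per-epoch mean training loss.
#' @export
tidy.adr_tagger <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' Summarise a trained tagger
#'
#' @param x An `adr_tagger`.
#' @param ... Unused.
#' @return One-row tibble with architecture and final loss.
#' @export
glance.adr_tagger <- function(x, ...) {
  tibble::tibble(
    window = x$window, hidden = x$hidden, epochs = x$epochs,
    n_parameters = length(x$W1) + length(x$b1) + length(x$W2) + length(x$b2),
    final_loss = utils::tail(x$loss_history, 1),
    seed = x$seed
  )
}

#' Plot a flagged signal table
#'
#' PRR per drug–reaction pair with the calibrated threshold and the fixed
#' PRR = 1 rule drawn as horizontal lines; flagged pairs highlighted.
#'
#' @param object An `adr_signal_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adr_signal_tbl <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$pair <- paste(d$drug_id, d$group_id, sep = " × ")
  d$prr_plot <- ifelse(is.finite(d$prr), d$prr, NA_real_)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$pair, .data$prr_plot),
                                  y = .data$prr_plot,
                                  fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = d$threshold[1], linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "proportional reporting ratio",
                  fill = "flagged") +
    ggplot2::theme_minimal()
}

#' Plot the negative-control PRR distribution with the calibrated threshold
#'
#' @param control_prrs Numeric vector of control PRR values.
#' @param threshold Calibrated threshold to mark.
#' @param bins Histogram bins (default 30).
#' @return A ggplot object.
#' @export
plot_control_distribution <- function(control_prrs, threshold = NULL,
                                      bins = 30) {
  d <- tibble::tibble(prr = control_prrs[is.finite(control_prrs)])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$prr)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60", colour = "white") +
    ggplot2::labs(x = "negative-control PRR", y = "pairs") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot a cumulative post-count detection curve
#'
#' Step curve of cumulative forum posts for a drug–reaction pair, with
#' optional vertical markers at literature publication dates.
#'
#' @param series Tibble from [cumulative_series()].
#' @param literature_dates Optional `Date` vector of publication dates.
#' @return A ggplot object.
#' @export
plot_cumulative_series <- function(series, literature_dates = NULL) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$date,
                                            y = .data$cumulative_count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = NULL, y = "cumulative post count") +
    ggplot2::theme_minimal()
  if (!is.null(literature_dates)) {
    p <- p + ggplot2::geom_vline(xintercept = as.Date(literature_dates),
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}
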