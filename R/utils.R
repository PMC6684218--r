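#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   distinct bind_rows left_join anti_join semi_join n n_distinct across
#'   row_number rename relocate pull first
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap walk
#' @importFrom stats quantile rbinom rpois runif setNames
#' @importFrom utils head tail
NULL

# Internal: stop with a classed condition so callers can test error classes.
stop_adr <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "adrsignal_error"), ...)
}

# Internal: check a probability (scalar or vector) lies in [0, 1].
check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_adr(
      sprintf("`%s` must be numeric in [0, 1].", name),
      "adrsignal_invalid_probability"
    )
  }
  invisible(x)
}
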