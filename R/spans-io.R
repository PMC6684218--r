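#' Read / write entity spans in standoff format
#'
#' Tab-separated with header `post_id`, `char_start`, `char_end`, `label`,
#' `surface` (one span per line; offsets half-open, 0-based). Used for
#' training data, gold test sets and predictions alike.
#'
#' @param path File path.
#' @return `read_spans()` returns the span tibble; `write_spans()` returns
#'   `path` invisibly.
#' @export
read_spans <- function(path) {
  sp <- readr::read_tsv(path, col_types = "ciicc", progress = FALSE)
  if (!all(sp$label %in% c("ADR", "IND"))) {
    stop_adr("Span labels must be ADR or IND.", "adrsignal_record_error")
  }
  if (any(sp$char_start >= sp$char_end)) {
    stop_adr("Spans must satisfy char_start < char_end.",
             "adrsignal_record_error")
  }
  sp
}

#' @param spans Span tibble.
#' @rdname read_spans
#' @export
write_spans <- function(spans, path) {
  readr::write_tsv(
    spans[c("post_id", "char_start", "char_end", "label", "surface")],
    path, progress = FALSE)
  invisible(path)
}

#' Read a known drug–condition association table
#'
#' Tab-separated with header `drug_id`, `group_id`, `relation` (`adr` or
#' `indication`); a stand-in for licensed adverse-effect/side-effect
#' resources.
#'
#' @param path File path.
#' @return Tibble of known associations.
#' @export
read_known_associations <- function(path) {
  k <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  if (!all(k$relation %in% c("adr", "indication"))) {
    stop_adr("Known-association relation must be 'adr' or 'indication'.",
             "adrsignal_record_error")
  }
  dplyr::distinct(k)
}

#' Read a manual negative-control exclusion list
#'
#' Tab-separated with header `drug_id`, `group_id`, `reason`
#' (`coprescription` or `syndromic`).
#'
#' @param path File path.
#' @return Tibble of exclusions.
#' @export
read_manual_exclusions <- function(path) {
  x <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  if (!all(x$reason %in% c("coprescription", "syndromic"))) {
    stop_adr("Exclusion reason must be 'coprescription' or 'syndromic'.",
             "adrsignal_record_error")
  }
  x
}

#' Read / write drug–reaction pair records
#'
#' Tab-separated with header `drug_id`, `group_id`, `user_id`, `post_id`,
#' `date` (ISO day precision).
#'
#' @param path File path.
#' @return `read_pair_records()` returns the pair-record tibble;
#'   `write_pair_records()` returns `path` invisibly.
#' @export
read_pair_records <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    drug_id = "c", group_id = "c", user_id = "c", post_id = "c",
    date = readr::col_date()), progress = FALSE)
}

#' @param records Pair-record tibble.
#' @rdname read_pair_records
#' @export
write_pair_records <- function(records, path) {
  readr::write_tsv(
    records[c("drug_id", "group_id", "user_id", "post_id", "date")],
    path, progress = FALSE)
  invisible(path)
}
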