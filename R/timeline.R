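#' First forum report date for a drug–reaction pair
#'
#' @param records Pair-record tibble (`drug_id`, `group_id`, `date`).
#' @param drug,group Pair to look up.
#' @return The earliest matching `Date`, or `NA` (length-1 Date) when the pair
#'   has no records.
#' @export
first_report_date <- function(records, drug, group) {
  d <- records$date[records$drug_id == drug & records$group_id == group]
  if (length(d) == 0) return(as.Date(NA))
  min(as.Date(d))
}

#' Cumulative post-count series for a drug–reaction pair
#'
#' One point per distinct posting date; the count at date `d` is the number
#' of matching records on or before `d`, so the series is non-decreasing and
#' ends at the total record count.
#'
#' @inheritParams first_report_date
#' @return Tibble `date`, `cumulative_count` with strictly ascending dates.
#' @export
cumulative_series <- function(records, drug, group) {
  d <- sort(as.Date(records$date[records$drug_id == drug &
                                   records$group_id == group]))
  if (length(d) == 0) {
    return(tibble::tibble(date = as.Date(character()),
                          cumulative_count = integer()))
  }
  tab <- table(d)
  tibble::tibble(date = as.Date(names(tab)),
                 cumulative_count = as.integer(cumsum(tab)))
}

#' Lead time in whole months between a forum report and the literature
#'
#' Computed on (year, month) only, days ignored: `literature - first_post`,
#' positive when the forum report precedes the literature report.
#'
#' @param first_post First forum report date (`Date` or `"YYYY-MM"` /
#'   `"YYYY-MM-DD"` string).
#' @param literature Literature publication date, same forms.
#' @return Integer month difference (vectorized).
#' @export
lead_time_months <- function(first_post, literature) {
  ym <- function(x) {
    if (inherits(x, "Date")) {
      as.integer(format(x, "%Y")) * 12L + as.integer(format(x, "%m"))
    } else {
      parts <- stringr::str_match(as.character(x),
                                  "^(\\d{4})-(\\d{2})(?:-\\d{2})?$")
      if (anyNA(parts[, 1])) {
        stop_adr("Dates must be Date or 'YYYY-MM'/'YYYY-MM-DD' strings.",
                 "adrsignal_bad_argument")
      }
      as.integer(parts[, 2]) * 12L + as.integer(parts[, 3])
    }
  }
  ym(literature) - ym(first_post)
}

#' Read literature events
#'
#' Tab-separated with header `drug_id`, `group_id`, `date` (`YYYY-MM`),
#' `citation`, `type` (`case_report`, `case_series` or `trial`).
#'
#' @param path File path.
#' @return Tibble of literature events.
#' @export
read_literature_events <- function(path) {
  ev <- readr::read_tsv(path, col_types = "ccccc", progress = FALSE)
  if (!all(grepl("^\\d{4}-\\d{2}$", ev$date))) {
    stop_adr("Literature event dates must be YYYY-MM.", "adrsignal_record_error")
  }
  if (!all(ev$type %in% c("case_report", "case_series", "trial"))) {
    stop_adr("Literature event type must be case_report, case_series or trial.",
             "adrsignal_record_error")
  }
  ev
}

#' Time-to-detection summary against literature events
#'
#' For each literature event, computes the first forum report date of the
#' pair and the lead time in whole months (positive when the forum report
#' precedes the publication). The earliest literature event per pair is used
#' as the reference.
#'
#' @param records Pair-record tibble.
#' @param literature Literature-event tibble (see [read_literature_events()]).
#' @return Tibble `drug_id`, `group_id`, `first_post`, `first_literature`,
#'   `lead_months` (NA when the pair has no forum records).
#' @export
detection_leads <- function(records, literature) {
  literature |>
    dplyr::group_by(.data$drug_id, .data$group_id) |>
    dplyr::summarise(first_literature = min(.data$date), .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::mutate(
      first_post = first_report_date(records, .data$drug_id, .data$group_id),
      lead_months = if (is.na(.data$first_post)) NA_integer_ else
        lead_time_months(.data$first_post, .data$first_literature)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("drug_id", "group_id", "first_post", "first_literature",
                  "lead_months")
}
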