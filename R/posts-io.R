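#' Read forum posts from JSON-lines or TSV
#'
#' A post record carries a unique `post_id`, the `user_id` of its author, a
#' day-precision `created_at` date, and the free-text `body`. The JSONL dialect
#' has one JSON object per line; the TSV dialect has a header row with the same
#' four field names.
#'
#' @param path Path to the posts file.
#' @param format `"jsonl"` or `"tsv"`. Defaults from the file extension
#'   (`.jsonl`/`.json` vs anything else).
#' @param date_range Length-2 `Date` (or coercible) vector; posts outside the
#'   range are rejected with a record-level error. Default 2000-01-01 to the
#'   current date.
#' @return A tibble with columns `post_id`, `user_id`, `created_at` (`Date`),
#'   `body`, in file order.
#' @export
read_posts <- function(path, format = NULL,
                       date_range = c(as.Date("2000-01-01"), Sys.Date())) {
  if (!file.exists(path)) {
    stop_adr(sprintf("Posts file not found: %s", path), "adrsignal_io_error")
  }
  format <- format %||%
    (if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "tsv")
  format <- match.arg(format, c("jsonl", "tsv"))

  required <- c("post_id", "user_id", "created_at", "body")
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines))
    recs <- purrr::imap(lines[keep], function(line, i) {
      rec <- tryCatch(
        jsonlite::fromJSON(line, simplifyVector = TRUE),
        error = function(e) stop_adr(
          sprintf("Line %d: malformed JSON record.", which(keep)[i]),
          "adrsignal_record_error"
        )
      )
      rec
    })
    lineno <- which(keep)
    df <- tibble::tibble(
      post_id    = purrr::map(recs, "post_id"),
      user_id    = purrr::map(recs, "user_id"),
      created_at = purrr::map(recs, "created_at"),
      body       = purrr::map(recs, "body"),
      .line      = lineno
    )
    for (fld in required) {
      bad <- purrr::map_lgl(df[[fld]], ~ is.null(.x) || !nzchar(as.character(.x)[1]))
      if (any(bad)) {
        stop_adr(
          sprintf("Line %d: missing required field `%s`.",
                  df$.line[which(bad)[1]], fld),
          "adrsignal_record_error"
        )
      }
    }
    posts <- tibble::tibble(
      post_id    = purrr::map_chr(df$post_id, ~ as.character(.x)[1]),
      user_id    = purrr::map_chr(df$user_id, ~ as.character(.x)[1]),
      created_at = purrr::map_chr(df$created_at, ~ as.character(.x)[1]),
      body       = purrr::map_chr(df$body, ~ as.character(.x)[1]),
      .line      = df$.line
    )
  } else {
    posts <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                             progress = FALSE)
    missing_cols <- setdiff(required, names(posts))
    if (length(missing_cols) > 0) {
      stop_adr(sprintf("TSV posts file lacks column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "adrsignal_record_error")
    }
    posts$.line <- seq_len(nrow(posts)) + 1L  # header is line 1
    for (fld in required) {
      bad <- is.na(posts[[fld]]) | !nzchar(posts[[fld]])
      if (any(bad)) {
        stop_adr(sprintf("Line %d: missing required field `%s`.",
                         posts$.line[which(bad)[1]], fld),
                 "adrsignal_record_error")
      }
    }
  }

  dates <- as.Date(posts$created_at, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop_adr(sprintf("Line %d: unparseable date `%s` (expected YYYY-MM-DD).",
                     posts$.line[which(is.na(dates))[1]],
                     posts$created_at[which(is.na(dates))[1]]),
             "adrsignal_record_error")
  }
  date_range <- as.Date(date_range)
  out_of_range <- dates < date_range[1] | dates > date_range[2]
  if (any(out_of_range)) {
    stop_adr(sprintf("Line %d: date %s outside allowed range [%s, %s].",
                     posts$.line[which(out_of_range)[1]],
                     dates[which(out_of_range)[1]],
                     date_range[1], date_range[2]),
             "adrsignal_record_error")
  }
  if (anyDuplicated(posts$post_id)) {
    dup <- posts$post_id[duplicated(posts$post_id)][1]
    stop_adr(sprintf("Duplicate post_id `%s`.", dup), "adrsignal_record_error")
  }

  tibble::tibble(
    post_id = posts$post_id, user_id = posts$user_id,
    created_at = dates, body = posts$body
  )
}

#' Write forum posts
#'
#' @param posts Tibble with `post_id`, `user_id`, `created_at`, `body`.
#' @param path Output path.
#' @param format `"jsonl"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- purrr::pmap_chr(
      posts[c("post_id", "user_id", "created_at", "body")],
      function(post_id, user_id, created_at, body) {
        jsonlite::toJSON(
          list(post_id = post_id, user_id = user_id,
               created_at = format(created_at, "%Y-%m-%d"), body = body),
          auto_unbox = TRUE
        )
      }
    )
    writeLines(lines, path)
  } else {
    out <- posts
    out$created_at <- format(out$created_at, "%Y-%m-%d")
    readr::write_tsv(out[c("post_id", "user_id", "created_at", "body")], path,
                     progress = FALSE)
  }
  invisible(path)
}

#' Read a drug alias table
#'
#' Two-column tab-separated file (`drug_id`, `alias`), one alias per line, no
#' header. Aliases are lowercased at load; every drug must have at least one
#' non-empty alias.
#'
#' @param path Path to the alias file.
#' @return A tibble with columns `drug_id`, `alias` (lowercase).
#' @export
read_drug_aliases <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("drug_id", "alias"),
                         col_types = "cc", progress = FALSE)
  if (nrow(tab) == 0 || anyNA(tab$alias) || any(!nzchar(trimws(tab$alias)))) {
    stop_adr("Alias table must give every drug >= 1 non-empty alias.",
             "adrsignal_record_error")
  }
  tab$alias <- tolower(trimws(tab$alias))
  dplyr::distinct(tab)
}
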