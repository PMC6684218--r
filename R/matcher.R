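#' Compile a drug-name matcher
#'
#' Builds a regular-expression matcher for a set of drug aliases (generic and
#' brand names). Matching is exact-string at alphanumeric word boundaries, so
#' `"erlotinib"` does not match inside `"erlotinibx"`, and is case-insensitive
#' by default. Longer aliases take precedence when one alias is a prefix of
#' another; occurrences are non-overlapping.
#'
#' @param aliases Character vector of surface strings (at least one non-empty).
#' @param case_sensitive Match case-sensitively? Default `FALSE`.
#' @return An object of class `drug_matcher`.
#' @export
compile_drug_matcher <- function(aliases, case_sensitive = FALSE) {
  aliases <- aliases[!is.na(aliases) & nzchar(trimws(aliases))]
  if (length(aliases) == 0) {
    stop_adr("At least one non-empty alias is required.",
             "adrsignal_empty_aliases")
  }
  aliases <- unique(trimws(aliases))
  # longest-first alternation so overlapping aliases resolve to the longer one
  ordered <- aliases[order(-nchar(aliases), aliases)]
  escaped <- stringr::str_replace_all(ordered, "([.\\\\+*?\\[\\]^$(){}=!<>|:#-])",
                                      "\\\\\\1")
  pattern <- paste0(
    "(?<![A-Za-z0-9])(?:", paste(escaped, collapse = "|"), ")(?![A-Za-z0-9])"
  )
  structure(
    list(aliases = ordered, pattern = pattern,
         case_sensitive = isTRUE(case_sensitive)),
    class = "drug_matcher"
  )
}

#' @export
print.drug_matcher <- function(x, ...) {
  cat("<drug_matcher> ", length(x$aliases), " alias(es): ",
      paste(utils::head(x$aliases, 5), collapse = ", "),
      if (length(x$aliases) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Find drug-alias matches in text
#'
#' @param matcher A `drug_matcher`.
#' @param text Character vector of post bodies.
#' @return A tibble with one row per match: `text_index`, `char_start`,
#'   `char_end` (half-open, 0-based offsets into the body), `surface`.
#' @export
match_drug <- function(matcher, text) {
  stopifnot(inherits(matcher, "drug_matcher"))
  pat <- stringr::regex(matcher$pattern,
                        ignore_case = !matcher$case_sensitive)
  loc <- stringr::str_locate_all(text, pat)
  purrr::imap(loc, function(m, i) {
    if (nrow(m) == 0) return(NULL)
    tibble::tibble(
      text_index = i,
      char_start = m[, "start"] - 1L,
      char_end   = m[, "end"],
      surface    = stringr::str_sub(text[i], m[, "start"], m[, "end"])
    )
  }) |>
    purrr::compact() |>
    dplyr::bind_rows() |>
    (function(d) if (nrow(d) == 0) {
      tibble::tibble(text_index = integer(), char_start = integer(),
                     char_end = integer(), surface = character())
    } else d)()
}

#' Build a per-drug corpus by keyword matching
#'
#' Retains exactly the posts whose body contains at least one alias match, and
#' records which alias matched (provenance).
#'
#' @param posts Posts tibble (see [read_posts()]).
#' @param matcher A `drug_matcher` from [compile_drug_matcher()].
#' @param drug_id Identifier attached to the corpus.
#' @return A tibble of the matching posts with columns of `posts` plus
#'   `drug_id` and `matched_alias` (first alias matched, lowercase), carrying
#'   class `drug_corpus`.
#' @export
build_drug_corpus <- function(posts, matcher, drug_id) {
  stopifnot(inherits(matcher, "drug_matcher"))
  hits <- match_drug(matcher, posts$body)
  if (nrow(hits) == 0) {
    out <- posts[0, , drop = FALSE]
    out$drug_id <- character()
    out$matched_alias <- character()
  } else {
    firsts <- hits |>
      dplyr::group_by(.data$text_index) |>
      dplyr::summarise(matched_alias = tolower(.data$surface[1]),
                       .groups = "drop")
    out <- posts[firsts$text_index, , drop = FALSE]
    out$drug_id <- drug_id
    out$matched_alias <- firsts$matched_alias
  }
  class(out) <- c("drug_corpus", class(tibble::tibble()))
  out
}

#' Merge per-drug corpora into a drug-class corpus
#'
#' Posts are deduplicated by `post_id` (a post mentioning several class members
#' counts once) and relabelled with `class_id`.
#'
#' @param corpora A list of corpora from [build_drug_corpus()].
#' @param class_id Identifier for the merged class.
#' @return A `drug_corpus` tibble with `drug_id` set to `class_id`.
#' @export
merge_corpora <- function(corpora, class_id) {
  if (length(corpora) == 0) {
    stop_adr("At least one corpus is required.", "adrsignal_empty_corpora")
  }
  merged <- dplyr::bind_rows(corpora) |>
    dplyr::distinct(.data$post_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$post_id)
  merged$drug_id <- rep(class_id, nrow(merged))
  class(merged) <- c("drug_corpus", class(tibble::tibble()))
  merged
}
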