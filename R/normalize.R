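#' Build a ranked-retrieval index over a lexicon
#'
#' Each lexicon entry becomes one index document keyed by the lemma bag of its
#' name (tokenized and lemmatized with [lemmatize()], the same preprocessing
#' applied to queries). Scoring is TF-IDF cosine; stop-words are retained but
#' naturally down-weighted by their low inverse document frequency. The index
#' is deterministic: documents are sorted internally by `(concept_id, name)`.
#'
#' @param lexicon Lexicon tibble (see [expand_lexicon()]); at least one entry.
#' @return A `concept_index` object.
#' @export
build_concept_index <- function(lexicon) {
  if (is.null(lexicon) || nrow(lexicon) == 0) {
    stop_adr("Cannot index an empty lexicon.", "adrsignal_empty_lexicon")
  }
  lexicon <- lexicon |>
    dplyr::distinct(.data$name, .data$concept_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$concept_id, .data$name)

  bags <- lemma_bags(lexicon$name)
  vocab <- sort(unique(unlist(purrr::map(bags, names))))
  n_doc <- nrow(lexicon)
  df <- table(factor(unlist(purrr::map(bags, names)), levels = vocab))
  idf <- log((n_doc + 1) / (as.numeric(df) + 1)) + 1
  names(idf) <- vocab

  mat <- matrix(0, nrow = n_doc, ncol = length(vocab),
                dimnames = list(NULL, vocab))
  for (i in seq_len(n_doc)) {
    b <- bags[[i]]
    if (length(b)) mat[i, names(b)] <- as.numeric(b) * idf[names(b)]
  }
  norms <- sqrt(rowSums(mat^2))
  norms[norms == 0] <- 1

  structure(
    list(entries = lexicon, vocab = vocab, idf = idf,
         doc_matrix = mat, doc_norms = norms, bags = bags),
    class = "concept_index"
  )
}

#' @export
print.concept_index <- function(x, ...) {
  cat("<concept_index> ", nrow(x$entries), " entries, ",
      length(x$vocab), " lemmas, ",
      dplyr::n_distinct(x$entries$group_id), " groups\n", sep = "")
  invisible(x)
}

# Internal: lemma count bags for a character vector of names/mentions.
lemma_bags <- function(texts) {
  toks <- tokenize_posts(as.character(texts))
  toks <- toks[grepl("^[A-Za-z0-9']+$", toks$surface), ]
  split_idx <- factor(toks$post_id, levels = as.character(seq_along(texts)))
  lapply(split(toks$lemma, split_idx), function(l) table(l))
}

#' Retrieve ranked concept candidates for a mention
#'
#' @param mention_text Character scalar, the mention surface text.
#' @param index A `concept_index`.
#' @param k Maximum number of candidates (default 5).
#' @return Tibble of up to `k` rows: `concept_id`, `name`, `group_id`,
#'   `score`, `rank`, sorted by descending score. Candidates must share at
#'   least one lemma with the query; ties are broken by larger lemma overlap,
#'   then lexicographic `concept_id`, then `name`.
#' @export
concept_candidates <- function(mention_text, index, k = 5L) {
  stopifnot(inherits(index, "concept_index"))
  empty <- tibble::tibble(concept_id = character(), name = character(),
                          group_id = character(), score = numeric(),
                          rank = integer())
  if (is.na(mention_text) || !nzchar(trimws(mention_text))) return(empty)
  qb <- lemma_bags(mention_text)[[1]]
  qb <- qb[names(qb) %in% index$vocab]
  if (length(qb) == 0) return(empty)

  qvec <- as.numeric(qb) * index$idf[names(qb)]
  qnorm <- sqrt(sum(qvec^2))
  scores <- as.numeric(index$doc_matrix[, names(qb), drop = FALSE] %*% qvec) /
    (index$doc_norms * qnorm)
  overlap <- purrr::map_int(index$bags, ~ length(intersect(names(.x), names(qb))))
  hit <- which(overlap > 0 & scores > 0)
  if (length(hit) == 0) return(empty)

  ord <- hit[order(-scores[hit], -overlap[hit],
                   index$entries$concept_id[hit], index$entries$name[hit])]
  ord <- utils::head(ord, k)
  tibble::tibble(
    concept_id = index$entries$concept_id[ord],
    name = index$entries$name[ord],
    group_id = index$entries$group_id[ord],
    score = scores[ord],
    rank = seq_along(ord)
  )
}

#' Normalize a mention to its top-ranked concept
#'
#' The mention is tokenized and lemmatized identically to the indexed names
#' and the rank-1 retrieval candidate is returned; no row is returned when no
#' entry shares an informative lemma with the mention.
#'
#' @inheritParams concept_candidates
#' @return A one-row tibble (`concept_id`, `name`, `group_id`, `score`,
#'   `rank`) or a zero-row tibble when nothing matches.
#' @export
normalize_mention <- function(mention_text, index, k = 5L) {
  utils::head(concept_candidates(mention_text, index, k), 1L)
}

#' Normalize a table of extracted mentions
#'
#' Maps each ADR-labelled span to its top concept; spans labelled as
#' indications are left unmapped by default (the pipeline normalizes ADR
#' mentions only).
#'
#' @param spans Tibble of entity spans (needs `surface`, `label`).
#' @param index A `concept_index`.
#' @param labels Labels to normalize (default `"ADR"`).
#' @return `spans` with added columns `concept_id`, `concept_name`,
#'   `group_id`, `norm_score` (`NA` where unmapped).
#' @export
normalize_mentions <- function(spans, index, labels = "ADR") {
  n <- nrow(spans)
  res <- tibble::tibble(concept_id = rep(NA_character_, n),
                        concept_name = rep(NA_character_, n),
                        group_id = rep(NA_character_, n),
                        norm_score = rep(NA_real_, n))
  todo <- which(spans$label %in% labels)
  # memoise per distinct surface: forum mentions repeat heavily
  uniq <- unique(spans$surface[todo])
  top <- purrr::map(uniq, normalize_mention, index = index)
  names(top) <- uniq
  for (i in todo) {
    hit <- top[[spans$surface[i]]]
    if (nrow(hit) == 1) {
      res$concept_id[i] <- hit$concept_id
      res$concept_name[i] <- hit$name
      res$group_id[i] <- hit$group_id
      res$norm_score[i] <- hit$score
    }
  }
  dplyr::bind_cols(spans, res)
}
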