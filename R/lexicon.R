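#' Read an ontology file
#'
#' Tab-separated with header `concept_id`, `preferred_name`, `synonyms`
#' (pipe-delimited, may be empty), `parents` (pipe-delimited concept ids, may
#' be empty). A lightweight stand-in for a licensed concept hierarchy: concept
#' ids are CUI-style strings and `parents` encodes the is-a relation.
#'
#' @param path Path to the ontology TSV.
#' @return A tibble with columns `concept_id`, `preferred_name`, `synonyms`
#'   (list of character), `parents` (list of character).
#' @export
read_ontology <- function(path) {
  raw <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  ont <- tibble::tibble(
    concept_id = raw$concept_id,
    preferred_name = raw$preferred_name,
    synonyms = strsplit(ifelse(is.na(raw$synonyms), "", raw$synonyms), "|",
                        fixed = TRUE),
    parents = strsplit(ifelse(is.na(raw$parents), "", raw$parents), "|",
                       fixed = TRUE)
  )
  validate_ontology(ont)
}

#' @noRd
validate_ontology <- function(ont) {
  if (anyDuplicated(ont$concept_id)) {
    stop_adr("Ontology concept_id values must be unique.",
             "adrsignal_ontology_error")
  }
  # acyclicity of parent links by iterative leaf stripping
  edges <- tibble::tibble(
    child = rep(ont$concept_id, lengths(ont$parents)),
    parent = unlist(ont$parents)
  )
  nodes <- ont$concept_id
  repeat {
    roots <- setdiff(nodes, edges$child[edges$parent %in% nodes])
    leaves <- setdiff(nodes, edges$parent[edges$child %in% nodes])
    drop <- union(roots, leaves)
    if (length(drop) == 0) break
    nodes <- setdiff(nodes, drop)
    if (length(nodes) == 0) break
  }
  if (length(nodes) > 0) {
    stop_adr("Ontology parent links contain a cycle.",
             "adrsignal_ontology_error")
  }
  ont
}

#' Expand seed concepts into a target-ADR lexicon
#'
#' For each seed concept the lexicon receives the seed's preferred name and
#' all its synonyms; when the seed is flagged `expand_children`, the preferred
#' names and synonyms of its direct is-a children (depth 1 by default) are
#' added as well. Colloquial phrases — lay wordings patients use for a
#' reaction — are attached to their group. Entries are deduplicated on
#' `(name, concept_id)`.
#'
#' @param seeds Tibble with columns `concept_id`, `group_id`,
#'   `expand_children` (logical).
#' @param ontology Ontology tibble from [read_ontology()].
#' @param colloquial Optional tibble with columns `phrase`, `group_id`.
#' @param depth Hierarchy depth for child expansion (default 1).
#' @return Lexicon tibble: `name`, `concept_id`, `seed_concept_id`,
#'   `group_id`, `source` (one of seed/synonym/child/colloquial).
#' @export
expand_lexicon <- function(seeds, ontology, colloquial = NULL, depth = 1L) {
  unknown <- setdiff(seeds$concept_id, ontology$concept_id)
  if (length(unknown) > 0) {
    stop_adr(sprintf("Seed concept(s) not in ontology: %s",
                     paste(unknown, collapse = ", ")),
             "adrsignal_unknown_seed")
  }
  child_map <- tibble::tibble(
    child = rep(ontology$concept_id, lengths(ontology$parents)),
    parent = unlist(ontology$parents)
  )

  entries_for <- function(cid, seed_cid, group, source) {
    row <- ontology[ontology$concept_id == cid, ]
    names <- c(row$preferred_name, row$synonyms[[1]])
    src <- c(if (source == "child") "child" else "seed",
             rep(if (source == "child") "child" else "synonym",
                 length(row$synonyms[[1]])))
    tibble::tibble(name = names, concept_id = cid, seed_concept_id = seed_cid,
                   group_id = group, source = src)
  }

  out <- purrr::pmap(seeds, function(concept_id, group_id, expand_children, ...) {
    res <- entries_for(concept_id, concept_id, group_id, "seed")
    if (isTRUE(expand_children)) {
      frontier <- concept_id
      for (d in seq_len(depth)) {
        kids <- unique(child_map$child[child_map$parent %in% frontier])
        kids <- setdiff(kids, concept_id)
        if (length(kids) == 0) break
        res <- dplyr::bind_rows(
          res,
          purrr::map(kids, entries_for, seed_cid = concept_id,
                     group = group_id, source = "child") |> dplyr::bind_rows()
        )
        frontier <- kids
      }
    }
    res
  }) |> dplyr::bind_rows()

  if (!is.null(colloquial) && nrow(colloquial) > 0) {
    seed_by_group <- seeds |>
      dplyr::group_by(.data$group_id) |>
      dplyr::summarise(seed_concept_id = .data$concept_id[1], .groups = "drop")
    coll <- colloquial |>
      dplyr::left_join(seed_by_group, by = "group_id")
    if (anyNA(coll$seed_concept_id)) {
      stop_adr("Colloquial phrase references a group with no seed concept.",
               "adrsignal_unknown_seed")
    }
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(name = coll$phrase, concept_id = coll$seed_concept_id,
                     seed_concept_id = coll$seed_concept_id,
                     group_id = coll$group_id, source = "colloquial")
    )
  }
  out |>
    dplyr::filter(nzchar(.data$name)) |>
    dplyr::distinct(.data$name, .data$concept_id, .keep_all = TRUE)
}

#' Read / write a lexicon file
#'
#' Tab-separated with header `name`, `concept_id`, `seed_concept_id`,
#' `group_id`, `source`.
#'
#' @param path File path.
#' @return `read_lexicon()` returns the lexicon tibble; `write_lexicon()`
#'   returns `path` invisibly.
#' @export
read_lexicon <- function(path) {
  readr::read_tsv(path, col_types = "ccccc", progress = FALSE)
}

#' @param lexicon Lexicon tibble.
#' @rdname read_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  readr::write_tsv(lexicon, path, progress = FALSE)
  invisible(path)
}

#' Read a colloquial-phrase file (tab-separated `phrase`, `group_id`)
#'
#' @param path File path.
#' @return Tibble with columns `phrase`, `group_id`.
#' @export
read_colloquial <- function(path) {
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}
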