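#' Tokenize post bodies into sentences and tokens with character offsets
#'
#' Rule-based sentence splitting on terminal punctuation (`.`, `!`, `?`) and
#' newlines; word tokens are maximal runs of letters, digits and apostrophes,
#' punctuation marks are single-character tokens. Offsets are half-open
#' `[char_start, char_end)` 0-based positions into the original body, so
#' `substr(body, char_start + 1, char_end)` recovers the surface.
#'
#' @param posts Posts tibble (needs `post_id`, `body`) or a character vector of
#'   texts (then `post_id` is the element index as character).
#' @return A tibble with columns `post_id`, `sentence_id` (1-based within
#'   post), `token_id` (1-based within sentence), `surface`, `lemma`,
#'   `char_start`, `char_end`.
#' @export
tokenize_posts <- function(posts) {
  if (is.character(posts)) {
    posts <- tibble::tibble(post_id = as.character(seq_along(posts)),
                            body = posts)
  }
  tok_pat <- "[A-Za-z0-9']+|[^A-Za-z0-9'\\s]"
  loc <- stringr::str_locate_all(posts$body, tok_pat)
  out <- purrr::map2(posts$post_id, seq_along(loc), function(pid, i) {
    m <- loc[[i]]
    if (nrow(m) == 0) return(NULL)
    surface <- stringr::str_sub(posts$body[i], m[, "start"], m[, "end"])
    # sentence boundary after terminal punctuation or when a newline separates
    # consecutive tokens
    terminal <- surface %in% c(".", "!", "?")
    gap_nl <- if (nrow(m) > 1) {
      gaps <- stringr::str_sub(posts$body[i],
                               utils::head(m[, "end"], -1) + 1,
                               utils::tail(m[, "start"], -1) - 1)
      c(FALSE, stringr::str_detect(gaps, stringr::fixed("\n")))
    } else FALSE
    sent <- cumsum(dplyr::lag(terminal, default = FALSE) | gap_nl) + 1L
    tibble::tibble(
      post_id = pid,
      sentence_id = sent,
      surface = surface,
      char_start = m[, "start"] - 1L,
      char_end = m[, "end"]
    )
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0) {
    return(tibble::tibble(post_id = character(), sentence_id = integer(),
                          token_id = integer(), surface = character(),
                          lemma = character(), char_start = integer(),
                          char_end = integer()))
  }
  out |>
    dplyr::group_by(.data$post_id, .data$sentence_id) |>
    dplyr::mutate(token_id = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(lemma = lemmatize(.data$surface)) |>
    dplyr::select("post_id", "sentence_id", "token_id", "surface", "lemma",
                  "char_start", "char_end")
}

# Irregular forms that the suffix rules cannot reach; keys are lowercase.
LEMMA_EXCEPTIONS <- c(
  been = "be", was = "be", were = "be", is = "be", are = "be", am = "be",
  being = "be",
  has = "have", had = "have", having = "have",
  feet = "foot", teeth = "tooth", men = "man", women = "woman",
  children = "child", worse = "bad", worst = "bad", better = "good",
  best = "good", felt = "feel", got = "get", gotten = "get", went = "go",
  gone = "go", did = "do", does = "do", done = "do", took = "take",
  taken = "take", saw = "see", seen = "see", itchy = "itch", dry = "dry",
  dries = "dry", dried = "dry", blistered = "blister", blistery = "blister"
)

#' Lemmatize tokens
#'
#' Dictionary-backed lemmatizer: lowercases, applies a small irregular-form
#' table, then conservative suffix stripping (`-ies` to `-y`, `-ing`, `-ed`,
#' plural `-s`). Intentionally lightweight and deterministic; the identical
#' function is applied at concept-index build time and query time.
#'
#' @param tokens Character vector of token surfaces.
#' @return Character vector of lemmas, same length.
#' @export
lemmatize <- function(tokens) {
  x <- tolower(tokens)
  exc <- !is.na(match(x, names(LEMMA_EXCEPTIONS)))
  x[exc] <- LEMMA_EXCEPTIONS[x[exc]]
  todo <- !exc & grepl("^[a-z]+$", x)
  strip <- function(x, sel, pattern, replacement, min_stem) {
    cand <- sub(pattern, replacement, x)
    ok <- sel & cand != x & nchar(cand) >= min_stem
    x[ok] <- cand[ok]
    list(x = x, done = ok)
  }
  r <- strip(x, todo, "ies$", "y", 3L);          x <- r$x; todo <- todo & !r$done
  r <- strip(x, todo, "([a-z])\\1ing$", "\\1", 3L); x <- r$x; todo <- todo & !r$done
  r <- strip(x, todo, "ing$", "", 3L);           x <- r$x; todo <- todo & !r$done
  r <- strip(x, todo, "([a-z])\\1ed$", "\\1", 3L);  x <- r$x; todo <- todo & !r$done
  r <- strip(x, todo, "ed$", "", 3L);            x <- r$x; todo <- todo & !r$done
  r <- strip(x, todo, "(sh|ch|x|z|ss)es$", "\\1", 3L); x <- r$x; todo <- todo & !r$done
  r <- strip(x, todo, "([^siu])s$", "\\1", 3L);  x <- r$x
  x
}
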