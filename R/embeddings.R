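#' Train word embeddings by skip-gram with negative sampling
#'
#' Learns dense vectors for every token above the minimum frequency from the
#' co-occurrence structure of tokenized sentences. Tokens below `min_count`
#' map to a shared OOV (out-of-vocabulary) vector. Training is plain
#' mini-batch SGD on the negative-sampling objective and is fully
#' deterministic for a fixed seed.
#'
#' @param tokens Tokenized sentences from [tokenize_posts()] (needs `post_id`,
#'   `sentence_id`, `surface`), or a list of character vectors (one sentence
#'   each).
#' @param dim Embedding dimension (default 150).
#' @param window Context window half-width (default 5).
#' @param min_count Minimum token frequency to enter the vocabulary (default 2).
#' @param negative Negative samples per positive pair (default 5).
#' @param epochs Training epochs (default 5).
#' @param learning_rate Initial SGD step size, decayed linearly (default 0.05).
#' @param seed Integer seed controlling initialization and sampling.
#' @return An `embedding_table`: list with `vectors` (matrix, rows = vocab plus
#'   an `"<OOV>"` row), `dim`, `vocab`.
#' @export
train_embeddings <- function(tokens, dim = 150L, window = 5L, min_count = 2L,
                             negative = 5L, epochs = 5L, learning_rate = 0.05,
                             seed = 1L) {
  sentences <- as_sentence_list(tokens)
  if (length(sentences) == 0 || sum(lengths(sentences)) == 0) {
    stop_adr("Cannot train embeddings on an empty corpus.",
             "adrsignal_empty_corpus")
  }
  if (dim < 2) stop_adr("`dim` must be >= 2.", "adrsignal_bad_argument")

  words <- tolower(unlist(sentences))
  freq <- sort(table(words), decreasing = TRUE)
  vocab <- names(freq)[freq >= min_count]
  vocab <- vocab[order(-freq[vocab], vocab)]  # deterministic order
  if (length(vocab) == 0) vocab <- names(freq)[order(-freq, names(freq))]
  V <- length(vocab)

  # integer-encode sentences; 0 = dropped (below min_count)
  ids <- purrr::map(sentences, ~ match(tolower(.x), vocab, nomatch = 0L))

  # positive (center, context) pairs within the window
  pairs <- purrr::map(ids, function(s) {
    s <- s[s > 0L]
    n <- length(s)
    if (n < 2) return(NULL)
    out <- purrr::map(seq_len(n), function(i) {
      ctx <- s[max(1, i - window):min(n, i + window)][-(i - max(1, i - window) + 1)]
      if (length(ctx) == 0) return(NULL)
      cbind(center = s[i], context = ctx)
    })
    do.call(rbind, purrr::compact(out))
  })
  pairs <- do.call(rbind, purrr::compact(pairs))
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop_adr("Corpus has no co-occurring in-vocabulary tokens.",
             "adrsignal_empty_corpus")
  }

  # unigram^(3/4) negative-sampling distribution
  uni <- as.numeric(freq[vocab])^0.75
  uni <- uni / sum(uni)

  set.seed(as.integer(seed))
  W_in <- matrix(runif(V * dim, -0.5, 0.5) / dim, nrow = V)
  W_out <- matrix(0, nrow = V, ncol = dim)

  n_pairs <- nrow(pairs)
  batch <- 256L
  total_steps <- epochs * ceiling(n_pairs / batch)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_pairs)
    for (b0 in seq(1, n_pairs, by = batch)) {
      idx <- ord[b0:min(b0 + batch - 1, n_pairs)]
      B <- length(idx)
      centers <- pairs[idx, "center"]
      pos <- pairs[idx, "context"]
      neg <- matrix(sample.int(V, B * negative, replace = TRUE, prob = uni),
                    nrow = B)
      outs <- cbind(pos, neg)                       # B x (1+negative)
      y <- cbind(1, matrix(0, B, negative))
      lr <- learning_rate * (1 - step / total_steps) + 1e-4
      step <- step + 1L

      Vc <- W_in[centers, , drop = FALSE]           # B x d
      K <- 1L + negative
      oi <- as.integer(outs)                        # length B*K
      Uo <- W_out[oi, , drop = FALSE]               # (B*K) x d
      Vrep <- Vc[rep(seq_len(B), K), , drop = FALSE]
      s <- rowSums(Vrep * Uo)
      g <- 1 / (1 + exp(-s)) - as.numeric(y)        # sigmoid - label

      grad_u <- Vrep * g                            # (B*K) x d
      grad_v <- rowsum(Uo * g, group = rep(seq_len(B), K), reorder = TRUE)
      # scatter-add with duplicate-index aggregation
      agg_u <- rowsum(grad_u, group = oi)
      W_out[as.integer(rownames(agg_u)), ] <-
        W_out[as.integer(rownames(agg_u)), , drop = FALSE] - lr * agg_u
      agg_v <- rowsum(grad_v, group = centers)
      W_in[as.integer(rownames(agg_v)), ] <-
        W_in[as.integer(rownames(agg_v)), , drop = FALSE] - lr * agg_v
    }
  }

  vectors <- rbind(W_in, colMeans(W_in))
  rownames(vectors) <- c(vocab, "<OOV>")
  structure(list(vectors = vectors, dim = as.integer(dim), vocab = vocab),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", length(x$vocab), " words, dim ", x$dim, "\n",
      sep = "")
  invisible(x)
}

#' Look up embedding vectors for tokens
#'
#' @param embeddings An `embedding_table`.
#' @param tokens Character vector; unknown tokens map to the OOV vector.
#' @return Numeric matrix, one row per token.
#' @export
embed_tokens <- function(embeddings, tokens) {
  idx <- match(tolower(tokens), rownames(embeddings$vectors))
  idx[is.na(idx)] <- nrow(embeddings$vectors)  # OOV row
  embeddings$vectors[idx, , drop = FALSE]
}

#' Cosine similarity between two words in an embedding table
#'
#' @param embeddings An `embedding_table`.
#' @param a,b Words to compare (unknown words use the OOV vector).
#' @return Cosine similarity in \[-1, 1\].
#' @export
embedding_similarity <- function(embeddings, a, b) {
  va <- embed_tokens(embeddings, a)[1, ]
  vb <- embed_tokens(embeddings, b)[1, ]
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

# Internal: accept a token tibble or a list of character vectors.
as_sentence_list <- function(tokens) {
  if (is.data.frame(tokens)) {
    words <- tokens[grepl("^[A-Za-z0-9']+$", tokens$surface), ]
    unname(split(words$surface,
                 interaction(words$post_id, words$sentence_id, drop = TRUE)))
  } else {
    tokens
  }
}

#' Write / read an embedding table in plain-text word-vector format
#'
#' First line `<n> <dim>`, then one `word v1 v2 ...` row per word (the final
#' row is the OOV vector, written as `<OOV>`).
#'
#' @param embeddings An `embedding_table`.
#' @param path File path.
#' @return `path` invisibly / an `embedding_table`.
#' @export
write_embeddings <- function(embeddings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- embeddings$vectors
  writeLines(paste(nrow(m), ncol(m)), con)
  writeLines(paste(rownames(m),
                   apply(m, 1, function(r) paste(format(r, digits = 17),
                                                 collapse = " "))), con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " +")
  words <- purrr::map_chr(parts, 1)
  vecs <- do.call(rbind, purrr::map(parts, ~ as.numeric(.x[-1])))
  rownames(vecs) <- words
  vocab <- setdiff(words, "<OOV>")
  structure(list(vectors = vecs, dim = hdr[2], vocab = vocab),
            class = "embedding_table")
}
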