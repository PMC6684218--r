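TAG_SET <- c("O", "B-ADR", "I-ADR", "B-IND", "I-IND")

#' Convert gold entity spans to per-token BIO tags
#'
#' Spans whose character boundaries fall inside tokens are snapped outward to
#' the covering tokens (never truncating gold text), with a warning. A span
#' that overlaps no token of its post is an error.
#'
#' @param tokens Token tibble from [tokenize_posts()].
#' @param spans Gold span tibble: `post_id`, `char_start`, `char_end`,
#'   `label` (`"ADR"` or `"IND"`).
#' @return `tokens` with an added `tag` column (BIO over ADR/IND).
#' @export
spans_to_bio <- function(tokens, spans) {
  tokens$tag <- "O"
  if (is.null(spans) || nrow(spans) == 0) return(tokens)
  stopifnot(all(spans$label %in% c("ADR", "IND")))
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, ]
    sel <- which(tokens$post_id == s$post_id &
                   tokens$char_end > s$char_start &
                   tokens$char_start < s$char_end)
    if (length(sel) == 0) {
      stop_adr(sprintf("Gold span [%d,%d) `%s` overlaps no token of post %s.",
                       s$char_start, s$char_end,
                       s$label, s$post_id),
               "adrsignal_span_error")
    }
    if (tokens$char_start[sel[1]] != s$char_start ||
        tokens$char_end[sel[length(sel)]] != s$char_end) {
      rlang::warn(sprintf(
        "Gold span [%d,%d) in post %s snapped outward to token boundaries.",
        s$char_start, s$char_end, s$post_id))
    }
    tokens$tag[sel] <- c(paste0("B-", s$label),
                         rep(paste0("I-", s$label), length(sel) - 1))
  }
  tokens
}

# Internal: windowed feature matrix for one ordered token table.
# Concatenates embeddings of tokens t-w .. t+w within each sentence; positions
# outside the sentence contribute zero vectors.
token_features <- function(tokens, embeddings, window) {
  d <- embeddings$dim
  emb <- embed_tokens(embeddings, tokens$surface)
  sent_key <- paste(tokens$post_id, tokens$sentence_id, sep = "\r")
  n <- nrow(tokens)
  X <- matrix(0, nrow = n, ncol = (2 * window + 1) * d)
  offsets <- -window:window
  for (j in seq_along(offsets)) {
    o <- offsets[j]
    src <- seq_len(n) + o
    ok <- src >= 1 & src <= n
    ok[ok] <- sent_key[src[ok]] == sent_key[ok]
    cols <- ((j - 1) * d + 1):(j * d)
    X[ok, cols] <- emb[src[ok], , drop = FALSE]
  }
  X
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train a feed-forward neural sequence tagger
#'
#' Per-token classification over a 5-tag BIO scheme (`O`, `B-ADR`, `I-ADR`,
#' `B-IND`, `I-IND`) from the concatenated word embeddings of a +/- `window`
#' token context, through one tanh hidden layer and a softmax output, trained
#' by mini-batch SGD on cross-entropy for a fixed epoch count. Deterministic
#' for a fixed seed.
#'
#' @param tokens Token tibble from [tokenize_posts()] covering the training
#'   posts.
#' @param gold_spans Gold span tibble (see [spans_to_bio()]); may have zero
#'   rows.
#' @param embeddings An `embedding_table` used for input features (frozen
#'   during tagger training).
#' @param window Context half-width in tokens (default 2).
#' @param hidden Hidden-layer width (default 300).
#' @param epochs Training epochs (default 30).
#' @param learning_rate SGD step size (default 0.1).
#' @param batch_size Mini-batch size (default 64).
#' @param seed Integer seed.
#' @return An `adr_tagger` model object (weights, config, loss history, the
#'   embedding table).
#' @export
train_tagger <- function(tokens, gold_spans, embeddings, window = 2L,
                         hidden = 300L, epochs = 30L, learning_rate = 0.1,
                         batch_size = 64L, seed = 1L) {
  if (nrow(tokens) == 0) {
    stop_adr("No training tokens supplied.", "adrsignal_empty_corpus")
  }
  tagged <- spans_to_bio(tokens, gold_spans)
  y <- match(tagged$tag, TAG_SET)
  X <- token_features(tagged, embeddings, window)
  n <- nrow(X); p <- ncol(X); K <- length(TAG_SET)

  set.seed(as.integer(seed))
  W1 <- matrix(runif(p * hidden, -0.5, 0.5) / sqrt(p), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(runif(hidden * K, -0.5, 0.5) / sqrt(hidden), hidden, K)
  b2 <- numeric(K)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1

  loss_history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      H <- tanh(sweep(Xb %*% W1, 2, b1, "+"))
      P <- softmax_rows(sweep(H %*% W2, 2, b2, "+"))
      ep_loss <- ep_loss - sum(log(pmax(P[Yb == 1], 1e-12)))
      G2 <- (P - Yb) / length(idx)
      dW2 <- crossprod(H, G2)
      db2 <- colSums(G2)
      GH <- (G2 %*% t(W2)) * (1 - H^2)
      dW1 <- crossprod(Xb, GH)
      db1 <- colSums(GH)
      W2 <- W2 - learning_rate * dW2; b2 <- b2 - learning_rate * db2
      W1 <- W1 - learning_rate * dW1; b1 <- b1 - learning_rate * db1
    }
    loss_history[ep] <- ep_loss / n
  }

  structure(
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
         window = as.integer(window), hidden = as.integer(hidden),
         epochs = as.integer(epochs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         tag_set = TAG_SET, embeddings = embeddings,
         loss_history = loss_history),
    class = "adr_tagger"
  )
}

#' @export
print.adr_tagger <- function(x, ...) {
  cat("<adr_tagger> window +/-", x$window, ", hidden ", x$hidden,
      ", trained ", x$epochs, " epochs (final loss ",
      format(utils::tail(x$loss_history, 1), digits = 4), ")\n", sep = "")
  invisible(x)
}

# Internal: per-token tag probabilities for a token table. Prediction is
# chunked by sentence blocks so the feature matrix stays bounded in memory.
predict_tags <- function(model, tokens, chunk_rows = 50000L) {
  n <- nrow(tokens)
  sent_key <- paste(tokens$post_id, tokens$sentence_id, sep = "\r")
  # chunk boundaries aligned to sentence starts
  starts <- which(!duplicated(sent_key))
  cuts <- starts[!duplicated((starts - 1L) %/% chunk_rows)]
  ends <- c(cuts[-1] - 1L, n)
  out <- matrix(0, n, length(TAG_SET))
  for (i in seq_along(cuts)) {
    rows <- cuts[i]:ends[i]
    X <- token_features(tokens[rows, ], model$embeddings, model$window)
    H <- tanh(sweep(X %*% model$W1, 2, model$b1, "+"))
    out[rows, ] <- softmax_rows(sweep(H %*% model$W2, 2, model$b2, "+"))
  }
  out
}

# Internal: BIO repair — an I-x not preceded by B-x/I-x becomes B-x.
repair_bio <- function(tags) {
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (startsWith(t, "I-")) {
      typ <- substring(t, 3)
      prev <- if (i > 1) tags[i - 1] else "O"
      if (!prev %in% paste0(c("B-", "I-"), typ)) {
        tags[i] <- paste0("B-", typ)
      }
    }
  }
  tags
}

# Internal: decode repaired BIO tags into spans for one post's token table.
decode_spans <- function(tokens, tags, probs, body, post_id) {
  tags <- repair_bio(tags)
  starts <- which(startsWith(tags, "B-"))
  if (length(starts) == 0) {
    return(tibble::tibble(post_id = character(), char_start = integer(),
                          char_end = integer(), surface = character(),
                          label = character(), score = numeric()))
  }
  purrr::map(starts, function(s) {
    typ <- substring(tags[s], 3)
    e <- s
    while (e + 1 <= length(tags) && tags[e + 1] == paste0("I-", typ) &&
           tokens$sentence_id[e + 1] == tokens$sentence_id[s]) {
      e <- e + 1
    }
    idx <- s:e
    cs <- tokens$char_start[s]; ce <- tokens$char_end[e]
    tibble::tibble(
      post_id = post_id, char_start = cs, char_end = ce,
      surface = substr(body, cs + 1, ce),
      label = typ,
      score = mean(probs[cbind(idx, match(tags[idx], TAG_SET))])
    )
  }) |> dplyr::bind_rows()
}

#' Tag posts with a trained model
#'
#' Tokenizes each post body, predicts per-token tag probabilities, repairs
#' invalid BIO sequences deterministically, and decodes maximal B/I runs into
#' non-overlapping entity spans. A span's score is the mean probability of its
#' tokens' assigned tags.
#'
#' @param posts Posts tibble (or a `drug_corpus`).
#' @param model An `adr_tagger`.
#' @return Entity-span tibble: `post_id`, `char_start`, `char_end`, `surface`,
#'   `label` (`"ADR"`/`"IND"`), `score`.
#' @export
tag_posts <- function(posts, model) {
  stopifnot(inherits(model, "adr_tagger"))
  toks <- tokenize_posts(posts)
  if (nrow(toks) == 0) {
    return(tibble::tibble(post_id = character(), char_start = integer(),
                          char_end = integer(), surface = character(),
                          label = character(), score = numeric()))
  }
  probs <- predict_tags(model, toks)
  tags <- TAG_SET[max.col(probs, ties.method = "first")]
  body_of <- setNames(posts$body, posts$post_id)
  split_idx <- split(seq_len(nrow(toks)), toks$post_id)
  purrr::imap(split_idx, function(rows, pid) {
    decode_spans(toks[rows, ], tags[rows], probs[rows, , drop = FALSE],
                 body_of[[pid]], pid)
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$post_id, .data$char_start)
}

#' Serialize / restore a tagger model
#'
#' The single-file archive contains the full configuration, weights and the
#' embedding table; restoring yields identical predictions.
#'
#' @param model An `adr_tagger`.
#' @param path File path.
#' @return `path` invisibly / an `adr_tagger`.
#' @export
write_tagger <- function(model, path) {
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname write_tagger
#' @export
read_tagger <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "adr_tagger"))
  model
}
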