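embedding_fixture_sentences <- function(n = 100) {
  # templated sentences in which "rash" and "eruption" share every context
  lapply(seq_len(n), function(i) {
    w <- if (i %% 2 == 0) "rash" else "eruption"
    c("the", w, "got", "worse", "after", "treatment",
      sample(c("today", "again", "slowly"), 1))
  })
}

test_that("embedding training is deterministic under a fixed seed", {
  set.seed(99)
  sents <- embedding_fixture_sentences()
  e1 <- train_embeddings(sents, dim = 16, epochs = 2, seed = 7)
  e2 <- train_embeddings(sents, dim = 16, epochs = 2, seed = 7)
  expect_identical(e1, e2)
  e3 <- train_embeddings(sents, dim = 16, epochs = 2, seed = 8)
  expect_false(identical(e1$vectors, e3$vectors))
})

test_that("tokens below the minimum frequency map to the OOV vector", {
  sents <- c(embedding_fixture_sentences(20), list(c("zzhapax", "word")))
  emb <- train_embeddings(sents, dim = 8, epochs = 1, min_count = 2, seed = 1)
  expect_false("zzhapax" %in% emb$vocab)
  expect_equal(embed_tokens(emb, "zzhapax"),
               emb$vectors["<OOV>", , drop = FALSE], ignore_attr = TRUE)
})

test_that("distributionally identical tokens end up more similar than random pairs", {
  sims <- vapply(1:10, function(s) {
    set.seed(s)
    emb <- train_embeddings(embedding_fixture_sentences(60), dim = 16,
                            epochs = 4, seed = s)
    target <- embedding_similarity(emb, "rash", "eruption")
    others <- setdiff(emb$vocab, c("rash", "eruption"))
    pairs <- utils::combn(others, 2)
    random_mean <- mean(apply(pairs, 2, function(p)
      embedding_similarity(emb, p[1], p[2])))
    target - random_mean
  }, numeric(1))
  expect_gt(mean(sims), 0)
})

test_that("empty corpus is rejected", {
  expect_error(train_embeddings(list()), class = "adrsignal_empty_corpus")
})

test_that("tagger training decreases loss and is byte-identical under a seed", {
  b <- tiny_ner_bundle()
  toks <- tokenize_posts(b$posts[1:80, ])
  emb <- train_embeddings(toks, dim = 16, epochs = 2, seed = 13)
  spans <- b$spans[b$spans$post_id %in% b$posts$post_id[1:80], ]
  m1 <- train_tagger(toks, spans, emb, hidden = 32, epochs = 8, seed = 13)
  expect_lt(utils::tail(m1$loss_history, 1), m1$loss_history[1])
  m2 <- train_tagger(toks, spans, emb, hidden = 32, epochs = 8, seed = 13)
  f1 <- tempfile(); f2 <- tempfile()
  write_tagger(m1, f1); write_tagger(m2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # serialization round-trip predicts identically
  m3 <- read_tagger(f1)
  p <- b$posts[81:85, ]
  expect_identical(tag_posts(p, m1), tag_posts(p, m3))
})

test_that("a tagger trained with no entities predicts all-O", {
  b <- tiny_ner_bundle()
  toks <- tokenize_posts(b$posts[1:40, ])
  emb <- train_embeddings(toks, dim = 8, epochs = 1, seed = 13)
  m <- train_tagger(toks, b$spans[0, ], emb, hidden = 16, epochs = 5,
                    seed = 13)
  pred <- tag_posts(b$posts[41:60, ], m)
  expect_equal(nrow(pred), 0L)
})

test_that("the tagger recovers an entity from a memorized training post", {
  b <- tiny_ner_bundle()
  with_span <- unique(b$spans$post_id[b$spans$label == "ADR"])
  train_posts <- b$posts[b$posts$post_id %in% utils::head(with_span, 60), ]
  toks <- tokenize_posts(train_posts)
  emb <- train_embeddings(toks, dim = 24, epochs = 3, seed = 13)
  spans <- b$spans[b$spans$post_id %in% train_posts$post_id, ]
  m <- train_tagger(toks, spans, emb, hidden = 48, epochs = 25, seed = 13)
  target_post <- train_posts[1, ]
  pred <- tag_posts(target_post, m)
  gold <- spans[spans$post_id == target_post$post_id & spans$label == "ADR", ]
  found <- dplyr::inner_join(pred, gold,
                             by = c("post_id", "char_start", "char_end",
                                    "label"))
  expect_gte(nrow(found), 1L)
})

test_that("every emitted span's surface equals the body slice at its offsets", {
  b <- tiny_ner_bundle()
  toks <- tokenize_posts(b$posts[1:60, ])
  emb <- train_embeddings(toks, dim = 16, epochs = 2, seed = 13)
  spans <- b$spans[b$spans$post_id %in% b$posts$post_id[1:60], ]
  m <- train_tagger(toks, spans, emb, hidden = 32, epochs = 15, seed = 13)
  posts <- b$posts[1:100, ]
  pred <- tag_posts(posts, m)
  body_of <- setNames(posts$body, posts$post_id)
  expect_true(all(substring(body_of[pred$post_id], pred$char_start + 1,
                            pred$char_end) == pred$surface))
  # no overlapping spans within a post
  by_post <- split(pred, pred$post_id)
  expect_true(all(vapply(by_post, function(d) {
    d <- d[order(d$char_start), ]
    all(utils::head(d$char_end, -1) <= utils::tail(d$char_start, -1))
  }, logical(1))))
  expect_true(all(pred$score >= 0 & pred$score <= 1))
})

test_that("BIO repair turns orphan I- tags into span starts", {
  expect_equal(adrsignal:::repair_bio(c("O", "I-ADR", "O")), c("O", "B-ADR", "O"))
  expect_equal(adrsignal:::repair_bio(c("I-ADR", "I-ADR")), c("B-ADR", "I-ADR"))
  expect_equal(adrsignal:::repair_bio(c("B-IND", "I-ADR")), c("B-IND", "B-ADR"))
  expect_equal(adrsignal:::repair_bio(c("B-ADR", "I-ADR", "O")),
               c("B-ADR", "I-ADR", "O"))
})

test_that("gold spans snapped to token boundaries warn; non-overlapping spans error", {
  posts <- tibble::tibble(post_id = "p1", user_id = "u1",
                          created_at = as.Date("2010-01-01"),
                          body = "severe rashes appeared")
  toks <- tokenize_posts(posts)
  # span cutting into "rashes" (chars 7..10 cover "rash") snaps outward
  expect_warning(
    tagged <- spans_to_bio(toks, tibble::tibble(
      post_id = "p1", char_start = 7L, char_end = 11L, label = "ADR")),
    "snapped"
  )
  expect_equal(tagged$tag[tagged$surface == "rashes"], "B-ADR")
  expect_error(
    spans_to_bio(toks, tibble::tibble(
      post_id = "p1", char_start = 400L, char_end = 410L, label = "ADR")),
    class = "adrsignal_span_error"
  )
})

test_that("empty posts tag to an empty span set", {
  b <- tiny_ner_bundle()
  toks <- tokenize_posts(b$posts[1:20, ])
  emb <- train_embeddings(toks, dim = 8, epochs = 1, seed = 13)
  m <- train_tagger(toks, b$spans[b$spans$post_id %in% b$posts$post_id[1:20], ],
                    emb, hidden = 16, epochs = 3, seed = 13)
  empty <- tibble::tibble(post_id = "px", user_id = "u",
                          created_at = as.Date("2010-01-01"), body = "")
  expect_equal(nrow(tag_posts(empty, m)), 0L)
})
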