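test_that("tokenization splits on whitespace, drops empties, honours the segmenter contract", {
  expect_equal(tokenize_text("acute chest pain")[[1]], c("acute", "chest", "pain"))
  expect_equal(tokenize_text("")[[1]], character(0))
  expect_equal(tokenize_text(NA_character_)[[1]], character(0))
  expect_equal(tokenize_text("  fever   cough ")[[1]], c("fever", "cough"))

  gappy <- function(s) c("a", "", "b", "", "")
  expect_equal(tokenize_text("anything", gappy)[[1]], c("a", "b"))
})

test_that("vocabulary keeps tokens at the frequency threshold and maps the rest to unk", {
  corpus <- c(rep("fever", 6), rep("rare", 5), rep("cough", 10))
  vocab <- build_vocabulary(list(corpus))
  expect_true("fever" %in% names(vocab$token_to_index))   # 6 occurrences kept
  expect_false("rare" %in% names(vocab$token_to_index))   # 5 occurrences -> unk
  expect_true("cough" %in% names(vocab$token_to_index))
  # cough (10) outranks fever (6)
  expect_lt(vocab$token_to_index[["cough"]], vocab$token_to_index[["fever"]])
  expect_equal(vocab$pad_index, 0L)
  expect_equal(vocab$unk_index, 3L)
  expect_equal(vocab$n_indices, 3L)
})

test_that("vocabulary construction is deterministic and order-independent", {
  set.seed(3)
  docs <- replicate(20, sample(letters[1:8], 30, replace = TRUE),
                    simplify = FALSE)
  v1 <- build_vocabulary(docs, min_occurrences = 3)
  v2 <- build_vocabulary(docs, min_occurrences = 3)
  v3 <- build_vocabulary(sample(docs), min_occurrences = 3)
  expect_identical(v1$token_to_index, v2$token_to_index)
  expect_identical(v1$token_to_index, v3$token_to_index)
})

test_that("no kept token falls below the threshold, for random small corpora", {
  for (s in 1:10) {
    set.seed(s)
    docs <- replicate(8, sample(letters[1:10], sample(5:40, 1), replace = TRUE),
                      simplify = FALSE)
    thr <- sample(2:5, 1)
    vocab <- build_vocabulary(docs, min_occurrences = thr)
    counts <- table(unlist(docs))
    kept <- names(vocab$token_to_index)
    expect_true(all(counts[kept] >= thr))
    dropped <- setdiff(names(counts), kept)
    expect_true(all(counts[dropped] < thr))
    idx <- vocab$token_to_index
    expect_true(all(idx >= 1L))
    expect_equal(anyDuplicated(idx), 0L)
  }
})

test_that("an empty corpus cannot produce a vocabulary", {
  expect_error(build_vocabulary(list()), "empty")
  expect_error(build_vocabulary(list(character(0))), "empty")
})

test_that("encoding pads short and truncates long sequences to the fixed length", {
  vocab <- build_vocabulary(list(rep(c("fever", "cough", "pain"), 10)),
                            min_occurrences = 6)
  enc <- encode_tokens(c("fever", "cough", "pain"), vocab, target_length = 130)
  expect_length(enc, 130)
  expect_equal(attr(enc, "n_real_tokens"), 3L)
  expect_true(all(enc[4:130] == 0))
  expect_equal(enc[1:3], unname(vocab$token_to_index[c("fever", "cough", "pain")]))

  long <- rep(c("fever", "cough", "pain"), 50)          # 150 tokens
  enc_long <- encode_tokens(long, vocab, target_length = 130)
  expect_length(enc_long, 130)
  expect_equal(attr(enc_long, "n_real_tokens"), 130L)
  expect_equal(enc_long, encode_tokens(long[1:130], vocab, 130),
               ignore_attr = TRUE)                      # head retention

  empty <- encode_tokens(character(0), vocab, 130)
  expect_true(all(empty == 0))
  expect_equal(attr(empty, "n_real_tokens"), 0L)

  oov <- encode_tokens("neverseen", vocab, 5)
  expect_equal(oov[1], vocab$unk_index)
})

test_that("non-pad count equals min(token count, target length) for arbitrary inputs", {
  vocab <- build_vocabulary(list(rep(letters[1:5], 4)), min_occurrences = 2)
  for (s in 1:20) {
    set.seed(s)
    n_tok <- sample(0:30, 1)
    toks <- sample(c(letters[1:5], "zz"), n_tok, replace = TRUE)
    N <- sample(1:20, 1)
    enc <- encode_tokens(toks, vocab, N)
    expect_equal(sum(enc != 0), min(n_tok, N))
    expect_equal(attr(enc, "n_real_tokens"), min(n_tok, N))
  }
})

test_that("corpus encoding concatenates the three fields head-first", {
  vocab <- build_vocabulary(list(c(rep("a", 6), rep("b", 6), rep("c", 6))),
                            min_occurrences = 6)
  rec <- tibble::tibble(record_id = "r1", chief_complaint = "a a",
                        present_illness_history = "b", physical_exam = "c c c",
                        label = "x")
  enc <- encode_corpus(rec, vocab, target_length = 10)
  ia <- vocab$token_to_index[["a"]]; ib <- vocab$token_to_index[["b"]]
  ic <- vocab$token_to_index[["c"]]
  expect_equal(enc$indices[1, 1:6], c(ia, ia, ib, ic, ic, ic))
  expect_equal(enc$n_real_tokens, 6L)
  expect_equal(as.character(enc$labels), "x")
  expect_error(encode_corpus(rec, vocab, label_col = "diagnosis"), "diagnosis")
})
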