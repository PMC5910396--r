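test_that("the reference configuration yields a 384-dim feature and 6 classes", {
  cfg <- emrcnn_config()
  expect_equal(cfg$feature_dim, 384L)
  expect_equal(cfg$n_classes, 6L)
  expect_equal(cfg$kernel_heights, c(4L, 5L, 6L))
  expect_equal(cfg$seq_length, 130L)
  expect_equal(cfg$embedding_dim, 300L)
  expect_error(emrcnn_config(kernel_heights = 200, seq_length = 130), "height")
  expect_error(emrcnn_config(n_classes = 1), "n_classes")
})

test_that("embedding lookup is a pure row lookup with a zero pad row", {
  cfg <- tiny_config()
  p <- init_parameters(4, cfg, seed = 1)
  allpad <- embed_sequence(rep(0L, 7), p$embedding)
  expect_true(all(allpad == 0))
  two <- embed_sequence(c(2L, 3L), p$embedding)
  expect_equal(two[1, ], p$embedding[3, ])
  expect_equal(two[2, ], p$embedding[4, ])
  swapped <- embed_sequence(c(3L, 2L), p$embedding)
  expect_equal(swapped, two[2:1, ])
  expect_error(embed_sequence(c(99L), p$embedding), "mismatch")
})

test_that("relu clamps negatives and passes positives", {
  expect_equal(relu(-1.5), 0)
  expect_equal(relu(2.0), 2.0)
  expect_equal(relu(0), 0)
  expect_equal(relu(c(-1, 0, 3)), c(0, 0, 3))
})

test_that("single-kernel convolution matches the hand-computed window sums", {
  x <- matrix(c(1, 0, 0, 1, 1, 1), nrow = 3, byrow = TRUE)
  w <- matrix(1, 2, 2)
  expect_equal(convolve_kernel(x, w, bias = 0), c(2, 3))
  expect_equal(convolve_kernel(matrix(0, 4, 2), w, bias = 0), c(0, 0, 0))
  # flipping the sign of a positive response lands in the ReLU dead zone
  expect_equal(convolve_kernel(x, -w, bias = 0), c(0, 0))
  expect_error(convolve_kernel(matrix(0, 1, 2), w), "short")
  expect_error(convolve_kernel(matrix(0, 3, 3), w), "width")
})

test_that("convolution agrees with the nested-loop oracle on random instances", {
  for (s in 1:25) {
    set.seed(s)
    N <- sample(3:10, 1); D <- sample(1:4, 1)
    H <- sample(seq_len(min(3, N)), 1)
    stride <- sample(1:2, 1)
    x <- matrix(rnorm(N * D), N, D)
    w <- matrix(rnorm(H * D), H, D)
    b <- rnorm(1)
    expect_equal(convolve_kernel(x, w, b, stride), naive_convolve(x, w, b, stride),
                 tolerance = 1e-12)
  }
})

test_that("pooling reproduces windowed and global maxima", {
  expect_equal(pool_features(c(0.2, 0.9, 0.1)), 0.9)
  expect_equal(pool_features(rep(3, 5), window = 2, stride = 1), rep(3, 4))
  expect_equal(pool_features(c(1, 3, 2, 5), window = 2, stride = 1), c(3, 3, 5))
  expect_equal(pool_features(c(1, 3, 2, 5), mode = "mean"), 2.75)
  expect_error(pool_features(c(1, 2), window = 3), "larger")
  for (s in 1:15) {
    set.seed(100 + s)
    v <- rnorm(sample(4:12, 1))
    w <- sample(seq_along(v), 1); st <- sample(1:2, 1)
    expect_equal(pool_features(v, w, st), naive_pool(v, w, st))
    expect_equal(pool_features(v, w, st, mode = "mean"),
                 naive_pool(v, w, st, mode = "mean"))
  }
})

test_that("feature concatenation is ordered, stable, and 384-long at reference size", {
  pooled <- purrr::map(1:384, ~ .x * 1.0)       # 3 heights x 128 kernels x global pool
  f <- concatenate_features(pooled)
  expect_length(f, 384)
  expect_equal(f, as.numeric(1:384))
  expect_equal(concatenate_features(list(7.5)), 7.5)
  expect_identical(concatenate_features(pooled), concatenate_features(pooled))
  expect_error(concatenate_features(list()), "concatenate")
})

test_that("the dense layer is the exact affine map", {
  W <- diag(3)[, 1:2]                            # selector of features 1 and 2
  f <- c(0.3, -1, 2)
  expect_equal(dense_forward(f, W, c(0, 0)), f[1:2])
  expect_equal(dense_forward(c(0, 0, 0), W, c(1, -1)), c(1, -1))
  expect_equal(dense_forward(2 * f, W, c(0, 0)), 2 * dense_forward(f, W, c(0, 0)))
  expect_error(dense_forward(c(1, 2), W, c(0, 0)), "match")
})

test_that("softmax normalizes scores into a shift-invariant distribution", {
  expect_equal(softmax_probs(rep(1.7, 6)), rep(1 / 6, 6))
  expect_equal(softmax_probs(c(0, log(3))), c(0.25, 0.75))
  set.seed(9)
  for (i in 1:20) {
    y <- rnorm(6, sd = 5)
    p <- softmax_probs(y)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(p, softmax_probs(y + 42), tolerance = 1e-12)
    expect_true(all(p > 0))
  }
  expect_equal(softmax_probs(c(1000, 1000)), c(0.5, 0.5))   # max-shift stability
  expect_error(softmax_probs(c(Inf, 0)), "finite")
})

test_that("forward pass equals chaining the primitives step by step", {
  cfg <- emrcnn_config(seq_length = 5, embedding_dim = 2,
                       kernel_heights = c(2, 3), kernels_per_height = 3,
                       n_classes = 4, init_range = 0.4)
  p <- init_parameters(6, cfg, seed = 21)
  for (s in 1:5) {
    set.seed(s)
    idx <- sample(0:6, 5, replace = TRUE)
    out <- forward_pass(idx, p, cfg, return_features = TRUE)
    expect_equal(sum(out$probabilities), 1, tolerance = 1e-9)
    expect_length(out$features, cfg$feature_dim)
    expect_equal(out$probabilities, chained_forward(idx, p, cfg),
                 tolerance = 1e-12)
  }
  idx <- c(1L, 2L, 0L, 0L, 0L)
  expect_identical(forward_pass(idx, p, cfg), forward_pass(idx, p, cfg))
})
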