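test_that("one-hot targets place a single 1 at the labeled disease", {
  expect_equal(one_hot(3, 6), c(0, 0, 1, 0, 0, 0))
  expect_equal(one_hot(1, 1), 1)
  for (L in c(2, 5, 9)) expect_equal(sum(one_hot(sample(L, 1), L)), 1)
  expect_error(one_hot(0, 6), "1..n_classes")
  expect_error(one_hot(7, 6), "1..n_classes")
})

test_that("the loss is batch squared error plus the dense-weight norm", {
  W <- matrix(c(3, 4, 0, 0), 2, 2)                 # Frobenius norm 5
  expect_equal(compute_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1), W,
                            l2_coefficient = 1), 5)
  expect_equal(compute_loss(c(0.5, 0.5), c(1, 0), W * 0, l2_coefficient = 1), 0.5)
  expect_equal(compute_loss(c(0.5, 0.5), c(1, 0), W, l2_coefficient = 1,
                            l2_squared = TRUE), 0.5 + 25)
  set.seed(4)
  for (i in 1:10) {
    P <- matrix(runif(6), 2); P <- P / rowSums(P)
    T_ <- rbind(one_hot(sample(3, 1), 3), one_hot(sample(3, 1), 3))
    expect_gte(compute_loss(P, T_, W, l2_coefficient = 0.1), 0)
  }
  expect_error(compute_loss(c(1, 0), c(1, 0, 0), W), "shape")
})

test_that("inverted dropout zeroes the stated fraction and is a no-op at inference", {
  f <- rnorm(100)
  off <- apply_dropout(f, rate = 0)
  expect_equal(off$values, f)
  expect_true(all(off$mask == 1))
  inf <- apply_dropout(f, rate = 0.9, training = FALSE)
  expect_equal(inf$values, f)

  set.seed(12)
  big <- apply_dropout(rep(1, 10000), rate = 0.5)
  frac_zero <- mean(big$mask == 0)
  expect_lt(abs(frac_zero - 0.5), 0.02)
  expect_equal(big$values[big$mask == 1], rep(2, sum(big$mask == 1)))  # 1/(1-rate)
  expect_error(apply_dropout(f, rate = 1), "rate")
})

test_that("momentum updates follow the velocity recursion exactly", {
  p <- list(w = matrix(1, 2, 2))
  g <- list(w = matrix(2, 2, 2))
  s1 <- momentum_step(p, g, NULL, learning_rate = 0.1, momentum = 0.9)
  expect_equal(s1$params$w, matrix(1 - 0.2, 2, 2))   # first step: plain SGD
  # zero gradient: velocity decays geometrically
  s2 <- momentum_step(s1$params, list(w = g$w * 0), s1$velocity, 0.1, 0.9)
  expect_equal(s2$velocity$w, matrix(-0.2 * 0.9, 2, 2))
  # two steps with constant gradient, unrolled by hand:
  # V1 = -lam*g ; w1 = w0 + V1 ; V2 = a*V1 - lam*g ; w2 = w1 + V2
  s2c <- momentum_step(s1$params, g, s1$velocity, 0.1, 0.9)
  expect_equal(s2c$velocity$w, matrix(0.9 * (-0.2) - 0.2, 2, 2))
  expect_equal(s2c$params$w, matrix(1 - 0.2 + (0.9 * (-0.2) - 0.2), 2, 2))
})

test_that("analytic gradients match central finite differences on tiny models", {
  # the full sweep (20 seeds) lives in the acceptance suite; here a quick
  # guard on one seed including the mean-pooling and squared-norm variants
  for (variant in list(list(pooling = "max", l2sq = FALSE),
                       list(pooling = "mean", l2sq = TRUE))) {
    cfg <- emrcnn_config(seq_length = 7, embedding_dim = 3,
                         kernel_heights = c(2, 3), kernels_per_height = 1,
                         n_classes = 2, init_range = 0.4,
                         pooling = variant$pooling)
    p <- init_parameters(5, cfg, seed = 31)
    set.seed(31)
    idx <- matrix(sample(0:5, 21, replace = TRUE), nrow = 3)
    tg <- one_hot_targets(sample(2, 3, replace = TRUE), 2)
    bw <- backward_pass(p, cfg, idx, tg, l2_coefficient = 1e-2,
                        l2_squared = variant$l2sq)
    err <- max_grad_check_error(p, cfg, idx, tg, bw$gradients,
                                l2_coefficient = 1e-2,
                                l2_squared = variant$l2sq, n_probe = 25)
    expect_lt(err, 1e-4)
  }
})

test_that("the regularizer's gradient touches only the dense weights", {
  cfg <- tiny_config()
  p <- init_parameters(5, cfg, seed = 2)
  set.seed(2)
  idx <- matrix(sample(0:5, 14, replace = TRUE), nrow = 2)
  tg <- one_hot_targets(c(1, 2), 2)
  g0 <- backward_pass(p, cfg, idx, tg, l2_coefficient = 0)$gradients
  g1 <- backward_pass(p, cfg, idx, tg, l2_coefficient = 10)$gradients
  expect_equal(g0$embedding, g1$embedding)
  expect_equal(g0$conv, g1$conv)
  expect_equal(g0$dense$b, g1$dense$b)
  expect_false(isTRUE(all.equal(g0$dense$W, g1$dense$W)))
})

test_that("training is reproducible and a zero learning rate freezes the model", {
  corpus <- synth_emr_corpus(n_classes = 3, records_per_class = 20,
                             doc_length_mean = 30, doc_length_sd = 5,
                             comorbid_duplicate_fraction = 0, seed = 2)
  args <- list(data = corpus, embedding_dim = 8L, kernels_per_height = 2L,
               kernel_heights = c(2L, 3L), seq_length = 40L,
               min_occurrences = 2L, epochs = 3L, batch_size = 16L,
               seed = 99L)
  f1 <- do.call(fit_emrcnn, args)
  f2 <- do.call(fit_emrcnn, args)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)

  f0 <- do.call(fit_emrcnn, c(args[-9], list(seed = 99L, learning_rate = 0,
                                             dropout_rate = 0)))
  init <- init_parameters(f0$vocab$n_indices, f0$config)
  # lr = 0: parameters keep their (seeded) initial values, loss is flat
  expect_equal(length(unique(round(f0$history$train_loss, 12))), 1L)
  g <- do.call(fit_emrcnn, c(args[-9], list(seed = 99L, learning_rate = 0,
                                            dropout_rate = 0)))
  expect_identical(f0$params, g$params)
})

test_that("a few epochs on separable text reduce the training loss", {
  corpus <- synth_emr_corpus(n_classes = 3, records_per_class = 30,
                             doc_length_mean = 40, doc_length_sd = 5,
                             keyword_rate = 0.5, comorbid_duplicate_fraction = 0,
                             seed = 6)
  # a 16-feature model: gentler step and lighter dropout suit its scale
  fit <- fit_emrcnn(corpus, embedding_dim = 12L, kernels_per_height = 8L,
                    kernel_heights = c(2L, 3L), seq_length = 50L,
                    min_occurrences = 2L, epochs = 15L, batch_size = 16L,
                    learning_rate = 0.5, dropout_rate = 0.2, seed = 5L)
  h <- fit$history
  expect_lt(h$train_loss[15], h$train_loss[1])
  expect_gt(h$train_accuracy[15], h$train_accuracy[1])
})
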