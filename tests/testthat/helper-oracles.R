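# Independent reference implementations used to cross-check the vectorized
# engine, plus small shared fixtures. Everything here is deliberately naive
# (explicit loops) so it shares no code path with the package internals.

naive_convolve <- function(x, kernel, bias = 0, stride = 1L) {
  H <- nrow(kernel); D <- ncol(kernel); N <- nrow(x)
  positions <- seq(1L, N - H + 1L, by = stride)
  out <- numeric(length(positions))
  for (t in seq_along(positions)) {
    acc <- 0
    for (i in seq_len(H)) {
      for (j in seq_len(D)) {
        acc <- acc + kernel[i, j] * x[positions[t] + i - 1L, j]
      }
    }
    out[t] <- max(0, acc + bias)
  }
  out
}

naive_pool <- function(values, window, stride = 1L, mode = "max") {
  starts <- seq(1L, length(values) - window + 1L, by = stride)
  out <- numeric(length(starts))
  for (i in seq_along(starts)) {
    w <- values[starts[i]:(starts[i] + window - 1L)]
    out[i] <- if (mode == "max") max(w) else mean(w)
  }
  out
}

# Step-by-step forward pass built only from the exported primitives, used as
# the oracle for the composed forward_pass()/engine path.
chained_forward <- function(indices, params, config) {
  X <- embed_sequence(indices, params$embedding)
  pooled <- list()
  for (H in config$kernel_heights) {
    layer <- params$conv[[paste0("h", H)]]
    for (k in seq_len(config$kernels_per_height)) {
      kern <- get_kernel(params, H, k)
      conv <- convolve_kernel(X, kern, layer$b[k], config$conv_stride)
      pooled[[length(pooled) + 1L]] <- pool_features(conv, mode = config$pooling)
    }
  }
  f <- concatenate_features(pooled)
  softmax_probs(dense_forward(f, params$dense$W, params$dense$b))
}

# Brute-force multiclass confusion counting for the metric-identity checks.
brute_counts <- function(predicted, truth, levels) {
  out <- list()
  for (cl in levels) {
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_along(truth)) {
      p_pos <- predicted[i] == cl
      t_pos <- truth[i] == cl
      if (p_pos && t_pos) tp <- tp + 1L
      else if (p_pos && !t_pos) fp <- fp + 1L
      else if (!p_pos && t_pos) fn <- fn + 1L
      else tn <- tn + 1L
    }
    out[[cl]] <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  }
  out
}

# Brute-force mean silhouette on a small matrix.
brute_silhouette <- function(X, labels) {
  labels <- as.character(labels)
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Small reusable architectures.
tiny_config <- function(...) {
  emrcnn_config(seq_length = 7L, embedding_dim = 3L, kernel_heights = c(2L, 3L),
                kernels_per_height = 2L, n_classes = 2L, init_range = 0.3, ...)
}

desk_config_args <- function() {
  list(embedding_dim = 32L, kernels_per_height = 16L)
}

# One separable-corpus training run shared by the learning-sanity and
# feature-space acceptance checks (computed on first use, then cached).
.fixture_env <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit_bundle)
  corpus <- synth_emr_corpus(seed = 7L)
  sp <- split_corpus(corpus, train_fraction = 0.9, seed = 7L)
  fit <- fit_emrcnn(sp$train, sp$test,
                    embedding_dim = 32L, kernels_per_height = 16L,
                    epochs = 30L, seed = 11L)
  .fixture_env$fit <- fit
  .fixture_env$fit_bundle <- list(fit = fit, train = sp$train, test = sp$test)
  .fixture_env$fit_bundle
}

one_hot_targets <- function(idx, L) {
  t(vapply(idx, one_hot, numeric(L), n_classes = L))
}

# Central finite-difference check of dLOSS/dtheta for randomly probed
# parameter entries; returns the largest relative error seen.
max_grad_check_error <- function(params, config, idx, targets, grads,
                                 l2_coefficient = 0, l2_squared = FALSE,
                                 n_probe = 20, h = 1e-5) {
  loss_at <- function(p) {
    emrcnn:::gradient_engine(idx, targets, p, config,
                             l2_coefficient = l2_coefficient,
                             l2_squared = l2_squared)$loss
  }
  probe_one <- function(getter, setter, g) {
    p_plus <- setter(params, h); p_minus <- setter(params, -h)
    n <- (loss_at(p_plus) - loss_at(p_minus)) / (2 * h)
    abs(g - n) / max(1e-6, abs(g), abs(n))
  }
  worst <- 0
  for (probe in seq_len(n_probe)) {
    grp <- sample(c("emb", "convW", "convb", "denseW", "denseb"), 1)
    if (grp == "emb") {
      i <- sample(2:nrow(params$embedding), 1)
      j <- sample(ncol(params$embedding), 1)
      err <- probe_one(NULL, function(p, d) { p$embedding[i, j] <- p$embedding[i, j] + d; p },
                       grads$embedding[i, j])
    } else if (grp == "convW") {
      hh <- sample(names(params$conv), 1)
      i <- sample(nrow(params$conv[[hh]]$W), 1)
      j <- sample(ncol(params$conv[[hh]]$W), 1)
      err <- probe_one(NULL, function(p, d) { p$conv[[hh]]$W[i, j] <- p$conv[[hh]]$W[i, j] + d; p },
                       grads$conv[[hh]]$W[i, j])
    } else if (grp == "convb") {
      hh <- sample(names(params$conv), 1)
      j <- sample(length(params$conv[[hh]]$b), 1)
      err <- probe_one(NULL, function(p, d) { p$conv[[hh]]$b[j] <- p$conv[[hh]]$b[j] + d; p },
                       grads$conv[[hh]]$b[j])
    } else if (grp == "denseW") {
      i <- sample(nrow(params$dense$W), 1); j <- sample(ncol(params$dense$W), 1)
      err <- probe_one(NULL, function(p, d) { p$dense$W[i, j] <- p$dense$W[i, j] + d; p },
                       grads$dense$W[i, j])
    } else {
      j <- sample(length(params$dense$b), 1)
      err <- probe_one(NULL, function(p, d) { p$dense$b[j] <- p$dense$b[j] + d; p },
                       grads$dense$b[j])
    }
    worst <- max(worst, err)
  }
  worst
}
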