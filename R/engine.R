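# Vectorized batch engine.
#
# A batch of B encoded records (B x N integer matrix, 0 = padding) is embedded
# into a (B*N) x D matrix with record-major row blocks. For each kernel height
# H the sliding windows are unrolled ("im2col") into a (B*P) x (H*D) matrix,
# so all K convolutions of that height are one matrix product. Global pooling
# reduces each record's P responses per kernel to one value; pooled features
# across heights concatenate (heights ascending, kernel index within) into the
# B x feature_dim matrix fed to the dense softmax layer.
#
# forward_engine() is inference; gradient_engine() recomputes the forward pass
# with an optional dropout mask and accumulates analytic gradients of
#   LOSS = sum_batch ||P - T||^2 + l2 * ||W_F||   (or ||W_F||^2)
# exactly as implemented, reusing per-height scratch so memory stays at one
# unrolled height at a time.

embed_batch <- function(idx_matrix, embedding) {
  flat <- as.integer(t(idx_matrix))    # record-major token stream
  if (any(flat < 0L) || any(flat > nrow(embedding) - 1L)) {
    abort("Batch contains indices outside the embedding table: vocabulary/model mismatch.")
  }
  list(x_all = embedding[flat + 1L, , drop = FALSE], flat = flat)
}

# Unrolled windows for one height: rows ordered record-major, position inner.
im2col <- function(x_all, n_records, seq_length, height, stride, emb_dim) {
  P <- conv_output_length(seq_length, height, stride)
  positions <- seq.int(1L, by = stride, length.out = P)
  base <- as.vector(outer(positions, (seq_len(n_records) - 1L) * seq_length, "+"))
  C <- matrix(0, nrow = n_records * P, ncol = height * emb_dim)
  for (i in seq_len(height)) {
    C[, ((i - 1L) * emb_dim + 1L):(i * emb_dim)] <-
      x_all[base + (i - 1L), , drop = FALSE]
  }
  list(C = C, base = base, P = P)
}

# Global pooling over the (B*P) x K activation matrix. Returns B x K pooled
# values and, for max pooling, the argmax window position per (record, kernel)
# with ties broken at the earliest position.
pool_global <- function(A, n_records, P, mode) {
  K <- ncol(A)
  Am <- matrix(A, nrow = P)            # P x (B*K); col j <-> (b, k), b inner
  if (mode == "max") {
    amax <- max.col(t(Am), ties.method = "first")
    vals <- Am[cbind(amax, seq_along(amax))]
    list(M = matrix(vals, nrow = n_records), argmax = amax)
  } else {
    list(M = matrix(colMeans(Am), nrow = n_records), argmax = NULL)
  }
}

forward_engine <- function(idx_matrix, params, config, dropout_mask = NULL,
                           dropout_rate = 0) {
  B <- nrow(idx_matrix)
  N <- config$seq_length
  D <- config$embedding_dim
  eb <- embed_batch(idx_matrix, params$embedding)
  pooled <- vector("list", length(config$kernel_heights))
  for (h in seq_along(config$kernel_heights)) {
    H <- config$kernel_heights[h]
    layer <- params$conv[[paste0("h", H)]]
    ic <- im2col(eb$x_all, B, N, H, config$conv_stride, D)
    Z <- ic$C %*% layer$W
    Z <- Z + rep(layer$b, each = nrow(Z))
    A <- relu(Z)
    pooled[[h]] <- pool_global(A, B, ic$P, config$pooling)$M
  }
  feats <- do.call(cbind, pooled)      # B x feature_dim
  fd <- feats
  if (!is.null(dropout_mask)) {
    fd <- fd * dropout_mask / (1 - dropout_rate)
  }
  Y <- fd %*% params$dense$W
  Y <- Y + rep(params$dense$b, each = B)
  list(probs = softmax_rows(Y), features = feats, scores = Y)
}

softmax_rows <- function(Y) {
  shifted <- Y - apply(Y, 1L, max)
  E <- exp(shifted)
  E / rowSums(E)
}

# Fused forward + backward over one batch. `targets` is a B x L one-hot
# matrix. Returns the batch loss (error sum + regularizer), probabilities and
# the gradient of LOSS w.r.t. every parameter array.
gradient_engine <- function(idx_matrix, targets, params, config,
                            l2_coefficient = 0, l2_squared = FALSE,
                            dropout_mask = NULL, dropout_rate = 0) {
  B <- nrow(idx_matrix)
  N <- config$seq_length
  D <- config$embedding_dim
  if (nrow(targets) != B || ncol(targets) != config$n_classes) {
    abort("Target matrix shape does not match the batch.")
  }
  eb <- embed_batch(idx_matrix, params$embedding)

  heights <- config$kernel_heights
  caches <- vector("list", length(heights))
  pooled <- vector("list", length(heights))
  for (h in seq_along(heights)) {
    H <- heights[h]
    layer <- params$conv[[paste0("h", H)]]
    ic <- im2col(eb$x_all, B, N, H, config$conv_stride, D)
    Z <- ic$C %*% layer$W
    Z <- Z + rep(layer$b, each = nrow(Z))
    A <- relu(Z)
    pg <- pool_global(A, B, ic$P, config$pooling)
    pooled[[h]] <- pg$M
    caches[[h]] <- list(C = ic$C, base = ic$base, P = ic$P, A = A,
                        argmax = pg$argmax)
  }
  feats <- do.call(cbind, pooled)
  scale <- 1
  fd <- feats
  if (!is.null(dropout_mask)) {
    scale <- 1 / (1 - dropout_rate)
    fd <- fd * dropout_mask * scale
  }
  Y <- fd %*% params$dense$W
  Y <- Y + rep(params$dense$b, each = B)
  P <- softmax_rows(Y)

  wf_norm <- sqrt(sum(params$dense$W^2))
  reg <- if (l2_squared) l2_coefficient * wf_norm^2 else l2_coefficient * wf_norm
  loss <- sum((P - targets)^2) + reg

  # d(sum of squared error)/dy through the softmax Jacobian
  e <- 2 * (P - targets)
  s <- rowSums(e * P)
  dY <- P * (e - s)                    # s recycles down rows

  d_reg <- if (l2_squared) {
    2 * l2_coefficient * params$dense$W
  } else if (wf_norm > 0) {
    l2_coefficient * params$dense$W / wf_norm
  } else {
    0 * params$dense$W
  }
  dW_f <- crossprod(fd, dY) + d_reg
  db_f <- colSums(dY)
  dF <- dY %*% t(params$dense$W)
  if (!is.null(dropout_mask)) dF <- dF * dropout_mask * scale

  K <- config$kernels_per_height
  dX_all <- matrix(0, nrow = nrow(eb$x_all), ncol = D)
  grads_conv <- vector("list", length(heights))
  for (h in seq_along(heights)) {
    H <- heights[h]
    layer <- params$conv[[paste0("h", H)]]
    ch <- caches[[h]]
    dM <- dF[, ((h - 1L) * K + 1L):(h * K), drop = FALSE]
    BP <- B * ch$P
    if (config$pooling == "max") {
      j <- seq_len(B * K)
      b_of_j <- (j - 1L) %% B
      k_of_j <- (j - 1L) %/% B
      pos <- k_of_j * BP + b_of_j * ch$P + ch$argmax
      dA <- numeric(BP * K)
      dA[pos] <- as.vector(dM)         # dM col-major == j order
      dA <- matrix(dA, nrow = BP, ncol = K)
    } else {
      dA <- matrix(rep(as.vector(dM) / ch$P, each = ch$P), nrow = BP, ncol = K)
    }
    dZ <- dA * (ch$A > 0)
    grads_conv[[h]] <- list(W = crossprod(ch$C, dZ), b = colSums(dZ))
    dC <- dZ %*% t(layer$W)
    for (i in seq_len(H)) {
      rows <- ch$base + (i - 1L)
      dX_all[rows, ] <- dX_all[rows, ] +
        dC[, ((i - 1L) * D + 1L):(i * D), drop = FALSE]
    }
    caches[h] <- list(NULL)            # free the unrolled windows
  }
  names(grads_conv) <- paste0("h", heights)

  d_emb <- matrix(0, nrow = nrow(params$embedding), ncol = D)
  agg <- rowsum(dX_all, group = eb$flat, reorder = FALSE)
  d_emb[as.integer(rownames(agg)) + 1L, ] <- agg
  if (!config$train_pad_row) d_emb[1L, ] <- 0

  list(
    loss = loss,
    probs = P,
    features = feats,
    gradients = structure(
      list(embedding = d_emb, conv = grads_conv,
           dense = list(W = dW_f, b = db_f)),
      class = "emrcnn_parameters"
    )
  )
}
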