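#' Network architecture configuration
#'
#' Collects the hyperparameters of the convolutional text classifier. The
#' defaults reproduce the reference architecture: 300-dimensional randomly
#' initialized word embeddings, convolution kernels of heights 4, 5 and 6
#' (128 kernels per height, width equal to the embedding dimension, stride 1),
#' ReLU, global max pooling (one feature per kernel, giving a 3 x 128 = 384
#' dimensional feature vector for an EMR), and a dense layer mapping to 6
#' disease scores passed through softmax.
#'
#' @param seq_length Fixed input length N in tokens.
#' @param embedding_dim Word vector dimension D.
#' @param kernel_heights Integer vector of kernel heights H.
#' @param kernels_per_height Number K of kernels for each height.
#' @param conv_stride Convolution step T_c (default 1).
#' @param pooling `"max"` (default; the pooling the feature equations define)
#'   or `"mean"`. Both pool globally over each kernel's output so each kernel
#'   contributes exactly one feature.
#' @param n_classes Number of diseases L.
#' @param init_range Half-width of the uniform initialization interval for all
#'   weights; parameters are drawn from U(-init_range, init_range).
#' @param train_pad_row Should the padding embedding row receive gradient
#'   updates? Default `FALSE`: padding carries no signal and its (zero) vector
#'   is held fixed.
#' @return An `emrcnn_config` list.
#' @export
emrcnn_config <- function(seq_length = 130L,
                          embedding_dim = 300L,
                          kernel_heights = c(4L, 5L, 6L),
                          kernels_per_height = 128L,
                          conv_stride = 1L,
                          pooling = c("max", "mean"),
                          n_classes = 6L,
                          init_range = 0.05,
                          train_pad_row = FALSE) {
  pooling <- match.arg(pooling)
  cfg <- list(
    seq_length = as.integer(seq_length),
    embedding_dim = as.integer(embedding_dim),
    kernel_heights = sort(as.integer(kernel_heights)),
    kernels_per_height = as.integer(kernels_per_height),
    conv_stride = as.integer(conv_stride),
    pooling = pooling,
    n_classes = as.integer(n_classes),
    init_range = init_range,
    train_pad_row = isTRUE(train_pad_row)
  )
  if (cfg$seq_length < 1L) abort("`seq_length` must be >= 1.")
  if (cfg$embedding_dim < 1L) abort("`embedding_dim` must be >= 1.")
  if (any(cfg$kernel_heights < 1L)) abort("kernel heights must be >= 1.")
  if (any(cfg$kernel_heights > cfg$seq_length)) {
    abort("Every kernel height must be <= `seq_length`.")
  }
  if (cfg$conv_stride < 1L) abort("`conv_stride` must be >= 1.")
  if (cfg$n_classes < 2L) abort("`n_classes` must be >= 2.")
  cfg$feature_dim <- length(cfg$kernel_heights) * cfg$kernels_per_height
  structure(cfg, class = "emrcnn_config")
}

# Number of window positions for one kernel height under the config's stride.
conv_output_length <- function(seq_length, height, stride = 1L) {
  if (height > seq_length) abort("Kernel height exceeds sequence length.")
  as.integer((seq_length - height) %/% stride + 1L)
}

#' Initialize the learnable parameters
#'
#' All weights and biases are drawn i.i.d. from U(-init_range, init_range);
#' the embedding row for the padding index is set to zero (and by default
#' excluded from updates). Kernel weights for height H are stored flattened as
#' an (H*D) x K matrix so a convolution is a single matrix product over
#' unrolled windows.
#'
#' @param vocab_size Number of distinct non-padding indices (kept tokens plus
#'   the unknown marker); the embedding matrix has `vocab_size + 1` rows, the
#'   first being the padding row.
#' @param config An [emrcnn_config()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return An `emrcnn_parameters` list: `embedding` ((V+1) x D), `conv` (one
#'   `list(W, b)` per kernel height, names `"h<height>"`), `dense`
#'   (`list(W, b)` with W of size feature_dim x L).
#' @export
init_parameters <- function(vocab_size, config, seed = NULL) {
  stopifnot(inherits(config, "emrcnn_config"))
  if (!is.null(seed)) set.seed(seed)
  r <- config$init_range
  D <- config$embedding_dim
  K <- config$kernels_per_height
  emb <- matrix(runif((vocab_size + 1L) * D, -r, r), nrow = vocab_size + 1L)
  emb[1L, ] <- 0                       # padding row
  conv <- purrr::map(config$kernel_heights, function(H) {
    list(
      W = matrix(runif(H * D * K, -r, r), nrow = H * D, ncol = K),
      b = runif(K, -r, r)
    )
  })
  names(conv) <- paste0("h", config$kernel_heights)
  dense <- list(
    W = matrix(runif(config$feature_dim * config$n_classes, -r, r),
               nrow = config$feature_dim, ncol = config$n_classes),
    b = runif(config$n_classes, -r, r)
  )
  structure(list(embedding = emb, conv = conv, dense = dense),
            class = "emrcnn_parameters")
}

#' Rectified linear unit
#'
#' @param x Numeric vector or matrix.
#' @return `max(0, x)` elementwise.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Look up embeddings for an encoded sequence
#'
#' Row i of the result is the embedding vector of the i-th token; padding
#' positions (index 0) yield the padding row.
#'
#' @param indices Integer vector of token indices (0 = padding).
#' @param embedding A (V+1) x D embedding matrix whose first row is the
#'   padding vector.
#' @return An N x D numeric matrix.
#' @export
embed_sequence <- function(indices, embedding) {
  indices <- as.integer(indices)
  if (any(indices < 0L) || any(indices > nrow(embedding) - 1L)) {
    abort("Sequence contains indices outside the embedding table: vocabulary/model mismatch.")
  }
  embedding[indices + 1L, , drop = FALSE]
}

#' Convolve one kernel over an input matrix
#'
#' Slides an H x D kernel from top to bottom of the N x D input with step
#' `stride`; at each position the response is the ReLU of the elementwise
#' product sum plus the kernel's scalar bias. The output has
#' `(N - H) %/% stride + 1` entries (equal to (N - H + 1) / stride whenever
#' the stride divides evenly).
#'
#' @param x N x D input matrix (embedded passage).
#' @param kernel H x D weight matrix.
#' @param bias Scalar bias.
#' @param stride Step size (default 1).
#' @return Numeric vector of non-negative post-ReLU responses.
#' @export
convolve_kernel <- function(x, kernel, bias = 0, stride = 1L) {
  x <- as.matrix(x); kernel <- as.matrix(kernel)
  if (ncol(kernel) != ncol(x)) {
    abort("Kernel width must equal the embedding dimension of the input.")
  }
  H <- nrow(kernel); N <- nrow(x)
  if (H > N) abort("Kernel height exceeds input length: sequence too short.")
  positions <- seq.int(1L, N - H + 1L, by = stride)
  w <- as.vector(kernel)               # column-major, matches window unroll
  out <- vapply(positions, function(t) {
    sum(as.vector(x[t:(t + H - 1L), , drop = FALSE]) * w) + bias
  }, numeric(1))
  relu(out)
}

#' Pool a convolution output
#'
#' With the default global window the entire response vector collapses to a
#' single value (its maximum, or mean for `mode = "mean"`), one feature per
#' kernel. A windowed pooling with height `window` and step `stride` is also
#' available: entry i is the pool over `window` consecutive values starting at
#' offset (i-1)*stride.
#'
#' @param values Numeric vector (one kernel's post-ReLU responses).
#' @param window Pooling window height H_p; `NULL` (default) pools globally.
#' @param stride Pooling step T_p (ignored for global pooling).
#' @param mode `"max"` or `"mean"`.
#' @return Numeric vector of pooled values.
#' @export
pool_features <- function(values, window = NULL, stride = 1L,
                          mode = c("max", "mean")) {
  mode <- match.arg(mode)
  n <- length(values)
  if (n == 0L) abort("Cannot pool an empty vector.")
  if (is.null(window)) window <- n
  window <- as.integer(window); stride <- as.integer(stride)
  if (window > n) abort("Pooling window is larger than the input.")
  if (window < 1L || stride < 1L) abort("`window` and `stride` must be >= 1.")
  starts <- seq.int(1L, n - window + 1L, by = stride)
  fun <- if (mode == "max") max else mean
  vapply(starts, function(s) fun(values[s:(s + window - 1L)]), numeric(1))
}

#' Concatenate pooled kernel features end to end
#'
#' Order is deterministic: kernel heights ascending, then kernel index within
#' a height. With the reference configuration (3 heights x 128 kernels,
#' global pooling) the result has length 384.
#'
#' @param pooled A list of numeric vectors, one per kernel, already ordered.
#' @return A single numeric feature vector.
#' @export
concatenate_features <- function(pooled) {
  if (length(pooled) == 0L) abort("No pooled features to concatenate.")
  unlist(pooled, use.names = FALSE)
}

#' Dense layer forward pass
#'
#' @param features Feature vector F.
#' @param weights feature_dim x L weight matrix W_F.
#' @param bias Length-L bias vector b_f.
#' @return Length-L score vector y = t(W_F) %*% F + b_f.
#' @export
dense_forward <- function(features, weights, bias) {
  if (length(features) != nrow(weights)) {
    abort("Feature vector length does not match the dense layer input size.")
  }
  as.vector(crossprod(weights, features)) + bias
}

#' Softmax class probabilities
#'
#' Numerically stable (max-shifted) exponential normalization of a score
#' vector into a probability distribution over diseases.
#'
#' @param scores Numeric score vector y.
#' @return Probability vector summing to 1.
#' @export
softmax_probs <- function(scores) {
  if (any(!is.finite(scores))) abort("Softmax requires finite scores.")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Full forward pass for one encoded record
#'
#' Chains embedding lookup, per-height convolutions with ReLU, global pooling,
#' feature concatenation, the dense layer and softmax. Used for inspection and
#' single-record prediction; batched inference and training use the same
#' arithmetic via the internal vectorized engine.
#'
#' @param indices Integer vector of length `config$seq_length` (0 = padding).
#' @param params An [init_parameters()] object.
#' @param config The matching [emrcnn_config()].
#' @param return_features If `TRUE`, also return the pre-dense feature vector.
#' @return A list with `probabilities` (length L, sums to 1) and, when
#'   requested, `features` (length `config$feature_dim`).
#' @export
forward_pass <- function(indices, params, config, return_features = FALSE) {
  stopifnot(inherits(params, "emrcnn_parameters"),
            inherits(config, "emrcnn_config"))
  if (length(indices) != config$seq_length) {
    abort("Encoded sequence length does not match `config$seq_length`.")
  }
  out <- forward_engine(matrix(as.integer(indices), nrow = 1L), params, config)
  res <- list(probabilities = as.vector(out$probs))
  if (return_features) res$features <- as.vector(out$features)
  res
}

#' Retrieve one convolution kernel as an H x D matrix
#'
#' Kernels are stored flattened ((H*D) x K per height, window row varying
#' slowest) so a whole height's convolutions run as one matrix product; this
#' accessor rebuilds the conventional H x D view of a single kernel for
#' inspection or hand computation.
#'
#' @param params An [init_parameters()] object.
#' @param height Kernel height H (must be one of the configured heights).
#' @param k Kernel index within that height.
#' @return An H x D numeric matrix.
#' @export
get_kernel <- function(params, height, k) {
  layer <- params$conv[[paste0("h", height)]]
  if (is.null(layer)) abort("No kernels of that height in the model.")
  matrix(layer$W[, k], nrow = height, byrow = TRUE)
}
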