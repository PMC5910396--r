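#' One-hot target vector
#'
#' @param label_index 1-based class index of the diagnosed disease.
#' @param n_classes Number of diseases L.
#' @return Numeric vector of length `n_classes` with a single 1.
#' @export
#' @examples
#' one_hot(3, 6)
one_hot <- function(label_index, n_classes) {
  label_index <- as.integer(label_index)
  n_classes <- as.integer(n_classes)
  if (label_index < 1L || label_index > n_classes) {
    abort("`label_index` must lie in 1..n_classes.")
  }
  out <- numeric(n_classes)
  out[label_index] <- 1
  out
}

one_hot_matrix <- function(label_indices, n_classes) {
  out <- matrix(0, nrow = length(label_indices), ncol = n_classes)
  out[cbind(seq_along(label_indices), as.integer(label_indices))] <- 1
  out
}

#' Training loss: batch squared error plus L2 regularizer
#'
#' The error term sums, over the batch, the squared Euclidean distance between
#' the predicted probability vector and the one-hot target. The regularizer is
#' the L2 (Frobenius) norm of the dense-layer weight matrix scaled by
#' `l2_coefficient`; set `l2_squared = TRUE` for the conventional squared-norm
#' variant.
#'
#' @param probs B x L matrix (or length-L vector) of predicted probabilities.
#' @param targets Matching one-hot matrix (or vector).
#' @param dense_weights The dense layer weight matrix W_F.
#' @param l2_coefficient Nonnegative regularization coefficient.
#' @param l2_squared Use `||W_F||^2` instead of `||W_F||`.
#' @return Scalar loss.
#' @export
compute_loss <- function(probs, targets, dense_weights,
                         l2_coefficient = 1e-3, l2_squared = FALSE) {
  probs <- rbind(probs); targets <- rbind(targets)
  if (!all(dim(probs) == dim(targets))) {
    abort("`probs` and `targets` must have matching shapes.")
  }
  if (l2_coefficient < 0) abort("`l2_coefficient` must be nonnegative.")
  nrm <- sqrt(sum(dense_weights^2))
  reg <- if (l2_squared) l2_coefficient * nrm^2 else l2_coefficient * nrm
  sum((probs - targets)^2) + reg
}

#' Inverted dropout on a feature vector
#'
#' In training mode each entry is zeroed independently with probability
#' `rate` and the survivors are scaled by 1/(1-rate), so the expected
#' activation is unchanged and no rescaling is needed at inference. Outside
#' training the input passes through untouched.
#'
#' @param features Numeric vector or matrix.
#' @param rate Dropout probability in [0, 1).
#' @param training Logical; dropout only applies when `TRUE`.
#' @return List with `values` and the binary `mask` used.
#' @export
apply_dropout <- function(features, rate, training = TRUE) {
  if (rate < 0 || rate >= 1) abort("`rate` must lie in [0, 1).")
  if (!training || rate == 0) {
    mask <- features * 0 + 1
    return(list(values = features, mask = mask))
  }
  mask <- (runif(length(features)) >= rate) * 1
  if (is.matrix(features)) mask <- matrix(mask, nrow(features), ncol(features))
  list(values = features * mask / (1 - rate), mask = mask)
}

#' Gradients of the training loss for one batch
#'
#' Computes, by backpropagation, the exact derivative of the batch loss (see
#' [compute_loss()]) with respect to every parameter array: the embedding rows
#' touched by the batch, each kernel bank and its biases, and the dense
#' weights and bias. When a dropout rate is given, a fresh mask is drawn (from
#' the current RNG state) for the forward pass and the same mask is used on
#' the way back.
#'
#' @param params An [init_parameters()] object.
#' @param config The matching [emrcnn_config()].
#' @param idx_matrix B x N integer matrix of encoded records.
#' @param targets B x L one-hot matrix ([one_hot()] rows).
#' @param l2_coefficient,l2_squared Regularizer, see [compute_loss()].
#' @param dropout_rate Dropout probability on the feature vector (0 disables).
#' @return List with `loss`, `probs`, `features` and `gradients` (a list
#'   mirroring the parameter structure, holding dLOSS/dtheta).
#' @export
backward_pass <- function(params, config, idx_matrix, targets,
                          l2_coefficient = 1e-3, l2_squared = FALSE,
                          dropout_rate = 0) {
  mask <- NULL
  if (dropout_rate > 0) {
    mask <- matrix((runif(nrow(idx_matrix) * config$feature_dim) >=
                      dropout_rate) * 1,
                   nrow = nrow(idx_matrix), ncol = config$feature_dim)
  }
  gradient_engine(idx_matrix, targets, params, config,
                  l2_coefficient = l2_coefficient, l2_squared = l2_squared,
                  dropout_mask = mask, dropout_rate = dropout_rate)
}

#' One momentum SGD update
#'
#' Applies the classical momentum recursion to every parameter array:
#' `V <- momentum * V - learning_rate * g` followed by `w <- w + V`, where `g`
#' is the batch-averaged gradient. With zero velocity this reduces to a plain
#' gradient step of size `learning_rate`.
#'
#' @param params Parameter list.
#' @param gradients Batch-averaged gradients, same structure as `params`.
#' @param velocity Momentum state, same structure (zeros to start), or `NULL`.
#' @param learning_rate Step size lambda.
#' @param momentum Momentum factor alpha in (0, 1].
#' @return List with updated `params` and `velocity`.
#' @export
momentum_step <- function(params, gradients, velocity = NULL,
                          learning_rate = 0.01, momentum = 0.9) {
  if (is.null(velocity)) velocity <- zero_like(params)
  step <- function(w, g, v) {
    v_new <- momentum * v - learning_rate * g
    list(w = w + v_new, v = v_new)
  }
  upd_layer <- function(w, g, v) {
    if (is.list(w)) {
      out <- purrr::pmap(list(w, g, v), upd_layer)
      list(w = purrr::map(out, "w"), v = purrr::map(out, "v"))
    } else {
      step(w, g, v)
    }
  }
  out <- upd_layer(unclass(params), unclass(gradients), unclass(velocity))
  list(params = structure(out$w, class = class(params)), velocity = out$v)
}

zero_like <- function(params) {
  rapply(unclass(params), function(x) x * 0, how = "replace")
}

scale_gradients <- function(gradients, factor) {
  rapply(unclass(gradients), function(x) x * factor, how = "replace")
}

#' Fit the convolutional diagnosis model
#'
#' End-to-end training on a tibble of EMR records: tokenizes the text fields,
#' builds the frequency-filtered vocabulary (unless one is supplied), encodes
#' every record to a fixed length, initializes the network, and runs
#' mini-batch momentum SGD on the squared-error-plus-L2 loss with dropout on
#' the feature vector. Each epoch shuffles the training set, then records the
#' mean per-record training loss, training accuracy, and (when `test_data` is
#' given) test accuracy. The whole run is reproducible from `seed`.
#'
#' @param data Training records: a data frame with the text columns, a label
#'   column, and optionally `record_id`.
#' @param test_data Optional held-out records evaluated once per epoch.
#' @param text_cols,label_col,segmenter Passed to [encode_corpus()].
#' @param vocab Optional pre-built [build_vocabulary()] vocabulary; by default
#'   one is built from the training text with `min_occurrences`.
#' @param min_occurrences Vocabulary frequency threshold (default 6: a token
#'   must appear more than five times).
#' @param config An [emrcnn_config()]; by default the reference architecture
#'   with `n_classes` set from the training labels.
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size.
#' @param learning_rate,momentum Momentum SGD hyperparameters. The default
#'   step size of 1 matches the scale of the squared-error-on-softmax loss,
#'   whose per-parameter gradients are orders of magnitude smaller than
#'   cross-entropy gradients; much smaller steps leave the softmax stuck near
#'   uniform for tens of epochs.
#' @param dropout_rate Dropout probability on the 384-dim feature vector.
#' @param l2_coefficient,l2_squared Regularizer, see [compute_loss()].
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @param verbose Print a one-line summary per epoch.
#' @param ... Arguments forwarded to [emrcnn_config()] when `config` is NULL.
#' @return An object of class `emrcnn`: parameters, vocabulary, config, label
#'   levels, and a per-epoch `history` tibble (`epoch`, `train_loss`,
#'   `train_accuracy`, `test_accuracy`).
#' @export
fit_emrcnn <- function(data,
                       test_data = NULL,
                       text_cols = c("chief_complaint",
                                     "present_illness_history",
                                     "physical_exam"),
                       label_col = "label",
                       segmenter = whitespace_segmenter,
                       vocab = NULL,
                       min_occurrences = 6L,
                       config = NULL,
                       epochs = 30L,
                       batch_size = 64L,
                       learning_rate = 1,
                       momentum = 0.9,
                       dropout_rate = 0.5,
                       l2_coefficient = 1e-3,
                       l2_squared = FALSE,
                       seed = 1L,
                       verbose = FALSE,
                       ...) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0L) abort("Training set is empty.")
  set.seed(seed)

  if (is.null(vocab)) {
    passages <- collapse_record_text(data, text_cols)
    vocab <- build_vocabulary(tokenize_text(passages, segmenter),
                              min_occurrences = min_occurrences)
  }
  labels <- factor(data[[label_col]])
  if (is.null(config)) {
    config <- emrcnn_config(n_classes = nlevels(labels), ...)
  }
  if (nlevels(labels) != config$n_classes) {
    abort("`config$n_classes` does not match the number of label levels.")
  }

  enc <- encode_corpus(data, vocab, target_length = config$seq_length,
                       text_cols = text_cols, label_col = label_col,
                       segmenter = segmenter)
  enc$labels <- labels                 # keep the training-level order
  enc_test <- NULL
  if (!is.null(test_data)) {
    test_data <- tibble::as_tibble(test_data)
    enc_test <- encode_corpus(test_data, vocab,
                              target_length = config$seq_length,
                              text_cols = text_cols, label_col = label_col,
                              segmenter = segmenter)
    enc_test$labels <- factor(test_data[[label_col]], levels = levels(labels))
  }

  params <- init_parameters(vocab$n_indices, config)
  velocity <- NULL
  n <- nrow(enc$indices)
  targets_all <- one_hot_matrix(as.integer(enc$labels), config$n_classes)

  history <- vector("list", epochs)
  for (epoch in seq_len(epochs)) {
    perm <- sample.int(n)
    epoch_err <- 0
    for (start in seq.int(1L, n, by = batch_size)) {
      take <- perm[start:min(start + batch_size - 1L, n)]
      bw <- backward_pass(params, config,
                          enc$indices[take, , drop = FALSE],
                          targets_all[take, , drop = FALSE],
                          l2_coefficient = l2_coefficient,
                          l2_squared = l2_squared,
                          dropout_rate = dropout_rate)
      epoch_err <- epoch_err + bw$loss
      upd <- momentum_step(params,
                           scale_gradients(bw$gradients, 1 / length(take)),
                           velocity, learning_rate, momentum)
      params <- upd$params
      velocity <- upd$velocity
    }
    train_acc <- batch_accuracy(enc, params, config)
    test_acc <- if (is.null(enc_test)) NA_real_ else {
      batch_accuracy(enc_test, params, config)
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_loss = epoch_err / n,
      train_accuracy = train_acc,
      test_accuracy = test_acc
    )
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  train acc %.3f  test acc %s\n",
                  epoch, epoch_err / n, train_acc,
                  ifelse(is.na(test_acc), "-", sprintf("%.3f", test_acc))))
    }
  }

  structure(
    list(
      params = params,
      vocab = vocab,
      config = config,
      label_levels = levels(labels),
      history = dplyr::bind_rows(history),
      text_cols = text_cols,
      label_col = label_col,
      segmenter = segmenter,
      training = list(epochs = epochs, batch_size = batch_size,
                      learning_rate = learning_rate, momentum = momentum,
                      dropout_rate = dropout_rate,
                      l2_coefficient = l2_coefficient,
                      l2_squared = l2_squared, seed = seed)
    ),
    class = "emrcnn"
  )
}

# Inference over an emr_encoded set in manageable chunks; argmax accuracy.
batch_accuracy <- function(enc, params, config, chunk = 256L) {
  pred <- predict_encoded(enc$indices, params, config, chunk = chunk)$class_idx
  mean(pred == as.integer(enc$labels))
}

predict_encoded <- function(idx_matrix, params, config, chunk = 256L,
                            return_features = FALSE) {
  n <- nrow(idx_matrix)
  probs <- matrix(NA_real_, n, config$n_classes)
  feats <- if (return_features) matrix(NA_real_, n, config$feature_dim)
  for (start in seq.int(1L, n, by = chunk)) {
    take <- start:min(start + chunk - 1L, n)
    out <- forward_engine(idx_matrix[take, , drop = FALSE], params, config)
    probs[take, ] <- out$probs
    if (return_features) feats[take, ] <- out$features
  }
  # argmax with deterministic lowest-index tie-break
  class_idx <- max.col(probs, ties.method = "first")
  list(probs = probs, class_idx = class_idx, features = feats)
}

#' @export
print.emrcnn <- function(x, ...) {
  cfg <- x$config
  cat("<emrcnn> convolutional diagnosis model\n")
  cat("  vocabulary: ", length(x$vocab$token_to_index), " tokens + unk\n",
      sep = "")
  cat("  input: ", cfg$seq_length, " tokens x ", cfg$embedding_dim,
      "-dim embeddings\n", sep = "")
  cat("  kernels: heights {", paste(cfg$kernel_heights, collapse = ", "),
      "} x ", cfg$kernels_per_height, " -> ", cfg$feature_dim,
      "-dim feature (", cfg$pooling, " pooling)\n", sep = "")
  cat("  classes: ", paste(x$label_levels, collapse = ", "), "\n", sep = "")
  h <- x$history
  if (nrow(h) > 0) {
    last <- h[nrow(h), ]
    cat(sprintf("  trained %d epochs; final train acc %.3f%s\n",
                nrow(h), last$train_accuracy,
                ifelse(is.na(last$test_accuracy), "",
                       sprintf(", test acc %.3f", last$test_accuracy))))
  }
  invisible(x)
}

#' Predict diagnoses for new records
#'
#' @param object A fitted [fit_emrcnn()] model.
#' @param new_data A data frame of records with the model's text columns.
#' @param type `"class"` for the top diagnosis, `"prob"` for per-disease
#'   probabilities, `"both"` for both.
#' @param ... Unused.
#' @return A tibble with `record_id`, `.pred_class` (factor) and, when
#'   requested, one `.pred_<label>` probability column per disease (rows sum
#'   to 1).
#' @export
predict.emrcnn <- function(object, new_data,
                           type = c("both", "class", "prob"), ...) {
  type <- match.arg(type)
  enc <- encode_corpus(new_data, object$vocab,
                       target_length = object$config$seq_length,
                       text_cols = object$text_cols, label_col = NULL,
                       segmenter = object$segmenter)
  out <- predict_encoded(enc$indices, object$params, object$config)
  res <- tibble::tibble(record_id = enc$record_id)
  if (type %in% c("class", "both")) {
    res$.pred_class <- factor(object$label_levels[out$class_idx],
                              levels = object$label_levels)
  }
  if (type %in% c("prob", "both")) {
    probs <- tibble::as_tibble(out$probs, .name_repair = "minimal")
    names(probs) <- paste0(".pred_", object$label_levels)
    res <- dplyr::bind_cols(res, probs)
  }
  res
}

#' @export
#' @method tidy emrcnn
tidy.emrcnn <- function(x, ...) {
  x$history
}

#' @export
#' @method glance emrcnn
glance.emrcnn <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  n_params <- sum(rapply(unclass(x$params), length, how = "unlist"))
  tibble::tibble(
    epochs = nrow(x$history),
    train_loss = last$train_loss,
    train_accuracy = last$train_accuracy,
    test_accuracy = last$test_accuracy,
    n_parameters = n_params,
    feature_dim = x$config$feature_dim,
    n_classes = x$config$n_classes
  )
}
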