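#' Extract per-record feature vectors
#'
#' Runs the forward pass with dropout disabled and captures each record's
#' feature vector as produced by the pooling/concatenation stage, before the
#' dense layer — the representation in which records of the same disease
#' cluster as training progresses. Model parameters are never modified.
#'
#' @param object A fitted [fit_emrcnn()] model (or a checkpoint with the same
#'   structure).
#' @param data Records to featurize; label column optional.
#' @param epoch_tag Optional string recording which checkpoint produced the
#'   table (stored as an attribute).
#' @return A tibble with `record_id`, `label` (NA when unlabeled) and feature
#'   columns `f001`, `f002`, ... (one per feature dimension, 384 in the
#'   reference configuration).
#' @export
extract_features <- function(object, data, epoch_tag = NULL) {
  stopifnot(inherits(object, "emrcnn"))
  data <- tibble::as_tibble(data)
  has_label <- object$label_col %in% names(data)
  enc <- encode_corpus(data, object$vocab,
                       target_length = object$config$seq_length,
                       text_cols = object$text_cols,
                       label_col = if (has_label) object$label_col else NULL,
                       segmenter = object$segmenter)
  out <- predict_encoded(enc$indices, object$params, object$config,
                         return_features = TRUE)
  feats <- tibble::as_tibble(out$features, .name_repair = "minimal")
  names(feats) <- sprintf("f%03d", seq_len(ncol(feats)))
  res <- dplyr::bind_cols(
    tibble::tibble(
      record_id = enc$record_id,
      label = if (has_label) as.character(enc$labels) else NA_character_
    ),
    feats
  )
  attr(res, "epoch_tag") <- epoch_tag
  res
}

feature_matrix <- function(table) {
  cols <- grep("^f\\d+$", names(table), value = TRUE)
  if (length(cols) == 0L) abort("No feature columns (f001, f002, ...) found.")
  as.matrix(table[, cols])
}

#' Project a feature table to two dimensions with t-SNE
#'
#' Delegates to the Barnes-Hut t-SNE implementation in \pkg{Rtsne} with a
#' fixed seed. The perplexity is capped at the largest value the sample size
#' admits; the values used are recorded as attributes for reproducibility.
#'
#' @param table A feature tibble from [extract_features()] (or any data frame
#'   with `f...` feature columns and optional `record_id`/`label`).
#' @param seed Integer seed for the embedding.
#' @param perplexity t-SNE perplexity (default 30, capped at (n-1)/3).
#' @param ... Further arguments passed to [Rtsne::Rtsne()].
#' @return A tibble of class `emrcnn_projection` with `record_id`, `label`,
#'   `dim1`, `dim2`; attributes `perplexity` and `seed` record the settings.
#' @export
project_2d <- function(table, seed = 1L, perplexity = 30, ...) {
  X <- feature_matrix(table)
  n <- nrow(X)
  if (n < 3L) abort("Need at least 3 records to project.")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  set.seed(seed)
  emb <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity,
                      check_duplicates = FALSE, pca = FALSE, ...)
  res <- tibble::tibble(
    record_id = table$record_id %||% as.character(seq_len(n)),
    label = as.character(table$label %||% NA_character_),
    dim1 = emb$Y[, 1],
    dim2 = emb$Y[, 2]
  )
  attr(res, "perplexity") <- perplexity
  attr(res, "seed") <- seed
  class(res) <- c("emrcnn_projection", class(res))
  res
}

#' Class-separation score of a feature table
#'
#' The mean silhouette coefficient of the records under their disease labels,
#' with Euclidean distance in the native feature space. Near 1 when each
#' disease forms a tight, well-separated cluster; near 0 when labels are
#' unrelated to feature geometry. Invariant to global rotation and
#' translation of the features.
#'
#' @param table A feature tibble from [extract_features()].
#' @param labels Optional label vector; defaults to the table's `label`
#'   column.
#' @return Mean silhouette width (scalar in [-1, 1]).
#' @export
separation_score <- function(table, labels = NULL) {
  X <- feature_matrix(table)
  labels <- labels %||% table$label
  if (is.null(labels)) abort("No labels available for the separation score.")
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2L) {
    abort("Separation score needs at least two classes.")
  }
  sil <- cluster::silhouette(as.integer(labels), stats::dist(X))
  mean(sil[, "sil_width"])
}

#' Plot a 2-D projection of the disease feature space
#'
#' @param object An [project_2d()] projection.
#' @param ... Unused.
#' @return A ggplot object: one point per record, colored by diagnosis.
#' @export
#' @method autoplot emrcnn_projection
autoplot.emrcnn_projection <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$dim1, .data$dim2, colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8, size = 1.5) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = "diagnosis",
                  title = "Feature space of medical records") +
    ggplot2::theme_minimal()
}

#' Plot training curves
#'
#' Training loss and train/test accuracy per epoch, in the style of standard
#' convergence diagnostics.
#'
#' @param object A fitted [fit_emrcnn()] model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot emrcnn
autoplot.emrcnn <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "value")
  h <- dplyr::filter(h, !is.na(.data$value))
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training history") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
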