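#' Generate a synthetic labeled EMR corpus
#'
#' Emulates the statistical shape of a de-identified clinical corpus for
#' desk-scale testing: short multi-class documents (6 diseases by default)
#' whose tokens are drawn from a shared background vocabulary except that,
#' with probability `keyword_rate`, a token comes from the record's
#' disease-specific keyword pool (pools are disjoint across diseases).
#' Document lengths are drawn from a clipped normal around 130 tokens so both
#' the padding and the truncation paths of the encoder are exercised, the
#' tokens are split across the three standard text fields (chief complaint,
#' history of present illness, physical examination), and a small fraction of
#' records is cloned verbatim under a different diagnosis — the multi-disease
#' patients whose identical text legitimately carries two labels. Tokens are
#' opaque symbols (`w0042`, `k3_07`), so whitespace tokenization applies.
#'
#' @param n_classes Number of diseases (default 6).
#' @param records_per_class Records generated per disease before cloning.
#' @param background_vocab_size Size of the shared background vocabulary.
#' @param keywords_per_class Disease-specific keyword pool size.
#' @param keyword_rate Probability that a token is a class keyword; 0 makes
#'   the text label-independent (chance-level control), 0.5 gives a strongly
#'   separable corpus.
#' @param doc_length_mean,doc_length_sd Token-count distribution (clipped
#'   normal, minimum 10 tokens).
#' @param comorbid_duplicate_fraction Fraction of records cloned with a
#'   different label (default 0.024, matching roughly 2.4% of records in a
#'   real multi-diagnosis clinical corpus).
#' @param seed Integer seed; the corpus is a deterministic function of it.
#' @return A tibble with `record_id`, `chief_complaint`,
#'   `present_illness_history`, `physical_exam`, `label`.
#' @export
synth_emr_corpus <- function(n_classes = 6L,
                             records_per_class = 100L,
                             background_vocab_size = 800L,
                             keywords_per_class = 20L,
                             keyword_rate = 0.5,
                             doc_length_mean = 130,
                             doc_length_sd = 25,
                             comorbid_duplicate_fraction = 0.024,
                             seed = 1L) {
  if (n_classes < 2L || records_per_class < 1L) {
    abort("Need at least 2 classes and 1 record per class.")
  }
  if (keyword_rate < 0 || keyword_rate > 1) {
    abort("`keyword_rate` must lie in [0, 1].")
  }
  if (comorbid_duplicate_fraction < 0 || comorbid_duplicate_fraction >= 1) {
    abort("`comorbid_duplicate_fraction` must lie in [0, 1).")
  }
  set.seed(seed)
  background <- sprintf("w%04d", seq_len(background_vocab_size))
  keyword_pools <- purrr::map(seq_len(n_classes), function(cl) {
    sprintf("k%d_%02d", cl, seq_len(keywords_per_class))
  })
  labels <- paste0("disease_", seq_len(n_classes))

  n <- n_classes * records_per_class
  cls <- rep(seq_len(n_classes), each = records_per_class)
  lengths <- pmax(10L, round(rnorm(n, doc_length_mean, doc_length_sd)))

  records <- purrr::map(seq_len(n), function(i) {
    len <- lengths[i]
    from_pool <- runif(len) < keyword_rate
    toks <- character(len)
    toks[!from_pool] <- sample(background, sum(!from_pool), replace = TRUE)
    toks[from_pool] <- sample(keyword_pools[[cls[i]]], sum(from_pool),
                              replace = TRUE)
    # split the passage across the three fields: complaint is short, the
    # history carries about half, the exam the rest
    n_cc <- max(1L, round(0.15 * len))
    n_hpi <- max(1L, round(0.50 * len))
    cc <- toks[seq_len(min(n_cc, len))]
    hpi <- if (n_cc < len) toks[(n_cc + 1L):min(n_cc + n_hpi, len)] else character(0)
    pe <- if (n_cc + n_hpi < len) toks[(n_cc + n_hpi + 1L):len] else character(0)
    tibble::tibble(
      chief_complaint = paste(cc, collapse = " "),
      present_illness_history = paste(hpi, collapse = " "),
      physical_exam = paste(pe, collapse = " "),
      label = labels[cls[i]]
    )
  })
  corpus <- dplyr::bind_rows(records)

  n_dup <- round(comorbid_duplicate_fraction * n)
  if (n_dup > 0L) {
    dup_idx <- sample.int(n, n_dup)
    dups <- corpus[dup_idx, ]
    dups$label <- purrr::map_chr(dups$label, function(l) {
      sample(setdiff(labels, l), 1L)
    })
    corpus <- dplyr::bind_rows(corpus, dups)
  }
  corpus$record_id <- sprintf("rec%05d", seq_len(nrow(corpus)))
  corpus[, c("record_id", "chief_complaint", "present_illness_history",
             "physical_exam", "label")]
}

#' Stratified train/test split
#'
#' Splits a labeled corpus into disjoint training and test sets preserving
#' per-class proportions (each class contributes `round(n_class *
#' train_fraction)` records to the training set, at least one record to each
#' side).
#'
#' @param corpus A labeled record tibble.
#' @param train_fraction Fraction assigned to training, strictly in (0, 1).
#' @param seed Integer seed.
#' @param label_col Name of the label column.
#' @return A list with tibbles `train` and `test`.
#' @export
split_corpus <- function(corpus, train_fraction = 0.9, seed = 1L,
                         label_col = "label") {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  corpus <- tibble::as_tibble(corpus)
  set.seed(seed)
  labels <- as.character(corpus[[label_col]])
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    abort("Every class needs at least 2 records to split.")
  }
  train_idx <- unlist(purrr::map(names(sizes), function(cl) {
    idx <- which(labels == cl)
    n_train <- min(max(1L, round(length(idx) * train_fraction)),
                   length(idx) - 1L)
    sample(idx, n_train)
  }), use.names = FALSE)
  list(train = corpus[sort(train_idx), ],
       test = corpus[-sort(train_idx), ])
}
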