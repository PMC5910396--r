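#' Whitespace segmenter
#'
#' The default segmenter: splits on runs of whitespace. Clinical Chinese text
#' needs a real word segmenter (e.g. jieba run externally, or any function
#' mapping a string to a character vector of tokens); synthetic corpora and
#' most tests use whitespace-delimited opaque tokens, for which this suffices.
#'
#' @param text A character scalar.
#' @return Character vector of tokens (empty for empty input).
#' @export
#' @examples
#' whitespace_segmenter("acute chest pain")
whitespace_segmenter <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  strsplit(trimws(text), "\\s+")[[1]]
}

#' Tokenize free text with a pluggable segmenter
#'
#' Applies `segmenter` to each element of `text` and strips empty tokens from
#' its output. The segmenter is any function taking one string and returning
#' an ordered character vector of tokens, so an external Chinese word
#' segmenter can be dropped in without touching the rest of the pipeline.
#'
#' @param text Character vector of passages.
#' @param segmenter Function: string -> character vector of tokens.
#' @return A list of character vectors, one per input passage.
#' @export
#' @examples
#' tokenize_text(c("fever and cough", ""))
tokenize_text <- function(text, segmenter = whitespace_segmenter) {
  stopifnot(is.function(segmenter))
  purrr::map(as.character(text), function(s) {
    if (is.na(s)) s <- ""
    toks <- segmenter(s)
    toks <- as.character(toks)
    toks[nzchar(toks)]
  })
}

#' Build a frequency-filtered vocabulary
#'
#' Counts token occurrences across a corpus and keeps every token whose count
#' is at least `min_occurrences`; all other tokens are represented by a single
#' unknown marker. The default threshold of 6 keeps words appearing more than
#' five times. Index 0 is reserved for padding and never assigned to a token;
#' real tokens get indices 1, 2, ... assigned deterministically (descending
#' count, ties broken lexicographically), and the unknown marker receives the
#' next index after all kept tokens.
#'
#' @param token_lists A list of character vectors (output of [tokenize_text()]).
#' @param min_occurrences Minimum corpus count for a token to keep its own
#'   index (default 6).
#' @param unk_token The unknown-word marker string.
#' @return An object of class `emr_vocabulary`: a list with `token_to_index`
#'   (named integer vector), `unk_token`, `unk_index`, `pad_index` (always 0),
#'   `min_occurrences`, and `n_indices` (number of distinct non-pad indices,
#'   i.e. kept tokens + unk).
#' @export
build_vocabulary <- function(token_lists, min_occurrences = 6L,
                             unk_token = "<unk>") {
  stopifnot(is.list(token_lists))
  min_occurrences <- as.integer(min_occurrences)
  if (min_occurrences < 1L) abort("`min_occurrences` must be >= 1.")
  all_tokens <- unlist(token_lists, use.names = FALSE)
  if (length(all_tokens) == 0L) {
    abort("Cannot build a vocabulary from an empty corpus.")
  }
  counts <- table(all_tokens)
  kept <- counts[counts >= min_occurrences]
  # descending count, lexicographic tie-break => reproducible index map
  ord <- order(-as.integer(kept), names(kept), method = "radix")
  kept_tokens <- names(kept)[ord]
  if (unk_token %in% kept_tokens) {
    abort("The unknown marker collides with a corpus token; choose another `unk_token`.")
  }
  token_to_index <- setNames(seq_along(kept_tokens), kept_tokens)
  unk_index <- length(kept_tokens) + 1L
  structure(
    list(
      token_to_index = token_to_index,
      unk_token = unk_token,
      unk_index = unk_index,
      pad_index = 0L,
      min_occurrences = min_occurrences,
      n_indices = unk_index
    ),
    class = "emr_vocabulary"
  )
}

#' @export
print.emr_vocabulary <- function(x, ...) {
  cat("<emr_vocabulary>\n")
  cat("  kept tokens: ", length(x$token_to_index),
      " (count >= ", x$min_occurrences, ")\n", sep = "")
  cat("  unk '", x$unk_token, "' -> index ", x$unk_index,
      "; pad -> index 0\n", sep = "")
  invisible(x)
}

#' Encode a token list as a fixed-length integer sequence
#'
#' Maps tokens to their vocabulary indices (unknown tokens to the unk index),
#' right-pads with 0 up to `target_length`, and truncates longer passages by
#' keeping the first `target_length` tokens — the head of the record (chief
#' complaint first) carries the most diagnostic signal.
#'
#' @param tokens Character vector of tokens for one record.
#' @param vocab An [build_vocabulary()] object.
#' @param target_length Fixed sequence length N (default 130).
#' @return Integer vector of length `target_length` with attribute
#'   `n_real_tokens` (number of non-padding positions).
#' @export
encode_tokens <- function(tokens, vocab, target_length = 130L) {
  stopifnot(inherits(vocab, "emr_vocabulary"))
  target_length <- as.integer(target_length)
  if (target_length < 1L) abort("`target_length` must be >= 1.")
  tokens <- as.character(tokens)
  if (length(tokens) > target_length) tokens <- tokens[seq_len(target_length)]
  idx <- unname(vocab$token_to_index[tokens])
  idx[is.na(idx)] <- vocab$unk_index
  n_real <- length(idx)
  out <- integer(target_length)        # zero-filled: pad index
  if (n_real > 0L) out[seq_len(n_real)] <- idx
  attr(out, "n_real_tokens") <- n_real
  out
}

# Concatenate the record's text fields into one passage, chief complaint first.
collapse_record_text <- function(data, text_cols) {
  missing_cols <- setdiff(text_cols, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("Missing text column(s): ", paste(missing_cols, collapse = ", ")))
  }
  parts <- purrr::map(text_cols, function(col) {
    v <- as.character(data[[col]])
    v[is.na(v)] <- ""
    v
  })
  txt <- do.call(paste, c(parts, sep = " "))
  trimws(txt)
}

#' Encode a corpus tibble into a model-ready matrix
#'
#' Concatenates the configured text fields of each record (chief complaint,
#' then history of present illness, then physical examination by default),
#' tokenizes, and encodes every record to a fixed length. This is the bridge
#' between the tabular record representation and the network input.
#'
#' @param data A data frame of records (one row per EMR).
#' @param vocab An [build_vocabulary()] vocabulary.
#' @param target_length Fixed sequence length N (default 130).
#' @param text_cols Character vector naming the text columns, in concatenation
#'   order.
#' @param label_col Name of the diagnosis label column, or `NULL` for
#'   unlabeled data.
#' @param segmenter Tokenizer function, see [tokenize_text()].
#' @return A list of class `emr_encoded`: `indices` (n x N integer matrix,
#'   0 = padding), `n_real_tokens` (integer vector), `labels` (factor or
#'   `NULL`), `record_id` (character).
#' @export
encode_corpus <- function(data, vocab, target_length = 130L,
                          text_cols = c("chief_complaint",
                                        "present_illness_history",
                                        "physical_exam"),
                          label_col = "label",
                          segmenter = whitespace_segmenter) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0L) abort("`data` has no records.")
  passages <- collapse_record_text(data, text_cols)
  token_lists <- tokenize_text(passages, segmenter)
  encoded <- purrr::map(token_lists, encode_tokens, vocab = vocab,
                        target_length = target_length)
  indices <- do.call(rbind, purrr::map(encoded, as.integer))
  labels <- NULL
  if (!is.null(label_col)) {
    if (!label_col %in% names(data)) {
      abort(paste0("Label column '", label_col, "' not found in `data`."))
    }
    labels <- factor(data[[label_col]])
  }
  record_id <- if ("record_id" %in% names(data)) {
    as.character(data$record_id)
  } else {
    as.character(seq_len(nrow(data)))
  }
  structure(
    list(
      indices = indices,
      n_real_tokens = purrr::map_int(encoded, ~ attr(.x, "n_real_tokens")),
      labels = labels,
      record_id = record_id
    ),
    class = "emr_encoded"
  )
}
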