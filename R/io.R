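#' Read EMR records from JSON-lines or delimited files
#'
#' The native format is JSON-lines (one UTF-8 JSON object per line with keys
#' `record_id`, `chief_complaint`, `present_illness_history`,
#' `physical_exam`, `label`); comma- and tab-delimited files are also
#' accepted. A column mapping adapts other layouts without code changes:
#' `col_map = c(chief_complaint = "zs", label = "diagnosis")` renames the
#' file's `zs` and `diagnosis` columns to the standard names.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"jsonl"`, `"csv"`, or `"tsv"`.
#' @param col_map Optional named character vector, `standard_name =
#'   "file_column"`.
#' @return A tibble of records.
#' @export
read_emr_records <- function(path, format = c("auto", "jsonl", "csv", "tsv"),
                             col_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("Dataset not found: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     jsonl = , ndjson = , json = "jsonl",
                     csv = "csv",
                     tsv = , tab = "tsv",
                     "jsonl")
  }
  data <- switch(format,
    jsonl = tibble::as_tibble(
      jsonlite::stream_in(file(path, encoding = "UTF-8"), verbose = FALSE)),
    csv = readr::read_csv(path, show_col_types = FALSE),
    tsv = readr::read_tsv(path, show_col_types = FALSE))
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(data))
    if (length(missing_src) > 0L) {
      abort(paste0("Column(s) named in `col_map` not in the file: ",
                   paste(missing_src, collapse = ", ")))
    }
    for (std in names(col_map)) names(data)[names(data) == col_map[[std]]] <- std
  }
  data
}

#' Write EMR records as JSON-lines
#'
#' @param data Record tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_emr_records <- function(data, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(data), con, verbose = FALSE)
  invisible(path)
}

#' Serialize a vocabulary to JSON
#'
#' Stores the token-to-index map together with its metadata (frequency
#' threshold, padding and unknown-token conventions) so encodings are
#' reproducible across sessions.
#'
#' @param vocab An [build_vocabulary()] vocabulary.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "emr_vocabulary"))
  jsonlite::write_json(
    list(
      token_to_index = as.list(vocab$token_to_index),
      unk_token = vocab$unk_token,
      unk_index = vocab$unk_index,
      pad_index = vocab$pad_index,
      min_occurrences = vocab$min_occurrences
    ),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a serialized vocabulary
#'
#' @param path JSON file written by [write_vocabulary()].
#' @return An `emr_vocabulary` object.
#' @export
read_vocabulary <- function(path) {
  raw <- jsonlite::read_json(path)
  tti <- unlist(raw$token_to_index)
  structure(
    list(
      token_to_index = setNames(as.integer(tti), names(tti)),
      unk_token = raw$unk_token,
      unk_index = as.integer(raw$unk_index),
      pad_index = as.integer(raw$pad_index),
      min_occurrences = as.integer(raw$min_occurrences),
      n_indices = as.integer(raw$unk_index)
    ),
    class = "emr_vocabulary"
  )
}

#' Save / load a fitted model
#'
#' The archive holds every parameter array, the vocabulary, the architecture
#' configuration, label names and the training history — everything needed to
#' reload the model and reproduce its forward passes bit for bit.
#'
#' @param object A fitted [fit_emrcnn()] model.
#' @param path Archive file (RDS).
#' @return `save_emrcnn()`: `path` invisibly; `load_emrcnn()`: the model.
#' @export
save_emrcnn <- function(object, path) {
  stopifnot(inherits(object, "emrcnn"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_emrcnn
#' @export
load_emrcnn <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "emrcnn")) abort("File is not a saved emrcnn model.")
  object
}

#' Write the per-epoch training history as CSV
#'
#' Columns `epoch`, `train_loss`, `train_accuracy`, `test_accuracy` — the
#' inputs for a standard training-curve figure.
#'
#' @param object A fitted [fit_emrcnn()] model.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_history <- function(object, path) {
  stopifnot(inherits(object, "emrcnn"))
  readr::write_csv(object$history, path)
  invisible(path)
}
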