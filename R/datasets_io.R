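#' Construct a labeled dataset
#'
#' The universal input container: a samples x features real matrix together
#' with one class label per sample. Labels are opaque strings (stage names
#' like `"PanIN-1"` survive verbatim; no numeric coercion).
#'
#' @param X numeric matrix, samples in rows.
#' @param y character vector of class labels, one per row of `X`.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to rownames of `X` or `sample_1..N`.
#' @param labels ordered character vector of the distinct class labels;
#'   defaults to order of first appearance in `y`.
#' @return An object of class `labeled_dataset` with fields `X`, `y`,
#'   `sample_ids`, `labels`.
#' @examples
#' d <- labeled_dataset(matrix(rnorm(12), 6, 2), rep(c("a", "b"), each = 3))
#' d
#' @export
labeled_dataset <- function(X, y, sample_ids = NULL, labels = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.character(y)
  if (nrow(X) != length(y))
    stop2("nrow(X) (", nrow(X), ") != length(y) (", length(y), ")")
  if (anyNA(X)) stop2("X contains missing values")
  if (anyNA(y)) stop2("y contains missing labels")
  if (is.null(sample_ids)) sample_ids <- rownames(X) %||% paste0("sample_", seq_len(nrow(X)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(X)) stop2("sample_ids length mismatch")
  if (anyDuplicated(sample_ids)) stop2("duplicate sample id: ",
                                       sample_ids[duplicated(sample_ids)][1])
  if (is.null(labels)) labels <- unique(y)
  labels <- as.character(labels)
  if (!all(y %in% labels)) stop2("labels in y missing from label set: ",
                                 paste(setdiff(y, labels), collapse = ", "))
  if (!all(labels %in% y)) stop2("label without samples: ",
                                 paste(setdiff(labels, y), collapse = ", "))
  rownames(X) <- sample_ids
  structure(list(X = X, y = y, sample_ids = sample_ids, labels = labels),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", nrow(x$X), "samples x", ncol(x$X), "features,",
      length(x$labels), "classes\n")
  cat("classes:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

.delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a labeled dataset from delimited text
#'
#' Reads a numeric matrix (first row and first column are identifiers) and a
#' two-column label table (`sample_id`, `label`), matching samples by
#' identifier. Samples present in only one of the two files are dropped with
#' a warning. The default orientation is samples-in-columns, matching the
#' GEO series-matrix convention.
#'
#' @param matrix_path path to a TSV/CSV numeric matrix with header.
#' @param labels_path path to a TSV/CSV table with columns
#'   `sample_id`, `label`.
#' @param orientation `"samples_in_columns"` (default) or
#'   `"samples_in_rows"`.
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(matrix_path, labels_path,
                         orientation = c("samples_in_columns", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  m <- utils::read.delim(matrix_path, sep = .delim_for(matrix_path),
                         header = TRUE, row.names = 1L,
                         check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(m)) {
    if (!is.numeric(m[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(m[[j]]))) & !is.na(m[[j]]))[1]
      stop2("non-numeric cell in matrix column '", colnames(m)[j], "'",
            if (!is.na(bad)) paste0(", row '", rownames(m)[bad], "'"))
    }
  }
  m <- as.matrix(m)
  if (anyNA(m)) stop2("matrix contains missing values")
  if (orientation == "samples_in_columns") m <- t(m)
  lab <- utils::read.delim(labels_path, sep = .delim_for(labels_path),
                           header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(lab)))
    stop2("label table must have columns sample_id, label")
  ids_m <- rownames(m)
  ids_l <- as.character(lab$sample_id)
  if (anyDuplicated(ids_m)) stop2("duplicate sample id in matrix: ",
                                  ids_m[duplicated(ids_m)][1])
  if (anyDuplicated(ids_l)) stop2("duplicate sample id in label table: ",
                                  ids_l[duplicated(ids_l)][1])
  common <- intersect(ids_m, ids_l)
  if (length(common) == 0L) stop2("zero samples shared between matrix and label table")
  dropped <- c(setdiff(ids_m, ids_l), setdiff(ids_l, ids_m))
  if (length(dropped)) {
    warning(length(dropped), " sample(s) present in only one input dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...", call. = FALSE)
  }
  lab <- lab[match(common, ids_l), , drop = FALSE]
  labeled_dataset(m[common, , drop = FALSE], lab$label, sample_ids = common)
}

#' Write a labeled dataset as delimited text
#'
#' Inverse of [read_dataset()]: writes the matrix (full double precision)
#' and the label table so that a read round-trip reproduces the dataset.
#'
#' @param dataset a [labeled_dataset()].
#' @param matrix_path,labels_path output paths (`.csv` switches to comma).
#' @param orientation matrix layout to write (default samples-in-columns).
#' @export
write_dataset <- function(dataset, matrix_path, labels_path,
                          orientation = c("samples_in_columns", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(dataset, "labeled_dataset"))
  m <- dataset$X
  if (is.null(colnames(m))) colnames(m) <- paste0("feature_", seq_len(ncol(m)))
  if (orientation == "samples_in_columns") m <- t(m)
  df <- data.frame(id = rownames(m), format(m, digits = 17, trim = TRUE,
                                            scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- ""
  utils::write.table(df, matrix_path, sep = .delim_for(matrix_path),
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = dataset$sample_ids, label = dataset$y),
    labels_path, sep = .delim_for(labels_path), quote = FALSE,
    row.names = FALSE)
  invisible(dataset)
}

#' Pipeline configuration
#'
#' Bundles the tunables of the screening pipeline. `theta`, the tolerated
#' per-class misclassification fraction when placing thresholds, is always
#' derived as `1 - min_sensitivity` (sensitivity floor in `[0.5, 1]`).
#'
#' @param min_sensitivity minimal class-wise sensitivity, in `[0.5, 1]`.
#' @param projection_pairs `"all"`, `"most_distant"`, or a list of
#'   2-element character vectors.
#' @param max_order_length maximal suborder length screened (`NULL` = all
#'   classes).
#' @param report_reversed keep both orientations of mirror-image suborders.
#' @param seed integer seed driving all randomness.
#' @return An object of class `run_config`.
#' @export
run_config <- function(min_sensitivity = 1, projection_pairs = "all",
                       max_order_length = NULL, report_reversed = FALSE,
                       seed = 1L) {
  if (!is.numeric(min_sensitivity) || length(min_sensitivity) != 1L ||
      min_sensitivity < 0.5 || min_sensitivity > 1)
    stop2("min_sensitivity must be a single value in [0.5, 1]")
  structure(list(min_sensitivity = min_sensitivity,
                 theta = 1 - min_sensitivity,
                 projection_pairs = projection_pairs,
                 max_order_length = max_order_length,
                 report_reversed = isTRUE(report_reversed),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config: min_sensitivity =", x$min_sensitivity,
      "(theta =", format(x$theta), "), seed =", x$seed, "\n")
  invisible(x)
}
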