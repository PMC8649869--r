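#' Construct a count matrix with sample metadata
#'
#' The central container of the pipeline: a features x samples matrix of
#' non-negative counts (or non-negative reals once normalized), together with
#' a per-sample metadata table (arm, replicate, group) and an optional
#' per-feature table mapping shRNA ids to gene symbols.
#'
#' @param counts Numeric matrix, features in rows and samples in columns. Row
#'   and column names are required and must be unique.
#' @param samples Optional data.frame with one row per sample; must contain a
#'   `sample` column matching `colnames(counts)`. Typical extra columns are
#'   `arm`, `replicate` and `group`. Defaults to a bare sample table.
#' @param features Optional data.frame with one row per feature; must contain
#'   a `feature_id` column matching `rownames(counts)`. A `gene` column, when
#'   present, is used for gene-level aggregation.
#' @param normalized Logical flag; `TRUE` marks the values as library-size
#'   normalized (e.g. CPM) rather than raw counts.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `samples`, `features` and `normalized`.
#' @export
count_matrix <- function(counts, samples = NULL, features = NULL,
                         normalized = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort_validation("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_validation("counts must have row (feature) and column (sample) names")
  if (anyDuplicated(rownames(counts)))
    abort_validation("feature ids must be unique")
  if (anyDuplicated(colnames(counts)))
    abort_validation("sample ids must be unique")
  if (any(!is.finite(counts)) || any(counts < 0))
    abort_validation("counts must be finite and non-negative")
  if (is.null(samples)) {
    samples <- data.frame(sample = colnames(counts),
                          stringsAsFactors = FALSE)
  }
  if (!"sample" %in% names(samples))
    abort_validation("samples table must have a 'sample' column")
  if (!setequal(samples$sample, colnames(counts)) ||
      anyDuplicated(samples$sample))
    abort_validation("samples table must match the matrix columns one-to-one")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(features)) {
    if (!"feature_id" %in% names(features))
      abort_validation("features table must have a 'feature_id' column")
    if (!setequal(features$feature_id, rownames(counts)) ||
        anyDuplicated(features$feature_id))
      abort_validation("features table must match the matrix rows one-to-one")
    features <- features[match(rownames(counts), features$feature_id), ,
                         drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(counts = counts, samples = samples, features = features,
                 normalized = isTRUE(normalized)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "normalized" else "raw counts"))
  if (!is.null(x$features) && "gene" %in% names(x$features))
    cat(sprintf("  %d genes\n", length(unique(x$features$gene))))
  cat("  samples:", paste(utils::head(x$samples$sample, 6), collapse = ", "),
      if (ncol(x$counts) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Counts-per-million normalization
#'
#' Rescales every sample (column) to a total of one million, the conventional
#' library-size correction applied before depletion scoring.
#'
#' @param cm A raw `count_matrix`.
#' @return A `count_matrix` flagged as normalized, each column summing to 1e6.
#' @export
cpm_normalize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- colSums(cm$counts)
  zero <- totals <= 0
  if (any(zero))
    abort_validation(sprintf("sample(s) with zero total count: %s",
                             paste(colnames(cm$counts)[zero], collapse = ", ")))
  out <- sweep(cm$counts, 2, 1e6 / totals, `*`)
  count_matrix(out, samples = cm$samples, features = cm$features,
               normalized = TRUE)
}

#' Write / read a count matrix as TSV plus sample sheet
#'
#' Counts go to a TSV whose first column (`feature_id`) holds feature ids and
#' remaining columns one sample each; sample metadata goes to a companion
#' sample-sheet TSV with at least a `sample` column.
#'
#' @param cm A `count_matrix`.
#' @param counts_path Path of the counts TSV.
#' @param samples_path Optional path of the sample sheet TSV.
#' @param features_path Optional path of the feature (shRNA -> gene) table.
#' @return `write_counts` invisibly returns the paths written; `read_counts`
#'   returns a `count_matrix`.
#' @export
write_counts <- function(cm, counts_path, samples_path = NULL,
                         features_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(samples_path))
    utils::write.table(cm$samples, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(features_path) && !is.null(cm$features))
    utils::write.table(cm$features, features_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(counts_path, samples_path, features_path))
}

#' @rdname write_counts
#' @param normalized Flag passed through to [count_matrix()] when reading.
#' @export
read_counts <- function(counts_path, samples_path = NULL,
                        features_path = NULL, normalized = FALSE) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort_io(sprintf("no sample columns in %s", counts_path))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  samples <- if (!is.null(samples_path))
    utils::read.delim(samples_path, stringsAsFactors = FALSE) else NULL
  features <- if (!is.null(features_path))
    utils::read.delim(features_path, stringsAsFactors = FALSE) else NULL
  count_matrix(m, samples = samples, features = features,
               normalized = normalized)
}
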