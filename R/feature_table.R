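#' Radiomic feature table
#'
#' The container every pipeline stage operates on: a samples x features
#' numeric matrix plus per-sample metadata (scanner batch, outcome, clinical
#' covariates) and per-feature metadata (modality, family, shape flag).
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   Row and column names, when present, must agree with the metadata ids.
#' @param sample_meta data.frame with at least `sample_id` and `batch`;
#'   optionally `outcome` (values `"pCR"` / `"non-pCR"`), `ER`, `PR`, `HER2`
#'   coded 0/1. Row order must match the rows of `values`.
#' @param feature_meta data.frame with at least `feature_id`, `modality`
#'   (`"CT"` or `"PET"`) and `is_shape` (0/1). Row order must match the
#'   columns of `values`.
#' @param feature_type provenance tag, e.g. `"raw"`, `"OR"`, `"TLR"`.
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, sample_meta, feature_meta,
                          feature_type = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.data.frame(sample_meta), is.data.frame(feature_meta))
  if (!"sample_id" %in% names(sample_meta))
    stop("sample_meta must contain a 'sample_id' column")
  if (!"batch" %in% names(sample_meta))
    stop("sample_meta must contain a 'batch' column")
  if (!"feature_id" %in% names(feature_meta))
    stop("feature_meta must contain a 'feature_id' column")
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  feature_meta$feature_id <- as.character(feature_meta$feature_id)
  if (nrow(values) != nrow(sample_meta))
    stop("values has ", nrow(values), " rows but sample_meta has ",
         nrow(sample_meta))
  if (ncol(values) != nrow(feature_meta))
    stop("values has ", ncol(values), " columns but feature_meta has ",
         nrow(feature_meta))
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicate sample_ids in sample_meta")
  if (anyDuplicated(feature_meta$feature_id))
    stop("duplicate feature_ids in feature_meta")
  if (!all(is.finite(values)))
    stop("values must be finite")
  if (!is.null(rownames(values)) &&
      !identical(rownames(values), sample_meta$sample_id))
    stop("rownames(values) disagree with sample_meta$sample_id")
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), feature_meta$feature_id))
    stop("colnames(values) disagree with feature_meta$feature_id")
  rownames(values) <- sample_meta$sample_id
  colnames(values) <- feature_meta$feature_id
  structure(
    list(values = values, sample_meta = sample_meta,
         feature_meta = feature_meta, feature_type = feature_type),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> [", x$feature_type, "] ",
      nrow(x$values), " samples x ", ncol(x$values), " features\n", sep = "")
  cat("  batches: ", paste(names(table(x$sample_meta$batch)),
                           table(x$sample_meta$batch),
                           sep = ":", collapse = ", "), "\n", sep = "")
  if ("outcome" %in% names(x$sample_meta))
    cat("  outcome: ", paste(names(table(x$sample_meta$outcome)),
                             table(x$sample_meta$outcome),
                             sep = ":", collapse = ", "), "\n", sep = "")
  mod <- table(x$feature_meta$modality)
  cat("  modality: ", paste(names(mod), mod, sep = ":", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table
#'
#' @param x a `feature_table`.
#' @param i sample index (integer, logical, or sample_id character vector).
#' @param j feature index (integer, logical, or feature_id character vector).
#' @param ... unused.
#' @return a `feature_table` restricted to the selected samples/features.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$sample_meta$sample_id)
  if (is.character(j)) j <- match(j, x$feature_meta$feature_id)
  if (anyNA(i)) stop("unknown sample_id in subset")
  if (anyNA(j)) stop("unknown feature_id in subset")
  feature_table(x$values[i, j, drop = FALSE],
                x$sample_meta[i, , drop = FALSE],
                x$feature_meta[j, , drop = FALSE],
                feature_type = x$feature_type)
}

#' Outcome labels as a 0/1 vector
#'
#' @param table a `feature_table` whose `sample_meta` has an `outcome` column.
#' @return integer vector, 1 for `"pCR"`, 0 for `"non-pCR"`.
#' @export
outcome01 <- function(table) {
  if (!"outcome" %in% names(table$sample_meta))
    stop("feature_table has no outcome column")
  out <- table$sample_meta$outcome
  bad <- setdiff(unique(as.character(out)), c("pCR", "non-pCR"))
  if (length(bad))
    stop("unexpected outcome levels: ", paste(bad, collapse = ", "))
  as.integer(as.character(out) == "pCR")
}

#' Write a feature table to CSV files
#'
#' Writes `<prefix>.csv` (sample_id first column, then one column per
#' feature), `<prefix>_samples.csv` (the sample metadata) and
#' `<prefix>_features.csv` (feature_id, modality, family, is_shape).
#'
#' @param table a `feature_table`.
#' @param prefix path prefix (directory must exist).
#' @return invisibly, the paths written.
#' @export
write_feature_table <- function(table, prefix) {
  vals <- data.frame(sample_id = table$sample_meta$sample_id,
                     table$values, check.names = FALSE)
  paths <- paste0(prefix, c(".csv", "_samples.csv", "_features.csv"))
  utils::write.csv(vals, paths[1], row.names = FALSE)
  utils::write.csv(table$sample_meta, paths[2], row.names = FALSE)
  utils::write.csv(table$feature_meta, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param prefix path prefix used at write time.
#' @param feature_type provenance tag to attach.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(prefix, feature_type = "raw") {
  vals <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  sm <- utils::read.csv(paste0(prefix, "_samples.csv"))
  fm <- utils::read.csv(paste0(prefix, "_features.csv"))
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- as.character(vals$sample_id)
  feature_table(m, sm, fm, feature_type = feature_type)
}
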