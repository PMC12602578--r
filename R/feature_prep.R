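#' Intraclass correlation coefficient ICC(2,1) per feature for two replicates
#'
#' Two-way random effects, absolute agreement, single rater — the standard
#' form for radiomics test-retest reproducibility. Computed per feature
#' (column) from the two replicate measurements of every sample.
#'
#' @param a,b numeric matrices, samples x features, identically indexed.
#' @return numeric vector of ICC values (NA where the denominator is zero).
#' @export
icc21 <- function(a, b) {
  n <- nrow(a)
  k <- 2
  grand <- (colMeans(a) + colMeans(b)) / 2
  row_mean <- (a + b) / 2
  msr <- k * colSums(sweep(row_mean, 2, grand)^2) / (n - 1)
  msc <- n * ((colMeans(a) - grand)^2 + (colMeans(b) - grand)^2) / (k - 1)
  resid_a <- sweep(a - row_mean, 2, colMeans(a) - grand)
  resid_b <- sweep(b - row_mean, 2, colMeans(b) - grand)
  mse <- (colSums(resid_a^2) + colSums(resid_b^2)) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  out <- (msr - mse) / denom
  out[abs(denom) < .Machine$double.eps * 100] <- NA_real_
  out
}

#' Reproducibility filter: retain features with all pairwise ICCs above a cut
#'
#' Three replicate segmentations (two readers, one reading twice) give three
#' replicate pairs; each feature's ICC(2,1) is computed for every pair and
#' the feature is retained only when all three exceed `threshold`. Features
#' with an undefined ICC in any pair (zero variance) are dropped with a
#' warning.
#'
#' @param rep_a,rep_b,rep_c `feature_table`s sharing identical samples and
#'   features.
#' @param threshold retention cut in (0, 1); 0.75 is the conventional
#'   "good reproducibility" cut.
#' @return an `icc_report` list: `icc` (data.frame with per-pair ICCs and the
#'   minimum), `retained` (feature_id character vector), `threshold`.
#' @export
icc_filter <- function(rep_a, rep_b, rep_c, threshold = 0.75) {
  stopifnot(threshold > 0, threshold < 1)
  ids <- rep_a$feature_meta$feature_id
  sids <- rep_a$sample_meta$sample_id
  for (r in list(rep_b, rep_c)) {
    if (!identical(r$feature_meta$feature_id, ids) ||
        !identical(r$sample_meta$sample_id, sids))
      stop("replicate tables are not aligned on identical samples/features")
  }
  icc_ab <- icc21(rep_a$values, rep_b$values)
  icc_ac <- icc21(rep_a$values, rep_c$values)
  icc_bc <- icc21(rep_b$values, rep_c$values)
  icc_min <- pmin(icc_ab, icc_ac, icc_bc)
  undef <- is.na(icc_min)
  if (any(undef))
    warning(sum(undef), " feature(s) with undefined ICC (zero variance) ",
            "dropped")
  retained <- ids[!undef & icc_min > threshold]
  structure(list(icc = data.frame(feature_id = ids, icc_ab = icc_ab,
                                  icc_ac = icc_ac, icc_bc = icc_bc,
                                  icc_min = icc_min),
                 retained = retained, threshold = threshold),
            class = "icc_report")
}

#' @export
print.icc_report <- function(x, ...) {
  cat("<icc_report> ", length(x$retained), "/", nrow(x$icc),
      " features retained at min pairwise ICC > ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Redundancy pruning by pairwise Pearson correlation
#'
#' Greedy, order-deterministic: features are visited in column order and a
#' feature is dropped when its absolute Pearson correlation with any
#' already-kept feature exceeds `r_max`. Constant features have undefined
#' correlations; these are treated as 0 (never pruned for correlation) and
#' reported via a message.
#'
#' @param table a `feature_table` with at least two samples.
#' @param r_max correlation cut in (0, 1).
#' @return the table restricted to kept features.
#' @export
correlation_prune <- function(table, r_max = 0.9) {
  stopifnot(r_max > 0, r_max < 1, nrow(table$values) >= 2)
  v <- table$values
  sds <- apply(v, 2, stats::sd)
  const <- sds == 0
  if (any(const))
    message(sum(const), " constant feature(s): correlation undefined, ",
            "treated as 0")
  cm <- suppressWarnings(abs(stats::cor(v)))
  cm[!is.finite(cm)] <- 0
  p <- ncol(v)
  kept <- logical(p)
  for (j in seq_len(p)) {
    kept[j] <- !any(cm[j, kept] > r_max)
  }
  table[, which(kept)]
}

#' Assemble the origin-radiomics (OR) feature set
#'
#' CT and PET tumor features combined as-is; an identity pass tagged `"OR"`.
#'
#' @param ct_pet_tumor a `feature_table` containing both modalities.
#' @return the same table tagged `"OR"`.
#' @export
assemble_or <- function(ct_pet_tumor) {
  mods <- unique(ct_pet_tumor$feature_meta$modality)
  if (!all(c("CT", "PET") %in% mods))
    stop("OR assembly requires both CT and PET features; found only: ",
         paste(mods, collapse = ", "))
  out <- ct_pet_tumor
  out$feature_type <- "OR"
  out
}

#' Assemble the tumor-to-liver-ratio (TLR) feature set
#'
#' Each PET intensity (non-shape) tumor feature is divided elementwise by its
#' same-named liver counterpart, cancelling the per-patient global uptake
#' factor that SUV-derived features share; PET shape/volume features and all
#' CT features pass through unchanged. A feature whose liver denominator is
#' smaller than `eps` in magnitude for any sample is excluded from the TLR
#' set entirely (reported via a message).
#'
#' @param tumor tumor `feature_table` (CT + PET).
#' @param liver liver `feature_table` with a same-named counterpart for every
#'   PET non-shape tumor feature, on the same samples.
#' @param eps minimum admissible |denominator|.
#' @return a `feature_table` tagged `"TLR"`.
#' @export
assemble_tlr <- function(tumor, liver, eps = 1e-12) {
  if (!identical(tumor$sample_meta$sample_id, liver$sample_meta$sample_id))
    stop("tumor and liver tables are not aligned on the same samples")
  fm <- tumor$feature_meta
  pet_int <- fm$modality == "PET" & fm$is_shape == 0
  missing <- setdiff(fm$feature_id[pet_int], liver$feature_meta$feature_id)
  if (length(missing))
    stop("missing liver counterpart for PET feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  vals <- tumor$values
  drop <- character(0)
  for (f in fm$feature_id[pet_int]) {
    denom <- liver$values[, f]
    if (any(abs(denom) < eps)) {
      drop <- c(drop, f)
    } else {
      vals[, f] <- vals[, f] / denom
    }
  }
  if (length(drop))
    message(length(drop), " PET feature(s) excluded from TLR ",
            "(near-zero liver denominator)")
  keep <- !fm$feature_id %in% drop
  out <- feature_table(vals[, keep, drop = FALSE],
                       tumor$sample_meta, fm[keep, , drop = FALSE],
                       feature_type = "TLR")
  out
}
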