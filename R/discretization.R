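#' Post-extraction feature discretization
#'
#' Discretizes extracted feature values (not image voxels) to integer bins
#' `1..n`, either by fixed bin number (FBN: equal-frequency, rank-based) or
#' fixed bin width (FBW: equal-range). For a feature A with value A(x) for
#' sample x:
#'
#' * FBN: `y = ceil(n * (Rank(A(x)) - 1) / (Counta(A) - 1))`, with `y = 1`
#'   when `A(x) = min(A)`; ranks are ascending competition ranks (tied values
#'   share the smallest ordinal), so ties never straddle a bin boundary.
#' * FBW: `y = ceil(n * (A(x) - min(A)) / (max(A) - min(A)))`, with `y = 1`
#'   when `A(x) = min(A)`; a constant feature (max = min) maps wholly to 1.
#'
#' A tolerance of 1e-12 is subtracted before the ceiling so floating-point
#' noise at an exact bin boundary cannot promote a value to the next bin.
#'
#' @name discretization
NULL

ceil_tol <- function(z) pmax(1L, as.integer(ceiling(z - 1e-12)))

fbn_bins <- function(x, n) {
  y <- rep(1L, length(x))
  mn <- min(x)
  nn <- length(x)
  if (nn >= 2) {
    r <- rank(x, ties.method = "min")
    sel <- x != mn
    y[sel] <- ceil_tol(n * (r[sel] - 1) / (nn - 1))
  }
  pmin(y, as.integer(n))
}

fbw_bins <- function(x, n, mn = min(x), mx = max(x)) {
  y <- rep(1L, length(x))
  if (mx > mn) {
    sel <- x != mn
    y[sel] <- ceil_tol(n * (x[sel] - mn) / (mx - mn))
  }
  pmin(pmax(y, 1L), as.integer(n))
}

#' Fixed-bin-number (equal-frequency) discretization
#'
#' @param table a `feature_table`.
#' @param n number of bins (>= 1); 32 and 64 are the conventional choices.
#' @return list with `table` (integer bins in `[1, n]`) and `model`
#'   (a `discretizer_model` usable with [discretize_apply()]).
#' @export
fbn_fit_transform <- function(table, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a single integer >= 1")
  v <- table$values
  out <- apply(v, 2, fbn_bins, n = n)
  dimnames(out) <- dimnames(v)
  model <- structure(
    list(method = "FBN", n = as.integer(n),
         feature_ids = colnames(v),
         sorted = apply(v, 2, sort, simplify = FALSE),
         counta = nrow(v)),
    class = "discretizer_model")
  new_table <- table
  new_table$values <- out
  list(table = new_table, model = model)
}

#' Fixed-bin-width (equal-range) discretization
#'
#' @inheritParams fbn_fit_transform
#' @return list with `table` and `model`, as for [fbn_fit_transform()].
#' @export
fbw_fit_transform <- function(table, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a single integer >= 1")
  v <- table$values
  mins <- apply(v, 2, min)
  maxs <- apply(v, 2, max)
  out <- v
  for (j in seq_len(ncol(v)))
    out[, j] <- fbw_bins(v[, j], n, mins[j], maxs[j])
  model <- structure(
    list(method = "FBW", n = as.integer(n), feature_ids = colnames(v),
         min = mins, max = maxs),
    class = "discretizer_model")
  new_table <- table
  new_table$values <- out
  list(table = new_table, model = model)
}

#' Fit a discretizer by method name
#'
#' @param table a `feature_table`.
#' @param method `"none"`, `"FBN"` or `"FBW"`.
#' @param n bin count (ignored for `"none"`).
#' @return list with `table` and `model`.
#' @export
discretize_fit_transform <- function(table, method = c("none", "FBN", "FBW"),
                                     n = 32) {
  method <- match.arg(method)
  switch(method,
         none = list(table = table,
                     model = structure(list(method = "none"),
                                       class = "discretizer_model")),
         FBN = fbn_fit_transform(table, n),
         FBW = fbw_fit_transform(table, n))
}

#' Apply a fitted discretizer to new samples (leakage-safe)
#'
#' FBW bins with the stored training min/max, clipping outputs into
#' `[1, n]`. FBN interpolates each new value's rank against the stored sorted
#' training values — the competition rank of the largest training value not
#' exceeding it (below-minimum maps to bin 1, above-maximum to bin n) — and
#' applies the formula with the training `Counta(A)`.
#'
#' @param model a `discretizer_model`.
#' @param table a `feature_table` containing every fitted feature.
#' @return the discretized `feature_table`.
#' @export
discretize_apply <- function(model, table) {
  stopifnot(inherits(model, "discretizer_model"))
  if (model$method == "none") return(table)
  miss <- setdiff(colnames(table$values), model$feature_ids)
  if (length(miss))
    stop("feature(s) not fitted by the discretizer: ",
         paste(utils::head(miss, 5), collapse = ", "))
  v <- table$values
  out <- v
  n <- model$n
  for (j in seq_len(ncol(v))) {
    f <- colnames(v)[j]
    x <- v[, j]
    if (model$method == "FBW") {
      out[, j] <- fbw_bins(x, n, model$min[[f]], model$max[[f]])
    } else {
      s <- model$sorted[[f]]
      nn <- model$counta
      y <- rep(1L, length(x))
      for (i in seq_along(x)) {
        if (x[i] <= s[1] || nn < 2) { y[i] <- 1L; next }
        if (x[i] > s[nn]) { y[i] <- as.integer(n); next }
        pos <- findInterval(x[i], s)          # largest training value <= x
        r <- match(s[pos], s)                 # its competition rank
        y[i] <- min(ceil_tol(n * (r - 1) / (nn - 1)), as.integer(n))
      }
      out[, j] <- y
    }
  }
  new_table <- table
  new_table$values <- out
  new_table
}
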