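#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' `(#{pos > neg} + 0.5 * #{pos = neg}) / (n_pos * n_neg)`, computed via
#' midranks.
#'
#' @param scores numeric prediction scores, higher = more positive.
#' @param labels 0/1 vector, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  if (m == 0 || n == 0)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

# midrank placements per DeLong's structural components:
# V10[i] = (1/n) * sum_j [ I(x_i > y_j) + 0.5 I(x_i = y_j) ], and dually V01
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x)
  n <- length(y)
  tz <- rank(c(x, y))
  tx <- rank(x)
  ty <- rank(y)
  v10 <- (tz[seq_len(m)] - tx) / n
  v01 <- 1 - (tz[m + seq_len(n)] - ty) / m
  list(auc = (sum(tz[seq_len(m)]) - m * (m + 1) / 2) / (m * n),
       v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong's test for two correlated AUCs
#'
#' Fast structural-components (midrank) algorithm for two classifiers scored
#' on the same samples; the paired covariance of the placement vectors enters
#' the variance of the AUC difference, and p-values come from the normal
#' approximation. Identical score vectors give zero estimated variance; the
#' comparison is then flagged degenerate with `z = 0`, `p = 1`.
#'
#' @param scores_1,scores_2 numeric score vectors on identical samples.
#' @param labels 0/1 outcome vector.
#' @return an `auc_comparison` list: `auc_1`, `auc_2`, `z`, `p` (two-sided),
#'   `p_less`/`p_greater` (one-sided), `var_diff`, `s10`/`s01` covariance
#'   components, `degenerate`.
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  stopifnot(length(scores_1) == length(labels),
            length(scores_2) == length(labels))
  p1 <- delong_placements(scores_1, labels)
  p2 <- delong_placements(scores_2, labels)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  s <- s10 / p1$m + s01 / p1$n
  var_diff <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  degenerate <- var_diff < .Machine$double.eps * 100
  z <- if (degenerate) 0 else (p1$auc - p2$auc) / sqrt(var_diff)
  structure(list(auc_1 = p1$auc, auc_2 = p2$auc, z = z,
                 p = if (degenerate) 1 else 2 * stats::pnorm(-abs(z)),
                 p_less = stats::pnorm(z),
                 p_greater = stats::pnorm(z, lower.tail = FALSE),
                 var_diff = var_diff, s10 = s10, s01 = s01,
                 degenerate = degenerate),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("DeLong test: AUC1 = %.4f, AUC2 = %.4f, z = %.3f, p = %.4g%s\n",
              x$auc_1, x$auc_2, x$z, x$p,
              if (x$degenerate) " (degenerate variance)" else ""))
  invisible(x)
}

#' Label-permutation test for a classifier statistic
#'
#' Permutes the outcome labels `B` times, recomputes the statistic, and
#' reports the add-one-corrected p-value
#' `p = (1 + #{null >= observed}) / (B + 1)`, which is never zero.
#'
#' @param statistic_fn function of `(table, labels)` returning one number
#'   (e.g. the cross-validated accuracy of a fitted model).
#' @param table a `feature_table` with an outcome column.
#' @param B number of permutations.
#' @param seed RNG seed driving the permutations.
#' @return a `permutation_result` list: `observed` (Sobs), `null` (length-B
#'   vector), `p`, `B`, `seed`.
#' @export
permutation_test <- function(statistic_fn, table, B = 999, seed = 1L) {
  stopifnot(B >= 1)
  labels <- outcome01(table)
  observed <- statistic_fn(table, labels)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  null <- vapply(seq_len(B), function(b) {
    statistic_fn(table, sample(labels))
  }, numeric(1))
  structure(list(observed = observed, null = null,
                 p = (1 + sum(null >= observed)) / (B + 1),
                 B = B, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: Sobs = %.4f, p = %.4g (B = %d)\n",
              x$observed, x$p, x$B))
  invisible(x)
}

#' Compare per-configuration AUC distributions across a grid factor
#'
#' For each level of a grid factor (feature type, batch method, ...):
#' the mean AUC and a 95% percentile interval of the per-configuration AUC
#' distribution; plus pairwise two-sided Welch t and Mann-Whitney p-values
#' between levels (Mann-Whitney primary: AUC distributions are bounded and
#' skewed).
#'
#' @param results data.frame of grid results (one row per configuration)
#'   containing `factor` and an `auc_mean` column.
#' @param factor name of the grouping column.
#' @param value name of the AUC column.
#' @return list with `summary` (level, n, mean_auc, ci_lo, ci_hi) and
#'   `pairwise` (level_1, level_2, p_welch, p_wilcox, mean_diff).
#' @export
compare_auc_groups <- function(results, factor, value = "auc_mean") {
  stopifnot(factor %in% names(results), value %in% names(results))
  lv <- split(results[[value]], results[[factor]])
  small <- vapply(lv, length, integer(1)) < 2
  if (any(small)) {
    warning("level(s) with < 2 configs skipped: ",
            paste(names(lv)[small], collapse = ", "))
    lv <- lv[!small]
  }
  if (length(lv) < 2)
    stop("need at least two levels of '", factor, "' with >= 2 configs")
  summary <- data.frame(
    level = names(lv),
    n = vapply(lv, length, integer(1)),
    mean_auc = vapply(lv, mean, numeric(1)),
    ci_lo = vapply(lv, function(x) unname(stats::quantile(x, 0.025)),
                   numeric(1)),
    ci_hi = vapply(lv, function(x) unname(stats::quantile(x, 0.975)),
                   numeric(1)),
    row.names = NULL)
  pairs <- utils::combn(names(lv), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- lv[[pairs[1, i]]]
    b <- lv[[pairs[2, i]]]
    p_w <- if (stats::sd(a) == 0 && stats::sd(b) == 0 &&
               mean(a) == mean(b)) 1 else
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
    data.frame(level_1 = pairs[1, i], level_2 = pairs[2, i],
               mean_diff = mean(a) - mean(b),
               p_welch = p_w,
               p_wilcox = suppressWarnings(
                 stats::wilcox.test(a, b, exact = FALSE)$p.value))
  }))
  list(summary = summary, pairwise = pairwise)
}

#' Association tests between clinical variables and outcome
#'
#' Categorical variables (few unique values) are tested with the chi-square
#' test against pCR status, falling back to Fisher's exact test when any
#' expected cell count is below 5; continuous variables use the Welch t test.
#' Variables with a single level are skipped with a warning.
#'
#' @param sample_meta data.frame with an `outcome` column plus clinical
#'   variables; `sample_id` and `batch` columns are ignored.
#' @return data.frame with `variable`, `test`, `p`.
#' @export
clinical_tests <- function(sample_meta) {
  stopifnot("outcome" %in% names(sample_meta))
  outcome <- factor(sample_meta$outcome)
  vars <- setdiff(names(sample_meta), c("sample_id", "batch", "outcome"))
  rows <- lapply(vars, function(v) {
    x <- sample_meta[[v]]
    if (length(unique(x)) < 2) {
      warning("variable '", v, "' has a single level: skipped")
      return(NULL)
    }
    categorical <- is.character(x) || is.factor(x) || is.logical(x) ||
      length(unique(x)) <= 5
    if (categorical) {
      tab <- table(factor(x), outcome)
      cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      if (any(cs$expected < 5)) {
        data.frame(variable = v, test = "fisher",
                   p = stats::fisher.test(tab)$p.value)
      } else {
        data.frame(variable = v, test = "chisq", p = cs$p.value)
      }
    } else {
      data.frame(variable = v, test = "welch_t",
                 p = stats::t.test(x ~ outcome)$p.value)
    }
  })
  do.call(rbind, rows)
}
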