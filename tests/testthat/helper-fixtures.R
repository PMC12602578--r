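# quick feature_table builder for hand-sized fixtures
make_table <- function(values, batch = NULL, outcome = NULL,
                       modality = "CT", is_shape = 0, ...) {
  values <- as.matrix(values)
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("f%02d", 1:p)
  sm <- data.frame(sample_id = sprintf("s%03d", 1:n),
                   batch = if (is.null(batch)) "a" else batch)
  if (!is.null(outcome)) sm$outcome <- outcome
  extra <- list(...)
  for (nm in names(extra)) sm[[nm]] <- extra[[nm]]
  fm <- data.frame(feature_id = colnames(values),
                   modality = rep_len(modality, p),
                   is_shape = rep_len(is_shape, p))
  rownames(values) <- sm$sample_id
  feature_table(values, sm, fm)
}

# one default cohort shared across test files (computed once)
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(simulation_design())
    cache
  }
})

default_feature_sets <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(prepare_feature_sets(default_cohort()))
    cache
  }
})

# brute-force discretization oracles: literal elementwise evaluation of the
# binning formulas, independent of the package's vectorized path. The
# ceiling is evaluated in exact integer arithmetic (ceil(p/q) =
# (p + q - 1) %/% q) wherever the inputs permit, so a float ulp at a
# mathematically exact bin edge cannot promote the oracle to the wrong bin.
ceil_frac <- function(p, q) as.integer((p + q - 1) %/% q)

fbn_oracle <- function(x, n) {
  vapply(x, function(v) {
    if (v == min(x)) return(1L)
    r <- sum(x < v) + 1                       # ascending competition rank
    ceil_frac(n * (r - 1), length(x) - 1)
  }, integer(1))
}

fbw_oracle <- function(x, n) {
  mn <- min(x)
  mx <- max(x)
  exact <- all(x == round(x))
  vapply(x, function(v) {
    if (v == mn) return(1L)
    if (exact) ceil_frac(n * (v - mn), mx - mn)
    else as.integer(ceiling(n * (v - mn) / (mx - mn)))
  }, integer(1))
}

# ICC(2,1) via aov mean squares — independent oracle for icc21()
icc21_aov <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subject = factor(rep(1:n, 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# cheap label-dependent "classifier accuracy" statistic for permutation tests:
# training accuracy of the mean-difference projection at the midpoint cutoff
projection_accuracy <- function(table, labels) {
  x <- table$values
  w <- colMeans(x[labels == 1, , drop = FALSE]) -
    colMeans(x[labels == 0, , drop = FALSE])
  s <- drop(x %*% w)
  thr <- (mean(s[labels == 1]) + mean(s[labels == 0])) / 2
  mean((s > thr) == (labels == 1))
}
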