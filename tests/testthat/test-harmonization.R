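make_batch_table <- function(n_per_batch = c(a = 25, b = 25), p = 30,
                             shift = 0, seed = 1) {
  set.seed(seed)
  n <- sum(n_per_batch)
  batch <- rep(names(n_per_batch), n_per_batch)
  v <- matrix(rnorm(n * p, mean = 10), n, p)
  v[batch == names(n_per_batch)[2], ] <-
    v[batch == names(n_per_batch)[2], ] + shift
  make_table(v, batch = batch)
}

test_that("a single batch is an identity transform with a warning", {
  t1 <- make_table(matrix(rnorm(40, 5), 10, 4))
  expect_warning(out <- combat_fit_transform(t1), "single batch")
  expect_equal(out$table$values, t1$values)
  expect_warning(out2 <- limma_fit_transform(t1), "single batch")
  expect_equal(out2$table$values, t1$values)
})

test_that("a batch with one sample is rejected", {
  t1 <- make_table(matrix(rnorm(20), 5, 4), batch = c("a", "a", "a", "a", "b"))
  expect_error(combat_fit_transform(t1), "single sample")
  expect_error(limma_fit_transform(t1), "single sample")
})

test_that("limma removal equalizes batch means exactly and preserves the
           overall feature mean", {
  t1 <- make_batch_table(shift = 4)
  out <- limma_fit_transform(t1)
  batch <- t1$sample_meta$batch
  for (j in 1:3) {
    bm <- tapply(out$table$values[, j], batch, mean)
    expect_lt(diff(range(bm)), 1e-10)
    expect_equal(mean(out$table$values[, j]), mean(t1$values[, j]),
                 tolerance = 1e-12)
  }
  # unbalanced two batches at m +/- delta/2: both land on the weighted mean
  t2 <- make_table(matrix(c(rep(7, 6), rep(3, 4)) + rnorm(10, sd = 1e-8)),
                   batch = rep(c("a", "b"), c(6, 4)))
  out2 <- limma_fit_transform(t2)
  bm <- tapply(out2$table$values[, 1], t2$sample_meta$batch, mean)
  expect_equal(unname(diff(bm)), 0, tolerance = 1e-9)
})

test_that("after limma removal a one-way ANOVA on batch finds nothing", {
  set.seed(9)
  t1 <- make_table(matrix(rnorm(40 * 20, 3), 40, 20),
                   batch = rep(c("a", "b", "c"), c(10, 15, 15)))
  out <- limma_fit_transform(t1)
  batch <- factor(t1$sample_meta$batch)
  f_stats <- apply(out$table$values, 2, function(y)
    summary(stats::aov(y ~ batch))[[1]]["batch", "F value"])
  expect_lt(max(f_stats), 1e-10)
})

test_that("limma agrees with limma::removeBatchEffect", {
  t1 <- make_batch_table(c(a = 20, b = 30, c = 10), p = 15, shift = 2,
                         seed = 4)
  ours <- limma_fit_transform(t1)$table$values
  ref <- t(limma::removeBatchEffect(t(t1$values),
                                    batch = t1$sample_meta$batch))
  # removeBatchEffect centers batch effects with unweighted contrasts; both
  # equalize batch means, so they can differ only by a per-feature constant
  for (j in 1:5) {
    shift_j <- ours[, j] - ref[, j]
    expect_lt(diff(range(shift_j)), 1e-10)
  }
})

test_that("combat matches the reference implementation elementwise", {
  t1 <- make_batch_table(c(a = 25, b = 25), p = 30, shift = 3, seed = 2)
  ours <- combat_fit_transform(t1)$table$values
  ref <- t(sva::ComBat(dat = t(t1$values), batch = t1$sample_meta$batch))
  expect_lt(max(abs(ours - ref)), 1e-4)

  t2 <- make_batch_table(c(a = 15, b = 20, c = 15), p = 25, shift = -2,
                         seed = 3)
  ours2 <- combat_fit_transform(t2)$table$values
  ref2 <- t(sva::ComBat(dat = t(t2$values), batch = t2$sample_meta$batch))
  expect_lt(max(abs(ours2 - ref2)), 1e-4)
})

test_that("combat removes an injected pure location shift", {
  delta <- 5
  t1 <- make_batch_table(c(a = 200, b = 200), p = 60, shift = delta,
                         seed = 6)
  out <- combat_fit_transform(t1)$table$values
  batch <- t1$sample_meta$batch
  resid <- apply(out, 2, function(y) abs(diff(tapply(y, batch, mean))))
  expect_gte(mean(resid < 0.05 * delta), 0.95)
})

test_that("harmonization leaves sample and feature metadata untouched", {
  co <- default_cohort()
  t1 <- co$tumor_table
  for (m in c("combat", "limma")) {
    out <- harmonize(t1, m)
    expect_identical(out$table$sample_meta, t1$sample_meta)
    expect_identical(out$table$feature_meta, t1$feature_meta)
  }
})

test_that("apply_harmonization reproduces fit_transform and rejects unseen
           batches", {
  t1 <- make_batch_table(c(a = 20, b = 20), p = 10, shift = 2, seed = 8)
  for (m in c("combat", "limma")) {
    fit <- harmonize(t1, m)
    expect_equal(apply_harmonization(fit$model, t1)$values,
                 fit$table$values, tolerance = 1e-12)
  }
  t2 <- t1
  t2$sample_meta$batch[1] <- "zz"
  fit <- harmonize(t1, "combat")
  expect_error(apply_harmonization(fit$model, t2), "zz")
  expect_equal(harmonize(t1, "none")$table$values, t1$values)
})

test_that("features constant within a batch pass through unadjusted", {
  v <- matrix(rnorm(40, 5), 20, 2)
  v[, 2] <- rep(c(1, 2), each = 10)              # constant within each batch
  t1 <- make_table(v, batch = rep(c("a", "b"), each = 10))
  expect_message(out <- combat_fit_transform(t1), "constant within a batch")
  expect_equal(out$table$values[, 2], t1$values[, 2])
})

test_that("a held-out scanner classifier loses the batch signal after
           harmonization", {
  d <- simulation_design(batch_shift_sd = 2, seed = 19)
  co <- simulate_cohort(d)
  t1 <- co$tumor_table
  two <- t1[t1$sample_meta$batch %in% c("scanner1", "scanner2"), ]
  yb <- as.integer(two$sample_meta$batch == "scanner2")
  zsc <- function(v) {
    mu <- colMeans(v); sd <- apply(v, 2, sd); sd[sd == 0] <- 1
    sweep(sweep(v, 2, mu), 2, sd, `/`)
  }
  cv_batch_auc <- function(tab) {
    set.seed(1)
    tr <- sort(sample(nrow(tab$values), nrow(tab$values) / 2))
    te <- setdiff(seq_len(nrow(tab$values)), tr)
    z <- zsc(tab$values)
    fit <- fit_classifier("SGD", z[tr, ], yb[tr], seed = 1)
    auc(predict_scores(fit, z[te, ]), yb[te])
  }
  expect_gt(cv_batch_auc(two), 0.9)
  harm <- suppressMessages(combat_fit_transform(two))$table
  expect_lt(cv_batch_auc(harm), 0.6)
})

test_that("harmonization preserves the outcome signal on informative
           features", {
  co <- default_cohort()
  t1 <- co$tumor_table
  y <- outcome01(t1)
  inf <- co$truth$informative
  tvec <- function(v) vapply(inf, function(f)
    unname(stats::t.test(v[y == 1, f], v[y == 0, f])$statistic), numeric(1))
  t_pre <- tvec(t1$values)
  t_post <- tvec(combat_fit_transform(t1)$table$values)
  expect_true(all(sign(t_post) == sign(t_pre)))
  expect_gte(mean(abs(t_post) >= 0.7 * abs(t_pre)), 0.9)
})
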