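test_that("AUC: perfect separation, all ties, and the exhaustive
           pair-counting oracle", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")

  pair_oracle <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(14)
  for (i in 1:20) {
    y <- sample(rep(0:1, 10))
    s <- sample(seq(0, 1, 0.1), 20, replace = TRUE)  # ties likely
    expect_equal(auc(s, y), pair_oracle(s, y))
  }
  # score negation flips the AUC for tie-free scores
  s <- rnorm(20); y <- rep(0:1, 10)
  expect_equal(auc(s, y) + auc(-s, y), 1)
})

test_that("DeLong structural components match the hand-enumerated placement
           definitions", {
  s <- c(0.9, 0.4, 0.7, 0.2, 0.6, 0.3)
  y <- c(1, 1, 1, 0, 0, 0)
  pos <- s[y == 1]; neg <- s[y == 0]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  v01 <- vapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)),
                numeric(1))
  pl <- radgrid:::delong_placements(s, y)
  expect_equal(pl$v10, v10)
  expect_equal(pl$v01, v01)
  expect_equal(pl$auc, auc(s, y))
})

test_that("DeLong: identical classifiers are degenerate; otherwise z and p
           agree with pROC", {
  set.seed(15)
  y <- rep(0:1, each = 40)
  s1 <- rnorm(80) + y
  res <- delong_test(s1, s1, y)
  expect_true(res$degenerate)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)

  for (i in 1:5) {
    s2 <- rnorm(80) + 0.5 * y
    ours <- delong_test(s1, s2, y)
    ref <- suppressMessages(pROC::roc.test(
      pROC::roc(y, s1, quiet = TRUE), pROC::roc(y, s2, quiet = TRUE),
      method = "delong"))
    expect_equal(abs(ours$z), abs(unname(ref$statistic)), tolerance = 1e-8)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
    expect_equal(sign(ours$z), sign(ours$auc_1 - ours$auc_2))
  }
})

test_that("DeLong keeps its nominal type-I error under the null", {
  set.seed(16)
  n <- 300
  y <- rep(0:1, each = n / 2)
  rejections <- 0
  n_sim <- 500
  for (i in seq_len(n_sim)) {
    if (delong_test(rnorm(n), rnorm(n), y)$p < 0.05) {
      rejections <- rejections + 1
    }
  }
  expect_gte(rejections / n_sim, 0.030)
  expect_lte(rejections / n_sim, 0.070)
})

test_that("permutation test: invariant statistic gives p = 1, separable data
           the minimum p, and p is never 0", {
  t1 <- make_table(matrix(rnorm(40), 20, 2),
                   outcome = rep(c("pCR", "non-pCR"), 10))
  res <- permutation_test(function(tab, lab) 42, t1, B = 99, seed = 1)
  expect_equal(res$p, 1)
  expect_length(res$null, 99)

  t2 <- make_table(matrix(c(rep(0, 10), rep(5, 10)), 20, 1),
                   outcome = rep(c("non-pCR", "pCR"), each = 10))
  res2 <- permutation_test(projection_accuracy, t2, B = 199, seed = 2)
  expect_equal(res2$observed, 1)
  expect_equal(res2$p, 1 / 200)
  expect_gt(res2$p, 0)
  # determinism
  res3 <- permutation_test(projection_accuracy, t2, B = 199, seed = 2)
  expect_identical(res2$null, res3$null)
})

test_that("permutation p-values are uniform when there is no signal", {
  set.seed(17)
  pvals <- vapply(1:150, function(i) {
    t1 <- make_table(matrix(rnorm(40 * 5), 40, 5),
                     outcome = sample(rep(c("pCR", "non-pCR"), 20)))
    permutation_test(projection_accuracy, t1, B = 99, seed = 1000 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("compare_auc_groups summarizes levels and flags real differences", {
  set.seed(18)
  res_same <- data.frame(feature_type = rep(c("OR", "TLR"), each = 10),
                         auc_mean = rep(seq(0.6, 0.69, 0.01), 2))
  out <- compare_auc_groups(res_same, "feature_type")
  expect_equal(out$pairwise$p_wilcox, 1, tolerance = 1e-6)
  expect_equal(out$pairwise$mean_diff, 0)

  res_diff <- data.frame(grp = rep(c("a", "b"), each = 315),
                         auc_mean = c(rnorm(315, 0.65, 0.05),
                                      rnorm(315, 0.60, 0.05)))
  out2 <- compare_auc_groups(res_diff, "grp")
  expect_lt(out2$pairwise$p_welch, 0.001)
  expect_equal(out2$summary$n, c(315L, 315L))
  expect_true(all(out2$summary$ci_lo < out2$summary$mean_auc))

  expect_error(suppressWarnings(compare_auc_groups(
    data.frame(grp = "a", auc_mean = 0.5), "grp")), "at least two levels")
})

test_that("clinical tests: chi-square closed form, Fisher fallback, balanced
           null, and constant skip", {
  # 2x2 table [[30,10],[10,30]]: X^2 = 20 on 1 df
  meta <- data.frame(
    outcome = rep(c("pCR", "non-pCR"), each = 40),
    ER = c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30)))
  out <- clinical_tests(meta)
  expect_equal(out$test, "chisq")
  expect_equal(out$p, stats::pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(out$p, 0.001)

  # identical distribution in both groups
  meta2 <- data.frame(outcome = rep(c("pCR", "non-pCR"), each = 40),
                      PR = rep(c(0, 1), 40))
  expect_gt(clinical_tests(meta2)$p, 0.9)

  # small expected counts fall back to Fisher
  meta3 <- data.frame(outcome = rep(c("pCR", "non-pCR"), c(5, 5)),
                      HER2 = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 1))
  expect_equal(clinical_tests(meta3)$test, "fisher")

  # continuous variable -> Welch t; constant variable skipped
  meta4 <- data.frame(outcome = rep(c("pCR", "non-pCR"), each = 30),
                      age = c(rnorm(30, 60), rnorm(30, 50)),
                      const = 1)
  expect_warning(out4 <- clinical_tests(meta4), "single level")
  expect_equal(out4$test, "welch_t")
  expect_lt(out4$p, 0.01)
})

test_that("the default cohort's clinical covariates associate with outcome", {
  co <- default_cohort()
  out <- clinical_tests(co$tumor_table$sample_meta)
  expect_setequal(out$variable, c("ER", "PR", "HER2"))
  expect_lt(min(out$p), 0.05)
})
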