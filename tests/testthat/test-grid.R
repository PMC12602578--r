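test_that("the configuration grid is the full 630 factorial with the printed
           marginal counts", {
  g <- enumerate_grid()
  expect_equal(nrow(g), 630)
  expect_equal(nrow(unique(g)), 630)
  expect_equal(as.vector(table(g$feature_type)), c(315, 315))
  expect_equal(unname(table(g$batch_method)[c("none", "combat", "limma")]),
               rep(210L, 3), ignore_attr = TRUE)
  expect_true(all(table(g$discretization) == 126))
  expect_true(all(table(g$selector) == 210))
  expect_true(all(table(g$classifier) == 90))
  # deterministic lexicographic order: last field varies fastest
  expect_identical(g, enumerate_grid())
  expect_equal(g$classifier[1:7], c("DT", "ET", "KNN", "RF", "SVM", "XGB",
                                    "SGD"))
})

test_that("down-sampling balances 95:52 to 52:52 and splits 41 + 11 per
           class", {
  set.seed(30)
  t1 <- make_table(matrix(rnorm(147 * 3), 147, 3),
                   outcome = rep(c("non-pCR", "pCR"), c(95, 52)))
  sp <- downsample_split(t1, 0.8, rng_seed = 5)
  ytr <- outcome01(sp$train)
  yva <- outcome01(sp$validation)
  expect_equal(sum(ytr == 1), 41)
  expect_equal(sum(ytr == 0), 41)
  expect_equal(sum(yva == 1), 11)
  expect_equal(sum(yva == 0), 11)
  expect_length(intersect(sp$train$sample_meta$sample_id,
                          sp$validation$sample_meta$sample_id), 0)
})

test_that("already-balanced classes lose no sample, and splits are seed
           deterministic", {
  t1 <- make_table(matrix(rnorm(40 * 2), 40, 2),
                   outcome = rep(c("pCR", "non-pCR"), 20))
  sp <- downsample_split(t1, 0.8, rng_seed = 9)
  expect_equal(nrow(sp$train$values) + nrow(sp$validation$values), 40)
  sp2 <- downsample_split(t1, 0.8, rng_seed = 9)
  expect_identical(sp$train$sample_meta$sample_id,
                   sp2$train$sample_meta$sample_id)
  t2 <- t1
  t2$sample_meta$outcome <- c("pCR", rep("non-pCR", 39))
  expect_error(downsample_split(t2, 0.8, 1), "at least 2")
})

test_that("select_features returns exactly k ranked features with their
           importance scores", {
  co <- default_cohort()
  tab <- assemble_or(co$tumor_table)
  sel <- select_features(tab, "RF", k = 10, rng_seed = 2)
  expect_equal(nrow(sel), 10)
  expect_true(all(diff(sel$importance) <= 0))
  one <- tab[, 1]
  expect_equal(select_features(one, "DT", k = 1)$feature_id,
               one$feature_meta$feature_id)
  expect_error(select_features(tab, "PCA", k = 10), "valid")
})

test_that("tree selectors enrich for the truly informative features", {
  co <- default_cohort()
  tab <- assemble_tlr(co$tumor_table, co$liver_table)
  src <- tab[tab$sample_meta$batch != "scanner3", ]
  inf <- intersect(co$truth$informative, colnames(tab$values))
  p_tot <- ncol(tab$values)
  hits <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    sp <- downsample_split(src, 0.8, rng_seed = 100 + r)
    sel <- select_features(sp$train, "RF", k = 10, rng_seed = 100 + r)
    hits <- hits + sum(sel$feature_id %in% inf)
  }
  # binomial upper bound on the null (selection blind to class signal)
  p_null <- length(inf) / p_tot
  p_enrich <- stats::pbinom(hits - 1, n_rep * 10, p_null,
                            lower.tail = FALSE)
  expect_lt(p_enrich, 0.01)
})

test_that("a label-determining feature yields validation AUC 1", {
  set.seed(31)
  n <- 60
  y <- rep(c("pCR", "non-pCR"), each = n / 2)
  v <- cbind(winner = ifelse(y == "pCR", 1, 0) * 10 + seq_len(n) / 100,
             noise1 = rnorm(n), noise2 = rnorm(n))
  t1 <- make_table(v, batch = rep(c("src", "tst"), n / 2), outcome = y)
  cfg <- data.frame(feature_type = "OR", batch_method = "none",
                    discretization = "none", selector = "DT",
                    classifier = "DT", stringsAsFactors = FALSE)
  res <- evaluate_config(cfg, list(OR = t1), test_batch = "tst",
                         repeats = 5, seed = 2, k = 1)
  expect_equal(res$auc_validation, 1.0)
  expect_equal(res$auc_test, 1.0)
})

test_that("run_grid returns a ranked table, is deterministic, and isolates
           per-config failures", {
  ps <- default_feature_sets()
  cfgs <- data.frame(feature_type = c("TLR", "TLR", "OR"),
                     batch_method = c("limma", "none", "bogus"),
                     discretization = c("FBW32", "none", "none"),
                     selector = "RF",
                     classifier = c("SVM", "KNN", "SVM"),
                     stringsAsFactors = FALSE)
  rg <- run_grid(ps, cfgs, test_batch = "scanner3", repeats = 5, seed = 4)
  expect_equal(nrow(rg$results), 3)
  ok <- rg$results[is.na(rg$results$error), ]
  expect_equal(nrow(ok), 2)
  expect_true(all(diff(ok$auc_mean) <= 0))
  expect_match(rg$results$error[!is.na(rg$results$error)], "should be one of")

  rg2 <- run_grid(ps, cfgs, test_batch = "scanner3", repeats = 5, seed = 4)
  expect_equal(rg$results$auc_mean, rg2$results$auc_mean)

  res <- rg$details[[which(cfgs$batch_method == "limma")]]
  expect_equal(res$auc_mean,
               (res$auc_validation + res$auc_test) / 2, tolerance = 1e-12)
  expect_true(all(res$per_repeat$auc_validation >= 0 &
                    res$per_repeat$auc_validation <= 1))
})

test_that("train-only preprocessing never uses the test scanner to fit", {
  ps <- default_feature_sets()
  cfg <- data.frame(feature_type = "OR", batch_method = "limma",
                    discretization = "FBN32", selector = "DT",
                    classifier = "DT", stringsAsFactors = FALSE)
  pr <- preprocess_config(ps, cfg, mode = "train_only",
                          test_batch = "scanner3")
  # source rows must match what fitting on the source scanners alone gives
  src <- ps$OR[ps$OR$sample_meta$batch != "scanner3", ]
  h <- harmonize(src, "limma")
  d <- discretize_fit_transform(h$table, "FBN", 32)
  src_idx <- ps$OR$sample_meta$batch != "scanner3"
  expect_equal(pr$values[src_idx, ], d$table$values)
  expect_error(preprocess_config(ps, cfg, mode = "train_only"),
               "test_batch")
})
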