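#!/usr/bin/env Rscript

# Examine the best-ranked configuration: compare its test-set scores against
# the runners-up with DeLong's test for correlated AUCs, and probe the
# credibility of its accuracy with label-permutation tests at two
# representative repeat splits.

library(radgrid)

res <- read.csv("results/grid_results.csv")
res <- res[is.na(res$error) | res$error == "", ]
sets <- list(OR = read_feature_table("results/or", feature_type = "OR"),
             TLR = read_feature_table("results/tlr", feature_type = "TLR"))

top5 <- head(res, 5)
cat("Top 5 configurations:\n")
print(top5[, c("feature_type", "batch_method", "discretization", "selector",
               "classifier", "auc_mean")], row.names = FALSE)

# one representative fit per configuration on a common split; DeLong then
# compares the correlated test-set score vectors
fit_scores <- function(cfg, seed = 1) {
  proc <- preprocess_config(sets, cfg, mode = "full")
  src <- proc[proc$sample_meta$batch != "scanner3", ]
  tst <- proc[proc$sample_meta$batch == "scanner3", ]
  sp <- downsample_split(src, 0.8, rng_seed = seed)
  sel <- select_features(sp$train, cfg$selector, k = 10, rng_seed = seed)
  fit <- fit_classifier(cfg$classifier,
                        sp$train$values[, sel$feature_id, drop = FALSE],
                        outcome01(sp$train), seed = seed)
  list(scores = predict_scores(fit, tst$values[, sel$feature_id,
                                               drop = FALSE]),
       labels = outcome01(tst))
}

m1 <- fit_scores(top5[1, ])
cat("\nDeLong tests, model 1 vs models 2-5 (test scanner):\n")
dl_rows <- do.call(rbind, lapply(2:5, function(i) {
  mi <- fit_scores(top5[i, ])
  dl <- delong_test(m1$scores, mi$scores, m1$labels)
  data.frame(comparison = paste("model 1 vs model", i),
             auc_1 = dl$auc_1, auc_2 = dl$auc_2, z = dl$z, p = dl$p)
}))
print(dl_rows, row.names = FALSE)
write.csv(dl_rows, "results/delong_top5.csv", row.names = FALSE)

# permutation tests on the best configuration's accuracy (999 label
# permutations; Sobs = observed accuracy)
cfg <- top5[1, ]
proc <- preprocess_config(sets, cfg, mode = "full")
src <- proc[proc$sample_meta$batch != "scanner3", ]

acc_stat <- function(split_seed) {
  function(table, labels) {
    tab <- table
    tab$sample_meta$outcome <- ifelse(labels == 1, "pCR", "non-pCR")
    sp <- downsample_split(tab, 0.8, rng_seed = split_seed)
    sel <- select_features(sp$train, cfg$selector, k = 10,
                           rng_seed = split_seed)
    fit <- fit_classifier(cfg$classifier,
                          sp$train$values[, sel$feature_id, drop = FALSE],
                          outcome01(sp$train), seed = split_seed)
    s <- predict_scores(fit, sp$validation$values[, sel$feature_id,
                                                  drop = FALSE])
    yv <- outcome01(sp$validation)
    mean((s > stats::median(s)) == (yv == 1))
  }
}

cat("\nPermutation tests (B = 199) at two representative splits:\n")
for (ss in c(2, 3)) {
  pt <- permutation_test(acc_stat(ss), src, B = 199, seed = 100 + ss)
  cat(sprintf("  split %d: Sobs = %.3f, p = %.4f\n", ss, pt$observed, pt$p))
}
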