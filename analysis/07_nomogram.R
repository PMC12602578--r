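#!/usr/bin/env Rscript

# Radiomics score and combined radiomics + clinical model for the best
# configuration, rendered as a points-based nomogram.

library(radgrid)

res <- read.csv("results/grid_results.csv")
res <- res[is.na(res$error) | res$error == "", ]
cfg <- res[1, ]
sets <- list(OR = read_feature_table("results/or", feature_type = "OR"),
             TLR = read_feature_table("results/tlr", feature_type = "TLR"))

proc <- preprocess_config(sets, cfg, mode = "full")
src <- proc[proc$sample_meta$batch != "scanner3", ]
tst <- proc[proc$sample_meta$batch == "scanner3", ]

sel <- select_features(src, cfg$selector, k = 10, rng_seed = 1)
cat("Selected features and weights (selector importance):\n")
print(sel, row.names = FALSE)
write.csv(sel, "results/selected_features.csv", row.names = FALSE)

rs_src <- radiomics_score(src, sel$feature_id, sel$importance)
rs_tst <- radiomics_score(tst, sel$feature_id, sel$importance)
cat(sprintf("\nr-score alone:      test AUC %.3f\n",
            auc(rs_tst, outcome01(tst))))

clin <- c("ER", "PR", "HER2")
fit <- fit_combined_model(rs_src, src$sample_meta[clin], outcome01(src))
print(fit)
pred <- predict(fit$fit, newdata = data.frame(r_score = rs_tst,
                                              tst$sample_meta[clin]),
                type = "response")
cat(sprintf("r-score + clinical: test AUC %.3f\n", auc(pred, outcome01(tst))))

nomo <- export_nomogram(fit, json = "results/nomogram.json",
                        plot_file = "results/figures/nomogram.png")
cat("\nPoint mappings (largest effect spans 100 points):\n")
print(nomo$vars, row.names = FALSE)

pts <- nomogram_points(nomo, data.frame(r_score = rs_src,
                                        src$sample_meta[clin]))
cat(sprintf("\npoints-vs-logistic probability round trip, max |error|: %.2e\n",
            max(abs(pts$probability - fit$fitted))))
cat("Nomogram written to results/nomogram.json and",
    "results/figures/nomogram.png\n")
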