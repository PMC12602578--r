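#!/usr/bin/env Rscript

# Reproducibility and redundancy filtering, then assembly of the two feature
# sets the grid compares: OR (origin radiomics, CT + PET as extracted) and
# TLR (PET intensity features divided by their liver counterparts).

library(radgrid)

tumor <- read_feature_table("results/data/tumor")
liver <- read_feature_table("results/data/liver", feature_type = "liver")
reps <- lapply(c("1a", "1b", "2"), function(s)
  read_feature_table(paste0("results/data/replicate_", s)))

icc <- icc_filter(reps[[1]], reps[[2]], reps[[3]], threshold = 0.75)
print(icc)
write.csv(icc$icc, "results/icc_report.csv", row.names = FALSE)

tumor_f <- tumor[, icc$retained]
or_table <- correlation_prune(assemble_or(tumor_f), r_max = 0.9)
tlr_table <- correlation_prune(assemble_tlr(tumor_f, liver), r_max = 0.9)

cat("\nAfter ICC > 0.75 and |r| <= 0.9 pruning:\n")
cat("  OR :", ncol(or_table$values), "features\n")
cat("  TLR:", ncol(tlr_table$values), "features\n")

write_feature_table(or_table, "results/or")
write_feature_table(tlr_table, "results/tlr")
cat("\nFeature sets written to results/or*.csv and results/tlr*.csv\n")
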