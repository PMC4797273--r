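#!/usr/bin/env Rscript
# Per-feature statistical contrasts between co-occupied and solo events in
# cell1: Welch two-sample t-tests on each feature column, with BH-adjusted
# p-values added for reference.

library(cooccupy)

fm <- read_feature_matrix("scratch/cells/cell1/feature_matrix.tsv")
contrasts <- contrast_all(fm)
contrasts <- contrasts[order(contrasts$p), ]
write_contrasts(contrasts, "results/04_contrasts.tsv")

message("features significant at p < 1e-5: ",
        sum(contrasts$p < 1e-5), " of ", nrow(contrasts))
print(head(contrasts[c("feature", "mean_pos", "mean_neg", "t", "p")], 8),
      row.names = FALSE)
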