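#!/usr/bin/env Rscript
# Quantify chromatin features at cell1's binding events: the 100-bp
# summit-window feature matrix used for modelling (log2-RPKM signals, GC
# content, CpG methylation, chromatin state) and 6-kb binned signal
# profiles around summits for two representative channels.

library(cooccupy)

cell <- read_cell("scratch/cells/cell1")
ev <- read_event_table("scratch/cells/cell1/events.tsv")

fm <- extract_features(ev, cell$tracks, genome = cell$genome,
                       seg = cell$segmentation, side = "A")
write_feature_matrix(fm, "scratch/cells/cell1/feature_matrix.tsv")

# methylation handled separately: only CpG-bearing windows carry a value
fm_me <- extract_features(ev, cell$tracks["DNase"], cpgs = cell$cpgs,
                          side = "A")

class_means <- do.call(rbind, lapply(attr(fm, "feature_names"), function(f) {
  data.frame(feature = f,
             mean_co = mean(fm[[f]][fm$label == 1]),
             mean_solo = mean(fm[[f]][fm$label == 0]))
}))
class_means <- rbind(class_means, data.frame(
  feature = "methylation",
  mean_co = mean(fm_me$methylation[fm_me$label == 1]),
  mean_solo = mean(fm_me$methylation[fm_me$label == 0])
))
class_means$difference <- class_means$mean_co - class_means$mean_solo
write.table(class_means, "results/03_feature_class_means.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("CpG-bearing sites: ", nrow(fm_me), " of ", nrow(fm))

profs <- do.call(rbind, lapply(c("DNase", "H3K4me3"), function(f) {
  aggregate_profile(ev[ev$source_tf == "A", ], cell$tracks[[f]],
                    span = 6000, bin_bp = 100)
}))
write.table(profs, "results/03_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

central <- subset(profs, offset %in% c(-50, 50))
message("central-bin mean RPKM (co vs solo):")
print(aggregate(mean_rpkm ~ feature + category, central, mean))
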