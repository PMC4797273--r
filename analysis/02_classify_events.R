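#!/usr/bin/env Rscript
# Classify each cell's two peak sets into solo and co-occupied binding
# events by 30% reciprocal overlap, write the event tables, and confirm
# that classification of the on-disk files reproduces the generator's
# truth labels exactly.

library(cooccupy)

rows <- lapply(c("cell1", "cell2", "cell_null"), function(nm) {
  cell <- read_cell(file.path("scratch/cells", nm))
  ev <- classify_events(cell$peaks_a, cell$peaks_b, min_frac = 0.30)
  write_event_table(ev, file.path("scratch/cells", nm, "events.tsv"))
  truth_ok <- identical(ev$category, cell$truth$category) &&
    identical(ev$partner_name, cell$truth$partner_name)
  counts <- table(ev$category)
  data.frame(cell = nm,
             A_only = counts[["A_only"]],
             co_occupied = counts[["co_occupied"]],
             B_only = counts[["B_only"]],
             truth_reproduced = truth_ok)
})
tab <- do.call(rbind, rows)
write.table(tab, "results/02_event_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
stopifnot(all(tab$truth_reproduced))
message("all truth labels reproduced from the written files")
print(tab)
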