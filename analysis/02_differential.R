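#!/usr/bin/env Rscript
# Stage 2 — normalize and compute differential statistics.
#
# Reads the raw quantifications from stage 1, applies total-intensity
# (relative iBAQ) normalization, flags detection per condition, and runs
# the per-protein two-sample test across batches. Writes the differential
# table, the volcano export and the marker-panel QC summary under
# results/differential/.

suppressPackageStartupMessages(library(rlmatch))

ind <- "results/data"; out <- "results/differential"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

qm <- read_quant_table(file.path(ind, "quant_raw.tsv"),
                       file.path(ind, "samples.tsv"))
qn <- normalize_ibaq(qm)
records <- differential(qn)
volc <- volcano_table(records)
markers <- marker_panel_summary(qn, records)

write_tsv(records, file.path(out, "differential.tsv"))
write_tsv(volc, file.path(out, "volcano.tsv"))
write_tsv(markers$summary, file.path(out, "marker_summary.tsv"))
write_tsv(markers$calls, file.path(out, "marker_calls.tsv"))

cat(sprintf("quantified proteins (detected in >=2 batches of a state): %d\n",
            nrow(records)))
up <- sum(records$ratio_B_over_A >= 10)
dn <- sum(records$ratio_B_over_A <= 0.1)
cat(sprintf(">=10-fold up in iN: %d; >=10-fold down: %d; volcano rows: %d\n",
            up, dn, nrow(volc)))
cat("marker panel calls:\n")
print(markers$calls, row.names = FALSE)
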