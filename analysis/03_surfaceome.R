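#!/usr/bin/env Rscript
# Stage 3 — annotation-mining funnel.
#
# Cross-references the differential table with the annotation export to
# inventory the membrane proteome, the growth-factor receptors and the
# neurotrophic subset. Writes the receptor tables and the funnel counts
# under results/funnel/.

suppressPackageStartupMessages(library(rlmatch))

out <- "results/funnel"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

records <- read_differential_tsv("results/differential/differential.tsv")
ann <- read_annotations("results/data/annotations.tsv")

memb <- filter_membrane(records, ann)
cls <- classify_receptors(memb, ann)
fc <- funnel_counts(records, ann)

write_tsv(memb, file.path(out, "membrane.tsv"))
write_tsv(cls$growth_factor,
          file.path(out, "growth_factor_receptors.tsv"))
write_tsv(cls$neurotrophic,
          file.path(out, "neurotrophic_receptors.tsv"))
jsonlite::write_json(as.list(fc), file.path(out, "funnel_counts.json"),
                     auto_unbox = TRUE)

cat("annotation snapshot:", attr(ann, "source_version"), "\n")
cat(sprintf("funnel: %d quantified -> %d membrane -> %d growth-factor receptors -> %d neurotrophic\n",
            fc[["quantified"]], fc[["membrane"]],
            fc[["growth_factor_receptors"]],
            fc[["neurotrophic_receptors"]]))
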