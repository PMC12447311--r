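#!/usr/bin/env Rscript
# Stage 4 — receptor-ligand matching.
#
# Applies the >=10-fold enrichment rule to the neurotrophic receptor
# inventory, joins the candidates to the ligand knowledgebase, ranks the
# recommendations, and diffs the supplementable ligand set against the
# conventional BDNF+NT3 medium. Writes results/rlm/.

suppressPackageStartupMessages(library(rlmatch))

out <- "results/rlm"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ntro <- read_differential_tsv("results/funnel/neurotrophic_receptors.tsv")
full <- read_differential_tsv("results/differential/differential.tsv")
kb <- read_ligand_kb("results/data/ligand_kb.tsv")

cand <- select_enriched_receptors(ntro)
recs <- match_ligands(cand, kb, rlm_params(require_ligand_available = TRUE))
write_report(recs, full, out)
writeLines(format_rlm_markdown(recs), file.path(out, "recommendations.md"))

star <- unique(recs$ligand_name[recs$selected_for_supplementation])
d <- compare_supplement_sets(star, c("BDNF", "NT3"))
jsonlite::write_json(d, file.path(out, "supplement_diff.json"))

cat(sprintf("candidates >=10-fold and quantifiable in iN: %d of %d neurotrophic receptors\n",
            nrow(cand), nrow(ntro)))
cat("recommended (commercially supplementable) ligands:",
    paste(star, collapse = ", "), "\n")
cat("vs conventional BDNF+NT3 — shared:", paste(d$shared, collapse = ", "),
    "| added:", paste(d$added, collapse = ", "),
    "| dropped:", paste(d$removed, collapse = ", "), "\n")
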