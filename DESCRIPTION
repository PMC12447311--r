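Package: rlmatch
Title: Receptor-Ligand Matching from Deep Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for deep-proteomics-based receptor-ligand
    matching (RLM): normalizes replicate label-free iBAQ protein
    quantifications from two cell states (human induced pluripotent stem
    cells versus induced neurons), computes per-protein differential
    statistics across batches, inventories the membrane and growth-factor
    receptor proteome by cross-referencing UniProt-style annotations,
    selects receptors enriched in the differentiated state, and matches
    them to culture-medium ligands from a curated knowledgebase to rank
    supplementation candidates. Includes a synthetic-data generator with
    log-normal intensities, multiplicative batch effects, left-censored
    (missing-not-at-random) non-detection and planted fold-change effects,
    with full ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
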