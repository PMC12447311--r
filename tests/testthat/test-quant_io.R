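test_that("a small wide table round-trips through read_quant_table", {
  d <- withr::local_tempdir()
  writeLines(c("accession\tgene_symbol\thiPSC_b1\tiN_b1",
               "P1\tGENE1\t2\t8",
               "P2\tGENE2\t3\t0",
               "P3\tGENE3\t5\t2"),
             file.path(d, "q.tsv"))
  writeLines(c("sample_id\tcondition\tbatch",
               "hiPSC_b1\thiPSC\tb1", "iN_b1\tiN\tb1"),
             file.path(d, "m.tsv"))
  qm <- read_quant_table(file.path(d, "q.tsv"), file.path(d, "m.tsv"))
  expect_s3_class(qm, "QuantMatrix")
  expect_equal(dim(qm), c(3L, 2L))
  expect_false(qm$normalized)
  expect_equal(qm$intensities["P2", ], c(hiPSC_b1 = 3, iN_b1 = 0))
  expect_equal(unname(qm$gene_symbols), c("GENE1", "GENE2", "GENE3"))
})

test_that("duplicate accessions are merged by summing, with a warning", {
  d <- withr::local_tempdir()
  writeLines(c("accession\thiPSC_b1\tiN_b1",
               "P1\t10\t1", "P1\t5\t2", "P2\t7\t7"),
             file.path(d, "q.tsv"))
  writeLines(c("sample_id\tcondition\tbatch",
               "hiPSC_b1\thiPSC\tb1", "iN_b1\tiN\tb1"),
             file.path(d, "m.tsv"))
  expect_warning(
    qm <- read_quant_table(file.path(d, "q.tsv"), file.path(d, "m.tsv")),
    "P1")
  expect_equal(nrow(qm$intensities), 2L)
  expect_equal(qm$intensities["P1", "hiPSC_b1"], 15)
  expect_equal(qm$intensities["P1", "iN_b1"], 3)
})

test_that("malformed quantification tables raise hard errors", {
  d <- withr::local_tempdir()
  writeLines(c("sample_id\tcondition\tbatch",
               "hiPSC_b1\thiPSC\tb1", "iN_b1\tiN\tb1"),
             file.path(d, "m.tsv"))
  # missing intensity column for a declared sample, named in the message
  writeLines(c("accession\thiPSC_b1", "P1\t2"), file.path(d, "q1.tsv"))
  expect_error(read_quant_table(file.path(d, "q1.tsv"),
                                file.path(d, "m.tsv")), "iN_b1")
  # negative intensity
  writeLines(c("accession\thiPSC_b1\tiN_b1", "P1\t-2\t1"),
             file.path(d, "q2.tsv"))
  expect_error(read_quant_table(file.path(d, "q2.tsv"),
                                file.path(d, "m.tsv")), "negative")
  # non-numeric cell with coordinates
  writeLines(c("accession\thiPSC_b1\tiN_b1", "P1\t2\t1", "P2\tfoo\t1"),
             file.path(d, "q3.tsv"))
  expect_error(read_quant_table(file.path(d, "q3.tsv"),
                                file.path(d, "m.tsv")),
               "row 2.*hiPSC_b1")
})

test_that("empty cells and NA map to the non-detection sentinel 0", {
  d <- withr::local_tempdir()
  writeLines(c("accession\thiPSC_b1\tiN_b1", "P1\tNA\t4", "P2\t\t5"),
             file.path(d, "q.tsv"))
  writeLines(c("sample_id\tcondition\tbatch",
               "hiPSC_b1\thiPSC\tb1", "iN_b1\tiN\tb1"),
             file.path(d, "m.tsv"))
  qm <- read_quant_table(file.path(d, "q.tsv"), file.path(d, "m.tsv"))
  expect_equal(unname(qm$intensities[, "hiPSC_b1"]), c(0, 0))
})

test_that("readers are invariant to row order", {
  d <- withr::local_tempdir()
  rows <- sprintf("P%02d\tG%02d\t%g\t%g", 1:8, 1:8, (1:8) * 1.5, 8:1)
  hdr <- "accession\tgene_symbol\thiPSC_b1\tiN_b1"
  writeLines(c(hdr, rows), file.path(d, "a.tsv"))
  set.seed(4)
  writeLines(c(hdr, sample(rows)), file.path(d, "b.tsv"))
  writeLines(c("sample_id\tcondition\tbatch",
               "hiPSC_b1\thiPSC\tb1", "iN_b1\tiN\tb1"),
             file.path(d, "m.tsv"))
  qa <- read_quant_table(file.path(d, "a.tsv"), file.path(d, "m.tsv"))
  qb <- read_quant_table(file.path(d, "b.tsv"), file.path(d, "m.tsv"))
  ord <- sort(rownames(qa$intensities))
  expect_identical(qa$intensities[ord, ], qb$intensities[ord, ])
})

test_that("write_quant_table / read_quant_table round-trip is exact to 1e-12", {
  set.seed(9)
  qm <- make_qm(matrix(rlnorm(60, 10, 2), 10, 6))
  d <- withr::local_tempdir()
  write_quant_table(qm, file.path(d, "q.tsv"), file.path(d, "m.tsv"))
  back <- read_quant_table(file.path(d, "q.tsv"), file.path(d, "m.tsv"))
  expect_equal(back$intensities, qm$intensities, tolerance = 1e-12)
  expect_identical(back$samples$batch, qm$samples$batch)
})

test_that("annotation flags derive from keywords, locations and curation", {
  d <- withr::local_tempdir()
  writeLines(c(
    "accession\tgene_symbol\tkeywords\tsubcellular_location",
    "A1\tMEMB1\tMembrane;Transport\t",
    "A2\tSOL1\tCytoplasm stuff\tCytoplasm",
    "A3\tLOC1\t\tCell membrane; single-pass",
    "P56159\tGFRA1\tMembrane;Growth factor receptor;Neurotrophic receptor\tCell membrane",
    "O00451\tGFRA2\tMembrane;Growth factor receptor;Neurotrophic receptor\tCell membrane",
    "O60609\tGFRA3\tMembrane;Growth factor receptor;Neurotrophic receptor\tCell membrane"),
    file.path(d, "ann.tsv"))
  ann <- read_annotations(file.path(d, "ann.tsv"))
  expect_true(ann$is_membrane[ann$accession == "A1"])
  expect_false(ann$is_membrane[ann$accession == "A2"])
  expect_true(ann$is_membrane[ann$accession == "A3"])
  for (a in c("P56159", "O00451", "O60609")) {
    row <- ann[ann$accession == a, ]
    expect_true(row$is_membrane)
    expect_true(row$is_growth_factor_receptor)
    expect_true(row$is_neurotrophic_receptor)
  }
})

test_that("curated receptor list wins even without receptor keywords", {
  d <- withr::local_tempdir()
  writeLines(c("accession\tgene_symbol\tkeywords\tsubcellular_location",
               "Q16620\tNTRK2\tMembrane\tCell membrane"),
             file.path(d, "ann.tsv"))
  ann <- read_annotations(file.path(d, "ann.tsv"))
  expect_true(ann$is_neurotrophic_receptor[1])
  expect_true(ann$is_growth_factor_receptor[1])
  ann2 <- read_annotations(file.path(d, "ann.tsv"), curated = NULL)
  expect_false(ann2$is_neurotrophic_receptor[1])
})

test_that("annotation reading is order-invariant and validates input", {
  d <- withr::local_tempdir()
  hdr <- "accession\tgene_symbol\tkeywords\tsubcellular_location"
  rows <- sprintf("B%02d\tGB%02d\t%s\t", 1:6, 1:6,
                  rep(c("Membrane", ""), 3))
  writeLines(c(hdr, rows), file.path(d, "a.tsv"))
  set.seed(5)
  writeLines(c(hdr, sample(rows)), file.path(d, "b.tsv"))
  a <- read_annotations(file.path(d, "a.tsv"), source_version = "v")
  b <- read_annotations(file.path(d, "b.tsv"), source_version = "v")
  expect_identical(a, b)  # AnnotationSet is sorted by accession

  writeLines(c("gene_symbol\tkeywords", "X\tMembrane"),
             file.path(d, "noacc.tsv"))
  expect_error(read_annotations(file.path(d, "noacc.tsv")), "accession")
  writeLines(hdr, file.path(d, "empty.tsv"))
  expect_error(read_annotations(file.path(d, "empty.tsv")), "empty")
})

test_that("annotation_set enforces the class-nesting invariant", {
  df <- data.frame(accession = "X1", gene_symbol = "X1",
                   is_membrane = FALSE, is_growth_factor_receptor = TRUE,
                   is_neurotrophic_receptor = FALSE,
                   subcellular_locations = "", stringsAsFactors = FALSE)
  expect_error(annotation_set(df), "nesting")
  df2 <- df
  df2$is_growth_factor_receptor <- FALSE
  df2$is_neurotrophic_receptor <- TRUE
  expect_error(annotation_set(df2), "nesting")
})

test_that("the packaged ligand KB reproduces the five supplementation pairs", {
  kb <- default_ligand_kb()
  pairs <- paste(kb$receptor_symbol, kb$ligand_name)
  for (p in c("NTRK2 BDNF", "CNTFR CNTF", "GFRA1 GDNF", "GFRA2 NRTN",
              "GFRA3 PSPN"))
    expect_true(p %in% pairs, label = p)
  expect_true(all(kb$ligand_available[match(
    c("NTRK2 BDNF", "CNTFR CNTF", "GFRA1 GDNF", "GFRA2 NRTN",
      "GFRA3 PSPN"), pairs)]))
})

test_that("ligand KB validation: duplicates fatal, multiplicity allowed", {
  d <- withr::local_tempdir()
  writeLines(c("receptor_symbol\treceptor_accession\tligand_name\tligand_available\tnotes",
               "R1\tA1\tL1\tTRUE\t",
               "R1\tA1\tL2\tTRUE\tsecond ligand",
               "R2\tA2\tL1\tFALSE\t"),
             file.path(d, "kb.tsv"))
  kb <- read_ligand_kb(file.path(d, "kb.tsv"))
  expect_equal(nrow(kb), 3L)        # one receptor, two ligands: both kept
  expect_identical(kb$notes[1], "") # empty notes accepted
  writeLines(c("receptor_symbol\treceptor_accession\tligand_name",
               "R1\tA1\tL1", "R1\tA1\tL1"),
             file.path(d, "dup.tsv"))
  expect_error(read_ligand_kb(file.path(d, "dup.tsv")), "duplicate")
})

test_that("KB survives a TSV write/read round trip", {
  kb <- default_ligand_kb()
  d <- withr::local_tempdir()
  write_ligand_kb(kb, file.path(d, "kb.tsv"))
  expect_identical(read_ligand_kb(file.path(d, "kb.tsv")), kb)
})

test_that("write_report is deterministic and round-trips values", {
  sim <- simulate_rlm_study(small_config(seed = 31L))
  qn <- normalize_ibaq(sim$quant)
  rec <- differential(qn)
  cls <- classify_receptors(filter_membrane(rec, sim$annotations),
                            sim$annotations)
  cand <- select_enriched_receptors(cls$neurotrophic)
  recs <- match_ligands(cand, sim$kb)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(recs, rec, d1)
  write_report(recs, rec, d2)
  for (f in c("recommendations.tsv", "differential.tsv",
              "recommendations.json"))
    expect_same_bytes(file.path(d1, f), file.path(d2, f))
  back <- read_differential_tsv(file.path(d1, "differential.tsv"))
  ord <- order(rec$accession)
  expect_equal(back$p_value, rec$p_value[ord], tolerance = 1e-12)
  expect_equal(back$log2_ratio, rec$log2_ratio[ord], tolerance = 1e-12)
})

test_that("an empty recommendation set writes a header-only TSV", {
  sim <- simulate_rlm_study(small_config(seed = 32L))
  qn <- normalize_ibaq(sim$quant)
  rec <- differential(qn)
  empty <- match_ligands(rec[0, ], sim$kb)
  d <- withr::local_tempdir()
  write_report(empty, rec, d, formats = "tsv")
  lines <- readLines(file.path(d, "recommendations.tsv"))
  expect_length(lines, 1L)
  expect_match(lines, "^rank\t")
})
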