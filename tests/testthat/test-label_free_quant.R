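test_that("total-intensity normalization yields relative iBAQ fractions", {
  qm <- make_qm(matrix(c(2, 3, 5, 2, 3, 5), 3, 2), n_batches = 1)
  qn <- normalize_ibaq(qm)
  expect_equal(unname(qn$intensities[, 1]), c(0.2, 0.3, 0.5))
  expect_true(qn$normalized)
  # zeros preserved
  qm2 <- make_qm(matrix(c(0, 1, 3, 4, 0, 6), 3, 2), n_batches = 1)
  expect_equal(unname(normalize_ibaq(qm2)$intensities[1, 1]), 0)
  # all-zero column is fatal and names the sample
  qm3 <- make_qm(matrix(c(0, 0, 0, 1, 2, 3), 3, 2), n_batches = 1)
  expect_error(normalize_ibaq(qm3), "hiPSC_b1")
})

test_that("normalization conserves column sums to 1e-12 on random matrices", {
  set.seed(21)
  for (rep in 1:20) {
    m <- matrix(rlnorm(30 * 6, meanlog = 8, sdlog = 2), 30, 6)
    m[sample(length(m), 25)] <- 0
    qn <- normalize_ibaq(make_qm(m))
    expect_true(all(abs(colSums(qn$intensities) - 1) < 1e-12))
  }
})

test_that("scaling a raw sample column leaves normalized values unchanged", {
  set.seed(22)
  m <- matrix(rlnorm(40 * 6, 8, 1.5), 40, 6)
  q1 <- normalize_ibaq(make_qm(m))
  m2 <- m
  m2[, 3] <- m2[, 3] * 10
  m2[, 5] <- m2[, 5] * 0.037
  q2 <- normalize_ibaq(make_qm(m2))
  expect_equal(q1$intensities, q2$intensities, tolerance = 1e-12)
  # and therefore all downstream differential records are unchanged
  expect_equal(differential(q1), differential(q2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("detection flags follow the min-batches rule per condition", {
  m <- rbind(P1 = c(0, 0, 0, 0, 0, 0),    # neither
             P2 = c(0, 0, 0, 5, 6, 7),    # iN only
             P3 = c(1, 2, 3, 0, 0, 0),    # hiPSC only
             P4 = c(1, 2, 3, 4, 5, 6),    # both
             P5 = c(0, 0, 0, 9, 0, 0))    # single iN batch
  det <- detection_flags(make_qm(m), min_batches = 2)
  expect_equal(det$detection_class,
               c("neither", "B_only", "A_only", "both", "neither"))
  expect_equal(det$n_detected_B, c(0L, 3L, 0L, 3L, 1L))
  expect_false(det$quantifiable_B[5])  # 1 batch < min_batches = 2
  det1 <- detection_flags(make_qm(m), min_batches = 1)
  expect_equal(det1$detection_class[5], "B_only")
  expect_error(detection_flags(make_qm(m), min_batches = 4), "min_batches")
  expect_error(detection_flags(make_qm(m), min_batches = 0), "min_batches")
})

test_that("a protein identical across all samples gives log2 0 and p 1", {
  m <- rbind(FLAT = rep(3, 6), OTHER = rep(7, 6))
  rec <- differential(normalize_ibaq(make_qm(m)))
  flat <- rec[rec$accession == "FLAT", ]
  expect_equal(flat$log2_ratio, 0)
  expect_equal(flat$p_value, 1)
})

test_that("a 16-fold planted protein is estimated near log2 = 4 and its
           p-value matches the independent Welch oracle to 1e-12", {
  set.seed(23)
  n <- 200
  # background proteins constant across samples so total intensity is
  # stable; protein 1 planted at 16-fold with negligible noise
  base_vec <- rlnorm(n, 8, 1.5)
  m <- matrix(rep(base_vec, 6), n, 6)
  m[1, ] <- 2e3 * c(exp(rnorm(3, 0, 0.01)), 16 * exp(rnorm(3, 0, 0.01)))
  m[2:11, ] <- m[2:11, ] * exp(matrix(rnorm(60, 0, 0.3), 10, 6))
  qn <- normalize_ibaq(make_qm(m))
  rec <- differential(qn, min_batches = 1, test = "welch")
  expect_gt(rec$log2_ratio[1], 3.9)
  expect_lt(rec$log2_ratio[1], 4.1)
  floor <- attr(rec, "floor")
  lg <- log10(qn$intensities + floor)
  for (i in c(1, 5, 8)) {
    p_oracle <- welch_p_oracle(lg[i, 4:6], lg[i, 1:3])
    expect_equal(rec$p_value[i], p_oracle, tolerance = 1e-12)
  }
})

test_that("swapping condition labels negates log2 ratios, p unchanged", {
  set.seed(24)
  m <- matrix(rlnorm(60 * 6, 8, 1.5), 60, 6)
  m[sample(length(m), 30)] <- 0
  r1 <- differential(normalize_ibaq(make_qm(m)), min_batches = 1)
  # same data, reversed condition assignment (iN first)
  m_sw <- m[, c(4:6, 1:3)]
  r2 <- differential(normalize_ibaq(make_qm(m_sw,
          condition_levels = c("iN", "hiPSC"))), min_batches = 1)
  r2 <- r2[match(r1$accession, r2$accession), ]
  expect_equal(r2$log2_ratio, -r1$log2_ratio, tolerance = 1e-10)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-10)
})

test_that("fewer than two batches per condition yields sentinel p = 1", {
  m <- matrix(c(1, 5, 2, 9), 2, 2,
              dimnames = list(c("P1", "P2"), NULL))
  qm <- make_qm(m, n_batches = 1)
  expect_warning(rec <- differential(normalize_ibaq(qm), min_batches = 1),
                 "p-values")
  expect_true(all(rec$p_value == 1))
  expect_false(any(is.na(rec$ratio_B_over_A)))  # ratios still computed
})

test_that("volcano table has finite coordinates and a counting oracle", {
  set.seed(25)
  m <- matrix(rlnorm(80 * 6, 8, 2), 80, 6)
  m[sample(length(m), 120)] <- 0
  rec <- differential(normalize_ibaq(make_qm(m)), min_batches = 2)
  v <- volcano_table(rec)
  expect_true(all(is.finite(v$log2_ratio)))
  expect_true(all(is.finite(v$minus_log10_p)))
  # independent naive filter over the records
  naive <- sum(is.finite(log2(rec$ratio_B_over_A)) &
                 is.finite(-log10(rec$p_value)))
  expect_equal(nrow(v), naive)
})

test_that("volcano maps p = 0.01 to 2 and the flat point to the origin", {
  rec <- data.frame(accession = c("A", "B"), gene_symbol = c("A", "B"),
                    ratio_B_over_A = c(2, 1), log2_ratio = c(1, 0),
                    p_value = c(0.01, 1), stringsAsFactors = FALSE)
  v <- volcano_table(rec)
  expect_equal(v$minus_log10_p, c(2, 0))
  expect_equal(v$log2_ratio[2], 0)
})

test_that("marker panels summarize and call enrichment directions", {
  set.seed(26)
  n <- 40
  base <- rlnorm(n, 8, 1)
  # markers are kept small relative to the total so planting them does not
  # disturb the per-sample totals that normalization divides by
  base[1:8] <- rlnorm(8, 4, 0.3)
  m <- matrix(rep(base, 6), n, 6) * exp(matrix(rnorm(n * 6, 0, 0.02), n, 6))
  sym <- sprintf("G%02d", seq_len(n))
  sym[1:3] <- c("OCT4", "SOX2", "LIN28A")   # planted high in hiPSC
  sym[4:6] <- c("SYP", "SHANK2", "SNCA")    # planted high in iN
  sym[7:8] <- c("ATP5F1A", "TUBB")          # balanced
  m[1:3, 4:6] <- m[1:3, 4:6] / 50
  m[4:6, 4:6] <- m[4:6, 4:6] * 50
  qn <- normalize_ibaq(make_qm(m, gene_symbols = sym))
  rec <- differential(qn, min_batches = 1)
  res <- marker_panel_summary(qn, rec)
  calls <- setNames(res$calls$call, res$calls$panel)
  expect_equal(calls[["pluripotency"]], "enriched-in-A")
  expect_equal(calls[["neuronal_synaptic"]], "enriched-in-B")
  expect_equal(calls[["housekeeping"]], "balanced")
  # summary has one row per marker and condition, with finite sem
  expect_equal(nrow(res$summary), 8L * 2L)
  expect_true(all(is.finite(res$summary$sem)))
  expect_length(res$unresolved, 0L)
})

test_that("unresolvable markers are reported without affecting the rest", {
  set.seed(27)
  m <- matrix(rlnorm(10 * 6, 8, 1), 10, 6)
  sym <- c("OCT4", "SOX2", "LIN28A", sprintf("G%d", 4:10))
  qn <- normalize_ibaq(make_qm(m, gene_symbols = sym))
  rec <- differential(qn, min_batches = 1)
  res <- suppressWarnings(marker_panel_summary(qn, rec))
  expect_true(any(grepl("SYP", res$unresolved)))
  expect_true("pluripotency" %in% res$summary$panel)
  expect_false("SYP" %in% res$summary$marker)
})

test_that("Benjamini-Hochberg adjustment is available and monotone", {
  set.seed(28)
  m <- matrix(rlnorm(50 * 6, 8, 1.5), 50, 6)
  rec <- differential(normalize_ibaq(make_qm(m)), adjust = "BH",
                      min_batches = 1)
  expect_true(all(rec$p_adjusted >= rec$p_value - 1e-15))
  expect_equal(rec$p_adjusted, p.adjust(rec$p_value, "BH"))
})
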