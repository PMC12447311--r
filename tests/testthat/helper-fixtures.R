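# Shared fixture builders and independent oracles. Everything is built in
# code; no binary fixtures.

# a minimal 2-condition x n_batches QuantMatrix from a numeric matrix
make_qm <- function(m, n_batches = ncol(m) / 2, gene_symbols = NULL,
                    normalized = FALSE,
                    condition_levels = c("hiPSC", "iN")) {
  batches <- sprintf("b%d", seq_len(n_batches))
  samples <- data.frame(
    sample_id = c(paste0(condition_levels[1], "_", batches),
                  paste0(condition_levels[2], "_", batches)),
    condition = factor(rep(condition_levels, each = n_batches),
                       levels = condition_levels),
    batch = rep(batches, 2), stringsAsFactors = FALSE)
  if (is.null(rownames(m))) rownames(m) <- sprintf("P%05d", seq_len(nrow(m)))
  colnames(m) <- samples$sample_id
  quant_matrix(m, samples, gene_symbols = gene_symbols,
               normalized = normalized)
}

# textbook Welch two-sample t-test, coded independently of stats::t.test
welch_p_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) return(if (mean(x) == mean(y)) 1 else 0)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

# small-study generator config used across tests (fast, fully featured)
small_config <- function(...) {
  defaults <- list(
    n_proteins = 400L, frac_membrane = 0.25, n_gf_receptors = 10L,
    n_neurotrophic = 8L,
    planted_effects = c(NTRK2 = 16, CNTFR = 16, GFRA1 = 16, GFRA2 = 16,
                        GFRA3 = 16),
    low_abundance = character(0), n_batches = 3L,
    base_log10_mean = 6, base_log10_sd = 1.2, batch_sd = 0.15,
    noise_sd = 0.05, detection_midpoint = 3.5, detection_slope = 1.2,
    seed = 101L)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# a no-censoring, no-effect null config
null_config <- function(n_proteins = 2000L, seed = 11L, ...) {
  small_config(n_proteins = n_proteins, planted_effects = numeric(0) |>
                 stats::setNames(character(0)),
               detection_midpoint = -50, detection_slope = Inf,
               noise_sd = 0.15, seed = seed, ...)
}

expect_same_bytes <- function(p1, p2) {
  expect_identical(readBin(p1, "raw", file.info(p1)$size),
                   readBin(p2, "raw", file.info(p2)$size))
}
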