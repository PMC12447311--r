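#' Total-intensity (relative iBAQ) normalization
#'
#' Divides every sample column by its column sum, turning raw iBAQ values
#' into relative iBAQ fractions so samples of different total signal are
#' comparable. Zeros (non-detections) are preserved as zeros; after
#' normalization every column sums to 1.
#'
#' @param qm a raw \code{QuantMatrix} (\code{normalized = FALSE}).
#' @return the normalized \code{QuantMatrix}.
#' @export
normalize_ibaq <- function(qm) {
  stopifnot(inherits(qm, "QuantMatrix"))
  if (qm$normalized) stop("QuantMatrix is already normalized")
  cs <- colSums(qm$intensities)
  if (any(cs <= 0))
    stop("all-zero sample column(s): ",
         paste(colnames(qm$intensities)[cs <= 0], collapse = ", "))
  m <- sweep(qm$intensities, 2, cs, "/")
  quant_matrix(m, qm$samples, gene_symbols = qm$gene_symbols,
               normalized = TRUE)
}

#' Per-protein detection status
#'
#' A protein is quantifiable in a condition iff it is nonzero in at least
#' \code{min_batches} batches of that condition (with one sample per
#' condition and batch this is a count of nonzero samples). The default of
#' 2 requires a majority of the standard three-batch design, so single
#' spurious detections do not count as quantified.
#'
#' @param qm a \code{QuantMatrix} (raw or normalized; zeros are what count).
#' @param min_batches integer in \[1, n_batches\].
#' @return data.frame with \code{accession}, per-condition detection counts
#'   \code{n_detected_A}/\code{n_detected_B}, quantifiability flags, and
#'   \code{detection_class} in \{both, A_only, B_only, neither\} (A is the
#'   reference condition, e.g. hiPSC; B the derived one, e.g. iN).
#' @export
detection_flags <- function(qm, min_batches = 2L) {
  stopifnot(inherits(qm, "QuantMatrix"))
  n_batches <- length(unique(qm$samples$batch))
  if (!is.numeric(min_batches) || length(min_batches) != 1L ||
      min_batches < 1 || min_batches > n_batches)
    stop("min_batches must be in [1, ", n_batches, "]")
  # count distinct batches (not samples) with signal, per condition
  batch_detect <- function(which) {
    sm <- qm$samples[qm$samples$condition ==
                       levels(qm$samples$condition)[which], ]
    pos <- qm$intensities[, sm$sample_id, drop = FALSE] > 0
    by_batch <- rowsum(t(pos) + 0L, group = sm$batch)
    rowSums(t(by_batch) > 0)
  }
  nA <- batch_detect(1)
  nB <- batch_detect(2)
  qA <- nA >= min_batches
  qB <- nB >= min_batches
  cls <- ifelse(qA & qB, "both",
         ifelse(qA, "A_only", ifelse(qB, "B_only", "neither")))
  data.frame(accession = rownames(qm$intensities),
             n_detected_A = as.integer(nA), n_detected_B = as.integer(nB),
             quantifiable_A = qA, quantifiable_B = qB,
             detection_class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Two-sample t on pre-transformed values; handles the degenerate
# zero-variance case (t.test refuses constant data): equal means -> p = 1,
# unequal -> p = 0 (unreachable with continuous noise).
.t_p <- function(x, y, pooled) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y, var.equal = pooled)$p.value
}
.student_p <- function(x, y) .t_p(x, y, pooled = TRUE)
.welch_p <- function(x, y) .t_p(x, y, pooled = FALSE)

.wilcox_p <- function(x, y) {
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
}

#' Differential protein expression between the two cell states
#'
#' For every protein quantifiable in at least one condition, computes the
#' per-condition means of normalized iBAQ, the B/A abundance ratio and its
#' log2, and a p-value from a two-sample test across batches on
#' log10(intensity + floor).
#'
#' The floor is a global pseudo-intensity,
#' \code{floor_factor * quantile(positive normalized values, floor_quantile)}
#' (default: half the smallest positive normalized intensity). It is applied
#' to both condition means before forming the ratio, so one-sided detections
#' give large but finite fold changes, the volcano stays plottable, and
#' swapping the condition labels exactly negates every log2 ratio.
#'
#' @param qm_normalized a normalized \code{QuantMatrix}.
#' @param floor_quantile quantile (in \[0, 1\]) of the positive normalized
#'   intensities used as the floor reference; 0 means the minimum.
#' @param floor_factor multiplier applied to that reference (default 0.5).
#' @param min_batches detection threshold passed to
#'   \code{\link{detection_flags}}.
#' @param test \code{"student"} (default: pooled two-sample t, exact under
#'   the equal-variance log-normal model and the only choice with nominal
#'   size at n = 3 per group; also the classical volcano test),
#'   \code{"welch"} (unequal-variance t; slightly conservative at n = 3),
#'   or \code{"wilcoxon"} (rank test for larger designs; degenerate at
#'   n = 3, where its smallest two-sided p is 0.1).
#' @param adjust \code{"none"} (default; raw p-values, as on the volcano) or
#'   \code{"BH"} to append a Benjamini-Hochberg adjusted column.
#' @return data.frame of class \code{rlm_differential}: accession,
#'   gene_symbol, mean_norm_A, mean_norm_B, ratio_B_over_A, log2_ratio,
#'   p_value, detection counts and class. The floor used is stored in
#'   \code{attr(, "floor")}.
#' @export
differential <- function(qm_normalized, floor_quantile = 0,
                         floor_factor = 0.5, min_batches = 2L,
                         test = c("student", "welch", "wilcoxon"),
                         adjust = c("none", "BH")) {
  stopifnot(inherits(qm_normalized, "QuantMatrix"))
  test <- match.arg(test); adjust <- match.arg(adjust)
  if (!qm_normalized$normalized)
    stop("differential() requires a normalized QuantMatrix")
  if (floor_quantile < 0 || floor_quantile > 1)
    stop("floor_quantile must be in [0, 1]")
  m <- qm_normalized$intensities
  pos <- m[m > 0]
  if (!length(pos)) stop("no positive intensities")
  floor <- floor_factor *
    as.numeric(stats::quantile(pos, floor_quantile, names = FALSE))
  a_cols <- condition_samples(qm_normalized, 1)
  b_cols <- condition_samples(qm_normalized, 2)
  det <- detection_flags(qm_normalized, min_batches = min_batches)
  keep <- det$detection_class != "neither"

  few <- length(a_cols) < 2L || length(b_cols) < 2L
  if (few)
    warning("fewer than 2 batches in a condition: p-values set to 1")
  pfun <- switch(test, student = .student_p, welch = .welch_p,
                 wilcoxon = .wilcox_p)

  mA <- rowMeans(m[, a_cols, drop = FALSE])
  mB <- rowMeans(m[, b_cols, drop = FALSE])
  ratio <- pmax(mB, floor) / pmax(mA, floor)
  lg <- log10(m + floor)
  pv <- rep(NA_real_, nrow(m))
  idx <- which(keep)
  if (few) {
    pv[idx] <- 1
  } else {
    for (i in idx) pv[i] <- pfun(lg[i, b_cols], lg[i, a_cols])
  }
  res <- data.frame(
    accession = rownames(m),
    gene_symbol = unname(qm_normalized$gene_symbols),
    mean_norm_A = mA, mean_norm_B = mB,
    ratio_B_over_A = ratio, log2_ratio = log2(ratio),
    p_value = pv,
    n_detected_A = det$n_detected_A, n_detected_B = det$n_detected_B,
    quantifiable_A = det$quantifiable_A, quantifiable_B = det$quantifiable_B,
    detection_class = det$detection_class,
    row.names = NULL, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(res) <- NULL
  if (adjust == "BH") res$p_adjusted <- stats::p.adjust(res$p_value, "BH")
  attr(res, "floor") <- floor
  attr(res, "test") <- test
  class(res) <- c("rlm_differential", "data.frame")
  res
}

#' Volcano export table
#'
#' Two plotting coordinates per plottable protein: log2 fold change and
#' -log10 p. Rows with non-finite coordinates are dropped (proteins
#' quantified in neither condition were already excluded upstream).
#'
#' @param records a \code{\link{differential}} table.
#' @return data.frame with accession, gene_symbol, log2_ratio,
#'   minus_log10_p.
#' @export
volcano_table <- function(records) {
  out <- data.frame(accession = records$accession,
                    gene_symbol = records$gene_symbol,
                    log2_ratio = records$log2_ratio,
                    minus_log10_p = -log10(records$p_value),
                    stringsAsFactors = FALSE)
  out <- out[is.finite(out$log2_ratio) & is.finite(out$minus_log10_p), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
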