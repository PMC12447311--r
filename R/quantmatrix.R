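#' Quantification matrix with sample metadata
#'
#' A \code{QuantMatrix} carries a protein-by-sample matrix of label-free
#' iBAQ intensities together with its sample metadata. Undetected proteins
#' are stored as exact zeros (the non-detection sentinel); intensities are
#' never negative. After \code{\link{normalize_ibaq}} every sample column
#' holds the relative iBAQ fraction and sums to 1.
#'
#' @param intensities numeric matrix, proteins in rows (rownames are UniProt
#'   accessions), samples in columns (colnames are sample ids). Non-negative;
#'   zeros mean "not detected".
#' @param samples data.frame with columns \code{sample_id}, \code{condition}
#'   (factor with exactly two levels; the first level is the reference state,
#'   by default "hiPSC", the second the derived state, "iN") and
#'   \code{batch}. Each batch label must appear in both conditions
#'   (paired-by-batch design).
#' @param gene_symbols character vector parallel to the rows (display only;
#'   the accession is the primary key). Defaults to the accessions.
#' @param normalized logical; \code{TRUE} once columns are relative iBAQ.
#' @return an object of class \code{QuantMatrix}.
#' @export
quant_matrix <- function(intensities, samples, gene_symbols = NULL,
                         normalized = FALSE) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix")
  if (is.null(rownames(intensities)))
    stop("'intensities' must have accession rownames")
  if (anyDuplicated(rownames(intensities)))
    stop("duplicate accessions in intensity matrix")
  if (anyNA(intensities))
    stop("NA intensities are not allowed; encode non-detection as 0")
  if (any(intensities < 0))
    stop("negative intensities are not allowed")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "batch")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample metadata")
  if (!is.factor(samples$condition))
    samples$condition <- factor(samples$condition)
  if (nlevels(samples$condition) != 2L)
    stop("'condition' must have exactly two levels, got: ",
         paste(levels(samples$condition), collapse = ", "))
  samples$batch <- as.character(samples$batch)
  tab <- table(samples$batch, samples$condition)
  if (any(tab == 0L))
    stop("every batch label must appear in both conditions")
  if (ncol(intensities) != nrow(samples))
    stop("intensity matrix has ", ncol(intensities),
         " columns but metadata lists ", nrow(samples), " samples")
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- samples$sample_id
  } else {
    if (!setequal(colnames(intensities), samples$sample_id))
      stop("intensity column names do not match sample_id metadata")
    intensities <- intensities[, samples$sample_id, drop = FALSE]
  }
  if (is.null(gene_symbols)) gene_symbols <- rownames(intensities)
  if (length(gene_symbols) != nrow(intensities))
    stop("'gene_symbols' must be parallel to the matrix rows")
  gene_symbols <- as.character(gene_symbols)
  names(gene_symbols) <- rownames(intensities)
  if (isTRUE(normalized)) {
    cs <- colSums(intensities)
    if (any(abs(cs - 1) > 1e-9))
      stop("normalized = TRUE but column sums deviate from 1")
  }
  structure(
    list(intensities = intensities, gene_symbols = gene_symbols,
         samples = samples, normalized = isTRUE(normalized)),
    class = "QuantMatrix")
}

#' @export
print.QuantMatrix <- function(x, ...) {
  cat(sprintf("QuantMatrix: %d proteins x %d samples (%s)\n",
              nrow(x$intensities), ncol(x$intensities),
              if (x$normalized) "normalized relative iBAQ" else "raw iBAQ"))
  cat("conditions:",
      paste(sprintf("%s (n=%d)", levels(x$samples$condition),
                    tabulate(x$samples$condition)), collapse = ", "), "\n")
  cat("batches:", paste(unique(x$samples$batch), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.QuantMatrix <- function(x) dim(x$intensities)

#' Accessions of a QuantMatrix
#' @param qm a QuantMatrix
#' @return character vector of protein accessions (row order)
#' @export
accessions <- function(qm) rownames(qm$intensities)

#' Sample ids of one condition
#' @param qm a QuantMatrix
#' @param which 1 for the reference condition (first factor level), 2 for
#'   the derived condition
#' @return character vector of sample ids
#' @export
condition_samples <- function(qm, which) {
  lev <- levels(qm$samples$condition)[which]
  qm$samples$sample_id[qm$samples$condition == lev]
}

#' Restrict a QuantMatrix to a set of accessions
#' @param qm a QuantMatrix
#' @param acc accessions to keep (order preserved from \code{qm})
#' @return a QuantMatrix
#' @export
subset_proteins <- function(qm, acc) {
  keep <- intersect(rownames(qm$intensities), acc)
  quant_matrix(qm$intensities[keep, , drop = FALSE], qm$samples,
               gene_symbols = qm$gene_symbols[keep],
               normalized = FALSE)
}
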