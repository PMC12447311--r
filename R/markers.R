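#' Default differentiation-QC marker panels
#'
#' Three panels used to judge differentiation efficiency from the proteome:
#' pluripotency markers (expected high in hiPSCs), neuronal/synaptic
#' markers (expected high in induced neurons) and housekeeping controls
#' (ATP synthase subunit alpha, beta-tubulin; expected balanced).
#' @return named list of character vectors of gene symbols.
#' @export
default_marker_panels <- function() {
  list(pluripotency = c("OCT4", "SOX2", "LIN28A"),
       neuronal_synaptic = c("SYP", "SHANK2", "SNCA"),
       housekeeping = c("ATP5F1A", "TUBB"))
}

#' Marker-panel summary (mean +/- SEM per condition)
#'
#' Resolves each panel member to an accession through the quantification
#' table's gene symbols, summarizes its normalized iBAQ per condition
#' (mean and SEM across samples), and issues a qualitative panel-level
#' call — enriched-in-A, enriched-in-B or balanced — from the panel median
#' log2 ratio against the same fold-threshold machinery the differential
#' analysis uses. Members absent from the table are reported as unresolved,
#' never fatal.
#'
#' @param qm_normalized normalized \code{QuantMatrix}.
#' @param records the \code{\link{differential}} table for the same matrix.
#' @param panels named list of gene-symbol vectors
#'   (default \code{\link{default_marker_panels}}).
#' @param fold_threshold panel-call fold threshold (default 2: a panel is
#'   enriched when its median member changes at least two-fold).
#' @return list with \code{summary} (panel, marker, accession, condition,
#'   mean, sem), \code{calls} (panel, call, median_log2_ratio) and
#'   \code{unresolved} (panel-qualified symbols not found).
#' @export
marker_panel_summary <- function(qm_normalized, records,
                                 panels = default_marker_panels(),
                                 fold_threshold = 2) {
  stopifnot(inherits(qm_normalized, "QuantMatrix"))
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    stop("panels must be a named list")
  sym2acc <- stats::setNames(names(qm_normalized$gene_symbols),
                             qm_normalized$gene_symbols)
  m <- qm_normalized$intensities
  lev <- levels(qm_normalized$samples$condition)
  sem <- function(x) stats::sd(x) / sqrt(length(x))

  rows <- list(); calls <- list(); unresolved <- character(0)
  for (pn in names(panels)) {
    members <- panels[[pn]]
    if (!length(members)) stop("panel '", pn, "' has no members")
    acc <- sym2acc[members]
    bad <- is.na(acc)
    if (any(bad))
      unresolved <- c(unresolved, paste(pn, members[bad], sep = ":"))
    acc <- acc[!bad]; members <- members[!bad]
    if (!length(acc)) {
      warning("panel '", pn, "' has no resolvable members")
      calls[[pn]] <- data.frame(panel = pn, call = "unresolved",
                                median_log2_ratio = NA_real_,
                                stringsAsFactors = FALSE)
      next
    }
    for (k in seq_along(acc)) {
      for (cond in lev) {
        cols <- qm_normalized$samples$sample_id[
          qm_normalized$samples$condition == cond]
        v <- m[acc[k], cols]
        rows[[length(rows) + 1L]] <- data.frame(
          panel = pn, marker = members[k], accession = unname(acc[k]),
          condition = cond, mean = mean(v), sem = sem(v),
          stringsAsFactors = FALSE)
      }
    }
    lr <- records$log2_ratio[match(acc, records$accession)]
    med <- stats::median(lr, na.rm = TRUE)
    call <- if (is.na(med)) "unresolved"
            else if (med >= log2(fold_threshold)) "enriched-in-B"
            else if (med <= -log2(fold_threshold)) "enriched-in-A"
            else "balanced"
    calls[[pn]] <- data.frame(panel = pn, call = call,
                              median_log2_ratio = med,
                              stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, rows),
       calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
       unresolved = unresolved)
}
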