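#' Receptor-ligand matching parameters
#'
#' The selection rule of the RLM strategy: a receptor is a supplementation
#' candidate when it is at least \code{fold_threshold}-fold more abundant
#' in the derived state (iN) than in the source state (hiPSC) and — by
#' default — quantifiable in the derived state. The 10-fold default is the
#' enrichment cut applied to the neurotrophic receptor inventory.
#'
#' @param fold_threshold positive fold-change threshold (default 10).
#' @param direction only \code{"enriched_in_B"} is defined: supplements are
#'   chosen for the differentiated state.
#' @param require_quantifiable_in_B drop receptors not quantifiable in the
#'   derived condition (default TRUE; receptors "undetected or too low for
#'   quantification" are not actionable).
#' @param require_ligand_available when TRUE, only receptors whose KB
#'   ligand is commercially available can be selected for supplementation
#'   (default FALSE so the full table stays visible).
#' @return list of class \code{rlm_params}.
#' @export
rlm_params <- function(fold_threshold = 10,
                       direction = "enriched_in_B",
                       require_quantifiable_in_B = TRUE,
                       require_ligand_available = FALSE) {
  direction <- match.arg(direction, "enriched_in_B")
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1L ||
      is.na(fold_threshold) || fold_threshold <= 0)
    stop("fold_threshold must be a positive number")
  structure(list(fold_threshold = fold_threshold, direction = direction,
                 require_quantifiable_in_B =
                   isTRUE(require_quantifiable_in_B),
                 require_ligand_available =
                   isTRUE(require_ligand_available)),
            class = "rlm_params")
}

#' Select receptors enriched in the derived state
#'
#' Applies the RLM fold rule to (typically neurotrophic-receptor)
#' differential records: candidates have \code{ratio_B_over_A >=
#' fold_threshold} and, if required, are quantifiable in condition B.
#' Candidates are ordered by descending log2 ratio, ties broken by
#' ascending p-value then lexicographic accession, so the order is
#' deterministic under input permutation.
#'
#' @param records differential records carrying ratio, p-value and
#'   detection columns.
#' @param params an \code{\link{rlm_params}}.
#' @return ordered subset of \code{records}.
#' @export
select_enriched_receptors <- function(records, params = rlm_params()) {
  stopifnot(inherits(params, "rlm_params"))
  keep <- records$ratio_B_over_A >= params$fold_threshold
  if (params$require_quantifiable_in_B)
    keep <- keep & records$quantifiable_B
  out <- records[keep, , drop = FALSE]
  out <- out[order(-out$log2_ratio, out$p_value, out$accession), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.unmatched_sentinel <- "(no ligand in KB)"

#' Match candidate receptors to culture-medium ligands
#'
#' Joins the ordered candidate list to the receptor-ligand knowledgebase:
#' every candidate is paired with each of its KB ligands; candidates
#' without a KB entry are emitted once with the unmatched sentinel and can
#' never be selected. A recommendation is selected for supplementation iff
#' all required rationale flags hold: the fold rule, detection in the
#' derived state, a KB match, and — when
#' \code{params$require_ligand_available} — commercial availability of the
#' ligand.
#'
#' @param candidates output of \code{\link{select_enriched_receptors}}.
#' @param kb knowledgebase data.frame (\code{\link{read_ligand_kb}}).
#' @param params an \code{\link{rlm_params}}.
#' @return data.frame of recommendations: rank (1..k, no gaps), receptor
#'   symbol and accession, ligand, log2_ratio, p_value,
#'   selected_for_supplementation, rationale_flags (comma-joined).
#' @export
match_ligands <- function(candidates, kb, params = rlm_params()) {
  stopifnot(inherits(params, "rlm_params"))
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    hits <- kb[kb$receptor_accession == cand$accession |
                 kb$receptor_symbol == cand$gene_symbol, , drop = FALSE]
    flags <- c("fold_pass",
               if (cand$quantifiable_B) "detected_B")
    if (nrow(hits) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        receptor_symbol = cand$gene_symbol,
        receptor_accession = cand$accession,
        ligand_name = .unmatched_sentinel,
        ligand_available = FALSE,
        log2_ratio = cand$log2_ratio, p_value = cand$p_value,
        selected_for_supplementation = FALSE,
        rationale_flags = paste(flags, collapse = ","),
        stringsAsFactors = FALSE)
      next
    }
    for (j in seq_len(nrow(hits))) {
      f <- c(flags, "kb_match",
             if (isTRUE(hits$ligand_available[j])) "ligand_available")
      selected <- cand$quantifiable_B &&
        (!params$require_ligand_available ||
           isTRUE(hits$ligand_available[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        receptor_symbol = cand$gene_symbol,
        receptor_accession = cand$accession,
        ligand_name = hits$ligand_name[j],
        ligand_available = isTRUE(hits$ligand_available[j]),
        log2_ratio = cand$log2_ratio, p_value = cand$p_value,
        selected_for_supplementation = selected,
        rationale_flags = paste(f, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(receptor_symbol = character(0),
               receptor_accession = character(0),
               ligand_name = character(0), ligand_available = logical(0),
               log2_ratio = numeric(0), p_value = numeric(0),
               selected_for_supplementation = logical(0),
               rationale_flags = character(0), stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  out[, c("rank", setdiff(names(out), "rank"))]
}

#' Compare two supplement (ligand) sets
#'
#' Structured diff between a proposed supplement set and a reference one,
#' e.g. the RLM-derived ligands versus the conventional \{BDNF, NT3\}.
#'
#' @param rec_set_a proposed ligand names (character).
#' @param rec_set_b reference ligand names (character).
#' @return list with sorted character vectors \code{shared},
#'   \code{added} (in a, not b) and \code{removed} (in b, not a).
#' @export
compare_supplement_sets <- function(rec_set_a, rec_set_b) {
  a <- unique(as.character(rec_set_a)); b <- unique(as.character(rec_set_b))
  list(shared = sort(intersect(a, b)),
       added = sort(setdiff(a, b)),
       removed = sort(setdiff(b, a)))
}

#' Human-readable markdown summary of recommendations
#'
#' @param recs output of \code{\link{match_ligands}}.
#' @return character vector of markdown lines.
#' @export
format_rlm_markdown <- function(recs) {
  hdr <- c("| rank | receptor | ligand | log2(iN/hiPSC) | p | selected |",
           "|-----:|----------|--------|---------------:|---|:--------:|")
  body <- sprintf("| %d | %s | %s | %.2f | %.3g | %s |",
                  recs$rank, recs$receptor_symbol, recs$ligand_name,
                  recs$log2_ratio, recs$p_value,
                  ifelse(recs$selected_for_supplementation, "*", ""))
  c(hdr, body)
}
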