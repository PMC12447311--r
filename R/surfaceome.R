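## The annotation-mining funnel: quantified proteome -> membrane proteins
## -> growth-factor receptors -> neurotrophic receptors. Pure filters over
## the differential table and an AnnotationSet; each step logs its counts
## so the run report can state the funnel.

#' Restrict differential records to annotated membrane proteins
#'
#' Keeps records whose accession carries \code{is_membrane = TRUE} in the
#' annotation set. Unannotated accessions are excluded and counted; the
#' input and surviving counts are attached as \code{attr(, "funnel")}.
#'
#' @param records a \code{\link{differential}} table (or any data.frame
#'   with an \code{accession} column).
#' @param ann an \code{\link{annotation_set}}.
#' @return the surviving subset, same columns and order.
#' @export
filter_membrane <- function(records, ann) {
  memb <- ann$accession[ann$is_membrane]
  keep <- records$accession %in% memb
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "funnel") <- c(input = nrow(records), membrane = nrow(out),
                           unannotated = sum(!records$accession %in%
                                               ann$accession))
  out
}

#' Classify membrane records into receptor subsets
#'
#' Splits the membrane-filtered records into the growth-factor receptor
#' inventory and its neurotrophic subset according to the annotation flags.
#' The nesting invariant (neurotrophic is a subset of growth-factor
#' receptors) is guaranteed by the \code{AnnotationSet} constructor.
#'
#' @param records_membrane membrane-filtered differential records.
#' @param ann an \code{\link{annotation_set}}.
#' @return list with elements \code{growth_factor} and \code{neurotrophic},
#'   each a subset of \code{records_membrane} in input order.
#' @export
classify_receptors <- function(records_membrane, ann) {
  gf <- ann$accession[ann$is_growth_factor_receptor]
  nt <- ann$accession[ann$is_neurotrophic_receptor]
  g <- records_membrane[records_membrane$accession %in% gf, , drop = FALSE]
  n <- records_membrane[records_membrane$accession %in% nt, , drop = FALSE]
  rownames(g) <- NULL; rownames(n) <- NULL
  list(growth_factor = g, neurotrophic = n)
}

#' Funnel counts at every mining stage
#'
#' @param records full differential table.
#' @param ann an \code{\link{annotation_set}}.
#' @return named integer vector: quantified, membrane,
#'   growth_factor_receptors, neurotrophic_receptors.
#' @export
funnel_counts <- function(records, ann) {
  memb <- filter_membrane(records, ann)
  cls <- classify_receptors(memb, ann)
  c(quantified = nrow(records), membrane = nrow(memb),
    growth_factor_receptors = nrow(cls$growth_factor),
    neurotrophic_receptors = nrow(cls$neurotrophic))
}
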