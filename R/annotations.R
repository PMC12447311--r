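## Annotation handling: UniProt-style tab exports are turned into an
## AnnotationSet with three nested boolean flags per accession:
##   is_neurotrophic_receptor => is_growth_factor_receptor => is_membrane
## Membrane status comes from declarative keyword/location rules; receptor
## classes come from the same rules OR'ed with a packaged curated list
## (the curated list wins: the boundary of the 29-receptor inventory is
## explicit and versioned rather than implied by keywords).

#' Default membrane-annotation rules
#'
#' Declarative rules mapping annotation text to flags. Each rule applies a
#' case-sensitive regular expression to one field (\code{keywords} or
#' \code{location}) and, on match, raises one flag. Read from
#' \code{inst/extdata/annotation_rules.tsv} so the operational definition of
#' "membrane protein list" is explicit and swappable.
#' @return data.frame with columns \code{field}, \code{pattern}, \code{flag}.
#' @export
default_annotation_rules <- function() {
  .read_table(system.file("extdata", "annotation_rules.tsv",
                          package = "rlmatch", mustWork = TRUE))
}

#' Packaged curated receptor classification
#'
#' The growth-factor receptor inventory used to classify the quantified
#' membrane proteome: 29 receptors, 15 of them neurotrophic (the TRK/p75,
#' GDNF-family and CNTF-family receptors plus MET and IGF1R). Includes every
#' receptor the differential analysis singles out (TRKB/NTRK2, CNTFR,
#' GFRA1/2/3, FGFR1, NTRK3/TRKC).
#' @return data.frame with columns \code{gene_symbol}, \code{accession},
#'   \code{class} (\code{growth_factor} or \code{neurotrophic}).
#' @export
default_receptor_classes <- function() {
  .read_table(system.file("extdata", "receptor_classes.tsv",
                          package = "rlmatch", mustWork = TRUE))
}

#' Construct and validate an AnnotationSet
#'
#' @param df data.frame with columns \code{accession}, \code{gene_symbol},
#'   \code{is_membrane}, \code{is_growth_factor_receptor},
#'   \code{is_neurotrophic_receptor}, \code{subcellular_locations}.
#' @param source_version free-text version label recorded in run reports
#'   (funnel counts depend on the annotation snapshot).
#' @return data.frame of class \code{AnnotationSet}, sorted by accession.
#' @export
annotation_set <- function(df, source_version = "unspecified") {
  req <- c("accession", "gene_symbol", "is_membrane",
           "is_growth_factor_receptor", "is_neurotrophic_receptor",
           "subcellular_locations")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$accession))
    stop("duplicate accessions in annotation: ",
         df$accession[duplicated(df$accession)][1])
  bad <- (df$is_neurotrophic_receptor & !df$is_growth_factor_receptor) |
         (df$is_growth_factor_receptor & !df$is_membrane)
  if (any(bad))
    stop("annotation violates class nesting (neurotrophic => growth-factor ",
         "receptor => membrane) for: ",
         paste(utils::head(df$accession[bad], 5), collapse = ", "))
  df <- df[order(df$accession), req, drop = FALSE]
  rownames(df) <- NULL
  attr(df, "source_version") <- source_version
  class(df) <- c("AnnotationSet", "data.frame")
  df
}

.first_col <- function(tab, candidates) {
  hit <- intersect(candidates, names(tab))
  if (length(hit)) tab[[hit[1]]] else NULL
}

#' Read a UniProt-style annotation export
#'
#' Parses a tab-separated UniProt export (human, organism code 9606) and
#' derives the flags. Column names are matched against the common UniProt
#' export headers (\code{Entry}, \code{Gene Names}, \code{Keywords},
#' \code{Subcellular location [CC]}) and their snake_case equivalents.
#'
#' Flags are derived from \code{rules}; receptor flags are OR'ed with the
#' curated list matched by accession or gene symbol. Implied flags are
#' propagated upward (a neurotrophic receptor is by definition a
#' growth-factor receptor at the cell membrane) before the nesting
#' invariant is validated.
#'
#' @param path tab-separated export.
#' @param rules rule table, see \code{\link{default_annotation_rules}}.
#' @param curated curated receptor table, see
#'   \code{\link{default_receptor_classes}}; \code{NULL} disables.
#' @param source_version label stored on the result; defaults to the file
#'   name.
#' @return an \code{AnnotationSet}.
#' @export
read_annotations <- function(path, rules = default_annotation_rules(),
                             curated = default_receptor_classes(),
                             source_version = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- .read_table(path)
  if (nrow(tab) == 0L) stop("annotation file is empty: ", path)
  acc <- .first_col(tab, c("Entry", "Accession", "accession"))
  if (is.null(acc)) stop("missing accession column in ", path)
  acc <- as.character(acc)
  sym <- .first_col(tab, c("Gene Names", "Gene Names (primary)",
                           "gene_symbol"))
  sym <- if (is.null(sym)) acc else sub(" .*", "", as.character(sym))
  kw <- .first_col(tab, c("Keywords", "keywords"))
  kw <- if (is.null(kw)) rep("", length(acc)) else as.character(kw)
  loc <- .first_col(tab, c("Subcellular location [CC]",
                           "subcellular_location", "Subcellular location"))
  loc <- if (is.null(loc)) rep("", length(acc)) else as.character(loc)
  kw[is.na(kw)] <- ""; loc[is.na(loc)] <- ""

  flags <- list(is_membrane = logical(length(acc)),
                is_growth_factor_receptor = logical(length(acc)),
                is_neurotrophic_receptor = logical(length(acc)))
  for (i in seq_len(nrow(rules))) {
    field <- switch(rules$field[i], keywords = kw, location = loc,
                    stop("unknown rule field: ", rules$field[i]))
    stopifnot(rules$flag[i] %in% names(flags))
    flags[[rules$flag[i]]] <- flags[[rules$flag[i]]] |
      grepl(rules$pattern[i], field)
  }
  if (!is.null(curated)) {
    hit <- acc %in% curated$accession | sym %in% curated$gene_symbol
    ntro <- curated$gene_symbol[curated$class == "neurotrophic"]
    ntro_acc <- curated$accession[curated$class == "neurotrophic"]
    flags$is_growth_factor_receptor <- flags$is_growth_factor_receptor | hit
    flags$is_neurotrophic_receptor <- flags$is_neurotrophic_receptor |
      (acc %in% ntro_acc | sym %in% ntro)
  }
  # nesting is definitional: propagate implied flags upward
  flags$is_growth_factor_receptor <- flags$is_growth_factor_receptor |
    flags$is_neurotrophic_receptor
  flags$is_membrane <- flags$is_membrane | flags$is_growth_factor_receptor

  annotation_set(
    data.frame(accession = acc, gene_symbol = sym,
               is_membrane = flags$is_membrane,
               is_growth_factor_receptor = flags$is_growth_factor_receptor,
               is_neurotrophic_receptor = flags$is_neurotrophic_receptor,
               subcellular_locations = loc, stringsAsFactors = FALSE),
    source_version = if (is.null(source_version)) basename(path)
                     else source_version)
}
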