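## Tabular I/O for quantification tables, sample metadata, the ligand
## knowledgebase and result reports. All readers are row-order invariant;
## all writers are deterministic (fixed column order, fixed row order,
## fixed number formatting) so outputs are byte-stable for fixed inputs.

# column-name conventions per input dialect; accession is always the key
.dialects <- list(
  generic_tsv = list(accession = "accession", gene = "gene_symbol",
                     intensity_prefix = ""),
  proteome_discoverer_export = list(accession = "Accession",
                                    gene = "Gene Symbol",
                                    intensity_prefix = "Abundance: ")
)

.read_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Read a wide protein-group quantification table
#'
#' Reads a wide TSV/CSV (one row per protein accession, one intensity column
#' per sample) plus a sample-metadata table, and returns a raw
#' \code{\link{quant_matrix}}. Empty cells, \code{NA} and 0 all map to the
#' non-detection sentinel 0: the analysis treats "undetected" and "too low
#' for quantification" as a single category.
#'
#' @param path quantification table. For \code{dialect = "generic_tsv"} the
#'   accession column is named \code{accession}, the optional gene column
#'   \code{gene_symbol}, and intensity columns are named exactly as the
#'   sample ids. For \code{"proteome_discoverer_export"} the columns are
#'   \code{Accession}, \code{Gene Symbol} and \code{Abundance: <sample_id>}.
#' @param meta_path sample metadata TSV/CSV with columns \code{sample_id},
#'   \code{condition}, \code{batch}.
#' @param dialect column-name convention, see above.
#' @param condition_levels order of the two condition levels; the first is
#'   the reference state. Default \code{c("hiPSC", "iN")} when both are
#'   present, otherwise the sorted unique values.
#' @return a \code{QuantMatrix} with \code{normalized = FALSE}. Rows sharing
#'   an accession are merged by summing intensities, with a warning.
#' @export
read_quant_table <- function(path, meta_path,
                             dialect = c("generic_tsv",
                                         "proteome_discoverer_export"),
                             condition_levels = NULL) {
  dialect <- match.arg(dialect)
  dd <- .dialects[[dialect]]
  if (!file.exists(path)) stop("quantification table not found: ", path)
  if (!file.exists(meta_path)) stop("sample metadata not found: ", meta_path)
  tab <- .read_table(path)
  meta <- .read_table(meta_path)
  req <- c("sample_id", "condition", "batch")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!dd$accession %in% names(tab))
    stop("missing accession column '", dd$accession, "' in ", path)
  if (is.null(condition_levels)) {
    u <- unique(as.character(meta$condition))
    condition_levels <- if (setequal(u, c("hiPSC", "iN"))) c("hiPSC", "iN")
                        else sort(u)
  }
  meta$condition <- factor(meta$condition, levels = condition_levels)

  icols <- paste0(dd$intensity_prefix, meta$sample_id)
  missing_cols <- setdiff(icols, names(tab))
  if (length(missing_cols))
    stop("missing intensity column(s) for declared sample(s): ",
         paste(missing_cols, collapse = ", "))

  acc <- as.character(tab[[dd$accession]])
  sym <- if (dd$gene %in% names(tab)) as.character(tab[[dd$gene]]) else acc
  sym[is.na(sym) | sym == ""] <- acc[is.na(sym) | sym == ""]

  m <- matrix(0, nrow(tab), length(icols),
              dimnames = list(NULL, meta$sample_id))
  for (j in seq_along(icols)) {
    v <- tab[[icols[j]]]
    if (is.character(v)) {
      v[v == "" | v == "NA"] <- "0"
      num <- suppressWarnings(as.numeric(v))
      if (anyNA(num)) {
        bad <- which(is.na(num))[1]
        stop("non-numeric intensity at row ", bad, ", column '", icols[j],
             "': '", v[bad], "'")
      }
      v <- num
    }
    v[is.na(v)] <- 0
    if (any(v < 0))
      stop("negative intensity in column '", icols[j], "' (row ",
           which(v < 0)[1], ")")
    m[, j] <- v
  }

  if (anyDuplicated(acc)) {
    dup <- unique(acc[duplicated(acc)])
    warning("merging ", length(dup),
            " duplicated accession(s) by summing intensities: ",
            paste(utils::head(dup, 5), collapse = ", "))
    m <- rowsum(m, group = acc, reorder = FALSE)
    sym <- sym[!duplicated(acc)]
    acc <- acc[!duplicated(acc)]
    m <- m[acc, , drop = FALSE]
  }
  rownames(m) <- acc
  quant_matrix(m, meta, gene_symbols = sym, normalized = FALSE)
}

#' Read a receptor-ligand knowledgebase
#'
#' The KB maps receptors to candidate culture-medium ligands. Accepted as
#' TSV (columns \code{receptor_symbol}, \code{receptor_accession},
#' \code{ligand_name}, \code{ligand_available}, \code{notes}) or as a JSON
#' array of objects with the same fields. One receptor may map to several
#' ligands; the (receptor_symbol, ligand_name) pair must be unique.
#'
#' @param path TSV or JSON file.
#' @return data.frame of KB entries.
#' @export
read_ligand_kb <- function(path) {
  if (!file.exists(path)) stop("ligand KB not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    kb <- jsonlite::fromJSON(path)
    kb <- as.data.frame(kb, stringsAsFactors = FALSE)
  } else {
    kb <- .read_table(path)
  }
  req <- c("receptor_symbol", "receptor_accession", "ligand_name")
  miss <- setdiff(req, names(kb))
  if (length(miss))
    stop("ligand KB lacks column(s): ", paste(miss, collapse = ", "))
  if (!"ligand_available" %in% names(kb)) kb$ligand_available <- TRUE
  if (!"notes" %in% names(kb)) kb$notes <- ""
  kb$notes[is.na(kb$notes)] <- ""
  kb$ligand_available <- as.logical(kb$ligand_available)
  key <- paste(kb$receptor_symbol, kb$ligand_name, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (receptor, ligand) pair in KB: ",
         sub("\r", " / ", key[duplicated(key)][1]))
  kb[, c("receptor_symbol", "receptor_accession", "ligand_name",
         "ligand_available", "notes")]
}

#' Packaged receptor-ligand knowledgebase
#'
#' The default KB curated for the neurotrophic receptor inventory of
#' NGN2-induced neurons: TRKB-BDNF, CNTFR-CNTF, GFRA1-GDNF, GFRA2-NRTN and
#' GFRA3-PSPN carry commercially available ligands (the supplementation
#' candidates); further neurotrophic receptors are listed with
#' \code{ligand_available = FALSE}.
#' @return data.frame of KB entries.
#' @export
default_ligand_kb <- function() {
  read_ligand_kb(system.file("extdata", "ligand_kb.tsv", package = "rlmatch",
                             mustWork = TRUE))
}

#' Write a QuantMatrix as a wide generic TSV plus sample metadata
#'
#' Inverse of \code{\link{read_quant_table}} (generic_tsv dialect); values
#' are written with 15 significant digits so the round trip is exact to
#' well under 1e-12 relative.
#' @param qm a QuantMatrix.
#' @param path output quantification TSV.
#' @param meta_path output sample-metadata TSV.
#' @return (invisibly) the paths written.
#' @export
write_quant_table <- function(qm, path, meta_path) {
  stopifnot(inherits(qm, "QuantMatrix"))
  df <- data.frame(accession = rownames(qm$intensities),
                   gene_symbol = unname(qm$gene_symbols),
                   stringsAsFactors = FALSE)
  for (s in colnames(qm$intensities)) df[[s]] <- qm$intensities[, s]
  .write_tsv(df, path)
  meta <- qm$samples
  meta$condition <- as.character(meta$condition)
  .write_tsv(meta, meta_path)
  invisible(c(path, meta_path))
}

#' Write an AnnotationSet as a UniProt-style tab export
#'
#' Keywords and locations are reconstructed from the flags so that
#' \code{\link{read_annotations}} with the default rules recovers the same
#' flags (use \code{curated = NULL} when reading back arbitrary sets).
#' @param ann an AnnotationSet.
#' @param path output TSV.
#' @return (invisibly) the path.
#' @export
write_annotations <- function(ann, path) {
  kw <- ifelse(ann$is_neurotrophic_receptor,
               "Membrane;Growth factor receptor;Neurotrophic receptor",
        ifelse(ann$is_growth_factor_receptor,
               "Membrane;Growth factor receptor",
        ifelse(ann$is_membrane, "Membrane", "")))
  df <- data.frame(accession = ann$accession,
                   gene_symbol = ann$gene_symbol,
                   keywords = kw,
                   subcellular_location = ann$subcellular_locations,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' Write any result table as a deterministic TSV
#'
#' Fixed column order, 15-significant-digit numeric formatting and binary
#' line endings: identical inputs give byte-identical files.
#' @param df data.frame.
#' @param path output TSV.
#' @return (invisibly) the path.
#' @export
write_tsv <- function(df, path) .write_tsv(df, path)

#' Write a ligand KB as TSV
#' @param kb KB data.frame.
#' @param path output TSV.
#' @return (invisibly) the path.
#' @export
write_ligand_kb <- function(kb, path) {
  .write_tsv(kb, path)
  invisible(path)
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.15g", v)
  }, character(1))
  out
}

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- .fmt_num(out[[j]])
  con <- file(path, open = "wb")  # binary mode: byte-stable line endings
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Write the result report
#'
#' Writes the recommendation table and the differential table with a
#' deterministic column order and row order (rank, then accession), so the
#' outputs are byte-identical for identical inputs. Numeric columns are
#' written with 15 significant digits and round-trip within 1e-12 relative.
#'
#' @param recommendations data.frame from \code{\link{match_ligands}} (may
#'   have zero rows).
#' @param differential_table data.frame from \code{\link{differential}}.
#' @param out_dir output directory (created if absent).
#' @param formats subset of \code{c("tsv", "json")}.
#' @return (invisibly) the paths written.
#' @export
write_report <- function(recommendations, differential_table, out_dir,
                         formats = c("tsv", "json")) {
  formats <- match.arg(formats, several.ok = TRUE)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir)
  rec <- recommendations[order(recommendations$rank,
                               recommendations$receptor_accession), ,
                         drop = FALSE]
  diff <- differential_table[order(differential_table$accession), ,
                             drop = FALSE]
  paths <- character(0)
  if ("tsv" %in% formats) {
    p1 <- file.path(out_dir, "recommendations.tsv")
    p2 <- file.path(out_dir, "differential.tsv")
    .write_tsv(rec, p1)
    .write_tsv(diff, p2)
    paths <- c(paths, p1, p2)
  }
  if ("json" %in% formats) {
    p3 <- file.path(out_dir, "recommendations.json")
    jsonlite::write_json(rec, p3, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' Read back a differential TSV written by \code{write_report}
#' @param path path to \code{differential.tsv}
#' @return data.frame
#' @export
read_differential_tsv <- function(path) {
  df <- .read_table(path)
  df
}
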