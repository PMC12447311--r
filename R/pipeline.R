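## End-to-end orchestration: normalize -> detect -> differential ->
## membrane filter -> receptor classify -> select -> match -> report.
## Driven by a single declarative config (a named list or a YAML file);
## every stage writes its table under out_dir, so any later stage can be
## resumed from disk, and the JSON run report records every parameter
## actually used plus the funnel counts.

.default_params <- list(
  min_batches = 2L, floor_quantile = 0, floor_factor = 0.5,
  test = "student", adjust = "none", fold_threshold = 10,
  require_quantifiable_in_B = TRUE, require_ligand_available = FALSE,
  marker_fold_threshold = 2)

.validate_config <- function(config) {
  known_top <- c("seed", "out_dir", "simulate", "input", "params",
                 "formats", "reference_supplements")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown))
    stop("config error: unknown field(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir))
    stop("config error: 'out_dir' is required")
  if (is.null(config$simulate) && is.null(config$input))
    stop("config error: either 'simulate' or 'input' must be given")
  if (!is.null(config$input)) {
    need <- c("quant", "meta", "annotations")
    miss <- setdiff(need, names(config$input))
    if (length(miss))
      stop("config error: input lacks field(s): ",
           paste(miss, collapse = ", "))
  }
  params <- utils::modifyList(.default_params,
                              as.list(config$params %||% list()))
  unknown_p <- setdiff(names(params), names(.default_params))
  if (length(unknown_p))
    stop("config error: unknown parameter(s): ",
         paste(unknown_p, collapse = ", "))
  config$params <- params
  config$seed <- as.integer(config$seed %||% 1L)
  config$formats <- config$formats %||% c("tsv", "json")
  config$reference_supplements <-
    config$reference_supplements %||% c("BDNF", "NT3")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full receptor-ligand matching pipeline
#'
#' Executes every stage from raw quantifications to the ranked
#' supplementation recommendation. The config is a named list or the path
#' to a YAML file with fields: \code{seed}; \code{out_dir}; either
#' \code{simulate} (logical TRUE or a list of \code{\link{synthetic_config}}
#' arguments) or \code{input} (paths \code{quant}, \code{meta},
#' \code{annotations}, optional \code{kb}, \code{dialect});
#' optional \code{params} (see Details), \code{formats},
#' \code{reference_supplements}.
#'
#' Parameters (all optional, shown with defaults): \code{min_batches} (2),
#' \code{floor_quantile} (0), \code{floor_factor} (0.5), \code{test}
#' ("welch"), \code{adjust} ("none"), \code{fold_threshold} (10),
#' \code{require_quantifiable_in_B} (TRUE),
#' \code{require_ligand_available} (FALSE),
#' \code{marker_fold_threshold} (2).
#'
#' @param config named list or YAML path.
#' @return (invisibly) a list with every stage result and the run report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .validate_config(config)
  p <- config$params
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    sim_args <- if (isTRUE(config$simulate)) list() else
      as.list(config$simulate)
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sim <- simulate_rlm_study(do.call(synthetic_config, sim_args))
    qm <- sim$quant; ann <- sim$annotations; kb <- sim$kb
    write_quant_table(qm, file.path(config$out_dir, "quant_raw.tsv"),
                      file.path(config$out_dir, "samples.tsv"))
    write_annotations(ann, file.path(config$out_dir, "annotations.tsv"))
  } else {
    sim <- NULL
    qm <- read_quant_table(config$input$quant, config$input$meta,
                           dialect = config$input$dialect %||% "generic_tsv")
    ann <- read_annotations(config$input$annotations)
    kb <- if (is.null(config$input$kb)) default_ligand_kb() else
      read_ligand_kb(config$input$kb)
  }

  qn <- normalize_ibaq(qm)
  records <- differential(qn, floor_quantile = p$floor_quantile,
                          floor_factor = p$floor_factor,
                          min_batches = p$min_batches, test = p$test,
                          adjust = p$adjust)
  volc <- volcano_table(records)
  markers <- marker_panel_summary(qn, records,
                                  fold_threshold = p$marker_fold_threshold)
  memb <- filter_membrane(records, ann)
  cls <- classify_receptors(memb, ann)
  params <- rlm_params(fold_threshold = p$fold_threshold,
                       require_quantifiable_in_B =
                         p$require_quantifiable_in_B,
                       require_ligand_available =
                         p$require_ligand_available)
  candidates <- select_enriched_receptors(cls$neurotrophic, params)
  recs <- match_ligands(candidates, kb, params)
  diff_sets <- compare_supplement_sets(
    recs$ligand_name[recs$selected_for_supplementation],
    config$reference_supplements)

  write_report(recs, records, config$out_dir, formats = config$formats)
  .write_tsv(volc, file.path(config$out_dir, "volcano.tsv"))
  .write_tsv(markers$summary, file.path(config$out_dir,
                                        "marker_summary.tsv"))
  .write_tsv(markers$calls, file.path(config$out_dir, "marker_calls.tsv"))
  writeLines(format_rlm_markdown(recs),
             file.path(config$out_dir, "recommendations.md"))

  funnel <- c(funnel_counts(records, ann),
              enriched_candidates = nrow(candidates),
              recommended_ligands =
                length(unique(recs$ligand_name[
                  recs$selected_for_supplementation])))
  report <- list(
    package_version = as.character(utils::packageVersion("rlmatch")),
    seed = config$seed,
    parameters = p,
    annotation_source_version = attr(ann, "source_version"),
    differential = list(test = attr(records, "test"),
                        floor = attr(records, "floor"),
                        p_adjustment = p$adjust),
    funnel = as.list(funnel),
    marker_calls = markers$calls,
    supplement_diff = diff_sets,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  invisible(list(quant = qm, normalized = qn, records = records,
                 volcano = volc, markers = markers, membrane = memb,
                 receptors = cls, candidates = candidates,
                 recommendations = recs, supplement_diff = diff_sets,
                 funnel = funnel, report = report, simulation = sim))
}
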