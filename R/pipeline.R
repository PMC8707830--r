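#' Pipeline run configuration
#'
#' Bundles every threshold and mode switch of [run_pipeline()] so a run is
#' fully described by one object, which is echoed into the run report.
#'
#' @param qc_threshold replicate-concordance threshold
#'   ([replicate_concordance()]).
#' @param qc_drop drop flagged replicates before analysis (default
#'   `FALSE`: report only).
#' @param alpha,r_min COR thresholds ([cor_screen()]).
#' @param cv_min,cv_basis CV threshold and basis ([cv_screen()]).
#' @param fc_min,dam_alpha,dam_gate DAM thresholds and p-value gating
#'   ([dam_screen()]).
#' @param screen_timepoints time points used by the COR and DAM filters.
#' @param combine `"union"` or `"intersection"` across varieties
#'   ([intersect_screens()]).
#' @param k_stages number of metabolome stages ([segment_stages()]).
#' @param pattern_basis z-score basis ([classify_patterns()]).
#' @param seed integer seed for anything stochastic in the run.
#' @return a list of class `run_config`.
#' @export
run_config <- function(qc_threshold = 0.9, qc_drop = FALSE,
                       alpha = 0.05, r_min = 0.8,
                       cv_min = 0.30, cv_basis = "means",
                       fc_min = 2, dam_alpha = 0.05,
                       dam_gate = "adjusted",
                       screen_timepoints = c(6, 9, 12, 24, 36, 48),
                       combine = "union", k_stages = 3,
                       pattern_basis = "per_variety", seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full screening pipeline
#'
#' Executes the whole analysis in order: replicate QC (optionally dropping
#' flagged replicates), per-time-point profiles and their correlation
#' matrix, stage segmentation and lag estimation, the three candidate
#' filters and their intersection, trajectory-pattern classification of
#' the candidates, and module annotation with direction-consistency
#' summary. Either pass a dataset (`mat` + `phenotype`) or a
#' [synthetic_config()] via `sim_config` to generate one. With an
#' `output_dir` every intermediate table is written as CSV alongside a
#' machine-readable JSON report, so every number in the report can be
#' recomputed from the emitted files. Runs are deterministic given the
#' config and inputs.
#'
#' @param mat a [metabolome_matrix()] (ignored if `sim_config` given).
#' @param phenotype a phenotype table (ignored if `sim_config` given).
#' @param config a [run_config()].
#' @param sim_config optional [synthetic_config()]; when given, the
#'   dataset is generated and the truth-based confusion counts are added
#'   to the report.
#' @param output_dir optional directory for the artifact files.
#' @return a list of class `germscreen_report` with elements `qc`,
#'   `stages`, `lag`, `screens` (edges/cv/dam tibbles),
#'   `screening_result`, `patterns`, `modules`, `confusion` (synthetic
#'   runs only) and `report` (the flat summary that is serialized to
#'   JSON).
#' @export
run_pipeline <- function(mat = NULL, phenotype = NULL,
                         config = run_config(), sim_config = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (!is.null(sim_config)) {
    sim <- generate_dataset(sim_config)
    mat <- sim$matrix
    phenotype <- sim$phenotype
    truth <- sim$truth
  }
  if (is.null(mat) || is.null(phenotype))
    stop("either a matrix + phenotype or a sim_config is required")

  qc <- replicate_concordance(mat, threshold = config$qc_threshold)
  if (config$qc_drop && any(qc$flagged)) mat <- drop_flagged(mat, qc)

  prof <- timepoint_profiles(mat)
  cormat <- profile_correlation(prof)
  vars <- unique(mat$samples$variety)
  stages <- lapply(stats::setNames(vars, vars), function(v)
    segment_stages(cormat, v, k = config$k_stages))
  lag <- if (length(vars) == 2)
    estimate_lag(cormat, fast = vars[1], slow = vars[2],
                 segmentation = stages[[vars[2]]])
  else NULL

  edges <- cor_screen(mat, phenotype,
                      timepoints = config$screen_timepoints,
                      alpha = config$alpha, r_min = config$r_min)
  cv_res <- cv_screen(mat, threshold = config$cv_min,
                      basis = config$cv_basis)
  dam <- dam_screen(mat, timepoints = config$screen_timepoints,
                    fc_min = config$fc_min, alpha = config$dam_alpha,
                    gate = config$dam_gate)
  screening <- intersect_screens(edges, cv_res, dam,
                                 annotations = mat$metabolites,
                                 combine = config$combine)

  patterns <- if (length(screening$candidates))
    classify_patterns(mat, screening$candidates,
                      basis = config$pattern_basis)
  else classify_patterns(mat, character(0))

  cand_names <- mat$metabolites$name[
    match(screening$candidates, mat$metabolites$metabolite_id)]
  annotated <- annotate_modules(
    data.frame(metabolite_id = screening$candidates, name = cand_names,
               stringsAsFactors = FALSE))
  mod_summary <- module_direction_summary(annotated, patterns)

  confusion <- if (!is.null(truth)) truth_confusion(screening, truth)

  report <- list(
    package_version = as.character(packageVersion("germscreen")),
    config = unclass(config),
    n_samples = nrow(mat$values),
    n_metabolites = ncol(mat$values),
    qc_flagged = sum(qc$flagged),
    qc_dropped = if (config$qc_drop) sum(qc$flagged) else 0L,
    stage_boundaries = lapply(stages, function(s) s$boundaries),
    median_lag_hours = if (!is.null(lag)) lag$median_lag,
    n_cor = length(screening$cor_set),
    n_cv = length(screening$cv_set),
    n_dam = length(screening$dam_set),
    n_candidates = length(screening$candidates),
    class_counts = as.list(screening$class_counts),
    module_summary = mod_summary,
    confusion = confusion)

  out <- list(matrix = mat, qc = qc, profiles = prof, cormat = cormat,
              stages = stages, lag = lag,
              screens = list(cor = edges, cv = cv_res, dam = dam),
              screening_result = screening, patterns = patterns,
              modules = list(annotated = annotated,
                             summary = mod_summary),
              confusion = confusion, report = report)
  class(out) <- "germscreen_report"

  if (!is.null(output_dir)) write_pipeline_artifacts(out, output_dir)
  out
}

write_pipeline_artifacts <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name)
    write.csv(as.data.frame(x), file.path(output_dir, name),
              row.names = FALSE, fileEncoding = "UTF-8")
  w(res$qc, "qc_report.csv")
  w(as.data.frame(unclass(res$cormat)), "profile_correlation.csv")
  w(res$screens$cor, "cor_edges.csv")
  w(res$screens$cv, "cv_results.csv")
  w(res$screens$dam, "dam_records.csv")
  w(data.frame(metabolite_id = res$screening_result$candidates),
    "candidates.csv")
  w(res$patterns, "patterns.csv")
  w(attr(res$patterns, "profiles"), "pattern_zscores_long.csv")
  w(res$modules$annotated, "module_annotation.csv")
  write_network(res$screens$cor, res$matrix$metabolites,
                file.path(output_dir, "network"))
  jsonlite::write_json(res$report,
                       file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(output_dir)
}

#' @export
print.germscreen_report <- function(x, ...) {
  r <- x$report
  cat("<germscreen_report>\n")
  cat("  ", r$n_samples, " samples x ", r$n_metabolites,
      " metabolites; QC flagged ", r$qc_flagged, "\n", sep = "")
  if (!is.null(r$median_lag_hours))
    cat("  median lag: ", r$median_lag_hours, " h\n", sep = "")
  cat("  COR ", r$n_cor, " | CV ", r$n_cv, " | DAM ", r$n_dam,
      " -> candidates ", r$n_candidates, "\n", sep = "")
  if (!is.null(x$confusion))
    cat("  vs planted truth: sensitivity ",
        round(x$confusion$sensitivity, 3), ", precision ",
        round(x$confusion$precision, 3), "\n", sep = "")
  invisible(x)
}
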