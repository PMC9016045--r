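#' Run configuration
#'
#' Plain nestable key-value configuration for the orchestration commands.
#' Precedence is CLI/`overrides` > config file > these defaults.
#'
#' @param outdir output directory.
#' @param seed master seed for simulation and calibration.
#' @param percentile_grid percentiles at which profiles are evaluated.
#' @param phantom_spacing phantom voxel size in mm (larger = faster).
#' @param calibrate calibrate the uptake model to
#'   [defaultCalibrationTargets()] before simulating.
#' @param calibration_n patients per calibration iteration.
#' @param censor_post_diagnosis drop post-diagnosis scans from the predictor.
#' @param cohort named list of [cohortSpec()] argument overrides.
#' @return A config list (class `irquant_config`).
#' @export
runConfig <- function(outdir = "irquant_out", seed = 1,
                      percentile_grid = defaultPercentileGrid(),
                      phantom_spacing = 4, calibrate = TRUE,
                      calibration_n = 160, censor_post_diagnosis = FALSE,
                      cohort = list()) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 percentile_grid = percentile_grid,
                 phantom_spacing = phantom_spacing, calibrate = calibrate,
                 calibration_n = calibration_n,
                 censor_post_diagnosis = censor_post_diagnosis,
                 cohort = cohort),
            class = "irquant_config")
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys mirror [runConfig()] arguments.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return A config list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- unclass(runConfig())
  if (!is.null(path)) cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  cfg <- utils::modifyList(cfg, overrides[!vapply(overrides, is.null,
                                                  logical(1))])
  structure(cfg, class = "irquant_config")
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[%s] done in %.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

.write_manifest <- function(config, dir) {
  manifest <- list(
    package = "iraePET",
    version = as.character(utils::packageVersion("iraePET")),
    seed = config$seed,
    config = unclass(config),
    config_hash = .config_hash(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
}

.prepare_model <- function(config, mask) {
  if (!isTRUE(config$calibrate)) return(uptakeModel())
  .stage("calibrate", calibrateBaseline(uptakeModel(), mask = mask,
                                        n = config$calibration_n,
                                        seed = config$seed))
}

#' Simulate a cohort to disk
#'
#' Builds the phantom, (optionally) calibrates the uptake model, simulates
#' the cohort, and writes volumes, masks, truth and profile tables plus a
#' manifest (seed, config echo, config hash, package version) under
#' `outdir/cohort`.
#'
#' @param config a config list from [runConfig()] / [readRunConfig()].
#' @return The [SyntheticCohort-class], invisibly.
#' @export
cmdSimulate <- function(config = runConfig()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  phantom <- phantomSpec(spacing = config$phantom_spacing)
  mask <- .stage("phantom", suppressMessages(buildPhantom(phantom)))
  model <- .prepare_model(config, mask)
  spec <- do.call(cohortSpec, utils::modifyList(list(seed = config$seed),
                                                as.list(config$cohort)))
  cohort <- .stage("simulate",
                   simulateCohort(spec, model = model, mask = mask,
                                  percentile_grid = config$percentile_grid))
  .stage("write", writeCohort(cohort, file.path(config$outdir, "cohort")))
  .write_manifest(config, config$outdir)
  invisible(cohort)
}

#' Run the full analysis pipeline
#'
#' quantify -> select -> normative -> monitor -> report, on a simulated (or
#' supplied) cohort. Writes per-organ biomarker JSON (percentile grid, AUROC
#' by percentile, SUV_OPT\%, AUROC, T_opt, J, sensitivity, specificity),
#' ROC-curve CSVs, a normal-ranges JSON, a per-scan monitor CSV, and the four
#' plot families (AUROC vs percentile, ROC with operating point, dichotomized
#' strip plot, longitudinal series with grey band). Organs whose cohort is
#' single-class are skipped at the biomarker stage with a notice; normative
#' ranges are still produced for them at the default target percentile.
#'
#' @param config a config list.
#' @param cohort optional prebuilt [SyntheticCohort-class]; simulated from
#'   the config when NULL.
#' @return list(cohort, score_table, selections, cutoffs, comparisons,
#'   ranges, monitor), invisibly.
#' @export
cmdPipeline <- function(config = runConfig(), cohort = NULL) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    phantom <- phantomSpec(spacing = config$phantom_spacing)
    mask <- .stage("phantom", suppressMessages(buildPhantom(phantom)))
    model <- .prepare_model(config, mask)
    spec <- do.call(cohortSpec, utils::modifyList(list(seed = config$seed),
                                                  as.list(config$cohort)))
    cohort <- .stage("simulate",
                     simulateCohort(spec, model = model, mask = mask,
                                    percentile_grid = config$percentile_grid))
  }
  profiles <- cohort@profiles
  truth <- cohort@truth
  table <- .stage("quantify",
                  buildScoreTable(profiles, truth,
                                  config$censor_post_diagnosis))

  default_pct <- stats::setNames(defaultCalibrationTargets()$percentile,
                                 defaultCalibrationTargets()$organ)
  selections <- list(); cutoffs <- list(); comparisons <- list()
  opt_pct <- default_pct
  for (organ in .organ_names) {
    sel <- tryCatch(selectOptimalPercentile(table, organ),
                    error = function(e) {
                      message("biomarker stage skipped for ", organ, ": ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(sel)) next
    selections[[organ]] <- sel
    opt_pct[[organ]] <- sel@opt_percentile
    sc <- scoresAtOptimum(table, sel)
    curve <- rocCurve(sc$score[sc$irae == 1], sc$score[sc$irae == 0])
    cut <- youdenCutoff(curve, organ)
    cutoffs[[organ]] <- cut
    comparisons[[organ]] <- compareGroups(table, organ, sel)
    jsonlite::write_json(
      list(organ = organ, grid = sel@scan$percentile,
           auroc_by_percentile = sel@scan$auroc,
           opt_percentile = sel@opt_percentile, auroc = sel@auroc,
           t_opt = cut@t_opt, j = cut@j, sensitivity = cut@sensitivity,
           specificity = cut@specificity,
           wilcoxon_p = comparisons[[organ]]$p_value),
      file.path(config$outdir, sprintf("biomarker_%s.json", organ)),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(curve,
                     file.path(config$outdir, sprintf("roc_%s.csv", organ)),
                     row.names = FALSE)
    .save_plot(plotAurocByPercentile(sel), config$outdir,
               sprintf("auroc_by_percentile_%s.pdf", organ))
    .save_plot(plotRocCurve(curve, cut), config$outdir,
               sprintf("roc_%s.pdf", organ))
    .save_plot(plotDichotomized(sc, organ, comparisons[[organ]]$p_value),
               config$outdir, sprintf("dichotomized_%s.pdf", organ))
  }

  ranges <- .stage("normative", {
    event_pts <- unique(truth$patient_id)
    base <- profiles[profiles$scan_day < 0 &
                       !profiles$patient_id %in% event_pts, ]
    out <- list()
    for (organ in .organ_names) {
      vals <- base$suv_gml[base$organ == organ &
                             base$percentile == opt_pct[[organ]]]
      if (length(vals) >= 2) out[[organ]] <- normalRange(vals, organ)
    }
    out
  })
  jsonlite::write_json(
    lapply(ranges, function(r) list(organ = r@organ, mu = r@mu,
                                    sigma = r@sigma, n = r@n, lo = r@lo,
                                    hi = r@hi)),
    file.path(config$outdir, "normal_ranges.json"), auto_unbox = TRUE,
    digits = NA)

  monitor <- .stage("monitor",
                    cohortMonitorReport(profiles, truth, ranges,
                                        opt_pct[names(ranges)]))
  utils::write.csv(monitor$scans, file.path(config$outdir, "monitor.csv"),
                   row.names = FALSE)
  if (nrow(monitor$events)) {
    shown <- 0L
    for (i in seq_len(nrow(monitor$events))) {
      ev <- monitor$events[i, ]
      if (!ev$organ %in% names(ranges)) next
      series <- longitudinalSeries(profiles, ev$patient_id, ev$organ,
                                   opt_pct[[ev$organ]])
      .save_plot(plotLongitudinal(series, ranges[[ev$organ]],
                                  ev$clinical_day, ev$organ),
                 config$outdir,
                 sprintf("longitudinal_%s_%s.pdf", ev$patient_id, ev$organ))
      shown <- shown + 1L
      if (shown >= 6L) break
    }
  }
  .write_manifest(config, config$outdir)
  invisible(list(cohort = cohort, score_table = table,
                 selections = selections, cutoffs = cutoffs,
                 comparisons = comparisons, ranges = ranges,
                 monitor = monitor))
}

.save_plot <- function(p, dir, file) {
  grDevices::pdf(file.path(dir, file), width = 5, height = 4)
  on.exit(grDevices::dev.off())
  print(p)
}
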