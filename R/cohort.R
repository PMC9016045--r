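#' CohortSpec: design of a synthetic patient cohort
#'
#' Cohort size, per-organ irAE prevalence, and the imaging schedule. Defaults
#' mirror the pilot-study conditions: 58 patients; organ prevalences 6/58
#' (bowel), 5/58 (lung), 9/58 (thyroid); baseline scan about day -36; first
#' follow-up about day 113 with subsequent scans about every 90 days; 2 to
#' ~16 scans per patient with median 4.
#'
#' @slot n_patients integer cohort size.
#' @slot prevalence named numeric(3), per-organ event probability.
#' @slot baseline_day numeric, nominal baseline scan day (negative).
#' @slot first_followup numeric, nominal first on-treatment scan day.
#' @slot followup_interval numeric, nominal days between later follow-ups.
#' @slot schedule_jitter numeric, uniform +/- jitter (days) on scheduled days.
#' @slot extra_scan_lambda numeric, scans per patient = 2 + Poisson(lambda).
#' @slot onset_range numeric(2), uniform range of event onset days.
#' @slot k_range numeric(2), uniform range of peak multipliers.
#' @slot focal_fraction numeric, affected fraction for focal events.
#' @slot clinical_lag_range numeric(2), uniform range of days from imaging
#'   onset to clinical detection.
#' @slot seed integer master seed.
#' @export
setClass("CohortSpec",
  slots = c(n_patients = "integer", prevalence = "numeric",
            baseline_day = "numeric", first_followup = "numeric",
            followup_interval = "numeric", schedule_jitter = "numeric",
            extra_scan_lambda = "numeric", onset_range = "numeric",
            k_range = "numeric", focal_fraction = "numeric",
            clinical_lag_range = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@n_patients < 1) return("n_patients must be >= 1")
  if (any(object@prevalence < 0 | object@prevalence > 1))
    return("prevalences must lie in [0, 1]")
  if (object@baseline_day >= 0) return("baseline_day must be negative")
  if (object@focal_fraction <= 0 || object@focal_fraction > 1)
    return("focal_fraction must lie in (0, 1]")
  if (any(object@k_range <= 1)) return("k_range must be > 1")
  TRUE
})

#' Construct a CohortSpec
#'
#' @param n_patients cohort size.
#' @param prevalence named per-organ event probabilities.
#' @param baseline_day,first_followup,followup_interval,schedule_jitter
#'   imaging schedule (days).
#' @param extra_scan_lambda Poisson mean of scans beyond the mandatory two.
#' @param onset_range,k_range,focal_fraction,clinical_lag_range event
#'   parameters.
#' @param seed master seed; per-patient streams are derived deterministically.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(n_patients = 58,
                       prevalence = c(bowel = 6, lung = 5, thyroid = 9) / 58,
                       baseline_day = -36, first_followup = 113,
                       followup_interval = 90, schedule_jitter = 14,
                       extra_scan_lambda = 2, onset_range = c(20, 200),
                       k_range = c(1.8, 3.2), focal_fraction = 0.1,
                       clinical_lag_range = c(14, 60), seed = 1) {
  new("CohortSpec", n_patients = as.integer(n_patients),
      prevalence = prevalence[.organ_names], baseline_day = baseline_day,
      first_followup = first_followup, followup_interval = followup_interval,
      schedule_jitter = schedule_jitter,
      extra_scan_lambda = extra_scan_lambda, onset_range = onset_range,
      k_range = k_range, focal_fraction = focal_fraction,
      clinical_lag_range = clinical_lag_range, seed = as.integer(seed))
}

#' SyntheticCohort: generated phantom cohort
#'
#' @slot profiles data.frame of long-format SUV percentile profiles:
#'   patient_id, organ, scan_day, percentile, suv_gml, n_voxels.
#' @slot truth data.frame of ground-truth events: patient_id, organ, pattern,
#'   onset_day, clinical_day, k, f.
#' @slot spec the generating [CohortSpec-class].
#' @slot mask the shared phantom [OrganMask-class].
#' @slot model the [UptakeModel-class] used.
#' @slot volumes list (per patient) of lists of [SUVVolume-class]; empty
#'   unless requested.
#' @export
setClass("SyntheticCohort",
  slots = c(profiles = "data.frame", truth = "data.frame",
            spec = "CohortSpec", mask = "OrganMask", model = "UptakeModel",
            volumes = "list"))

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d patients, %d scans, %d irAE events (%s)\n",
              object@spec@n_patients,
              length(unique(paste(object@profiles$patient_id,
                                  object@profiles$scan_day))),
              nrow(object@truth),
              paste(sprintf("%s=%d", .organ_names,
                            vapply(.organ_names, function(o)
                              sum(object@truth$organ == o), integer(1))),
                    collapse = ", ")))
})

.derive_seed <- function(seed, i, salt = 104729L) {
  as.integer((as.numeric(seed) + salt * as.numeric(i)) %% 2147483647)
}

## draw the full cohort plan (schedules, events, patient multipliers) from
## the master stream; rendering then uses derived per-scan seeds only
.plan_cohort <- function(spec, mask, model) {
  organ_world <- lapply(.organ_names, function(organ) {
    idx <- which(mask@labels == organCodes()[[organ]])
    co <- arrayInd(idx, mask@grid@dims)
    sweep(sweep(co - 1, 2, mask@grid@spacing, "*"), 2, mask@grid@origin, "+")
  })
  names(organ_world) <- .organ_names
  set.seed(spec@seed)
  plan <- vector("list", spec@n_patients)
  for (p in seq_len(spec@n_patients)) {
    id <- sprintf("P%03d", p)
    n_scans <- 2L + stats::rpois(1, spec@extra_scan_lambda)
    jit <- function(k) stats::runif(k, -spec@schedule_jitter,
                                    spec@schedule_jitter)
    days <- round(c(min(spec@baseline_day + jit(1), -1),
                    spec@first_followup + jit(1) +
                      (seq_len(n_scans - 1L) - 1L) * spec@followup_interval +
                      c(0, cumsum(jit(max(n_scans - 2L, 0))))[seq_len(n_scans - 1L)]))
    days <- sort(unique(days))
    events <- list()
    for (organ in .organ_names) {
      if (stats::runif(1) >= spec@prevalence[[organ]]) next
      pattern <- if (organ == "thyroid") "diffuse" else "focal"
      world <- organ_world[[organ]]
      center <- world[sample.int(nrow(world), 1), ]
      events[[length(events) + 1L]] <- iraeEvent(
        organ, pattern,
        onset_day = stats::runif(1, spec@onset_range[1], spec@onset_range[2]),
        k = stats::runif(1, spec@k_range[1], spec@k_range[2]),
        f = if (pattern == "diffuse") 1 else spec@focal_fraction,
        clinical_lag = stats::runif(1, spec@clinical_lag_range[1],
                                    spec@clinical_lag_range[2]),
        focal_center = center)
    }
    plan[[p]] <- list(id = id, days = days, events = events,
                      mult = drawPatientMultipliers(model),
                      seed = .derive_seed(spec@seed, p))
  }
  plan
}

#' Quantify one scan into percentile profile rows
#'
#' @param vol an [SUVVolume-class].
#' @param mask an [OrganMask-class] on the same grid.
#' @param grid percentile grid.
#' @return data.frame rows (patient_id, organ, scan_day, percentile, suv_gml,
#'   n_voxels) for every organ present in the mask.
#' @export
quantifyScan <- function(vol, mask, grid = defaultPercentileGrid()) {
  meta <- vol@meta
  out <- lapply(.organ_names, function(organ) {
    if (!any(mask@labels == organCodes()[[organ]])) return(NULL)
    vals <- extractMaskedValues(vol, mask, organ)
    data.frame(patient_id = meta@patient_id, organ = organ,
               scan_day = meta@scan_day, percentile = grid,
               suv_gml = unname(organPercentiles(vals, grid)),
               n_voxels = length(vals))
  })
  do.call(rbind, out)
}

#' Simulate a synthetic phantom PET cohort
#'
#' Generates the full cohort: imaging schedule, ground-truth irAE events
#' (diffuse for thyroid, focal for bowel/lung), per-scan phantom renders, and
#' long-format SUV percentile profiles. Reproducible under the spec's master
#' seed; per-patient and per-scan seeds are derived deterministically so a
#' subset of patients can be regenerated without rerunning the cohort.
#'
#' @param spec a [CohortSpec-class].
#' @param phantom a [PhantomSpec-class] (ignored when `mask` is given).
#' @param model an [UptakeModel-class] (typically calibrated).
#' @param percentile_grid percentiles at which profiles are evaluated.
#' @param keep_volumes keep rendered [SUVVolume-class] objects in the result
#'   (memory-heavy; meant for small cohorts).
#' @param mask optional prebuilt phantom [OrganMask-class].
#' @return A [SyntheticCohort-class].
#' @export
simulateCohort <- function(spec = cohortSpec(), phantom = phantomSpec(),
                           model = uptakeModel(),
                           percentile_grid = defaultPercentileGrid(),
                           keep_volumes = FALSE, mask = NULL) {
  stopifnot(is(spec, "CohortSpec"), is(model, "UptakeModel"))
  validObject(spec)
  if (is.null(mask)) mask <- suppressMessages(buildPhantom(phantom))
  if (all(spec@prevalence * spec@n_patients < 1) && any(spec@prevalence > 0))
    warning("expected event count below 1 for every organ; ",
            "the cohort may contain no events")
  plan <- .plan_cohort(spec, mask, model)

  profiles <- vector("list", length(plan))
  truth <- list()
  volumes <- if (keep_volumes) vector("list", length(plan)) else list()
  for (p in seq_along(plan)) {
    pt <- plan[[p]]
    rows <- vector("list", length(pt$days))
    vols <- if (keep_volumes) vector("list", length(pt$days))
    for (s in seq_along(pt$days)) {
      day <- pt$days[s]
      vol <- sampleUptake(mask, model, seed = .derive_seed(pt$seed, s, 7919L),
                          events = pt$events, scan_day = day,
                          patient_mult = pt$mult,
                          meta = scanMeta(pt$id, day))
      rows[[s]] <- quantifyScan(vol, mask, percentile_grid)
      if (keep_volumes) vols[[s]] <- vol
    }
    profiles[[p]] <- do.call(rbind, rows)
    if (keep_volumes) volumes[[p]] <- stats::setNames(
      vols, paste0("day", pt$days))
    for (ev in pt$events)
      truth[[length(truth) + 1L]] <- data.frame(
        patient_id = pt$id, organ = ev@organ, pattern = ev@pattern,
        onset_day = ev@onset_day, clinical_day = clinicalDay(ev),
        k = ev@k, f = ev@f)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(patient_id = character(), organ = character(),
               pattern = character(), onset_day = numeric(),
               clinical_day = numeric(), k = numeric(), f = numeric())
  if (keep_volumes) names(volumes) <- vapply(plan, `[[`, "", "id")
  new("SyntheticCohort", profiles = do.call(rbind, profiles), truth = truth,
      spec = spec, mask = mask, model = model, volumes = volumes)
}

#' Baseline-only simulation of irAE-free patients
#'
#' Fast path used by calibration checks and normative-range construction:
#' renders one baseline scan per irAE-free patient and returns each organ's
#' SUV percentile at the requested percentile.
#'
#' @param n number of patients.
#' @param model an [UptakeModel-class].
#' @param mask phantom [OrganMask-class].
#' @param percentiles named numeric, percentile per organ (defaults to the
#'   calibration targets).
#' @param seed integer seed.
#' @param crop render each organ on its cropped sub-grid (see
#'   [cropOrganMask()]); statistically identical and much faster.
#' @return data.frame(patient_id, organ, value) of baseline SUV_OPT\% values.
#' @export
simulateBaselines <- function(n, model, mask,
                              percentiles = stats::setNames(
                                defaultCalibrationTargets()$percentile,
                                defaultCalibrationTargets()$organ),
                              seed = 1, crop = TRUE) {
  organs <- names(percentiles)
  masks <- if (crop) {
    stats::setNames(lapply(organs, function(o) cropOrganMask(mask, o)),
                    organs)
  } else stats::setNames(rep(list(mask), length(organs)), organs)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    vals <- vapply(seq_along(organs), function(j) {
      organ <- organs[j]
      vol <- sampleUptake(masks[[organ]], model,
                          seed = .derive_seed(seed, i * 11L + j, 6007L))
      unname(organPercentiles(extractMaskedValues(vol, masks[[organ]], organ),
                              percentiles[[organ]]))
    }, numeric(1))
    out[[i]] <- data.frame(patient_id = sprintf("N%04d", i), organ = organs,
                           value = vals)
  }
  do.call(rbind, out)
}

#' Write a synthetic cohort to disk
#'
#' Re-renders every scan from its derived seed and writes NIfTI volumes (one
#' per scan), the shared mask, the truth table CSV, the scan metadata CSV,
#' the profiles CSV, and a JSON echo of the cohort spec.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort@spec
  mask <- cohort@mask
  writeOrganMask(mask, file.path(dir, "organ_mask.nii.gz"))
  plan <- .plan_cohort(spec, mask, cohort@model)
  scan_rows <- list()
  for (pt in plan) {
    pdir <- file.path(dir, pt$id)
    dir.create(pdir, showWarnings = FALSE)
    for (s in seq_along(pt$days)) {
      day <- pt$days[s]
      vol <- sampleUptake(mask, cohort@model,
                          seed = .derive_seed(pt$seed, s, 7919L),
                          events = pt$events, scan_day = day,
                          patient_mult = pt$mult,
                          meta = scanMeta(pt$id, day))
      writeSUVVolume(vol, file.path(pdir, sprintf("scan_day%+04d.nii.gz",
                                                  day)))
      scan_rows[[length(scan_rows) + 1L]] <- data.frame(
        patient_id = pt$id, scan_day = day, weight_g = NA_real_,
        dose_Bq = NA_real_, suv_precomputed = 1L)
    }
  }
  writeScanTable(do.call(rbind, scan_rows), file.path(dir, "scans.csv"))
  utils::write.csv(cohort@truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort@profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  spec_echo <- list(n_patients = spec@n_patients,
                    prevalence = as.list(spec@prevalence),
                    baseline_day = spec@baseline_day,
                    first_followup = spec@first_followup,
                    followup_interval = spec@followup_interval,
                    schedule_jitter = spec@schedule_jitter,
                    extra_scan_lambda = spec@extra_scan_lambda,
                    onset_range = spec@onset_range, k_range = spec@k_range,
                    focal_fraction = spec@focal_fraction,
                    clinical_lag_range = spec@clinical_lag_range,
                    seed = spec@seed)
  jsonlite::write_json(spec_echo, file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
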