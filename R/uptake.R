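#' UptakeModel: generative model of organ FDG uptake
#'
#' Baseline organ voxels are drawn log-normal (positive, right-skewed, as SUV
#' distributions are); a per-patient, per-organ multiplier ~ N(1, patient_sd)
#' carries the between-patient spread of the summary percentiles (within-organ
#' dispersion alone cannot: with thousands of voxels a percentile concentrates
#' tightly around its population value). Background is Gaussian clipped at
#' zero. The field is blurred with a Gaussian point-spread function of stated
#' FWHM, then voxelwise Gaussian noise is added and the result clipped at 0.
#'
#' @slot location named numeric(3), log-scale location per organ.
#' @slot scale named numeric(3), voxel-level log-sd per organ (> 0).
#' @slot patient_sd named numeric(3), sd of the between-patient uptake
#'   multiplier (>= 0).
#' @slot bg_mean,bg_sd numeric, background SUV mean and sd (g/mL).
#' @slot psf_fwhm_mm numeric, PSF full width at half maximum in mm (>= 0).
#' @slot noise_sd numeric, additive voxel noise sd (g/mL, >= 0).
#' @export
setClass("UptakeModel",
  slots = c(location = "numeric", scale = "numeric", patient_sd = "numeric",
            bg_mean = "numeric", bg_sd = "numeric", psf_fwhm_mm = "numeric",
            noise_sd = "numeric"))

setValidity("UptakeModel", function(object) {
  for (s in c("location", "scale", "patient_sd")) {
    v <- slot(object, s)
    if (length(v) != 3L || !all(.organ_names %in% names(v)))
      return(paste0(s, " must be named numeric(3) over bowel/lung/thyroid"))
  }
  if (any(object@scale <= 0)) return("scale must be > 0")
  if (any(object@patient_sd < 0)) return("patient_sd must be >= 0")
  if (object@psf_fwhm_mm < 0) return("psf_fwhm_mm must be >= 0")
  if (object@noise_sd < 0) return("noise_sd must be >= 0")
  if (object@bg_sd < 0) return("bg_sd must be >= 0")
  TRUE
})

#' Construct an UptakeModel
#'
#' Defaults are plausible uninflamed-organ values; use [calibrateBaseline()]
#' to tune `location` and `patient_sd` so the simulated summary percentiles
#' reproduce stated normative targets.
#'
#' @param location named numeric(3) log-location per organ.
#' @param scale named numeric(3) voxel log-sd per organ.
#' @param patient_sd named numeric(3) between-patient multiplier sd.
#' @param bg_mean,bg_sd background SUV mean/sd (g/mL).
#' @param psf_fwhm_mm PSF FWHM in mm.
#' @param noise_sd additive noise sd (g/mL).
#' @return An [UptakeModel-class].
#' @export
uptakeModel <- function(location = log(c(bowel = 1.9, lung = 0.95,
                                         thyroid = 1.6)),
                        scale = c(bowel = 0.25, lung = 0.20, thyroid = 0.25),
                        patient_sd = c(bowel = 0.12, lung = 0.17,
                                       thyroid = 0.20),
                        bg_mean = 0.5, bg_sd = 0.1, psf_fwhm_mm = 6,
                        noise_sd = 0.05) {
  new("UptakeModel", location = location[.organ_names],
      scale = scale[.organ_names], patient_sd = patient_sd[.organ_names],
      bg_mean = bg_mean, bg_sd = bg_sd, psf_fwhm_mm = psf_fwhm_mm,
      noise_sd = noise_sd)
}

#' IraeEvent: one organ inflammation episode
#'
#' Encodes the two inflammation morphologies: `diffuse` (thyroiditis-like,
#' the whole organ SUV histogram shifts up uniformly) and `focal`
#' (colitis/pneumonitis-like, elevation confined to a connected sub-region of
#' fraction `f` of the organ volume, so only the top percentiles move).
#' The uptake multiplier ramps sigmoidally from 1 to `k` over the 30 days
#' following `onset_day` and, when `resolution_day` is set, decays back
#' afterwards. Clinical detection occurs `clinical_lag` days after imaging
#' onset.
#'
#' @slot organ character organ name.
#' @slot pattern "diffuse" or "focal".
#' @slot onset_day numeric, imaging-visible onset (days from treatment start).
#' @slot k numeric > 1, peak uptake multiplier.
#' @slot f numeric in (0, 1], affected fraction of organ volume (1 for
#'   diffuse; focal defaults to 0.1).
#' @slot clinical_lag numeric >= 0, days from onset to clinical detection.
#' @slot resolution_day numeric, optional day inflammation starts resolving
#'   (NA for none).
#' @slot focal_center numeric(3) world mm seed point of the focal sub-region
#'   (NA = organ centroid).
#' @export
setClass("IraeEvent",
  slots = c(organ = "character", pattern = "character", onset_day = "numeric",
            k = "numeric", f = "numeric", clinical_lag = "numeric",
            resolution_day = "numeric", focal_center = "numeric"))

setValidity("IraeEvent", function(object) {
  if (!object@organ %in% .organ_names) return("unknown organ")
  if (!object@pattern %in% c("diffuse", "focal"))
    return("pattern must be 'diffuse' or 'focal'")
  if (object@k <= 1) return("k must be > 1")
  if (object@f <= 0 || object@f > 1)
    return("spec error: f must lie in (0, 1]")
  if (object@pattern == "diffuse" && object@f != 1)
    return("diffuse events affect the whole organ (f = 1)")
  if (object@clinical_lag < 0) return("clinical_lag must be >= 0")
  TRUE
})

#' Construct an IraeEvent
#'
#' @param organ "bowel", "lung" or "thyroid".
#' @param pattern "diffuse" or "focal"; defaults to diffuse for thyroid,
#'   focal for bowel/lung.
#' @param onset_day imaging-visible onset day.
#' @param k peak multiplier (> 1).
#' @param f affected organ fraction; forced to 1 for diffuse.
#' @param clinical_lag days from imaging onset to clinical detection.
#' @param resolution_day optional resolution start day (NA = none).
#' @param focal_center optional world-mm seed point for the focal region.
#' @return An [IraeEvent-class].
#' @export
iraeEvent <- function(organ, pattern = if (organ == "thyroid") "diffuse"
                      else "focal",
                      onset_day = 60, k = 2.5,
                      f = if (pattern == "diffuse") 1 else 0.1,
                      clinical_lag = 30, resolution_day = NA_real_,
                      focal_center = c(NA_real_, NA_real_, NA_real_)) {
  if (pattern == "diffuse") f <- 1
  new("IraeEvent", organ = organ, pattern = pattern,
      onset_day = as.numeric(onset_day), k = as.numeric(k), f = as.numeric(f),
      clinical_lag = as.numeric(clinical_lag),
      resolution_day = as.numeric(resolution_day),
      focal_center = as.numeric(focal_center))
}

#' Clinical detection day of an event
#' @param event an [IraeEvent-class].
#' @return onset_day + clinical_lag.
#' @export
clinicalDay <- function(event) event@onset_day + event@clinical_lag

## uptake multiplier at a scan day: exactly 1 before onset, then a logistic
## ramp reaching ~k by onset + 30 d, exponential relaxation after resolution
.event_multiplier <- function(event, scan_day) {
  if (scan_day < event@onset_day) return(1)
  ramp <- stats::plogis((scan_day - event@onset_day - 15) / 3.75)
  m <- 1 + (event@k - 1) * ramp
  if (!is.na(event@resolution_day) && scan_day > event@resolution_day) {
    ramp_res <- stats::plogis((event@resolution_day - event@onset_day - 15) /
                                3.75)
    m_res <- 1 + (event@k - 1) * ramp_res
    m <- 1 + (m_res - 1) * exp(-(scan_day - event@resolution_day) / 30)
  }
  m
}

## connected focal sub-region: the round(f * n) organ voxels nearest (in
## world mm) to the seed point; ball-within-organ, deterministic given seed
.focal_region <- function(mask, code, f, center) {
  idx <- which(mask@labels == code)
  n <- length(idx)
  coords <- arrayInd(idx, mask@grid@dims)
  world <- sweep(sweep(coords - 1, 2, mask@grid@spacing, "*"), 2,
                 mask@grid@origin, "+")
  if (any(is.na(center))) center <- colMeans(world)
  d2 <- rowSums(sweep(world, 2, center)^2)
  # snap the seed to the organ, then grow by distance from that voxel
  seed <- world[which.min(d2), ]
  d2 <- rowSums(sweep(world, 2, seed)^2)
  take <- max(1L, round(f * n))
  idx[order(d2)[seq_len(take)]]
}

#' Apply an irAE inflammation event to an SUV volume
#'
#' Multiplies the affected voxels by the event's time-dependent uptake
#' multiplier: the whole organ for diffuse events, a connected sub-region of
#' fraction `f` of the organ volume for focal events. Scans dated before the
#' event onset are returned unchanged.
#'
#' @param suv an [SUVVolume-class].
#' @param mask an [OrganMask-class] on the same grid.
#' @param event an [IraeEvent-class].
#' @param scan_day day of the scan relative to treatment start.
#' @return An [SUVVolume-class].
#' @export
applyIrae <- function(suv, mask, event, scan_day) {
  stopifnot(is(suv, "SUVVolume"), is(mask, "OrganMask"),
            is(event, "IraeEvent"))
  validObject(event)
  if (!sameGrid(suv@grid, mask@grid))
    stop("SUV volume and mask are on different grids", call. = FALSE)
  code <- .organ_code(event@organ)
  if (!any(mask@labels == code))
    stop("empty organ: event organ '", event@organ, "' absent from mask",
         call. = FALSE)
  vox <- .apply_event_array(suv@voxels, mask, event, scan_day)
  suvVolume(vox, suv@grid, suv@meta)
}

.apply_event_array <- function(vox, mask, event, scan_day) {
  code <- .organ_code(event@organ)
  m <- .event_multiplier(event, scan_day)
  if (m == 1) return(vox)
  if (event@pattern == "diffuse") {
    sel <- mask@labels == code
    vox[sel] <- vox[sel] * m
  } else {
    region <- .focal_region(mask, code, event@f, event@focal_center)
    vox[region] <- vox[region] * m
  }
  vox
}

#' Simulate one PET scan of a phantom
#'
#' Renders a phantom scan: background ~ N(bg_mean, bg_sd) clipped at 0, organ
#' voxels ~ log-normal(location, scale) times the patient's organ multiplier,
#' any inflammation events applied, then PSF blurring and additive noise
#' (clipped at 0). Bit-reproducible under a fixed seed.
#'
#' @param mask an [OrganMask-class] phantom.
#' @param model an [UptakeModel-class].
#' @param seed integer seed (NULL = use current RNG state).
#' @param events list of [IraeEvent-class] active for this patient.
#' @param scan_day day of the scan.
#' @param patient_mult named numeric(3) per-organ patient multiplier; drawn
#'   from N(1, patient_sd) when NULL.
#' @param meta optional [ScanMeta-class] (patient id / day bookkeeping).
#' @return An [SUVVolume-class].
#' @export
sampleUptake <- function(mask, model, seed = NULL, events = list(),
                         scan_day = 0, patient_mult = NULL, meta = NULL) {
  stopifnot(is(mask, "OrganMask"), is(model, "UptakeModel"))
  validObject(model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(meta)) meta <- scanMeta(scan_day = scan_day)
  if (is.null(patient_mult))
    patient_mult <- drawPatientMultipliers(model)
  dims <- mask@grid@dims
  vox <- stats::rnorm(prod(dims), model@bg_mean, model@bg_sd)
  vox[vox < 0] <- 0
  dim(vox) <- dims
  for (organ in .organ_names) {
    sel <- mask@labels == organCodes()[[organ]]
    n <- sum(sel)
    if (n == 0) next
    vox[sel] <- stats::rlnorm(n, model@location[[organ]],
                              model@scale[[organ]]) * patient_mult[[organ]]
  }
  for (ev in events) {
    code <- .organ_code(ev@organ)
    if (!any(mask@labels == code))
      stop("empty organ: event organ '", ev@organ, "' absent from mask",
           call. = FALSE)
    validObject(ev)
    vox <- .apply_event_array(vox, mask, ev, scan_day)
  }
  if (model@psf_fwhm_mm > 0)
    vox <- .gauss_smooth3d(vox, .fwhm_to_sigma(model@psf_fwhm_mm,
                                               mask@grid@spacing))
  if (model@noise_sd > 0)
    vox <- vox + stats::rnorm(length(vox), 0, model@noise_sd)
  vox[vox < 0] <- 0
  suvVolume(vox, mask@grid, meta)
}

#' Draw per-patient organ uptake multipliers
#'
#' One multiplier per organ, ~ N(1, patient_sd) truncated below at 0.05;
#' constant across a patient's scans.
#'
#' @param model an [UptakeModel-class].
#' @return Named numeric(3).
#' @export
drawPatientMultipliers <- function(model) {
  m <- stats::rnorm(3, 1, model@patient_sd[.organ_names])
  names(m) <- .organ_names
  pmax(m, 0.05)
}

#' Normative calibration targets from published reference bands
#'
#' Inverts a 95\% reference band \eqn{[lo, hi] = \mu \pm 1.96\sigma} to the
#' (mu, sigma) the simulator must reproduce for each organ's optimal
#' percentile: bowel SUV95\% in [1.74, 2.86], lung SUV95\% in [0.73, 1.46],
#' thyroid SUV75\% in [0.86, 1.99] g/mL.
#'
#' @return data.frame with columns organ, percentile, mu, sigma.
#' @export
defaultCalibrationTargets <- function() {
  bands <- data.frame(
    organ = c("bowel", "lung", "thyroid"),
    percentile = c(95, 95, 75),
    lo = c(1.74, 0.73, 0.86),
    hi = c(2.86, 1.46, 1.99))
  data.frame(organ = bands$organ, percentile = bands$percentile,
             mu = (bands$lo + bands$hi) / 2,
             sigma = (bands$hi - bands$lo) / 3.92)
}

#' Calibrate baseline uptake to normative targets
#'
#' Iteratively adjusts each organ's log-location and between-patient sd so
#' that, across `n` simulated irAE-free patients, the mean and sd of the
#' organ's target SUV percentile match `targets` within `tol` relative
#' tolerance. Uses common random numbers across iterations (fixed per-patient
#' seeds) so the fixed-point iteration is stable and the result reproducible.
#'
#' @param model starting [UptakeModel-class].
#' @param targets data.frame(organ, percentile, mu, sigma); see
#'   [defaultCalibrationTargets()].
#' @param mask phantom [OrganMask-class] to simulate on.
#' @param n patients simulated per iteration.
#' @param seed integer seed.
#' @param max_iter iteration cap.
#' @param tol relative tolerance on mean and sd.
#' @param damping step damping in (0, 1].
#' @return The calibrated [UptakeModel-class], with a `calibration` attribute
#'   holding the achieved means/sds and iteration count.
#' @export
calibrateBaseline <- function(model, targets = defaultCalibrationTargets(),
                              mask, n = 160, seed = 1, max_iter = 15,
                              tol = 0.05, damping = 0.8) {
  stopifnot(is(model, "UptakeModel"), is(mask, "OrganMask"))
  organs <- targets$organ
  pct <- stats::setNames(targets$percentile, organs)
  mu_t <- stats::setNames(targets$mu, organs)
  sd_t <- stats::setNames(targets$sigma, organs)

  # common random numbers across iterations: same per-patient seeds each time
  measure <- function(mod) {
    base <- simulateBaselines(n, mod, mask, percentiles = pct, seed = seed)
    m <- tapply(base$value, base$organ, mean)[organs]
    s <- tapply(base$value, base$organ, stats::sd)[organs]
    list(m = m, s = s)
  }

  for (it in seq_len(max_iter)) {
    est <- measure(model)
    ok <- abs(est$m - mu_t) / mu_t < tol & abs(est$s - sd_t) / sd_t < tol
    if (all(ok)) {
      attr(model, "calibration") <- list(
        iterations = it, achieved_mu = est$m, achieved_sigma = est$s,
        target_mu = mu_t, target_sigma = sd_t)
      return(model)
    }
    loc <- model@location
    psd <- model@patient_sd
    for (organ in organs) {
      loc[[organ]] <- loc[[organ]] + damping * log(mu_t[[organ]] /
                                                     est$m[[organ]])
      ratio <- (sd_t[[organ]] / est$s[[organ]])^damping
      psd[[organ]] <- min(max(psd[[organ]] * min(max(ratio, 0.25), 4), 1e-4),
                          0.8)
    }
    model <- uptakeModel(location = loc, scale = model@scale,
                         patient_sd = psd, bg_mean = model@bg_mean,
                         bg_sd = model@bg_sd, psf_fwhm_mm = model@psf_fwhm_mm,
                         noise_sd = model@noise_sd)
  }
  stop(sprintf(paste0("calibration error: not converged after %d iterations ",
                      "(achieved mu: %s; target mu: %s; achieved sigma: %s; ",
                      "target sigma: %s)"),
               max_iter, paste(signif(est$m, 4), collapse = ", "),
               paste(signif(mu_t, 4), collapse = ", "),
               paste(signif(est$s, 4), collapse = ", "),
               paste(signif(sd_t, 4), collapse = ", ")), call. = FALSE)
}
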