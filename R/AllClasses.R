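#' @import methods
NULL

#' Organ label codes
#'
#' Integer codes used in labeled organ masks: 1 = bowel, 2 = lung,
#' 3 = thyroid, 0 = background. These are the three organs most commonly
#' affected by immune-related adverse events (colitis, pneumonitis,
#' thyroiditis) under immune-checkpoint-inhibitor therapy.
#'
#' @return Named integer vector of organ codes.
#' @export
#' @examples
#' organCodes()
organCodes <- function() c(bowel = 1L, lung = 2L, thyroid = 3L)

.organ_names <- c("bowel", "lung", "thyroid")

#' ImageGrid: regular 3-D sampling grid
#'
#' Axis-aligned voxel lattice in world (scanner) coordinates. The world
#' position of 0-based voxel index \code{(i, j, k)} is
#' \code{origin + c(i, j, k) * spacing}, i.e. \code{origin} is the centre of
#' the first voxel. Axis order is fixed (x, y, z).
#'
#' @slot dims integer(3), voxels per axis (all >= 1).
#' @slot spacing numeric(3), mm per voxel along each axis (all > 0).
#' @slot origin numeric(3), world coordinate (mm) of the first voxel centre.
#'
#' @export
setClass("ImageGrid",
  slots = c(dims = "integer", spacing = "numeric", origin = "numeric"))

setValidity("ImageGrid", function(object) {
  if (length(object@dims) != 3L || length(object@spacing) != 3L ||
      length(object@origin) != 3L)
    return("dims, spacing and origin must each have length 3")
  if (any(!is.finite(object@dims)) || any(object@dims < 1L))
    return("all dims must be >= 1")
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("all spacing must be > 0")
  if (any(!is.finite(object@origin)))
    return("origin must be finite")
  TRUE
})

#' Construct an ImageGrid
#'
#' @param dims integer(3) voxel counts per axis.
#' @param spacing numeric mm per voxel; scalar is recycled to 3 axes.
#' @param origin numeric(3) world mm of the first voxel centre.
#' @return An [ImageGrid-class] object.
#' @export
#' @examples
#' imageGrid(c(64, 64, 96), spacing = 4)
imageGrid <- function(dims, spacing = 1, origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageGrid", dims = as.integer(dims), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' ScanMeta: PET scan metadata
#'
#' Metadata needed to normalize a reconstructed activity image to
#' standardized uptake values, plus the scan's position on the treatment
#' timeline.
#'
#' @slot patient_id character, opaque patient identifier.
#' @slot scan_day numeric, day offset from treatment start (negative =
#'   baseline, before treatment).
#' @slot weight_g numeric, patient weight in grams (> 0 unless the image is
#'   already SUV-normalized).
#' @slot dose_Bq numeric, injected, decay-corrected dose in Bq (> 0 unless
#'   already SUV-normalized).
#' @slot suv_precomputed logical, TRUE when the stored voxels are already SUV
#'   so no weight/dose normalization is applied.
#'
#' @export
setClass("ScanMeta",
  slots = c(patient_id = "character", scan_day = "numeric",
            weight_g = "numeric", dose_Bq = "numeric",
            suv_precomputed = "logical"),
  prototype = prototype(patient_id = "unknown", scan_day = 0,
                        weight_g = NA_real_, dose_Bq = NA_real_,
                        suv_precomputed = TRUE))

setValidity("ScanMeta", function(object) {
  if (!object@suv_precomputed) {
    if (!is.finite(object@weight_g) || object@weight_g <= 0)
      return("weight_g must be a positive, finite number")
    if (!is.finite(object@dose_Bq) || object@dose_Bq <= 0)
      return("dose_Bq must be a positive, finite number")
  }
  TRUE
})

#' Construct ScanMeta
#'
#' @param patient_id character identifier.
#' @param scan_day day offset from treatment start (negative for baseline).
#' @param weight_g patient weight in grams.
#' @param dose_Bq injected dose in Bq.
#' @param suv_precomputed TRUE when voxels are already SUV-normalized.
#' @return A [ScanMeta-class] object.
#' @export
scanMeta <- function(patient_id = "unknown", scan_day = 0,
                     weight_g = NA_real_, dose_Bq = NA_real_,
                     suv_precomputed = is.na(weight_g) && is.na(dose_Bq)) {
  new("ScanMeta", patient_id = as.character(patient_id),
      scan_day = as.numeric(scan_day), weight_g = as.numeric(weight_g),
      dose_Bq = as.numeric(dose_Bq),
      suv_precomputed = isTRUE(suv_precomputed))
}

.check_shape <- function(voxels, grid) {
  d <- dim(voxels)
  if (is.null(d) || length(d) != 3L || !all(d == grid@dims))
    return("voxel array shape must equal grid dims")
  NULL
}

#' ActivityVolume: decay-corrected activity image
#'
#' Reconstructed PET activity concentration (Bq/mL), decay-corrected to
#' injection time, on a stated [ImageGrid-class].
#'
#' @slot voxels 3-D numeric array, Bq/mL, all >= 0.
#' @slot grid the sampling [ImageGrid-class].
#' @export
setClass("ActivityVolume", slots = c(voxels = "array", grid = "ImageGrid"))

setValidity("ActivityVolume", function(object) {
  msg <- .check_shape(object@voxels, object@grid)
  if (!is.null(msg)) return(msg)
  if (any(!is.finite(object@voxels))) return("activity must be finite")
  if (any(object@voxels < 0)) return("activity must be non-negative")
  TRUE
})

#' Construct an ActivityVolume
#' @param voxels 3-D array of activity (Bq/mL).
#' @param grid an [ImageGrid-class].
#' @return An [ActivityVolume-class].
#' @export
activityVolume <- function(voxels, grid) {
  new("ActivityVolume", voxels = voxels, grid = grid)
}

#' SUVVolume: standardized uptake value image
#'
#' PET image in standardized uptake values (g/mL): activity concentration
#' normalized by injected dose and patient weight, so SUV 1.0 corresponds to
#' uniform distribution of the tracer over the body mass.
#'
#' @slot voxels 3-D numeric array of SUV (g/mL), all >= 0.
#' @slot grid the sampling [ImageGrid-class].
#' @slot meta the scan's [ScanMeta-class].
#' @export
setClass("SUVVolume",
  slots = c(voxels = "array", grid = "ImageGrid", meta = "ScanMeta"))

setValidity("SUVVolume", function(object) {
  msg <- .check_shape(object@voxels, object@grid)
  if (!is.null(msg)) return(msg)
  if (any(!is.finite(object@voxels))) return("SUV must be finite")
  if (any(object@voxels < 0)) return("SUV must be non-negative everywhere")
  TRUE
})

#' Construct an SUVVolume
#' @param voxels 3-D array of SUV (g/mL).
#' @param grid an [ImageGrid-class].
#' @param meta a [ScanMeta-class]; defaults to an anonymous precomputed-SUV
#'   record.
#' @return An [SUVVolume-class].
#' @export
suvVolume <- function(voxels, grid, meta = scanMeta()) {
  new("SUVVolume", voxels = voxels, grid = grid, meta = meta)
}

#' OrganMask: labeled organ segmentation
#'
#' Integer label volume on a stated grid. Codes follow [organCodes()]:
#' 0 background, 1 bowel, 2 lung, 3 thyroid.
#'
#' @slot labels 3-D integer array with values in \{0, 1, 2, 3\}.
#' @slot grid the sampling [ImageGrid-class].
#' @export
setClass("OrganMask", slots = c(labels = "array", grid = "ImageGrid"))

setValidity("OrganMask", function(object) {
  msg <- .check_shape(object@labels, object@grid)
  if (!is.null(msg)) return(msg)
  vals <- unique(as.vector(object@labels))
  if (!all(vals %in% c(0L, organCodes())))
    return("mask labels must be in {0, 1, 2, 3}")
  TRUE
})

#' Construct an OrganMask
#' @param labels 3-D integer array of organ codes.
#' @param grid an [ImageGrid-class].
#' @return An [OrganMask-class].
#' @export
organMask <- function(labels, grid) {
  storage.mode(labels) <- "integer"
  new("OrganMask", labels = labels, grid = grid)
}

#' NormalRange: normative band for an organ biomarker
#'
#' Mean, standard deviation and 95\% reference band
#' \eqn{[\mu - 1.96\sigma, \mu + 1.96\sigma]} of baseline SUV_OPT\% values in
#' patients who experienced no irAE of any organ. The band is the grey
#' normative region against which longitudinal series are flagged.
#'
#' @slot organ character organ name.
#' @slot mu numeric mean (g/mL).
#' @slot sigma numeric standard deviation (g/mL, n-1 denominator).
#' @slot n integer number of contributing patients.
#' @slot lo,hi numeric band endpoints (g/mL).
#' @export
setClass("NormalRange",
  slots = c(organ = "character", mu = "numeric", sigma = "numeric",
            n = "integer", lo = "numeric", hi = "numeric"))

setValidity("NormalRange", function(object) {
  if (abs(object@lo - (object@mu - 1.96 * object@sigma)) > 1e-8 ||
      abs(object@hi - (object@mu + 1.96 * object@sigma)) > 1e-8)
    return("band endpoints must equal mu -/+ 1.96 sigma")
  if (object@hi < object@lo) return("hi must be >= lo")
  TRUE
})

#' CutoffResult: Youden-optimal operating point
#'
#' @slot organ character organ name (may be NA for generic use).
#' @slot t_opt numeric threshold (g/mL); scores strictly above it are called
#'   positive.
#' @slot j numeric Youden's index, sensitivity + specificity - 1.
#' @slot sensitivity,specificity numeric in [0, 1].
#' @export
setClass("CutoffResult",
  slots = c(organ = "character", t_opt = "numeric", j = "numeric",
            sensitivity = "numeric", specificity = "numeric"))

setValidity("CutoffResult", function(object) {
  if (abs(object@j - (object@sensitivity + object@specificity - 1)) > 1e-8)
    return("j must equal sensitivity + specificity - 1")
  if (object@j < -1 || object@j > 1) return("j must lie in [-1, 1]")
  TRUE
})

#' BiomarkerSelection: AUROC-optimal percentile for one organ
#'
#' @slot organ character organ name.
#' @slot opt_percentile numeric, the percentile X maximizing AUROC (SUV_OPT\%).
#' @slot auroc numeric, AUROC at the optimum.
#' @slot scan data.frame with columns percentile, auroc: AUROC over the whole
#'   percentile grid.
#' @export
setClass("BiomarkerSelection",
  slots = c(organ = "character", opt_percentile = "numeric",
            auroc = "numeric", scan = "data.frame"))

setValidity("BiomarkerSelection", function(object) {
  if (!object@opt_percentile %in% object@scan$percentile)
    return("opt_percentile must belong to the scanned grid")
  if (abs(object@auroc - max(object@scan$auroc)) > 1e-12)
    return("auroc must equal the maximum over the grid")
  TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %s voxels @ %s mm, origin (%s) mm\n",
              paste(object@dims, collapse = "x"),
              paste(format(object@spacing), collapse = "x"),
              paste(format(object@origin), collapse = ", ")))
})

setMethod("show", "SUVVolume", function(object) {
  cat(sprintf("SUVVolume [%s, day %g]: %s voxels, SUV range [%.3g, %.3g] g/mL\n",
              object@meta@patient_id, object@meta@scan_day,
              paste(object@grid@dims, collapse = "x"),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "OrganMask", function(object) {
  counts <- vapply(organCodes(), function(code)
    sum(object@labels == code), integer(1))
  cat(sprintf("OrganMask: %s voxels; %s\n",
              paste(object@grid@dims, collapse = "x"),
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
})

setMethod("show", "NormalRange", function(object) {
  cat(sprintf("NormalRange [%s]: mu=%.3f sigma=%.3f n=%d CI95=[%.2f, %.2f] g/mL\n",
              object@organ, object@mu, object@sigma, object@n,
              object@lo, object@hi))
})

setMethod("show", "CutoffResult", function(object) {
  cat(sprintf("CutoffResult [%s]: T_opt=%.3g g/mL J=%.3f sens=%.2f spec=%.2f\n",
              object@organ, object@t_opt, object@j,
              object@sensitivity, object@specificity))
})

setMethod("show", "BiomarkerSelection", function(object) {
  cat(sprintf("BiomarkerSelection [%s]: SUV_%g%% AUROC=%.3f (grid of %d percentiles)\n",
              object@organ, object@opt_percentile, object@auroc,
              nrow(object@scan)))
})
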