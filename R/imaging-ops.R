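#' Compute standardized uptake values
#'
#' Normalizes a decay-corrected activity image by patient weight and injected
#' dose: \deqn{SUV = A \mathrm{[Bq/mL]} \times w \mathrm{[g]} / D \mathrm{[Bq]}}
#' giving SUV in g/mL. Decay correction is assumed to have been applied during
#' reconstruction; no re-correction is performed here.
#'
#' @param activity an [ActivityVolume-class] (Bq/mL).
#' @param meta a [ScanMeta-class] with positive `weight_g` and `dose_Bq`.
#' @return An [SUVVolume-class] on the same grid.
#' @export
#' @examples
#' g <- imageGrid(c(2, 2, 2), spacing = 4)
#' act <- activityVolume(array(5000, c(2, 2, 2)), g)
#' m <- scanMeta("p1", 0, weight_g = 70000, dose_Bq = 3.5e8,
#'               suv_precomputed = FALSE)
#' max(voxels(computeSUV(act, m)))  # 1.0 g/mL
computeSUV <- function(activity, meta) {
  stopifnot(is(activity, "ActivityVolume"), is(meta, "ScanMeta"))
  if (!is.finite(meta@weight_g) || meta@weight_g <= 0 ||
      !is.finite(meta@dose_Bq) || meta@dose_Bq <= 0)
    stop("invalid metadata: weight_g and dose_Bq must be positive for SUV ",
         "normalization", call. = FALSE)
  suv <- activity@voxels * (meta@weight_g / meta@dose_Bq)
  suvVolume(suv, activity@grid, meta)
}

#' Resample an organ mask onto a target grid
#'
#' Nearest-neighbour label resampling in world coordinates, so masks can be
#' moved onto the PET grid before quantification. Labels are looked up, never
#' interpolated: the label set can shrink but no new label can appear. Target
#' voxels falling outside the source extent become background.
#'
#' @param mask an [OrganMask-class].
#' @param target an [ImageGrid-class] overlapping the mask in world space.
#' @return An [OrganMask-class] on `target`.
#' @export
resampleMaskTo <- function(mask, target) {
  stopifnot(is(mask, "OrganMask"), is(target, "ImageGrid"))
  if (sameGrid(mask@grid, target)) return(mask)
  src <- mask@grid
  es <- .world_extent(src); et <- .world_extent(target)
  if (any(es["hi", ] < et["lo", ] | et["hi", ] < es["lo", ]))
    stop("alignment error: mask and target grids have disjoint world extents",
         call. = FALSE)
  # per-axis nearest source index (1-based), NA outside the source lattice
  idx <- lapply(1:3, function(ax) {
    w <- .axis_coords(target, ax)
    i <- round((w - src@origin[ax]) / src@spacing[ax]) + 1
    i[i < 1 | i > src@dims[ax]] <- NA_integer_
    as.integer(i)
  })
  out <- array(0L, target@dims)
  ok <- lapply(idx, function(i) !is.na(i))
  sub <- mask@labels[idx[[1]][ok[[1]]], idx[[2]][ok[[2]]], idx[[3]][ok[[3]]],
                     drop = FALSE]
  out[ok[[1]], ok[[2]], ok[[3]]] <- sub
  organMask(out, target)
}

#' Extract SUV values under an organ label
#'
#' Applies an organ contour to a PET image: returns the SUV values at exactly
#' the voxels carrying the requested label. The SUV volume and the mask must
#' already share a grid (use [resampleMaskTo()] first otherwise).
#'
#' @param suv an [SUVVolume-class].
#' @param mask an [OrganMask-class] on the same grid.
#' @param organ organ name ("bowel", "lung", "thyroid") or integer code.
#' @return Numeric vector of SUV values, length = organ voxel count; order
#'   unspecified.
#' @export
extractMaskedValues <- function(suv, mask, organ) {
  stopifnot(is(suv, "SUVVolume"), is(mask, "OrganMask"))
  if (!sameGrid(suv@grid, mask@grid))
    stop("SUV volume and mask are on different grids; resample the mask first",
         call. = FALSE)
  code <- .organ_code(organ)
  sel <- mask@labels == code
  if (!any(sel))
    stop(sprintf("empty organ: label '%s' has no voxels in this mask",
                 .organ_name(code)), call. = FALSE)
  suv@voxels[sel]
}

.organ_code <- function(organ) {
  codes <- organCodes()
  if (is.character(organ)) {
    if (!organ %in% names(codes))
      stop("unknown organ '", organ, "'", call. = FALSE)
    return(codes[[organ]])
  }
  organ <- as.integer(organ)
  if (!organ %in% codes) stop("unknown organ code ", organ, call. = FALSE)
  organ
}

.organ_name <- function(code) names(organCodes())[match(code, organCodes())]

#' Crop a mask to one organ's bounding box
#'
#' Returns a single-organ mask on the sub-grid spanning the organ's bounding
#' box plus a margin (world origin adjusted accordingly). Useful for fast
#' percentile-only simulations: with a margin of at least the PSF kernel
#' radius, rendering the crop is statistically identical to rendering the
#' full field of view, at a fraction of the cost.
#'
#' @param mask an [OrganMask-class].
#' @param organ organ name or code.
#' @param margin margin in voxels around the bounding box (default 4).
#' @return An [OrganMask-class] containing only the requested organ.
#' @export
cropOrganMask <- function(mask, organ, margin = 4L) {
  stopifnot(is(mask, "OrganMask"))
  code <- .organ_code(organ)
  sel <- mask@labels == code
  if (!any(sel))
    stop("empty organ: label '", .organ_name(code), "' has no voxels",
         call. = FALSE)
  co <- arrayInd(which(sel), mask@grid@dims)
  lo <- pmax(apply(co, 2, min) - margin, 1L)
  hi <- pmin(apply(co, 2, max) + margin, mask@grid@dims)
  sub <- mask@labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub[sub != code] <- 0L
  grid <- imageGrid(hi - lo + 1L, spacing = mask@grid@spacing,
                    origin = mask@grid@origin + (lo - 1) * mask@grid@spacing)
  organMask(sub, grid)
}

## ---- separable Gaussian smoothing -----------------------------------------
## Truncated (3 sigma) kernel applied axis by axis as a dense banded matrix
## product; rows are renormalized so edge voxels keep unit total weight.

.gauss_matrix <- function(d, sigma) {
  if (sigma <= 0) return(NULL)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-0.5 * ((-r:r) / sigma)^2)
  m <- matrix(0, d, d)
  for (k in -r:r) {
    i <- seq_len(d)
    j <- i + k
    keep <- j >= 1 & j <= d
    m[cbind(i[keep], j[keep])] <- w[k + r + 1]
  }
  m / rowSums(m)
}

.gauss_smooth3d <- function(arr, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  if (all(sigma_vox <= 0)) return(arr)
  d <- dim(arr)
  m1 <- .gauss_matrix(d[1], sigma_vox[1])
  if (!is.null(m1)) {
    dim(arr) <- c(d[1], d[2] * d[3])
    arr <- m1 %*% arr
  }
  m2 <- .gauss_matrix(d[2], sigma_vox[2])
  if (!is.null(m2)) {
    dim(arr) <- d
    arr <- aperm(arr, c(2, 1, 3))
    dim(arr) <- c(d[2], d[1] * d[3])
    arr <- m2 %*% arr
    dim(arr) <- c(d[2], d[1], d[3])
    arr <- aperm(arr, c(2, 1, 3))
  }
  m3 <- .gauss_matrix(d[3], sigma_vox[3])
  if (!is.null(m3)) {
    dim(arr) <- c(d[1] * d[2], d[3])
    arr <- arr %*% t(m3)
  }
  dim(arr) <- d
  as.array(arr)
}

.fwhm_to_sigma <- function(fwhm_mm, spacing) {
  (fwhm_mm / (2 * sqrt(2 * log(2)))) / spacing
}
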