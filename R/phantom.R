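#' PhantomSpec: parametric digital phantom geometry
#'
#' A simple anthropomorphic stand-in used by the synthetic cohort generator:
#' lungs as two large ellipsoids, thyroid as two small ellipsoids joined by a
#' bridge (the isthmus), and bowel as a folded tube of stated radius following
#' a serpentine path through the abdomen. All geometry is in world mm, so the
#' same spec voxelizes consistently at any grid resolution.
#'
#' @slot grid the sampling [ImageGrid-class] (default 64 x 64 x 96 at 4 mm).
#' @slot lung list(centers = 2 x 3 matrix, axes = numeric(3) semi-axes), mm.
#' @slot thyroid list(lobe_centers = 2 x 3 matrix, lobe_axes = numeric(3),
#'   bridge_center = numeric(3), bridge_axes = numeric(3)), mm.
#' @slot bowel list(path = n x 3 matrix of polyline points, radius = numeric),
#'   mm.
#' @export
setClass("PhantomSpec",
  slots = c(grid = "ImageGrid", lung = "list", thyroid = "list",
            bowel = "list"))

#' Construct a PhantomSpec
#'
#' The default geometry fills a 256 x 256 x 384 mm field of view; pass a
#' coarser `spacing` (e.g. 8) for fast test phantoms — organ shapes stay
#' fixed in mm, only the voxelization changes.
#'
#' @param spacing voxel size in mm (scalar, cubic voxels).
#' @param fov field of view in mm per axis.
#' @param lung,thyroid,bowel optional geometry overrides (see
#'   [PhantomSpec-class]).
#' @return A [PhantomSpec-class].
#' @export
#' @examples
#' spec <- phantomSpec()
#' mask <- buildPhantom(spec)
#' organVoxelCounts(mask)
phantomSpec <- function(spacing = 4, fov = c(256, 256, 384),
                        lung = NULL, thyroid = NULL, bowel = NULL) {
  dims <- as.integer(round(fov / spacing))
  grid <- imageGrid(dims, spacing = spacing, origin = c(0, 0, 0))
  if (is.null(lung))
    lung <- list(centers = rbind(c(88, 128, 235), c(168, 128, 235)),
                 axes = c(40, 55, 65))
  if (is.null(thyroid))
    thyroid <- list(lobe_centers = rbind(c(108, 120, 336), c(148, 120, 336)),
                    lobe_axes = c(10, 10, 22),
                    bridge_center = c(128, 120, 330),
                    bridge_axes = c(14, 6, 8))
  if (is.null(bowel))
    bowel <- list(path = rbind(c(48, 100, 55), c(208, 100, 55),
                               c(208, 140, 70), c(48, 140, 70),
                               c(48, 100, 85), c(208, 100, 85),
                               c(208, 140, 100), c(48, 140, 100)),
                  radius = 14)
  new("PhantomSpec", grid = grid, lung = lung, thyroid = thyroid,
      bowel = bowel)
}

setValidity("PhantomSpec", function(object) {
  if (any(object@lung$axes <= 0) || any(object@thyroid$lobe_axes <= 0) ||
      any(object@thyroid$bridge_axes <= 0) || object@bowel$radius <= 0)
    return("degenerate geometry: all semi-axes and radii must be > 0")
  TRUE
})

## rasterize an ellipsoid on the grid; separable quadratic form
.raster_ellipsoid <- function(grid, center, axes) {
  tx <- ((.axis_coords(grid, 1) - center[1]) / axes[1])^2
  ty <- ((.axis_coords(grid, 2) - center[2]) / axes[2])^2
  tz <- ((.axis_coords(grid, 3) - center[3]) / axes[3])^2
  q <- outer(outer(tx, ty, "+"), tz, "+")
  q <= 1
}

## rasterize a tube around a polyline, segment by segment in bounding boxes
.raster_tube <- function(grid, path, radius) {
  out <- array(FALSE, grid@dims)
  cx <- .axis_coords(grid, 1); cy <- .axis_coords(grid, 2)
  cz <- .axis_coords(grid, 3)
  for (s in seq_len(nrow(path) - 1)) {
    p0 <- path[s, ]; p1 <- path[s + 1, ]
    lo <- pmin(p0, p1) - radius; hi <- pmax(p0, p1) + radius
    ix <- which(cx >= lo[1] & cx <= hi[1])
    iy <- which(cy >= lo[2] & cy <= hi[2])
    iz <- which(cz >= lo[3] & cz <= hi[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    pts <- as.matrix(expand.grid(x = cx[ix], y = cy[iy], z = cz[iz]))
    v <- p1 - p0
    len2 <- sum(v^2)
    d <- sweep(pts, 2, p0)
    t <- if (len2 > 0) pmin(pmax((d %*% v) / len2, 0), 1) else 0
    res <- d - outer(as.vector(t), v)
    inside <- rowSums(res^2) <= radius^2
    out[ix, iy, iz] <- out[ix, iy, iz] | array(inside, c(length(ix),
                                                         length(iy),
                                                         length(iz)))
  }
  out
}

.check_in_fov <- function(grid, lo, hi, organ) {
  ext <- .world_extent(grid)
  if (any(lo < ext["lo", ]) || any(hi > ext["hi", ]))
    stop("phantom spec error: ", organ, " geometry exceeds the grid",
         call. = FALSE)
}

#' Voxelize a phantom into a labeled organ mask
#'
#' Deterministic rasterization of the spec's geometry. Errors if any organ
#' extends outside the grid or if organs overlap; reports organ voxel counts
#' as a message.
#'
#' @param spec a [PhantomSpec-class].
#' @return An [OrganMask-class] on the spec's grid.
#' @export
buildPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  grid <- spec@grid

  lu <- spec@lung
  .check_in_fov(grid, apply(sweep(lu$centers, 2, lu$axes), 2, min),
                apply(sweep(lu$centers, 2, -lu$axes), 2, max), "lung")
  lung <- .raster_ellipsoid(grid, lu$centers[1, ], lu$axes) |
    .raster_ellipsoid(grid, lu$centers[2, ], lu$axes)

  th <- spec@thyroid
  .check_in_fov(grid,
                pmin(apply(sweep(th$lobe_centers, 2, th$lobe_axes), 2, min),
                     th$bridge_center - th$bridge_axes),
                pmax(apply(sweep(th$lobe_centers, 2, -th$lobe_axes), 2, max),
                     th$bridge_center + th$bridge_axes), "thyroid")
  thyroid <- .raster_ellipsoid(grid, th$lobe_centers[1, ], th$lobe_axes) |
    .raster_ellipsoid(grid, th$lobe_centers[2, ], th$lobe_axes) |
    .raster_ellipsoid(grid, th$bridge_center, th$bridge_axes)

  bo <- spec@bowel
  .check_in_fov(grid, apply(bo$path, 2, min) - bo$radius,
                apply(bo$path, 2, max) + bo$radius, "bowel")
  bowel <- .raster_tube(grid, bo$path, bo$radius)

  if (any((lung & thyroid) | (lung & bowel) | (thyroid & bowel)))
    stop("phantom spec error: organ geometries overlap", call. = FALSE)

  labels <- array(0L, grid@dims)
  labels[bowel] <- organCodes()[["bowel"]]
  labels[lung] <- organCodes()[["lung"]]
  labels[thyroid] <- organCodes()[["thyroid"]]
  mask <- organMask(labels, grid)
  counts <- organVoxelCounts(mask)
  if (any(counts < 1))
    stop("phantom spec error: organ(s) with zero voxels at this resolution: ",
         paste(names(counts)[counts < 1], collapse = ", "), call. = FALSE)
  message("phantom organ voxel counts: ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  mask
}
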