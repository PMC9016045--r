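#' Accessors for imaging objects
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `voxelGrid()` returns the [ImageGrid-class], `voxels()` the numeric voxel
#' array, `maskArray()` the integer label array and `scanMeta()` the
#' [ScanMeta-class] of a scan.
#'
#' @param x an imaging object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("scanInfo", function(x) standardGeneric("scanInfo"))

#' @rdname accessors
#' @export
setMethod("voxelGrid", "SUVVolume", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("voxelGrid", "ActivityVolume", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("voxelGrid", "OrganMask", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("voxels", "SUVVolume", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("voxels", "ActivityVolume", function(x) x@voxels)

#' @rdname accessors
#' @export
setMethod("maskArray", "OrganMask", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("scanInfo", "SUVVolume", function(x) x@meta)

#' Organ voxel counts of a mask
#'
#' @param mask an [OrganMask-class].
#' @return Named integer vector of voxel counts for bowel, lung, thyroid.
#' @export
organVoxelCounts <- function(mask) {
  stopifnot(is(mask, "OrganMask"))
  vapply(organCodes(), function(code) sum(mask@labels == code), integer(1))
}

#' Test whether two grids coincide
#'
#' @param a,b [ImageGrid-class] objects.
#' @param tol numeric tolerance on spacing/origin (mm).
#' @return TRUE when dims match and spacing/origin agree within `tol`.
#' @export
sameGrid <- function(a, b, tol = 1e-6) {
  all(a@dims == b@dims) &&
    all(abs(a@spacing - b@spacing) < tol) &&
    all(abs(a@origin - b@origin) < tol)
}

## world-coordinate helpers (0-based indices; origin = centre of voxel 0)
.axis_coords <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@dims[axis]) - 1) * grid@spacing[axis]
}

.world_extent <- function(grid) {
  lo <- grid@origin - grid@spacing / 2
  hi <- grid@origin + (grid@dims - 1) * grid@spacing + grid@spacing / 2
  rbind(lo = lo, hi = hi)
}
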