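#' Default SUV percentile grid
#'
#' Percentiles at which organ SUV profiles are evaluated: 5, 10, ..., 95, 100.
#'
#' @return Numeric vector of percentiles.
#' @export
defaultPercentileGrid <- function() seq(5, 100, by = 5)

#' Organ SUV percentiles (SUV_X\%)
#'
#' Percentiles of the SUV distribution over an organ's voxels, by sorted
#' linear interpolation between closest ranks: rank
#' \eqn{r = 1 + (n - 1) X / 100}, interpolating between the floor and ceiling
#' order statistics (the type-7 convention of [stats::quantile()]). The
#' convention is the analysis' central reproducibility choice and is exposed
#' via `type` for sensitivity checks.
#'
#' @param values numeric vector of SUV values (non-empty).
#' @param grid percentiles in [0, 100].
#' @param type quantile convention passed to [stats::quantile()].
#' @return Named numeric vector, one SUV_X\% (g/mL) per grid entry,
#'   non-decreasing in X.
#' @export
#' @examples
#' organPercentiles(c(1, 2, 3, 4), 95)  # 3.85
organPercentiles <- function(values, grid = defaultPercentileGrid(),
                             type = 7) {
  if (length(values) == 0)
    stop("empty organ: no values to compute percentiles from", call. = FALSE)
  if (any(grid < 0 | grid > 100))
    stop("percentiles must lie in [0, 100]", call. = FALSE)
  q <- stats::quantile(values, probs = grid / 100, type = type, names = FALSE)
  stats::setNames(q, grid)
}

.organ_logical <- function(x, organ) {
  if (is(x, "OrganMask")) x@labels == .organ_code(organ) else as.array(x) > 0
}

#' Dice similarity coefficient
#'
#' Volume overlap \eqn{2 |A \cap B| / (|A| + |B|)} between one organ's voxel
#' sets in two masks; 1 iff identical sets, 0 iff disjoint.
#'
#' @param a,b [OrganMask-class] objects on the same grid (or logical arrays).
#' @param organ organ name or code selecting the voxel sets.
#' @return DSC in [0, 1].
#' @export
diceCoefficient <- function(a, b, organ = "bowel") {
  if (is(a, "OrganMask") && is(b, "OrganMask") && !sameGrid(a@grid, b@grid))
    stop("masks are on different grids", call. = FALSE)
  A <- .organ_logical(a, organ); B <- .organ_logical(b, organ)
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0)
    stop("DSC undefined: both masks are empty for this organ", call. = FALSE)
  2 * sum(A & B) / (na + nb)
}

## boundary voxels under 6-connectivity: organ voxels with at least one
## face-neighbour outside the organ (the volume border counts as outside)
.surface_voxels <- function(sel) {
  d <- dim(sel)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    lo <- slice.index(sel, ax) > 1
    hi <- slice.index(sel, ax) < d[ax]
    idx <- lapply(d, seq_len)
    # neighbour towards lower index
    src <- idx; src[[ax]] <- c(1L, seq_len(d[ax] - 1L))
    shift_lo <- do.call(`[`, c(list(sel), src, list(drop = FALSE)))
    shift_lo[!lo] <- FALSE
    src <- idx; src[[ax]] <- c(seq_len(d[ax] - 1L) + 1L, d[ax])
    shift_hi <- do.call(`[`, c(list(sel), src, list(drop = FALSE)))
    shift_hi[!hi] <- FALSE
    interior <- interior & shift_lo & shift_hi
  }
  sel & !interior
}

.surface_coords <- function(mask, organ) {
  sel <- .organ_logical(mask, organ)
  if (!any(sel))
    stop("ASSD undefined: empty mask for this organ", call. = FALSE)
  surf <- which(.surface_voxels(sel))
  grid <- if (is(mask, "OrganMask")) mask@grid else
    imageGrid(dim(sel), spacing = 1)
  co <- arrayInd(surf, grid@dims)
  sweep(sweep(co - 1, 2, grid@spacing, "*"), 2, grid@origin, "+")
}

## directed mean nearest-neighbour distance between two point sets, chunked
.mean_nn_dist <- function(A, B, chunk = 2048L) {
  b2 <- rowSums(B^2)
  total <- 0
  for (start in seq(1, nrow(A), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(A))
    Ac <- A[rows, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), b2, "+") - 2 * tcrossprod(Ac, B)
    mins <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
    total <- total + sum(sqrt(pmax(mins, 0)))
  }
  total / nrow(A)
}

#' Average symmetric surface distance (ASSD)
#'
#' Surfaces are the 6-connected boundary voxels of each mask; distances are
#' Euclidean between surface voxel centres in world mm. ASSD is the mean of
#' the two directed mean nearest-surface distances, symmetric by
#' construction; 0 iff the surfaces coincide.
#'
#' @param a,b [OrganMask-class] objects on the same grid (or logical arrays,
#'   in which case `spacing` applies).
#' @param organ organ name or code.
#' @param spacing voxel spacing in mm when passing bare logical arrays.
#' @return ASSD in mm.
#' @export
assd <- function(a, b, organ = "bowel", spacing = c(1, 1, 1)) {
  if (is(a, "OrganMask") && is(b, "OrganMask") && !sameGrid(a@grid, b@grid))
    stop("masks are on different grids", call. = FALSE)
  wrap <- function(x) {
    if (is(x, "OrganMask")) return(x)
    arr <- array(as.integer(as.array(x) > 0), dim(as.array(x)))
    organMask(arr * .organ_code(organ), imageGrid(dim(arr), spacing = spacing))
  }
  A <- .surface_coords(wrap(a), organ)
  B <- .surface_coords(wrap(b), organ)
  (.mean_nn_dist(A, B) + .mean_nn_dist(B, A)) / 2
}
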