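#' Read and write volumes and masks as NIfTI-1
#'
#' One NIfTI file per scan and one labeled mask file per scan. Spacing is
#' carried in pixdim; the world origin is carried in the xform translation.
#' Scan metadata travels in a CSV sidecar (see [readScanTable()]).
#'
#' @param x an [SUVVolume-class] or [OrganMask-class].
#' @param path file path, `.nii` or `.nii.gz`.
#' @param meta a [ScanMeta-class] to attach on read.
#' @return `readSUVVolume` an [SUVVolume-class]; `readOrganMask` an
#'   [OrganMask-class]; the writers return `path` invisibly.
#' @name nifti-io
NULL

.as_nifti <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  mat <- diag(4)
  diag(mat)[1:3] <- grid@spacing
  mat[1:3, 4] <- grid@origin
  RNifti::`sform<-`(img, structure(mat, code = 2L))
}

.grid_from_nifti <- function(img) {
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3-D NIfTI volume", call. = FALSE)
  x <- RNifti::xform(img)
  imageGrid(d, spacing = abs(diag(x)[1:3]), origin = x[1:3, 4])
}

#' @rdname nifti-io
#' @export
writeSUVVolume <- function(x, path) {
  stopifnot(is(x, "SUVVolume"))
  RNifti::writeNifti(.as_nifti(x@voxels, x@grid), path)
  invisible(path)
}

#' @rdname nifti-io
#' @export
readSUVVolume <- function(path, meta = scanMeta()) {
  img <- RNifti::readNifti(path)
  suvVolume(array(as.numeric(img), dim(img)), .grid_from_nifti(img), meta)
}

#' @rdname nifti-io
#' @export
writeOrganMask <- function(x, path) {
  stopifnot(is(x, "OrganMask"))
  RNifti::writeNifti(.as_nifti(x@labels, x@grid), path, datatype = "int16")
  invisible(path)
}

#' @rdname nifti-io
#' @export
readOrganMask <- function(path) {
  img <- RNifti::readNifti(path)
  organMask(array(as.integer(img), dim(img)), .grid_from_nifti(img))
}

#' Read or write a scan metadata table
#'
#' CSV sidecar with one row per scan: `patient_id`, `scan_day`, `weight_g`,
#' `dose_Bq`, `suv_precomputed` (0/1). When `suv_precomputed` is 1 the volume
#' is taken as already SUV-normalized and weight/dose may be blank.
#'
#' @param path CSV path.
#' @param table data.frame in the sidecar layout.
#' @return `readScanTable` returns a list of [ScanMeta-class] keyed by
#'   `patient_id:scan_day`; `writeScanTable` returns `path` invisibly.
#' @export
readScanTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "scan_day", "weight_g", "dose_Bq", "suv_precomputed")
  if (!all(need %in% names(df)))
    stop("scan table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    scanMeta(df$patient_id[i], df$scan_day[i], df$weight_g[i], df$dose_Bq[i],
             suv_precomputed = df$suv_precomputed[i] != 0))
  names(out) <- paste(df$patient_id, df$scan_day, sep = ":")
  out
}

#' @rdname readScanTable
#' @export
writeScanTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
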