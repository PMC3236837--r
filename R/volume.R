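#' 3-D image volume
#'
#' Lightweight container for a 3-D scalar grid with per-axis voxel spacing
#' (mm) and a physical origin offset (mm). Voxel indices are 1-based; the
#' physical position of voxel \code{(i, j, k)} is
#' \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @param data 3-D numeric array of intensities.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, physical offset in mm.
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  if (any(!is.finite(data)))
    stop("volume intensities must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  cat("  intensity range [", format(min(x$data)), ", ",
      format(max(x$data)), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Binary segmentation mask
#'
#' A binary mask sharing an \code{\link{image_volume}} grid, together with the
#' provenance (parameters) of the segmentation that produced it.
#'
#' @param mask 3-D logical (or 0/1) array of object voxels.
#' @param spacing voxel size in mm per axis.
#' @param origin physical origin in mm.
#' @param provenance named list of parameters recorded for reproducibility.
#' @return An object of class \code{segmentation}.
#' @export
segmentation <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         provenance = list()) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L)
    stop("`mask` must be a 3-D array")
  storage.mode(mask) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)")
  structure(list(mask = mask, spacing = spacing, origin = as.numeric(origin),
                 provenance = provenance),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation> ", paste(dim(x$mask), collapse = " x "),
      " grid, ", sum(x$mask), " object voxels\n", sep = "")
  invisible(x)
}

#' @export
dim.segmentation <- function(x) dim(x$mask)

#' Read a NIfTI volume
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return An \code{\link{image_volume}}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("cannot read volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    img <- array(img, dim = d[1:3])
    d <- d[1:3]
  }
  sp <- RNifti::pixdim(img)[seq_len(min(3L, length(RNifti::pixdim(img))))]
  if (length(sp) < 3L) sp <- c(sp, rep(1, 3L - length(sp)))
  orig <- tryCatch({
    xf <- RNifti::xform(img)
    as.numeric(xf[1:3, 4])
  }, error = function(e) c(0, 0, 0))
  image_volume(array(as.numeric(img), dim = d), spacing = as.numeric(sp),
               origin = orig)
}

#' Write a volume or segmentation as NIfTI
#'
#' Segmentations are written as uint8; volumes keep floating-point intensity.
#'
#' @param x an \code{\link{image_volume}} or \code{\link{segmentation}}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "segmentation")) {
    arr <- array(as.integer(x$mask), dim = dim(x$mask))
    sp <- x$spacing
    datatype <- "uint8"
  } else if (inherits(x, "image_volume")) {
    arr <- x$data
    sp <- x$spacing
    datatype <- "double"
  } else stop("`x` must be an image_volume or segmentation")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Convert voxel indices to physical coordinates
#'
#' @param index integer matrix (n x 3) of 1-based voxel indices, or length-3
#'   vector.
#' @param spacing voxel spacing in mm.
#' @param origin physical origin in mm.
#' @return numeric matrix (n x 3) of mm coordinates.
#' @export
voxel_to_mm <- function(index, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  index <- rbind(index)
  sweep(sweep(index - 1, 2, spacing, "*"), 2, origin, "+")
}

#' Convert physical coordinates to (rounded) voxel indices
#'
#' @param coord numeric matrix (n x 3) of mm coordinates, or length-3 vector.
#' @inheritParams voxel_to_mm
#' @return integer matrix (n x 3) of 1-based voxel indices.
#' @export
mm_to_voxel <- function(coord, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  coord <- rbind(coord)
  idx <- sweep(sweep(coord, 2, origin, "-"), 2, spacing, "/") + 1
  round(idx)
}

# internal: 1-based (x,y,z) matrix -> 0-based linear index
vox_to_lin0 <- function(idx, dm) {
  idx <- rbind(idx)
  (idx[, 1] - 1) + dm[1] * ((idx[, 2] - 1) + dm[2] * (idx[, 3] - 1))
}

# internal: 0-based linear index -> 1-based (x,y,z) matrix
lin0_to_vox <- function(lin, dm) {
  x <- lin %% dm[1]
  r <- lin %/% dm[1]
  y <- r %% dm[2]
  z <- r %/% dm[2]
  cbind(x, y, z) + 1
}
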