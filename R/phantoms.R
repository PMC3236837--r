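#' Parametric centerline
#'
#' An ordered polyline of continuous 3-D positions in voxel units with a
#' strictly increasing arc parameter, used as the ground-truth backbone of a
#' numeric tube phantom.
#'
#' @param points numeric matrix (n x 3), continuous voxel-unit positions.
#' @param arc_parameter strictly increasing numeric vector of length n.
#' @return An object of class \code{parametric_centerline}.
#' @export
parametric_centerline <- function(points, arc_parameter = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("a centerline needs at least 2 points")
  if (ncol(points) != 3L) stop("`points` must be an n x 3 matrix")
  if (is.null(arc_parameter))
    arc_parameter <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  arc_parameter <- as.numeric(arc_parameter)
  if (length(arc_parameter) != nrow(points))
    stop("`arc_parameter` must match the number of points")
  if (any(diff(arc_parameter) <= 0))
    stop("`arc_parameter` must be strictly increasing")
  if (any(rowSums(diff(points)^2) == 0))
    stop("consecutive centerline points must be distinct")
  structure(list(points = points, arc_parameter = arc_parameter),
            class = "parametric_centerline")
}

#' @export
print.parametric_centerline <- function(x, ...) {
  len <- sum(sqrt(rowSums(diff(x$points)^2)))
  cat("<parametric_centerline> ", nrow(x$points), " samples, polyline length ",
      format(len, digits = 6), " voxels\n", sep = "")
  invisible(x)
}

# Shift a set of point matrices into a nonnegative frame with a margin and
# report the enclosing grid dimensions.
frame_centerlines <- function(point_list, tube_radius, margin) {
  all_pts <- do.call(rbind, point_list)
  lo <- apply(all_pts, 2, min)
  hi <- apply(all_pts, 2, max)
  shift <- -(lo) + tube_radius + margin
  dm <- ceiling(hi - lo + 2 * (tube_radius + margin)) + 1
  list(shifted = lapply(point_list, function(p) sweep(p, 2, shift, "+")),
       dim = as.integer(dm))
}

#' Helix centerline
#'
#' Samples the helix \eqn{h(t) = [r\cos t,\; r\sin t,\; p t / (2\pi)]} for
#' \eqn{t \in [0, 2\pi\,\mathrm{turns}]}. The pitch \code{p} is the rise in
#' z per full turn, so a pitch written as \dQuote{5(2\eqn{\pi})} is
#' \code{p = 5 * 2 * pi} and the helix climbs \eqn{p} voxels per coil.
#' Points are returned in the original (possibly negative) frame; the
#' rasterizer translates them into a nonnegative grid.
#'
#' @param radius helix radius r in voxels (> 0).
#' @param pitch rise per turn p in voxels (> 0).
#' @param turns number of full turns (> 0, may be fractional).
#' @param samples_per_turn sampling density (>= 16); the default is chosen so
#'   consecutive samples are well under one voxel apart for r = 100.
#' @return A \code{\link{parametric_centerline}} with \code{arc_parameter} t.
#' @export
helix_centerline <- function(radius, pitch, turns, samples_per_turn = 720) {
  if (radius <= 0 || pitch <= 0 || turns <= 0)
    stop("helix radius, pitch and turns must be positive")
  if (samples_per_turn < 16) stop("`samples_per_turn` must be >= 16")
  n <- max(2L, ceiling(samples_per_turn * turns) + 1L)
  t <- seq(0, 2 * pi * turns, length.out = n)
  pts <- cbind(radius * cos(t), radius * sin(t), pitch * t / (2 * pi))
  # guarantee sub-voxel sample spacing after construction
  step <- max(sqrt(rowSums(diff(pts)^2)))
  if (step >= 1) {
    n <- ceiling(n * step / 0.5)
    t <- seq(0, 2 * pi * turns, length.out = n)
    pts <- cbind(radius * cos(t), radius * sin(t), pitch * t / (2 * pi))
  }
  parametric_centerline(pts, t)
}

#' Comb centerline set
#'
#' A straight spine along x with perpendicular teeth along y, attached at
#' evenly spaced junctions starting at the spine origin (so a spine longer
#' than \code{tooth_spacing * (n_teeth - 1)} keeps a free handle at the far
#' end). Returned as a list of polyline branches sharing junction points.
#'
#' @param spine_length spine length in voxels.
#' @param tooth_length tooth length in voxels.
#' @param n_teeth number of teeth (>= 1).
#' @param tooth_spacing spacing between tooth junctions in voxels.
#' @return A list of class \code{centerline_set}: elements are
#'   \code{parametric_centerline} branches; attribute \code{junctions} holds
#'   the junction coordinates.
#' @export
comb_centerline <- function(spine_length = 100, tooth_length = 40,
                            n_teeth = 5, tooth_spacing = 20) {
  if (n_teeth < 1) stop("`n_teeth` must be >= 1")
  if (n_teeth > 1 && tooth_spacing <= 0)
    stop("`tooth_spacing` must be positive for multiple teeth")
  span <- tooth_spacing * (n_teeth - 1)
  if (span > spine_length)
    stop("teeth span exceeds the spine: tooth_spacing * (n_teeth - 1) must ",
         "be <= spine_length")
  jx <- tooth_spacing * (seq_len(n_teeth) - 1)
  step <- 0.5
  spine_t <- seq(0, spine_length, by = step)
  if (spine_t[length(spine_t)] < spine_length)
    spine_t <- c(spine_t, spine_length)
  branches <- list(
    parametric_centerline(cbind(spine_t, 0, 0), spine_t)
  )
  tooth_t <- seq(0, tooth_length, by = step)
  if (tooth_t[length(tooth_t)] < tooth_length)
    tooth_t <- c(tooth_t, tooth_length)
  for (x in jx)
    branches[[length(branches) + 1L]] <-
      parametric_centerline(cbind(x, tooth_t, 0), tooth_t)
  structure(branches, class = "centerline_set",
            junctions = cbind(jx, 0, 0))
}

#' Y-branching centerline set
#'
#' A trunk along +y splitting at a junction into two arms at symmetric
#' angles in the xy-plane: a minimal three-tube bifurcation used for the
#' noisy branching-phantom series.
#'
#' @param trunk_length trunk length in voxels.
#' @param arm_length arm length in voxels.
#' @param arm_angle half-angle between each arm and the trunk axis, degrees.
#' @return A \code{centerline_set} of three branches meeting at one junction.
#' @export
branching_centerline <- function(trunk_length = 60, arm_length = 50,
                                 arm_angle = 40) {
  if (trunk_length <= 0 || arm_length <= 0)
    stop("trunk and arm lengths must be positive")
  step <- 0.5
  tt <- seq(0, trunk_length, by = step)
  if (tt[length(tt)] < trunk_length) tt <- c(tt, trunk_length)
  ta <- seq(0, arm_length, by = step)
  if (ta[length(ta)] < arm_length) ta <- c(ta, arm_length)
  a <- arm_angle * pi / 180
  junction <- c(0, trunk_length, 0)
  trunk <- cbind(0, tt, 0)
  left <- cbind(junction[1] - sin(a) * ta, junction[2] + cos(a) * ta, 0)
  right <- cbind(junction[1] + sin(a) * ta, junction[2] + cos(a) * ta, 0)
  structure(list(parametric_centerline(trunk, tt),
                 parametric_centerline(left, ta),
                 parametric_centerline(right, ta)),
            class = "centerline_set",
            junctions = rbind(junction))
}

#' Rasterize a tube phantom around centerlines
#'
#' Builds a binary tube mask (all voxels whose centre lies within
#' \code{tube_radius} of any centerline sample), an intensity volume
#' (foreground on the mask, background elsewhere, optional additive i.i.d.
#' Gaussian noise clipped at zero), and the discretized ground-truth
#' centerline (nearest-voxel positions, deduplicated, order-preserving).
#'
#' @param centerlines a \code{parametric_centerline} or a
#'   \code{centerline_set} (list of branches).
#' @param tube_radius tube radius in voxels (>= 1).
#' @param margin empty border in voxels (>= 1).
#' @param foreground,background intensities of object and background voxels.
#' @param noise_sd standard deviation of additive Gaussian noise (intensity
#'   units, >= 0); sampled from the current RNG state, so set a seed for
#'   reproducibility.
#' @param spacing voxel spacing of the phantom grid in mm.
#' @return An object of class \code{phantom}: list with \code{volume}
#'   (\code{image_volume}), \code{mask} (\code{segmentation}), \code{truth}
#'   (m x 3 matrix of 1-based voxel indices per branch, row-bound, with a
#'   \code{branch} attribute), and \code{spec} (generation parameters).
#' @export
rasterize_tube <- function(centerlines, tube_radius, margin = 8,
                           foreground = 200, background = 0, noise_sd = 0,
                           spacing = c(1, 1, 1)) {
  if (tube_radius < 1) stop("`tube_radius` must be >= 1")
  if (margin < 1) stop("`margin` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (inherits(centerlines, "parametric_centerline"))
    centerlines <- structure(list(centerlines), class = "centerline_set")
  point_list <- lapply(centerlines, function(b) b$points)
  fr <- frame_centerlines(point_list, tube_radius, margin)
  dm <- fr$dim
  if (prod(as.numeric(dm)) > 6e8)
    stop("phantom grid of ", paste(dm, collapse = " x "),
         " voxels exceeds the supported size; reduce geometry or margin")
  samples <- do.call(rbind, fr$shifted)
  mask_vec <- cpp_rasterize_tube(dm, samples, tube_radius)
  mask <- array(mask_vec, dim = dm)
  vol <- array(ifelse(mask_vec, foreground, background), dim = dm)
  if (noise_sd > 0) {
    vol <- vol + array(stats::rnorm(prod(dm), 0, noise_sd), dim = dm)
    vol[vol < 0] <- 0
  }
  truth_list <- lapply(fr$shifted, function(p) {
    v <- round(p) + 1  # nearest voxel, 1-based
    keep <- c(TRUE, rowSums(abs(diff(v))) > 0)
    v[keep, , drop = FALSE]
  })
  truth <- do.call(rbind, truth_list)
  branch_id <- rep(seq_along(truth_list), vapply(truth_list, nrow, 1L))
  dimnames(truth) <- list(NULL, c("x", "y", "z"))
  attr(truth, "branch") <- branch_id
  structure(list(
    volume = image_volume(vol, spacing = spacing),
    mask = segmentation(mask, spacing = spacing,
                        provenance = list(source = "rasterize_tube",
                                          tube_radius = tube_radius,
                                          margin = margin,
                                          foreground = foreground,
                                          background = background,
                                          noise_sd = noise_sd)),
    truth = truth,
    spec = list(tube_radius = tube_radius, margin = margin,
                foreground = foreground, background = background,
                noise_sd = noise_sd, spacing = spacing,
                n_branches = length(point_list))
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> grid ", paste(dim(x$mask$mask), collapse = " x "),
      ", ", sum(x$mask$mask), " tube voxels, ", nrow(x$truth),
      " truth centerline voxels, noise sd ", x$spec$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Standard helix phantom
#'
#' Convenience constructor for the validation helices: radius 100 voxels,
#' tube radius 6, pitches quoted in units of \eqn{2\pi} (so
#' \code{pitch_turns = 5} means a rise of \eqn{5 \cdot 2\pi \approx 31.4}
#' voxels per coil) and turn counts 8/4/2/1 chosen to give all four phantoms
#' the same z-extent.
#'
#' @param pitch_turns pitch in multiples of \eqn{2\pi} (5, 10, 20 or 40 for
#'   the standard series; any positive value is accepted).
#' @param radius helix radius in voxels.
#' @param tube_radius tube radius in voxels.
#' @param turns number of coils; the default \code{40 / pitch_turns} gives
#'   the standard series (8/4/2/1 coils for pitches 5/10/20/40) a constant
#'   z-extent of \eqn{80\pi} voxels.
#' @param scale overall geometric scale factor (DFM is scale-invariant, so a
#'   half-scale phantom is a fast smoke version of the same shape).
#' @param ... passed to \code{\link{rasterize_tube}}.
#' @return A \code{phantom}.
#' @export
helix_phantom <- function(pitch_turns, radius = 100, tube_radius = 6,
                          turns = 40 / pitch_turns, scale = 1, ...) {
  cl <- helix_centerline(radius * scale, pitch_turns * 2 * pi * scale, turns)
  rasterize_tube(cl, tube_radius * scale, ...)
}

#' Standard comb phantom
#'
#' @param tube_radius tube radius in voxels (the validation comb uses 3).
#' @inheritParams comb_centerline
#' @param ... passed to \code{\link{rasterize_tube}}.
#' @return A \code{phantom}.
#' @export
comb_phantom <- function(tube_radius = 3, spine_length = 100,
                         tooth_length = 40, n_teeth = 5, tooth_spacing = 20,
                         ...) {
  cl <- comb_centerline(spine_length, tooth_length, n_teeth, tooth_spacing)
  rasterize_tube(cl, tube_radius, ...)
}

#' Standard Y-branching phantom
#'
#' @param noise_sd additive Gaussian noise SD (the validation series uses 10
#'   and 20 against a foreground of 200).
#' @param tube_radius tube radius in voxels.
#' @param ... passed to \code{\link{branching_centerline}} and
#'   \code{\link{rasterize_tube}}.
#' @return A \code{phantom}.
#' @export
branching_phantom <- function(noise_sd = 10, tube_radius = 4, ...) {
  cl <- branching_centerline(...)
  rasterize_tube(cl, tube_radius, noise_sd = noise_sd)
}

#' Write a phantom to disk
#'
#' Writes the intensity volume and mask as NIfTI, the ground-truth centerline
#' as a 3-column CSV of 1-based voxel indices, and a JSON sidecar echoing the
#' generation parameters.
#'
#' @param phantom a \code{phantom}.
#' @param dir output directory (created if missing).
#' @param name file-name stem.
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir, name = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$volume, file.path(dir, paste0(name, ".nii.gz")))
  write_volume(phantom$mask, file.path(dir, paste0(name, "_mask.nii.gz")))
  utils::write.csv(as.data.frame(phantom$truth),
                   file.path(dir, paste0(name, "_truth.csv")),
                   row.names = FALSE)
  jsonlite::write_json(phantom$spec,
                       file.path(dir, paste0(name, "_spec.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
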