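#' Z-buffer seed detection
#'
#' Casts a ray along z through every (x, y) column of the volume and records
#' the position of the brightest voxel. The resulting 3-D point cloud is
#' clustered by single-linkage proximity; clusters with at least
#' \code{min_cluster} members become region-growing seeds. Bright, spatially
#' coherent structures (vessels) produce large clusters, while background
#' noise maxima scatter in z and are rejected.
#'
#' @param vol an \code{\link{image_volume}}.
#' @param cluster_radius link distance between cluster members in voxels;
#'   the default \code{sqrt(3)} connects 26-neighbouring maxima.
#' @param min_cluster minimum cluster size for a seed cluster.
#' @return An object of class \code{seed_set}: list with \code{seeds}
#'   (n x 3 matrix of 1-based voxel indices) and \code{intensities}.
#' @export
zbs_detect_seeds <- function(vol, cluster_radius = sqrt(3), min_cluster = 5) {
  if (!inherits(vol, "image_volume")) stop("`vol` must be an image_volume")
  d <- dim(vol$data)
  flat <- matrix(vol$data, nrow = d[1] * d[2], ncol = d[3])
  zmax <- max.col(flat, ties.method = "first")
  inten <- flat[cbind(seq_len(nrow(flat)), zmax)]
  if (max(inten) <= min(vol$data))
    stop("no seeds: volume is constant along every column")
  xy <- arrayInd(seq_len(d[1] * d[2]), d[1:2])
  # drop uninformative columns first: a column whose maximum equals the
  # global intensity floor carries no brightest-voxel information (its
  # argmax is an arbitrary tie), and in noise-free volumes such columns
  # would form a large spurious cluster in the z = 1 plane
  informative <- inten > min(vol$data)
  pts <- cbind(xy[informative, 1], xy[informative, 2], zmax[informative])
  inten <- inten[informative]
  lab <- cpp_cluster_points(pts - 1, cluster_radius)
  sizes <- tabulate(lab)
  keep <- sizes[lab] >= min_cluster
  if (!any(keep))
    stop("no seeds: no bright cluster of size >= ", min_cluster, " found")
  seeds <- pts[keep, , drop = FALSE]
  dimnames(seeds) <- list(NULL, c("x", "y", "z"))
  structure(list(seeds = seeds, intensities = inten[keep]),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("<seed_set> ", nrow(x$seeds), " seeds, intensity range [",
      format(min(x$intensities)), ", ", format(max(x$intensities)), "]\n",
      sep = "")
  invisible(x)
}

#' Percentile-threshold region growing
#'
#' Thresholds at the stated percentile of the seed intensities (linear
#' interpolation between order statistics) and returns the union of
#' 26-connected components reachable from the seeds through voxels at or
#' above the threshold.
#'
#' @param vol an \code{\link{image_volume}}.
#' @param seeds a \code{\link{zbs_detect_seeds}} result.
#' @param percentile percentile (0-100) of seed intensities used as the
#'   growth threshold.
#' @return A \code{\link{segmentation}} with the threshold recorded in its
#'   provenance.
#' @export
grow_region <- function(vol, seeds, percentile = 20) {
  if (!inherits(seeds, "seed_set")) stop("`seeds` must be a seed_set")
  if (nrow(seeds$seeds) == 0L) stop("empty seed set")
  tau <- as.numeric(stats::quantile(seeds$intensities, percentile / 100,
                                    type = 7))
  d <- dim(vol$data)
  lin0 <- vox_to_lin0(seeds$seeds, d)
  mask_vec <- cpp_region_grow(vol$data, d, as.integer(lin0), tau)
  if (!any(mask_vec))
    stop("region growing produced an empty mask (threshold ", format(tau),
         ")")
  segmentation(array(mask_vec, dim = d), spacing = vol$spacing,
               origin = vol$origin,
               provenance = list(stage = "grow_region", threshold = tau,
                                 percentile = percentile,
                                 n_seeds = nrow(seeds$seeds),
                                 connectivity = 26))
}

#' Fill enclosed bubbles
#'
#' Relabels as object every background connected component (6-connectivity)
#' that does not touch the volume boundary — cavities caused by slow or
#' recirculating blood inside vessels.
#'
#' @param seg a \code{\link{segmentation}}.
#' @return A \code{segmentation} with cavities filled.
#' @export
fill_bubbles <- function(seg) {
  if (!inherits(seg, "segmentation")) stop("`seg` must be a segmentation")
  d <- dim(seg$mask)
  bg <- !seg$mask
  lab <- array(cpp_label_components(bg, d, 6L), dim = d)
  if (max(lab) > 0L) {
    border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                       lab[, , 1], lab[, , d[3]]))
    border <- border[border > 0L]
    enclosed <- lab > 0L & !(lab %in% border)
    mask <- seg$mask | enclosed
  } else mask <- seg$mask
  segmentation(mask, spacing = seg$spacing, origin = seg$origin,
               provenance = c(seg$provenance, list(bubbles_filled = TRUE)))
}

#' Directional hole filling
#'
#' Iteratively fills small holes at the segmentation edge: a background voxel
#' becomes object when rays cast along the 26 discrete neighbour directions
#' meet an object voxel within \code{ray_span} steps in at least
#' \code{directions_required} directions. Rays step along exact integer
#' neighbour offsets, the starting offset counting as step 1; each iteration
#' is a synchronous sweep over the updated mask.
#'
#' @param seg a \code{\link{segmentation}}.
#' @param iterations number of sweeps (default 3).
#' @param ray_span maximum steps per ray (default 8).
#' @param directions_required hits required to fill (default 24, max 26).
#' @return A \code{segmentation} with edge holes filled.
#' @export
fill_edge_holes <- function(seg, iterations = 3, ray_span = 8,
                            directions_required = 24) {
  if (!inherits(seg, "segmentation")) stop("`seg` must be a segmentation")
  if (directions_required > 26) stop("`directions_required` must be <= 26")
  d <- dim(seg$mask)
  out <- cpp_fill_edge_holes(seg$mask, d, as.integer(iterations),
                             as.integer(ray_span),
                             as.integer(directions_required))
  segmentation(array(out, dim = d), spacing = seg$spacing,
               origin = seg$origin,
               provenance = c(seg$provenance,
                              list(hole_fill = list(
                                iterations = iterations,
                                ray_span = ray_span,
                                directions_required = directions_required))))
}

#' Z-buffer segmentation pipeline
#'
#' Full ZBS composition: seed detection by z-ray casting, percentile-
#' threshold region growing, bubble filling, directional edge-hole filling,
#' and a final bubble-filling pass.
#'
#' @param vol an \code{\link{image_volume}}.
#' @param percentile growth threshold percentile of seed intensities.
#' @param cluster_radius,min_cluster seed clustering parameters
#'   (\code{\link{zbs_detect_seeds}}).
#' @param iterations,ray_span,directions_required hole-filling parameters
#'   (\code{\link{fill_edge_holes}}).
#' @return A \code{\link{segmentation}} whose provenance records every stage
#'   parameter.
#' @export
zbs_segment <- function(vol, percentile = 20, cluster_radius = sqrt(3),
                        min_cluster = 5, iterations = 3, ray_span = 8,
                        directions_required = 24) {
  stage <- "seed detection"
  seg <- tryCatch({
    seeds <- zbs_detect_seeds(vol, cluster_radius, min_cluster)
    stage <- "region growing"
    seg <- grow_region(vol, seeds, percentile)
    stage <- "bubble filling"
    seg <- fill_bubbles(seg)
    stage <- "edge-hole filling"
    seg <- fill_edge_holes(seg, iterations, ray_span, directions_required)
    stage <- "final bubble filling"
    fill_bubbles(seg)
  }, error = function(e) {
    stop("zbs_segment failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  seg$provenance$pipeline <- "zbs_segment"
  seg
}
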