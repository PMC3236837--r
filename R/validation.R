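#' Centerline accuracy (RMSE against ground truth)
#'
#' Root-mean-square, over the computed centerline voxels, of the Euclidean
#' distance from each computed voxel to the nearest ground-truth centerline
#' voxel (in voxel units). The direction is computed-to-truth: the truth is
#' densely sampled, so every computed voxel has a meaningful nearest truth
#' point, while the converse would penalize deliberate pruning.
#'
#' @param computed n x 3 matrix of voxel indices, a
#'   \code{\link{centerline_path}}, or a \code{\link{centerline_tree}}
#'   (branches are row-bound).
#' @param truth m x 3 matrix of ground-truth centerline voxel indices.
#' @return RMSE in voxels.
#' @export
centerline_rmse <- function(computed, truth) {
  computed <- centerline_points(computed)
  truth <- rbind(truth)[, 1:3, drop = FALSE]
  if (nrow(computed) == 0L || nrow(truth) == 0L)
    stop("empty centerline input")
  dd <- cpp_min_dists(computed * 1.0, truth * 1.0)
  sqrt(mean(dd^2))
}

# normalize the accepted centerline representations to a voxel matrix
centerline_points <- function(x) {
  if (inherits(x, "centerline_tree"))
    x <- do.call(rbind, x$branches)
  else if (inherits(x, "centerline_path"))
    x <- x$points
  m <- rbind(x)[, 1:3, drop = FALSE]
  storage.mode(m) <- "double"
  unique(m)
}

#' Centerline stability across goal choices
#'
#' Mean over all run pairs of the symmetric fraction of centerline voxels in
#' one run lying within \code{tolerance} voxels of the other run — a
#' tolerance-relaxed Dice-style overlap in [0, 1]. Identical runs score 1;
#' disjoint, far-apart runs score 0.
#'
#' @param runs list (length >= 2) of centerline voxel matrices, paths or
#'   trees.
#' @param tolerance matching distance in voxels (default 1).
#' @return Stability in [0, 1].
#' @export
centerline_stability <- function(runs, tolerance = 1) {
  if (length(runs) < 2L) stop("stability requires at least 2 runs")
  pts <- lapply(runs, centerline_points)
  pairs <- utils::combn(length(pts), 2)
  vals <- apply(pairs, 2, function(ij) {
    a <- pts[[ij[1]]]; b <- pts[[ij[2]]]
    fa <- mean(cpp_min_dists(a, b) <= tolerance)
    fb <- mean(cpp_min_dists(b, a) <= tolerance)
    (fa + fb) / 2
  })
  mean(vals)
}

#' Validate a centerline algorithm on a phantom
#'
#' Runs tree extraction from several distinct goal nodes (the canonical
#' automatic goal plus goals sampled deterministically from high-DFE voxels)
#' and reports the modal tree count, the stability across the runs, and the
#' RMSE of the canonical run against the phantom's ground truth.
#'
#' @param phantom a \code{\link{rasterize_tube}} phantom (with truth).
#' @param method cost method (\code{"dfe_com"}, \code{"com"},
#'   \code{"mdfe"}).
#' @param n_goals number of goal nodes (>= 1); stability needs >= 2.
#' @param seed integer seed for the deterministic goal sampling.
#' @param tolerance stability matching distance in voxels.
#' @return A list of class \code{validation_report}: \code{algorithm},
#'   \code{n_trees} (modal count), \code{stability} (NA when n_goals < 2),
#'   \code{rmse} (voxels), and the per-run tree counts.
#' @export
validate_algorithm <- function(phantom, method = "dfe_com", n_goals = 5,
                               seed = 1, tolerance = 1) {
  stopifnot(inherits(phantom, "phantom"))
  cost <- compute_cost(phantom$mask, method)
  dfe <- compute_dfe(phantom$mask)
  auto_goal <- select_goal(cost)
  goals <- list(auto_goal)
  if (n_goals > 1) {
    d <- dim(phantom$mask$mask)
    high <- which(dfe >= 0.8 * max(dfe))
    set.seed(seed)
    extra <- sample(high, min(n_goals - 1, length(high)))
    for (g in extra) goals[[length(goals) + 1L]] <-
      as.integer(lin0_to_vox(g - 1, d)[1, ])
  }
  runs <- lapply(goals, function(g) extract_tree(cost, goal = g))
  counts <- vapply(runs, function(r) r$n_trees, 1L)
  n_trees <- as.integer(names(sort(-table(counts)))[1])
  stability <- if (length(runs) >= 2)
    centerline_stability(runs, tolerance) else NA_real_
  rmse <- centerline_rmse(runs[[1]], phantom$truth)
  structure(list(algorithm = method, n_trees = n_trees,
                 stability = stability, rmse = rmse,
                 tree_counts = counts, goals = goals),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> algorithm ", x$algorithm, "\n", sep = "")
  cat("  number of trees: ", x$n_trees, " (runs: ",
      paste(x$tree_counts, collapse = ", "), ")\n", sep = "")
  cat("  stability:       ",
      if (is.na(x$stability)) "n/a (single goal)" else
        format(x$stability, digits = 4), "\n", sep = "")
  cat("  RMSE of accuracy: ", format(x$rmse, digits = 4), " voxels\n",
      sep = "")
  invisible(x)
}
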