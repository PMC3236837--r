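#' Select the Dijkstra goal node
#'
#' The \code{min_cost_central} strategy returns the object voxel with
#' minimal cost, breaking ties first by proximity to the mask centroid and
#' then by lexicographic (linear index) order; the \code{user} strategy
#' validates a supplied voxel index against the mask. Automatic selection is
#' restricted to the largest 26-connected component of the mask, so isolated
#' speckle that survived segmentation cannot become the tree root.
#'
#' @param cost a \code{\link{cost_field}}.
#' @param strategy \code{"min_cost_central"} or \code{"user"}.
#' @param index 1-based voxel index (x, y, z) for the \code{user} strategy.
#' @return Integer vector (x, y, z), 1-based.
#' @export
select_goal <- function(cost, strategy = c("min_cost_central", "user"),
                        index = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(cost, "cost_field"))
  d <- dim(cost$values)
  if (strategy == "user") {
    if (is.null(index)) stop("`index` required for the user strategy")
    index <- as.integer(index)
    if (length(index) != 3L || any(index < 1L) || any(index > d))
      stop("goal index outside the volume grid")
    if (!cost$mask$mask[index[1], index[2], index[3]])
      stop("user-supplied goal voxel is outside the segmentation mask")
    return(index)
  }
  lab <- cpp_label_components(cost$mask$mask, d, 26L)
  main <- which.max(tabulate(lab[lab > 0L]))
  v <- cost$values
  v[lab != main] <- NA
  mn <- min(v, na.rm = TRUE)
  cand <- which(v == mn)
  if (length(cand) > 1L) {
    vox <- lin0_to_vox(cand - 1, d)
    centroid <- colMeans(lin0_to_vox(which(lab == main) - 1, d))
    d2 <- rowSums(sweep(vox, 2, centroid, "-")^2)
    cand <- cand[order(d2, cand)][1]
  }
  as.integer(lin0_to_vox(cand - 1, d)[1, ])
}

#' Single-source lowest-cost paths over the object-voxel graph
#'
#' Runs Dijkstra's algorithm from the goal over the 26-connected graph of
#' mask voxels. The weight of the edge between two voxels is the mean of
#' their costs times the physical step length in mm, so accumulated cost is
#' spacing-aware and symmetric in the endpoints. Ties in the priority queue
#' are broken by insertion order, making the result deterministic.
#'
#' @param cost a \code{\link{cost_field}}.
#' @param goal 1-based voxel index (x, y, z); must lie in the mask.
#' @return An object of class \code{dijkstra_result}: arrays \code{dist}
#'   (accumulated cost; \code{Inf} = unreachable, \code{NA} = background),
#'   \code{parent} (0-based linear index of the predecessor toward the goal,
#'   -1 = none) and \code{pathlen} (physical path length in mm), plus the
#'   goal and grid metadata.
#' @export
dijkstra_costs <- function(cost, goal) {
  stopifnot(inherits(cost, "cost_field"))
  d <- dim(cost$values)
  goal <- as.integer(goal)
  if (!cost$mask$mask[goal[1], goal[2], goal[3]])
    stop("goal voxel is outside the mask")
  vals <- cost$values
  vals[is.na(vals)] <- 0
  res <- cpp_dijkstra(as.numeric(vals), cost$mask$mask, d,
                      cost$mask$spacing, as.integer(vox_to_lin0(goal, d)))
  structure(list(dist = array(res$dist, dim = d),
                 parent = array(res$parent, dim = d),
                 pathlen = array(res$pathlen, dim = d),
                 goal = goal, dim = d, spacing = cost$mask$spacing,
                 origin = cost$mask$origin),
            class = "dijkstra_result")
}

# Follow parent pointers from a 0-based linear index until the goal (or a
# claimed voxel); returns the 0-based linear chain including the terminal.
trace_chain <- function(parent_vec, from0, claimed = NULL) {
  chain <- integer(0)
  cur <- from0
  repeat {
    chain <- c(chain, cur)
    if (!is.null(claimed) && claimed[cur + 1]) break
    nxt <- parent_vec[cur + 1]
    if (nxt < 0L) break
    cur <- nxt
  }
  chain
}

#' Ordered path between two voxels
#'
#' Lowest-cost path between two user-chosen endpoints: Dijkstra from
#' \code{start}, parent chain traced back from \code{end}. Cumulative
#' physical length along the path is returned per point.
#'
#' @param cost a \code{\link{cost_field}}.
#' @param start,end 1-based voxel indices (x, y, z); both must lie in the
#'   mask.
#' @return An object of class \code{centerline_path}: \code{points} (n x 3
#'   1-based voxel indices ordered start to end), \code{coords} (n x 3 mm),
#'   \code{cumulative_length} (mm, starting at 0).
#' @export
path_between <- function(cost, start, end) {
  stopifnot(inherits(cost, "cost_field"))
  d <- dim(cost$values)
  start <- as.integer(start); end <- as.integer(end)
  for (p in list(start, end))
    if (!cost$mask$mask[p[1], p[2], p[3]])
      stop("path endpoint outside the mask")
  dij <- dijkstra_costs(cost, start)
  end0 <- as.integer(vox_to_lin0(end, d))
  if (!is.finite(dij$dist[end0 + 1]))
    stop("endpoints are not connected within the mask")
  chain0 <- trace_chain(as.integer(dij$parent), end0)
  chain0 <- rev(chain0)  # start -> end
  pts <- lin0_to_vox(chain0, d)
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  coords <- voxel_to_mm(pts, dij$spacing, dij$origin)
  cum <- dij$pathlen[chain0 + 1]
  centerline_path(pts, coords, cum)
}

#' Centerline path container
#'
#' @param points n x 3 matrix of 1-based voxel indices (consecutive rows
#'   26-connected).
#' @param coords n x 3 matrix of physical coordinates (mm).
#' @param cumulative_length length-n nonnegative vector (mm), starting at 0
#'   and strictly increasing.
#' @return An object of class \code{centerline_path}.
#' @export
centerline_path <- function(points, coords, cumulative_length) {
  points <- rbind(points)
  coords <- rbind(coords)
  cumulative_length <- as.numeric(cumulative_length)
  if (nrow(points) != nrow(coords) ||
      nrow(points) != length(cumulative_length))
    stop("points, coords and cumulative_length must agree in length")
  if (cumulative_length[1] != 0)
    stop("cumulative_length must start at 0")
  if (length(cumulative_length) > 1 && any(diff(cumulative_length) <= 0))
    stop("cumulative_length must be strictly increasing")
  structure(list(points = points, coords = coords,
                 cumulative_length = cumulative_length),
            class = "centerline_path")
}

#' @export
print.centerline_path <- function(x, ...) {
  cat("<centerline_path> ", nrow(x$points), " voxels, length ",
      format(max(x$cumulative_length), digits = 6), " mm\n", sep = "")
  invisible(x)
}

#' Extract the centerline tree
#'
#' The longest lowest-cost paths from the distal ends of the object back to
#' the goal are the centerlines. Branches are emitted iteratively: the
#' unclaimed voxel with the greatest physical path length to the goal is the
#' next distal tip; its parent chain is traced to the first already-claimed
#' voxel (or the goal) and emitted, and a tube of local-DFE radius around
#' the emitted path is claimed so each artery yields a single branch.
#' Candidate branches shorter than the pruning threshold (by default
#' \code{prune_factor} times the DFE at the tip — surface whiskers) are
#' discarded. Emission stops when every remaining candidate is below
#' threshold. The local vessel radius entering the pruning threshold is the
#' largest DFE along the candidate branch, since the tip voxel itself lies
#' on the cap surface where the DFE is near 1 for vessels of any width.
#'
#' @param cost a \code{\link{cost_field}}.
#' @param goal 1-based voxel index; defaults to
#'   \code{\link{select_goal}(cost)}.
#' @param min_branch_length fixed pruning threshold in mm; overrides the
#'   adaptive \code{prune_factor * DFE(tip)} rule when given.
#' @param prune_factor multiplier of the tip DFE for the adaptive pruning
#'   threshold (default 3).
#' @param claim_factor multiplier of the local DFE for the claimed radius
#'   around emitted branches (default 1).
#' @return An object of class \code{centerline_tree}: \code{goal},
#'   \code{branches} (list of n x 3 matrices of 1-based voxel indices,
#'   ordered tip to junction/goal), \code{branch_lengths} (mm),
#'   \code{n_trees}, and the underlying \code{dijkstra_result}.
#' @export
extract_tree <- function(cost, goal = NULL, min_branch_length = NULL,
                         prune_factor = 3, claim_factor = 1) {
  stopifnot(inherits(cost, "cost_field"))
  if (!any(cost$mask$mask)) stop("empty mask")
  if (is.null(goal)) goal <- select_goal(cost)
  d <- dim(cost$values)
  dij <- dijkstra_costs(cost, goal)
  dfe <- compute_dfe(cost$mask)
  vox_scale <- min(cost$mask$spacing)
  plen <- as.numeric(dij$pathlen)
  parent <- as.integer(dij$parent)
  reach <- which(is.finite(plen))  # 1-based linear
  ord <- reach[order(-plen[reach], reach)]
  claimed <- logical(prod(d))
  branches <- list()
  lengths <- numeric(0)
  for (lin1 in ord) {
    if (claimed[lin1]) next
    tip0 <- lin1 - 1L
    chain0 <- trace_chain(parent, tip0, claimed)
    blen <- plen[lin1] - plen[chain0[length(chain0)] + 1]
    # Local vessel radius for pruning: the largest DFE along the candidate
    # branch and a few parent steps beyond its attachment point. The tip
    # voxel itself sits on the cap surface (DFE ~ 1 for vessels of any
    # width), and a surface whisker attaches near the wall of its parent
    # vessel, so the radius is read from the parent core instead.
    thr <- if (!is.null(min_branch_length)) min_branch_length else {
      ext <- integer(0)
      cur <- parent[chain0[length(chain0)] + 1]
      k <- 0L
      while (cur >= 0L && k < 8L) {
        ext <- c(ext, cur)
        cur <- parent[cur + 1]
        k <- k + 1L
      }
      prune_factor * max(dfe[c(chain0, ext) + 1])
    }
    if (blen < thr) next
    pts <- lin0_to_vox(chain0, d)
    dimnames(pts) <- list(NULL, c("x", "y", "z"))
    branches[[length(branches) + 1L]] <- pts
    lengths <- c(lengths, blen)
    radii <- pmax(claim_factor * dfe[chain0 + 1] / vox_scale, 1)
    claimed <- cpp_claim_balls(claimed, d, pts - 1L, radii)
  }
  structure(list(goal = goal, branches = branches,
                 branch_lengths = lengths, n_trees = length(branches),
                 dijkstra = dij, method = cost$method),
            class = "centerline_tree")
}

#' @export
print.centerline_tree <- function(x, ...) {
  cat("<centerline_tree> ", x$n_trees, " branches (method ", x$method,
      "), goal at (", paste(x$goal, collapse = ", "), ")\n", sep = "")
  if (x$n_trees > 0)
    cat("  branch lengths (mm): ",
        paste(format(x$branch_lengths, digits = 4), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Convert a tree branch to a centerline path
#'
#' @param tree a \code{\link{centerline_tree}}.
#' @param branch branch number (1 = longest-path branch emitted first).
#' @return A \code{\link{centerline_path}} ordered tip to junction/goal.
#' @export
tree_branch_path <- function(tree, branch = 1) {
  stopifnot(inherits(tree, "centerline_tree"))
  if (branch < 1 || branch > tree$n_trees) stop("no such branch")
  pts <- tree$branches[[branch]]
  coords <- voxel_to_mm(pts, tree$dijkstra$spacing, tree$dijkstra$origin)
  seglen <- sqrt(rowSums(diff(coords)^2))
  centerline_path(pts, coords, c(0, cumsum(seglen)))
}

#' Serialize a centerline tree to JSON
#'
#' Per-branch 1-based voxel lists with physical lengths, suitable for
#' downstream tools.
#'
#' @param tree a \code{\link{centerline_tree}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tree <- function(tree, path) {
  obj <- list(goal = tree$goal, method = tree$method,
              n_trees = tree$n_trees,
              branch_lengths_mm = tree$branch_lengths,
              branches = lapply(tree$branches, function(b)
                unname(as.data.frame(b))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
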