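# Shared fixture builders: all fixtures are generated in code at test time.

dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# solid axis-aligned cylinder mask along `axis` with given radius/length,
# centred in a grid with a border margin
cylinder_mask <- function(radius = 4, length = 30, axis = 3, margin = 3) {
  r <- ceiling(radius)
  side <- 2 * (r + margin) + 1
  dm <- rep(side, 3)
  dm[axis] <- length + 2 * margin
  m <- array(FALSE, dm)
  ctr <- (side + 1) / 2
  perp <- setdiff(1:3, axis)
  idx <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                               z = seq_len(dm[3])))
  inside <- (idx[, perp[1]] - ctr)^2 + (idx[, perp[2]] - ctr)^2 <= radius^2 &
    idx[, axis] > margin & idx[, axis] <= margin + length
  m[idx[inside, , drop = FALSE]] <- TRUE
  m
}

# digital ball mask of radius R centred in a cube (side overridable so
# balls of different radii can share one grid)
ball_mask <- function(R, margin = 2, side = 2 * (R + margin) + 1) {
  ctr <- (side + 1) / 2
  idx <- as.matrix(expand.grid(seq_len(side), seq_len(side), seq_len(side)))
  m <- array(FALSE, rep(side, 3))
  inside <- rowSums(sweep(idx, 2, ctr)^2) <= R^2
  m[idx[inside, , drop = FALSE]] <- TRUE
  m
}

# centerline_path from raw mm coordinates (1 mm spacing voxel grid implied)
make_path <- function(coords) {
  coords <- as.matrix(coords)
  seglen <- sqrt(rowSums(diff(coords)^2))
  centerline_path(points = round(coords) + 1, coords = coords,
                  cumulative_length = c(0, cumsum(seglen)))
}

# brute-force R oracle: min Euclidean distance from each row of a to rows of b
oracle_min_dists <- function(a, b) {
  apply(a, 1, function(p) sqrt(min(colSums((t(b) - p)^2))))
}

# brute-force Bellman-Ford over the 26-connected object-voxel graph with
# edge weight = mean endpoint cost * physical step length
oracle_bellman_ford <- function(values, mask, spacing, goal) {
  dm <- dim(mask)
  nodes <- which(mask)
  vox <- arrayInd(nodes, dm)
  id <- setNames(seq_along(nodes), nodes)
  # edge list
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  edges <- NULL
  for (k in seq_len(nrow(off))) {
    nb <- sweep(vox, 2, off[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    lin <- nb[ok, 1] + dm[1] * (nb[ok, 2] - 1) + dm[1] * dm[2] * (nb[ok, 3] - 1)
    inmask <- mask[lin]
    if (!any(inmask)) next
    from <- which(ok)[inmask]
    to <- id[as.character(lin[inmask])]
    w <- 0.5 * (values[nodes[from]] + values[nodes[to]]) *
      sqrt(sum((off[k, ] * spacing)^2))
    edges <- rbind(edges, cbind(from, to, w))
  }
  dist <- rep(Inf, length(nodes))
  g <- goal[1] + dm[1] * (goal[2] - 1) + dm[1] * dm[2] * (goal[3] - 1)
  dist[id[as.character(g)]] <- 0
  for (iter in seq_along(nodes)) {
    nd <- pmin(dist, tapply(dist[edges[, 1]] + edges[, 3], edges[, 2], min)[
      as.character(seq_along(nodes))], na.rm = TRUE)
    if (isTRUE(all.equal(nd, dist, tolerance = 0))) break
    dist <- nd
  }
  out <- array(NA_real_, dm)
  out[nodes] <- dist
  out
}

# explicit ray census oracle for directional hole filling: number of the 26
# neighbour directions in which an object voxel occurs within `span` steps
oracle_ray_census <- function(mask, at, span = 8) {
  dm <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  hits <- 0L
  for (k in seq_len(nrow(off))) {
    p <- at
    for (s in seq_len(span)) {
      p <- p + off[k, ]
      if (any(p < 1) || any(p > dm)) break
      if (mask[p[1], p[2], p[3]]) { hits <- hits + 1L; break }
    }
  }
  hits
}
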