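test_that("goal selection finds the centre of symmetric objects and
           validates user goals", {
  b <- ball_mask(5)
  seg <- segmentation(b)
  cf <- compute_com_cost(seg)
  g <- select_goal(cf)
  ctr <- (dim(b) + 1) / 2
  expect_lte(sqrt(sum((g - ctr)^2)), 1)
  expect_equal(select_goal(cf, "user", index = g), g)
  expect_error(select_goal(cf, "user", index = c(1, 1, 1)),
               "outside the segmentation")
  # on the comb, the automatic DFE-COM goal sits on the true centerline
  ph <- comb_phantom()
  cfc <- compute_cost(ph$mask, "dfe_com")
  gc_ <- select_goal(cfc)
  expect_lte(min(oracle_min_dists(rbind(gc_), ph$truth)), 1.5)
})

test_that("Dijkstra on a uniform-cost line accumulates monotonically along
           the parent chain and flags disconnected components", {
  m <- array(FALSE, c(12, 5, 5))
  m[2:11, 3, 3] <- TRUE
  m[1, 1, 1] <- TRUE  # disconnected voxel (no 26-neighbour in the line)
  seg <- segmentation(m)
  vals <- array(NA_real_, dim(m)); vals[m] <- 1
  cf <- cost_field(vals, seg, "COM")
  dij <- dijkstra_costs(cf, c(2, 3, 3))
  line_d <- dij$dist[2:11, 3, 3]
  expect_true(all(diff(line_d) > 0))
  expect_equal(line_d, 0:9)  # unit cost x unit steps
  expect_true(is.infinite(dij$dist[1, 1, 1]))
  expect_true(is.na(dij$dist[1, 5, 5]))  # background
  # parent chain walks straight down the line
  p <- vesseltort:::trace_chain(as.integer(dij$parent),
                                vesseltort:::vox_to_lin0(c(11, 3, 3),
                                                         dim(m)))
  expect_equal(length(p), 10L)
})

test_that("Dijkstra accumulated costs match a brute-force Bellman-Ford
           oracle exactly on small random graphs", {
  set.seed(17)
  for (rep in 1:3) {
    m <- array(runif(6 * 6 * 5) < 0.6, c(6, 6, 5))
    m[3, 3, 3] <- TRUE
    expect_lte(sum(m), 200)
    seg <- segmentation(m, spacing = c(1, 1, 1.5))
    vals <- array(NA_real_, dim(m))
    vals[m] <- runif(sum(m), 0.1, 5)
    cf <- cost_field(vals, seg, "COM")
    dij <- dijkstra_costs(cf, c(3, 3, 3))
    oracle <- oracle_bellman_ford(vals, m, c(1, 1, 1.5), c(3, 3, 3))
    expect_equal(dij$dist[m], oracle[m], tolerance = 1e-12)
  }
})

test_that("tree extraction yields one branch per distal tip: 1 for a
           cylinder, 6 for the comb, 3 for the Y phantom", {
  m <- cylinder_mask(radius = 3, length = 30, axis = 3)
  seg <- segmentation(m)
  cf <- compute_cost(seg, "dfe_com")
  ctr <- (dim(m)[1] + 1) / 2
  tr <- extract_tree(cf, goal = c(ctr, ctr, 4))
  expect_equal(tr$n_trees, 1L)
  ph <- comb_phantom()
  trc <- extract_tree(compute_cost(ph$mask, "dfe_com"))
  expect_equal(trc$n_trees, 6L)
  phy <- branching_phantom(noise_sd = 0)
  try_ <- extract_tree(compute_cost(phy$mask, "dfe_com"))
  expect_equal(try_$n_trees, 3L)
  # every branch is a simple path
  for (b in trc$branches)
    expect_equal(anyDuplicated(b), 0L)
  # branch paths are 26-connected walks
  for (b in trc$branches)
    expect_true(all(apply(abs(diff(b)), 1, max) <= 1))
})

test_that("paths between endpoints track tube length", {
  m <- cylinder_mask(radius = 3, length = 40, axis = 1)
  seg <- segmentation(m)
  cf <- compute_cost(seg, "dfe_com")
  ctr <- (dim(m)[2] + 1) / 2
  p <- path_between(cf, c(4, ctr, ctr), c(43, ctr, ctr))
  euclid <- 39
  expect_lt(abs(max(p$cumulative_length) - euclid) / euclid, 0.05)
  # degenerate path: start = end
  p0 <- path_between(cf, c(10, ctr, ctr), c(10, ctr, ctr))
  expect_equal(nrow(p0$points), 1L)
  expect_equal(p0$cumulative_length, 0)
  # unreachable pair reported
  m2 <- m
  m2[20, , ] <- FALSE
  seg2 <- segmentation(m2)
  cf2 <- compute_cost(seg2, "dfe_com")
  expect_error(path_between(cf2, c(4, ctr, ctr), c(43, ctr, ctr)),
               "not connected")
})

test_that("the extracted helix path length stays close to the continuous
           arc length", {
  # digital 26-connected chains systematically overestimate a smooth curve's
  # length; the tolerance reflects that known metrication bias
  ph <- helix_phantom(40, scale = 0.5)
  cf <- compute_cost(ph$mask, "dfe_com")
  p <- path_between(cf, ph$truth[1, ], ph$truth[nrow(ph$truth), ])
  arc <- 2 * pi * sqrt(50^2 + 20^2)  # quadrature oracle, constant speed
  expect_lt(abs(max(p$cumulative_length) - arc) / arc, 0.15)
  expect_gt(max(p$cumulative_length), arc * 0.98)
})
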