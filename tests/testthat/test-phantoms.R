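test_that("helix centerline follows h(t) = [r cos t, r sin t, p t / (2 pi)]", {
  cl <- helix_centerline(100, 40 * 2 * pi, turns = 1, samples_per_turn = 720)
  expect_equal(cl$points[1, ], c(100, 0, 0), tolerance = 1e-12)
  expect_equal(cl$points[nrow(cl$points), ], c(100, 0, 40 * 2 * pi),
               tolerance = 1e-8)
  # pitch 5(2pi), 8 turns: total z-extent 5 * 16 * pi
  cl8 <- helix_centerline(100, 5 * 2 * pi, turns = 8)
  expect_equal(max(cl8$points[, 3]), 5 * 16 * pi, tolerance = 1e-8)
  # consecutive samples stay below one voxel apart
  expect_lt(max(sqrt(rowSums(diff(cl$points)^2))), 1)
  expect_error(helix_centerline(-1, 10, 1), "positive")
  expect_error(helix_centerline(10, 0, 1), "positive")
})

test_that("helix polyline length matches the quadrature oracle", {
  # |h'(t)| = sqrt(r^2 + (p/2pi)^2) is constant, so the arc length of one
  # turn is 2 pi sqrt(r^2 + (p/2pi)^2); numerical quadrature as the oracle
  r <- 100; p <- 40 * 2 * pi
  tt <- seq(0, 2 * pi, length.out = 20001)
  speed <- sqrt((r * sin(tt))^2 + (r * cos(tt))^2 + (p / (2 * pi))^2)
  oracle <- sum((speed[-1] + speed[-length(speed)]) / 2 * diff(tt))
  expect_equal(oracle, 2 * pi * sqrt(100^2 + 40^2), tolerance = 1e-9)
  cl <- helix_centerline(r, p, 1)
  polylen <- sum(sqrt(rowSums(diff(cl$points)^2)))
  expect_equal(polylen, oracle, tolerance = 1e-4)
})

test_that("comb centerline has the stated branch and junction structure", {
  cb <- comb_centerline(100, 40, 5, 20)
  expect_length(cb, 6L)
  expect_equal(nrow(attr(cb, "junctions")), 5L)
  total <- sum(vapply(cb, function(b)
    sum(sqrt(rowSums(diff(b$points)^2))), 1.0))
  expect_equal(total, 100 + 5 * 40, tolerance = 1e-9)
  # teeth attach on the spine at evenly spaced junctions
  expect_equal(attr(cb, "junctions")[, 1], seq(0, 80, by = 20))
  # single tooth: a T shape of two branches
  tshape <- comb_centerline(100, 40, 1, 0)
  expect_length(tshape, 2L)
  expect_error(comb_centerline(100, 40, 7, 20), "span exceeds")
})

test_that("rasterized straight tube has the expected voxel count and no
           voxel strays beyond the tube radius", {
  line <- parametric_centerline(cbind(seq(0, 100, by = 0.25), 0, 0))
  ph <- rasterize_tube(line, tube_radius = 3, margin = 3)
  n <- sum(ph$mask$mask)
  expect_lt(abs(n - pi * 9 * 100) / (pi * 9 * 100), 0.15)
  # brute force: every mask voxel within tube_radius + half voxel diagonal
  # of the continuous centerline (R-side distance computation)
  vox <- arrayInd(which(ph$mask$mask), dim(ph$mask$mask))
  # recompute the frame shift exactly as the rasterizer does
  lo <- apply(line$points, 2, min)
  shift <- -lo + 3 + 3
  s2 <- sweep(line$points, 2, shift, "+")
  dmin <- oracle_min_dists(vox - 1, s2)
  expect_lte(max(dmin), 3 + sqrt(3) / 2 + 1e-9)
})

test_that("phantom volumes are binary without noise and reproducible with
           a seed", {
  line <- parametric_centerline(cbind(seq(0, 20, by = 0.25), 0, 0))
  ph <- rasterize_tube(line, tube_radius = 2, margin = 2)
  expect_length(unique(as.numeric(ph$volume$data)), 2L)
  set.seed(11)
  a <- rasterize_tube(line, tube_radius = 2, margin = 2, noise_sd = 10)
  set.seed(11)
  b <- rasterize_tube(line, tube_radius = 2, margin = 2, noise_sd = 10)
  expect_identical(a$volume$data, b$volume$data)
  expect_gte(min(a$volume$data), 0)  # noise clipped at zero
})

test_that("ground-truth centerline voxels lie inside the mask and are
           26-connected", {
  ph <- helix_phantom(40, scale = 0.5)
  inside <- ph$mask$mask[ph$truth]
  expect_true(all(inside))
  branch <- attr(ph$truth, "branch")
  steps <- abs(diff(ph$truth))
  same_branch <- diff(branch) == 0
  expect_true(all(apply(steps[same_branch, , drop = FALSE], 1, max) <= 1))
  # comb truth: per-branch connectivity holds too
  phc <- comb_phantom()
  stepsc <- abs(diff(phc$truth))
  samec <- diff(attr(phc$truth, "branch")) == 0
  expect_true(all(apply(stepsc[samec, , drop = FALSE], 1, max) <= 1))
})

test_that("oversized phantom requests are rejected with a sizing message", {
  big <- parametric_centerline(cbind(seq(0, 5000, by = 0.5), 0, 0))
  expect_error(rasterize_tube(big, tube_radius = 100, margin = 100),
               "exceeds")
})
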