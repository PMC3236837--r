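test_that("DFE matches brute-force nearest-background distances", {
  # isolated voxel: nearest background neighbour at distance 1
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  expect_equal(compute_dfe(segmentation(m))[4, 4, 4], 1)
  # 7-voxel slab: centre plane at distance 4 under the voxel-centre
  # convention
  slab <- array(FALSE, c(15, 15, 13)); slab[, , 4:10] <- TRUE
  expect_equal(compute_dfe(segmentation(slab))[8, 8, 7], 4)
  # digital balls: max DFE within [R, R + 1]; cross-checked against an
  # R-side brute-force nearest-background search for R = 4
  for (R in c(4, 7, 10)) {
    b <- ball_mask(R)
    dfe <- compute_dfe(segmentation(b))
    expect_gte(max(dfe), R)
    expect_lte(max(dfe), R + 1)
  }
  b <- ball_mask(4)
  dfe <- compute_dfe(segmentation(b))
  obj <- arrayInd(which(b), dim(b))
  bg <- arrayInd(which(!b), dim(b))
  oracle <- oracle_min_dists(obj, bg)
  expect_equal(dfe[b], oracle, tolerance = 1e-12)
})

test_that("DFE respects anisotropic spacing", {
  slab <- array(FALSE, c(9, 9, 9)); slab[, , 3:7] <- TRUE
  dfe <- compute_dfe(segmentation(slab, spacing = c(1, 1, 2)))
  expect_equal(dfe[5, 5, 5], 6)  # 3 voxel steps x 2 mm
})

test_that("COM collapse is symmetric on cubes and orders cylinder voxels by
           centrality", {
  cube <- array(FALSE, c(9, 9, 9)); cube[4:6, 4:6, 4:6] <- TRUE
  cf <- compute_com_cost(segmentation(cube), iterations = 1)
  disp <- cf$extra$displacement
  expect_equal(disp[5, 5, 5], 0, tolerance = 1e-12)   # symmetric centre
  expect_gt(disp[4, 4, 4], disp[4, 5, 5])             # corner > face
  # straight cylinder: cost grows with distance from the axis
  m <- cylinder_mask(radius = 4, length = 20, axis = 3)
  seg <- segmentation(m)
  cf <- compute_com_cost(seg, 30)
  ctr <- (dim(m)[1] + 1) / 2
  z <- 10
  idx <- arrayInd(which(m[, , z]), dim(m)[1:2])
  rad <- round(sqrt((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2))
  costs <- cf$values[, , z][m[, , z]]
  means <- tapply(costs, rad, mean)
  expect_true(all(diff(means) > 0))
  # the minimum-cost voxel per interior cross-section is within 1 voxel of
  # the true axis
  for (z in c(6, 10, 14)) {
    sl <- cf$values[, , z]
    best <- arrayInd(which.min(ifelse(m[, , z], sl, NA)), dim(sl))
    expect_lte(sqrt(sum((best - ctr)^2)), 1)
  }
})

test_that("COM cost is the cube of displacement normalized by the minimum
           positive displacement", {
  m <- cylinder_mask(radius = 3, length = 8)
  cf <- compute_com_cost(segmentation(m), 10)
  disp <- cf$extra$displacement[m]
  mn <- cf$extra$min_displacement
  expect_equal(mn, min(disp[disp > 0]))
  expect_equal(cf$values[m], (disp / mn)^3, tolerance = 1e-12)
  # single-voxel object: uniform zero cost with a warning
  s <- array(FALSE, c(5, 5, 5)); s[3, 3, 3] <- TRUE
  expect_warning(cf1 <- compute_com_cost(segmentation(s)), "single-voxel")
  expect_equal(cf1$values[3, 3, 3], 0)
})

test_that("MDFE breaks DFE ties toward the more central neighbourhood and
           singles out the cylinder axis", {
  m <- cylinder_mask(radius = 4, length = 16, axis = 3)
  seg <- segmentation(m)
  cf <- compute_mdfe_cost(seg)
  dfe <- cf$extra$dfe
  # find two 26-adjacent voxels with equal DFE but different neighbourhood
  # mean DFE; the higher-mean one must cost less
  dm <- dim(m)
  nm <- array(vesseltort:::cpp_neighbor_mean(as.numeric(dfe), m, dm), dm)
  obj <- which(m)
  found <- FALSE
  for (i in obj) {
    v <- arrayInd(i, dm)
    for (dx in c(1, 0)) for (dy in c(0, 1)) {
      w <- v + c(dx, dy, 0)
      if (any(w > dm)) next
      j <- w[1] + dm[1] * (w[2] - 1) + dm[1] * dm[2] * (w[3] - 1)
      if (m[j] && dfe[i] == dfe[j] && nm[i] != nm[j]) {
        hi <- if (nm[i] > nm[j]) i else j
        lo <- if (nm[i] > nm[j]) j else i
        expect_lt(cf$values[hi], cf$values[lo])
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
  # axis voxels take the strict minimum within each interior cross-section
  ctr <- (dm[1] + 1) / 2
  for (z in c(6, 9, 12)) {
    sl <- ifelse(m[, , z], cf$values[, , z], NA)
    best <- arrayInd(which.min(sl), dm[1:2])
    expect_equal(as.numeric(best), c(ctr, ctr))
    expect_equal(sum(sl == min(sl, na.rm = TRUE), na.rm = TRUE), 1L)
  }
  # single-voxel object costs zero
  s <- array(FALSE, c(5, 5, 5)); s[3, 3, 3] <- TRUE
  cfs <- compute_mdfe_cost(segmentation(s))
  expect_equal(cfs$values[3, 3, 3], 0)
})

test_that("cost dispatch covers the field, differs between COM and DFE-COM,
           and is deterministic", {
  ph <- branching_phantom(noise_sd = 0, trunk_length = 30, arm_length = 25)
  for (meth in c("dfe_com", "com", "mdfe")) {
    cf <- compute_cost(ph$mask, meth)
    expect_identical(is.na(cf$values), !ph$mask$mask)
    expect_true(all(cf$values[ph$mask$mask] >= 0))
  }
  a <- compute_cost(ph$mask, "com")
  b <- compute_cost(ph$mask, "dfe_com")
  expect_false(isTRUE(all.equal(a$values, b$values)))
  expect_identical(compute_cost(ph$mask, "dfe_com")$values, b$values)
  expect_error(compute_cost(segmentation(array(FALSE, c(4, 4, 4)))),
               "empty mask")
  expect_error(compute_cost(ph$mask, "frangi"))
})
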