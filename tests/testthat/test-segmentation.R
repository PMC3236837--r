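test_that("z-ray seeds land inside a bright cylinder and isolated bright
           voxels are rejected by the cluster-size filter", {
  m <- cylinder_mask(radius = 3, length = 10, axis = 3, margin = 4)
  vol <- image_volume(array(ifelse(m, 150, 0), dim(m)))
  seeds <- zbs_detect_seeds(vol)
  expect_gt(nrow(seeds$seeds), 0)
  expect_true(all(m[seeds$seeds]))
  # add one isolated bright voxel in the far corner: excluded at
  # min_cluster = 5
  v2 <- vol$data
  v2[2, 2, 2] <- 200
  seeds2 <- zbs_detect_seeds(image_volume(v2), min_cluster = 5)
  expect_false(any(seeds2$seeds[, 1] == 2 & seeds2$seeds[, 2] == 2))
  expect_error(zbs_detect_seeds(image_volume(array(5, c(4, 4, 4)))),
               "no seeds")
})

test_that("region growing thresholds at the stated percentile of seed
           intensities and captures full foreground components", {
  seeds <- structure(list(seeds = cbind(5:14, 5, 5),
                          intensities = seq(10, 100, by = 10)),
                     class = "seed_set")
  vol <- image_volume(array(500, c(20, 10, 10)))
  seg <- grow_region(vol, seeds, percentile = 20)
  expect_equal(seg$provenance$threshold,
               as.numeric(stats::quantile(seq(10, 100, 10), 0.2)))
  # binary phantom: any percentile yields the full foreground component
  m <- cylinder_mask(radius = 3, length = 12)
  volb <- image_volume(array(ifelse(m, 200, 0), dim(m)))
  sds <- zbs_detect_seeds(volb)
  for (pct in c(5, 20, 80)) {
    segb <- grow_region(volb, sds, pct)
    expect_identical(segb$mask, m)
  }
})

test_that("bubble filling closes cavities, leaves solids and open tori
           unchanged", {
  # hollow sphere shell -> solid ball
  shell <- ball_mask(6) & !ball_mask(4, side = 17)
  dm <- dim(shell)
  seg <- segmentation(shell)
  filled <- fill_bubbles(seg)
  expect_identical(filled$mask, ball_mask(6))
  # solid cylinder unchanged
  cyl <- segmentation(cylinder_mask(3, 10))
  expect_identical(fill_bubbles(cyl)$mask, cyl$mask)
  # torus: the hole's background connects to the outside, so unchanged
  side <- 25; ctr <- 13
  idx <- as.matrix(expand.grid(1:side, 1:side, 1:side))
  rho <- sqrt((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2)
  tor <- array(FALSE, rep(side, 3))
  tor[idx[(rho - 7)^2 + (idx[, 3] - ctr)^2 <= 9, , drop = FALSE]] <- TRUE
  # oracle: the background component through the torus hole reaches the
  # volume boundary
  expect_true(!tor[ctr, ctr, 1] && !tor[ctr, ctr, ctr])
  segt <- segmentation(tor)
  expect_identical(fill_bubbles(segt)$mask, tor)
})

test_that("directional hole filling matches an explicit ray census: face
           pits survive, interior cavities fill", {
  blk <- array(FALSE, c(21, 21, 21))
  blk[3:19, 3:19, 3:11] <- TRUE  # solid block with a flat top face at z=11
  pit <- blk
  pit[11, 11, 11] <- FALSE       # single-voxel pit on the face
  expect_equal(oracle_ray_census(pit, c(11, 11, 11), span = 8), 17L)
  segp <- fill_edge_holes(segmentation(pit))
  expect_false(segp$mask[11, 11, 11])  # 17 of 26 < 24: not filled
  cav <- blk
  cav[11, 11, 7] <- FALSE        # fully enclosed single-voxel cavity
  expect_equal(oracle_ray_census(cav, c(11, 11, 7), span = 8), 26L)
  segc <- fill_edge_holes(segmentation(cav), iterations = 1)
  expect_true(segc$mask[11, 11, 7])
  # empty mask unchanged; impossible direction count rejected
  empty <- segmentation(array(FALSE, c(5, 5, 5)))
  expect_identical(fill_edge_holes(empty)$mask, empty$mask)
  expect_error(fill_edge_holes(empty, directions_required = 27), "26")
})

test_that("hole and bubble filling are monotone and bubble filling is
           idempotent; filled masks have no enclosed cavities", {
  set.seed(21)
  for (rep in 1:3) {
    m <- array(runif(12^3) < 0.35, c(12, 12, 12))
    seg <- segmentation(m)
    fb <- fill_bubbles(seg)
    fh <- fill_edge_holes(seg, iterations = 1)
    expect_true(all(fb$mask >= m))
    expect_true(all(fh$mask >= m))
    expect_identical(fill_bubbles(fb)$mask, fb$mask)
    # Euler-style check: every background component of the filled mask
    # touches the boundary (second Betti number 0)
    dm <- dim(fb$mask)
    lab <- array(vesseltort:::cpp_label_components(!fb$mask, dm, 6L), dm)
    border <- unique(c(lab[1, , ], lab[dm[1], , ], lab[, 1, ],
                       lab[, dm[2], ], lab[, , 1], lab[, , dm[3]]))
    expect_setequal(setdiff(unique(as.integer(lab)), 0L),
                    setdiff(border, 0L))
  }
})

test_that("the full ZBS pipeline recovers binary phantoms exactly and fails
           loudly on empty volumes", {
  ph <- comb_phantom()
  seg <- zbs_segment(ph$volume)
  expect_gte(dice_coefficient(seg$mask, ph$mask$mask), 0.999)
  # pipeline output contains the grown region
  seeds <- zbs_detect_seeds(ph$volume)
  grown <- grow_region(ph$volume, seeds, 20)
  expect_true(all(seg$mask[grown$mask]))
  expect_error(zbs_segment(image_volume(array(0, c(6, 6, 6)))),
               "seed detection")
})
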