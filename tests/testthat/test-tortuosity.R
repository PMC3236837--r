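test_that("straight paths have DFM identically 1 in any orientation", {
  straight <- cbind(seq(0, 30, by = 0.5), 0, 0)
  cv <- dfm_curve(make_path(straight))
  expect_true(all(cv$dfm == 1))
  set.seed(5)
  for (rep in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    rot <- straight %*% t(q)
    cvr <- dfm_curve(make_path(sweep(rot, 2, c(10, 20, 30), "+")))
    expect_equal(max(abs(cvr$dfm - 1)), 0, tolerance = 1e-9)
  }
})

test_that("a semicircle ends at DFM = pi/2", {
  theta <- seq(0, pi, length.out = 2000)
  arc <- cbind(10 * cos(theta), 10 * sin(theta), 0)
  m <- read_measurement(dfm_curve(make_path(arc)), "end")
  expect_equal(m$value, pi / 2, tolerance = 1e-4)
})

test_that("the continuous helix tortuosity curve peaks near the full-coil
           value of the quadrature oracle", {
  r <- 100; p <- 40 * 2 * pi
  tt <- seq(1e-4, 2 * pi, length.out = 20000)
  L <- tt * sqrt(r^2 + (p / (2 * pi))^2)        # constant-speed closed form
  d <- sqrt(2 * r^2 * (1 - cos(tt)) + (p * tt / (2 * pi))^2)
  oracle_peak <- max((L / d)[d >= 2 * sqrt(3)])
  expect_equal(oracle_peak, 2.6926, tolerance = 1e-3)
  h <- cbind(r * cos(tt), r * sin(tt), p * tt / (2 * pi))
  cv <- dfm_curve(make_path(h))
  pk <- read_measurement(cv, "peak")
  expect_equal(pk$value, oracle_peak, tolerance = 5e-3)
})

test_that("DFM never drops below 1 and peak readout is invariant to rigid
           motion of the path", {
  set.seed(8)
  for (rep in 1:5) {
    steps <- matrix(rnorm(60 * 3, sd = 1), ncol = 3)
    walk <- apply(steps, 2, cumsum)
    cv <- dfm_curve(make_path(walk))
    expect_true(all(cv$dfm >= 1 - 1e-12))
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    cv2 <- dfm_curve(make_path(sweep(walk %*% t(q), 2, rnorm(3, sd = 50),
                                     "+")))
    p1 <- read_measurement(cv, "peak")$value
    p2 <- read_measurement(cv2, "peak")$value
    expect_equal(p1, p2, tolerance = 1e-9)
  }
})

test_that("peak equals end for monotone curves and the d-floor guards the
           near-origin singularity", {
  theta <- seq(0, 0.9 * pi, length.out = 500)
  arc <- cbind(20 * cos(theta), 20 * sin(theta), 0)
  cv <- dfm_curve(make_path(arc))
  i_floor <- cv$d >= 2 * sqrt(3)
  expect_true(all(diff(cv$dfm[i_floor]) > -1e-9))  # monotone beyond floor
  expect_equal(read_measurement(cv, "peak")$value,
               read_measurement(cv, "end")$value, tolerance = 1e-9)
  # a hairpin at the very start would dominate without the floor
  hook <- rbind(cbind(seq(0, 1, by = 0.1), 0, 0),
                cbind(seq(0.9, 0.2, by = -0.1), 0.05, 0),
                cbind(seq(0.3, 40, by = 0.5), 0.1, 0))
  cvh <- dfm_curve(make_path(hook))
  pk <- read_measurement(cvh, "peak")
  expect_gte(pk$d, 2 * sqrt(3))
})

test_that("artery aggregation averages within groups and selects by
           laterality", {
  expect_equal(aggregate_arteries(c(2, 4))$value, 3)
  expect_equal(aggregate_arteries(7)$value, 7)
  df <- data.frame(subject = c(1, 1, 1, 1), artery = "LSA",
                   value = c(1.5, 2.0, 2.5, 3.0),
                   start_x = c(10, 20, 30, 40))
  expect_equal(aggregate_arteries(df)$value, 2.25)
  expect_equal(aggregate_arteries(df, "leftmost")$value, 1.5)
  expect_equal(aggregate_arteries(df, "rightmost")$value, 3.0)
  expect_error(aggregate_arteries(data.frame()), "no measurements")
})

test_that("group comparisons report the full battery with Bonferroni
           thresholds", {
  g <- c(1.2, 1.4, 1.9, 2.3, 2.8)
  cmp <- compare_groups(g, g, n_comparisons = 8)
  expect_equal(cmp$p_values$wilcoxon_2sided, 1.0)
  expect_equal(cmp$beta, 0.00625)
  cmp13 <- compare_groups(g, g + 1, n_comparisons = 13)
  expect_equal(cmp13$beta, 0.05 / 13)
  expect_lt(cmp13$p_values$wilcoxon_1sided, 1)
  expect_true(is.finite(cmp13$p_values$anova))
  expect_true(is.finite(cmp13$p_values$f_var))
  # unequal lengths flag the paired test instead of failing
  cmp2 <- compare_groups(c(1, 2, 3), c(1, 2, 3, 4))
  expect_true(is.na(cmp2$p_values$wilcoxon_paired))
  expect_match(cmp2$notes$wilcoxon_paired, "equal")
  # small untied samples use the exact distribution
  cmp3 <- compare_groups(c(1.1, 2.2, 3.3), c(4.4, 5.5, 6.6))
  expect_equal(cmp3$wilcoxon_variant, "exact")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
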