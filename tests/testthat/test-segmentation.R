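test_that("fixed segmentation tiles the series and discards the remainder", {
  s <- imu_series(matrix(rnorm(2400 * 6), ncol = 6))
  b <- segment_fixed(s)
  expect_equal(nrow(b), 3)
  expect_equal(b$start, c(0, 800, 1600))
  expect_equal(b$end, c(800, 1600, 2400))

  s2 <- imu_series(matrix(rnorm(2000 * 6), ncol = 6))
  b2 <- segment_fixed(s2)
  expect_equal(nrow(b2), 2)          # 400 trailing samples discarded
  expect_equal(max(b2$end), 1600)

  # one default block spans 4 s at the default 200 Hz rate
  expect_equal((b$end[1] - b$start[1]) / s$sampling_rate_hz, 4)

  s3 <- imu_series(matrix(rnorm(60), ncol = 6))
  expect_warning(b3 <- segment_fixed(s3), "shorter")
  expect_equal(nrow(b3), 0)
})

test_that("hotelling statistic matches a literal implementation of its formula", {
  set.seed(42)
  for (i in 1:25) {
    m <- sample(5:60, 1); n <- sample(5:60, 1)
    a <- matrix(rnorm(m * 6), m, 6)
    b <- matrix(rnorm(n * 6, mean = runif(1, -1, 1)), n, 6)
    expect_equal(hotelling_t2(a, b, ridge_eps = 0), t2_oracle(a, b),
                 tolerance = 1e-8)
  }
})

test_that("hotelling statistic reduces to the squared pooled-t in one dimension", {
  set.seed(7)
  for (i in 1:10) {
    x <- matrix(rnorm(30, 1), ncol = 1)
    y <- matrix(rnorm(25), ncol = 1)
    t_stat <- t.test(x, y, var.equal = TRUE)$statistic
    expect_equal(hotelling_t2(x, y, ridge_eps = 0), unname(t_stat^2),
                 tolerance = 1e-10)
  }
})

test_that("hotelling statistic handles degenerate and invalid inputs", {
  a <- matrix(rnorm(120), 20, 6)
  expect_equal(hotelling_t2(a, a), 0)
  const <- matrix(1, 10, 6)
  expect_equal(hotelling_t2(const, const), 0)  # zero covariance, zero shift
  expect_error(hotelling_t2(a[1, , drop = FALSE], a), "at least 2 rows")
  bad <- a; bad[1, 1] <- NA
  expect_error(hotelling_t2(bad, a), "data error")
})

test_that("hotelling statistic is invariant under common affine channel maps", {
  set.seed(9)
  a <- matrix(rnorm(300), 50, 6)
  b <- matrix(rnorm(300, 0.5), 50, 6)
  base <- hotelling_t2(a, b, ridge_eps = 0)
  for (i in 1:5) {
    w <- matrix(rnorm(36), 6, 6) + diag(6) * 2  # well-conditioned
    shift <- rnorm(6)
    ta <- sweep(a %*% w, 2, shift, `+`)
    tb <- sweep(b %*% w, 2, shift, `+`)
    expect_equal(hotelling_t2(ta, tb, ridge_eps = 0), base, tolerance = 1e-6)
  }
})

test_that("hotelling statistic grows monotonically with the mean shift", {
  set.seed(13)
  a <- matrix(rnorm(600), 100, 6)
  b0 <- matrix(rnorm(600), 100, 6)
  t2s <- vapply(seq(0, 2, by = 0.25), function(delta)
    hotelling_t2(a, b0 + delta, ridge_eps = 0), numeric(1))
  expect_true(all(diff(t2s) >= 0))
})

test_that("windowed statistic from cumulative moments equals the direct form", {
  s <- toy_series(n = 5000, seed = 21)
  cs <- wearfu:::.series_cumstats(s)
  for (b in c(2000, 2600, 3000)) {
    direct <- hotelling_t2(s$channels[(b - 2000 + 1):b, ],
                           s$channels[(b + 1):(b + 2000), ])
    expect_equal(wearfu:::.t2_at_boundary(cs, b, 2000, 1e-6), direct,
                 tolerance = 1e-6)
  }
})

test_that("variable segmentation closes blocks on the candidate lattice", {
  # change exactly at 2000: detected at the first comparison
  s1 <- shift_series(n = 8000, change_at = 2000, delta = 2, seed = 2)
  # threshold sits between the diluted statistic of a window straddling the
  # change (~5e3 here) and the full-contrast statistic (~6e5)
  cfg <- segmentation_config(t2_threshold = 1e4)
  b1 <- segment_variable(s1, cfg)
  expect_equal(b1$end[1], 2000)
  # change at 2600: first comparison sees homogeneous data, second fires
  s2 <- shift_series(n = 8000, change_at = 2600, delta = 2, seed = 3)
  b2 <- segment_variable(s2, cfg)
  expect_equal(b2$end[1], 2600)
  # blocks always partition the series
  for (b in list(b1, b2)) {
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], 8000)
    expect_true(all(b$start[-1] == b$end[-nrow(b)]))
  }
})

test_that("a single mean shift is localized within one shift of its true position", {
  s <- shift_series(n = 10000, change_at = 3000, delta = 1.5, seed = 4)
  cfg <- segmentation_config(t2_threshold = 1e4)
  b <- segment_variable(s, cfg)
  bounds <- b$end[-nrow(b)]
  expect_true(any(abs(bounds - 3000) <= 600))
  # exhaustive scan oracle: the statistic is maximized at the true shift
  cs <- wearfu:::.series_cumstats(s)
  lattice <- seq(2000, 10000 - 2000, by = 200)
  t2s <- vapply(lattice, function(bb)
    wearfu:::.t2_at_boundary(cs, bb, 2000, 1e-6), numeric(1))
  expect_equal(lattice[which.max(t2s)], 3000)
})

test_that("a homogeneous series yields exactly one block at a high threshold", {
  set.seed(6)
  s <- imu_series(matrix(rnorm(9000 * 6), ncol = 6))
  cfg <- segmentation_config(t2_threshold = 1e6)
  b <- segment_variable(s, cfg)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(0, 9000))
  # short series: single block with a warning
  s_short <- imu_series(matrix(rnorm(3000 * 6), ncol = 6))
  expect_warning(bs <- segment_variable(s_short, cfg), "shorter")
  expect_equal(nrow(bs), 1)
})

test_that("threshold calibration reaches the target rate on separable regimes", {
  cfg <- quick_config(duration_s = 300)
  subj <- generate_subject(cfg, subject_seed = 8)
  seg <- segmentation_config()
  cal <- calibrate_threshold(list(subj$series), list(subj$transitions), seg)
  expect_gte(attr(cal, "tpr"), 0.80)
  expect_true(is.numeric(cal$t2_threshold) && cal$t2_threshold > 0)
  # degenerate target: no detections are required, so segmentation with the
  # returned threshold declares no boundary on the training series
  seg0 <- segmentation_config(target_tpr = 0)
  cal0 <- calibrate_threshold(list(subj$series), list(subj$transitions), seg0)
  b0 <- segment_variable(subj$series, cal0)
  expect_equal(nrow(b0), 1)
})

test_that("calibrated detector recovers transitions on a held-out recording", {
  cohort <- generate_cohort(generator_config(), n_subjects = 4,
                            cohort_seed = 42)
  seg <- calibrate_threshold(lapply(cohort[1:3], function(s) s$series),
                             lapply(cohort[1:3], function(s) s$transitions),
                             segmentation_config())
  held <- cohort[[4]]
  b <- segment_variable(held$series, seg)
  tpr <- transition_tpr(wearfu:::.internal_boundaries(b), held$transitions,
                        tol = 600)
  expect_gte(tpr, 0.80)
})
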