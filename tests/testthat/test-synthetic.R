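test_that("generated recordings have the configured size and are reproducible", {
  cfg <- quick_config(duration_s = 60)
  s <- generate_subject(cfg, subject_seed = 4)
  expect_equal(n_samples(s$series), 12000)  # 60 s at 200 Hz
  expect_equal(length(s$states), 12000)
  expect_true(all(s$codes %in% c(0L, 1L, 3L)))
  s2 <- generate_subject(cfg, subject_seed = 4)
  expect_identical(s$series$channels, s2$series$channels)
  expect_identical(s$transitions, s2$transitions)
  s3 <- generate_subject(cfg, subject_seed = 5)
  expect_false(identical(s$series$channels, s3$series$channels))
  # identical seeds export identical bytes
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_imu_csv(s$series, f1); write_imu_csv(s2$series, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("state-conditional signal structure orders the variances", {
  s <- generate_subject(generator_config(duration_s = 600), subject_seed = 42)
  for (ch in c("gx", "gy", "az")) {
    v <- tapply(s$series$channels[, ch], s$states, var)
    expect_lt(v["rest"], v["gait"])
    expect_lt(v["rest"], v["functional"])
  }
})

test_that("generated data pass the i/o and annotation validity checks", {
  cfg <- quick_config(duration_s = 90)
  s <- generate_subject(cfg, subject_seed = 11)
  expect_s3_class(s$series, "imu_series")
  ann <- simulate_annotators(s, seed = 2)
  expect_s3_class(ann, "annotator_set")
  expect_length(ann$tracks, 3)
  d <- subject_dataset(s, annotator_seed = 2)
  expect_equal(length(d$merged_codes), n_samples(s$series))
  # generated FU share is recovered from the true per-sample codes
  expect_equal(functional_use_percent(collapse_binary(s$codes),
                                      rep(1, length(s$codes))),
               s$true_fu_percent)
})

test_that("noiseless annotators reproduce the truth exactly", {
  cfg <- quick_config(duration_s = 90, annotator_error_rate = 0,
                      annotator_boundary_jitter_frames = 0L)
  s <- generate_subject(cfg, subject_seed = 13)
  ann <- simulate_annotators(s, seed = 3)
  expect_identical(ann$tracks[[1]], ann$tracks[[2]])
  expect_identical(ann$tracks[[1]], ann$tracks[[3]])
  # frame codes equal the true code at the frame midpoint
  n_frames <- length(ann$tracks[[1]])
  mid <- floor(((seq_len(n_frames) - 0.5) / 30) * 200) + 1
  expect_identical(ann$tracks[[1]], s$codes[mid])
})

test_that("fully random annotators produce the enumerated no-majority share", {
  cfg <- quick_config(duration_s = 300, annotator_error_rate = 1,
                      annotator_boundary_jitter_frames = 0L)
  s <- generate_subject(cfg, subject_seed = 17)
  ann <- simulate_annotators(s, seed = 5)
  merged <- merge_annotators(do.call(cbind, ann$tracks))
  # analytic expectation: each annotator draws uniformly from the 4 codes
  # other than the truth; unknown results from no agreement or agreeing on -1
  other <- function(truth) setdiff(c(-1L, 0L, 1L, 2L, 3L), truth)
  p_unknown <- mean(sapply(c(0L, 1L, 3L), function(truth) {
    g <- expand.grid(a = other(truth), b = other(truth), c = other(truth))
    mean(apply(g, 1, function(x) {
      tab <- table(x)
      maj <- names(tab)[tab >= 2]
      length(maj) == 0 || as.integer(maj[1]) == -1L
    }))
  }))
  obs <- mean(merged == -1L)
  expect_lt(abs(obs - p_unknown), 0.03)
})

test_that("default annotator noise keeps label corruption and exclusion small", {
  cfg <- generator_config(duration_s = 600)
  s <- generate_subject(cfg, subject_seed = 19)
  d <- subject_dataset(s, annotator_seed = 7)
  expect_lt(mean(d$merged_codes == -1L), 0.02)
  disagree <- mean(d$merged_codes != s$codes)
  expect_lt(disagree, 0.02)
})

test_that("cohorts are reproducible and subject-distinct", {
  cfg <- quick_config(duration_s = 60)
  c1 <- generate_cohort(cfg, n_subjects = 4, cohort_seed = 7)
  c2 <- generate_cohort(cfg, n_subjects = 4, cohort_seed = 7)
  expect_identical(lapply(c1, function(s) s$series$channels),
                   lapply(c2, function(s) s$series$channels))
  expect_false(identical(c1[[1]]$series$channels, c1[[2]]$series$channels))
  expect_named(c1, c("synth01", "synth02", "synth03", "synth04"))
  expect_error(generate_cohort(cfg, n_subjects = 0), "n_subjects")
})

test_that("without idiosyncrasies subjects are exchangeable across protocols", {
  cfg <- generator_config(duration_s = 240, subject_gain_sd = 0,
                          mount_rotation_deg = 0, mount_tilt_sd_deg = 0)
  cohort <- generate_cohort(cfg, n_subjects = 3, cohort_seed = 11)
  datasets <- lapply(seq_along(cohort), function(i)
    subject_dataset(cohort[[i]], annotator_seed = i))
  names(datasets) <- names(cohort)
  res <- evaluate_cohort(datasets, "fixed", k = 5)
  expect_lt(abs(mean(res$per_subject$acc_inter) -
                  mean(res$per_subject$acc_intra)), 0.05)
})

test_that("invalid generator configurations are rejected", {
  bad <- rbind(c(0.5, 0.5, 0.1), c(0.3, 0, 0.7), c(0.5, 0.5, 0))
  expect_error(generator_config(transition = bad), "config error")
  expect_error(generator_config(annotator_error_rate = 2))
})
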