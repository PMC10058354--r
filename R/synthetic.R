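#' Synthetic-cohort generator configuration
#'
#' The generator emulates the structure of a wrist recording taken while a
#' subject alternates between rest (seated conversation), walking (arm
#' swing), and functional object manipulation. Each state has a distinct
#' wrist orientation, so the gravity component of the accelerometer mean
#' differs between states (this is what makes transitions visible to a
#' mean-based change detector), plus a state-specific dynamic signature:
#' rest is low-variance noise; gait adds a ~1 Hz arm-swing sinusoid and its
#' first harmonic, dominant on the gyroscope; functional movement adds
#' irregular smooth bell-shaped velocity pulses with randomized amplitude
#' and duration plus broadband noise, giving it the highest variance and
#' entropy. State dwell times are lognormal (semi-Markov), long relative to
#' the 2000-sample probe window so variable segmentation is meaningful.
#'
#' @param sampling_rate_hz IMU rate (default 200).
#' @param duration_s recording length in seconds (default 600, i.e. 10 min).
#' @param mean_dwell_s mean state dwell time in seconds (default 20).
#' @param dwell_sdlog lognormal log-scale sd of dwell times (default 0.35).
#' @param transition matrix of state transition probabilities (rows
#'   rest/gait/functional summing to 1, zero diagonal).
#' @param subject_gain_sd sd of per-subject lognormal channel gains
#'   (default 0.15); 0 makes subjects statistically exchangeable.
#' @param mount_rotation_deg half-range of the per-subject strap rotation
#'   about the forearm axis, degrees (default 30): each subject wears the
#'   device at a different rotation, so the gravity direction seen by the
#'   accelerometer differs between subjects even in identical postures.
#'   Together with the gains and gait frequency this drives the
#'   intra-subject vs inter-subject generalization gap; 0 disables it.
#' @param mount_tilt_sd_deg sd of an additional small random-axis mounting
#'   tilt, degrees (default 5).
#' @param annotator_error_rate per-frame probability that an annotator
#'   records a uniformly random other code (default 0.05).
#' @param annotator_boundary_jitter_frames max frames by which each
#'   annotator misplaces a state boundary (default 2).
#' @param frame_rate_hz video frame rate of the simulated annotators (30).
#' @param n_annotators number of simulated annotators (default 3).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(sampling_rate_hz = 200, duration_s = 600,
                             mean_dwell_s = 20, dwell_sdlog = 0.35,
                             transition = NULL, subject_gain_sd = 0.15,
                             mount_rotation_deg = 30, mount_tilt_sd_deg = 5,
                             annotator_error_rate = 0.05,
                             annotator_boundary_jitter_frames = 2L,
                             frame_rate_hz = 30, n_annotators = 3L) {
  if (is.null(transition)) {
    transition <- rbind(rest = c(0, 0.5, 0.5),
                        gait = c(0.3, 0, 0.7),
                        functional = c(0.5, 0.5, 0))
    colnames(transition) <- rownames(transition)
  }
  if (!is.matrix(transition) || any(dim(transition) != 3L) ||
      any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    stop("config error: transition must be a 3x3 row-stochastic matrix")
  stopifnot(sampling_rate_hz > 0, duration_s > 0, mean_dwell_s > 0,
            annotator_error_rate >= 0, annotator_error_rate <= 1,
            n_annotators >= 1, n_annotators <= 3,
            frame_rate_hz > 0, frame_rate_hz <= sampling_rate_hz)
  stopifnot(mount_rotation_deg >= 0, mount_tilt_sd_deg >= 0)
  structure(list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
                 mean_dwell_s = mean_dwell_s, dwell_sdlog = dwell_sdlog,
                 transition = transition, subject_gain_sd = subject_gain_sd,
                 mount_rotation_deg = mount_rotation_deg,
                 mount_tilt_sd_deg = mount_tilt_sd_deg,
                 annotator_error_rate = annotator_error_rate,
                 annotator_boundary_jitter_frames =
                   as.integer(annotator_boundary_jitter_frames),
                 frame_rate_hz = frame_rate_hz,
                 n_annotators = as.integer(n_annotators)),
            class = "generator_config")
}

# Per-state signal parameters. Accelerometer means are gravity projections
# for the typical wrist orientation of the state (device units ~ g);
# orientations differ between states by ~1 g in total.
.state_params <- list(
  rest = list(acc_mean = c(0.05, 0.05, 1.00), gyro_mean = c(0, 0, 0),
              acc_sd = 0.02, gyro_sd = 0.02),
  gait = list(acc_mean = c(0.05, 0.70, 0.70), gyro_mean = c(0, 0, 0),
              acc_sd = 0.06, gyro_sd = 0.05,
              swing_freq_hz = 1.0, gyro_amp = c(0.80, 0.30, 0.20),
              acc_amp = c(0.10, 0.25, 0.15)),
  functional = list(acc_mean = c(0.55, 0.35, 0.70), gyro_mean = c(0, 0, 0),
                    acc_sd = 0.12, gyro_sd = 0.10,
                    pulse_rate_hz = 0.8,
                    pulse_amp_gyro = c(0.3, 1.5), pulse_amp_acc = c(0.1, 0.6),
                    pulse_width_s = c(0.08, 0.30)))

# Sample a semi-Markov state sequence: lognormal dwells with the configured
# mean, then a transition drawn from the corresponding matrix row.
.sample_states <- function(config, n) {
  fs <- config$sampling_rate_hz
  meanlog <- log(config$mean_dwell_s) - config$dwell_sdlog^2 / 2
  state <- sample.int(3L, 1)
  states <- integer(0)
  transitions <- integer(0)
  while (length(states) < n) {
    dwell <- max(2L, round(stats::rlnorm(1, meanlog, config$dwell_sdlog) * fs))
    states <- c(states, rep(state, dwell))
    if (length(states) < n) transitions <- c(transitions, length(states))
    state <- sample.int(3L, 1, prob = config$transition[state, ])
  }
  list(states = states[seq_len(n)],
       transitions = transitions[transitions < n])
}

.bell_pulses <- function(n, fs, rate_hz, amp_range, width_range) {
  out <- numeric(n)
  n_pulses <- stats::rbinom(1, n, rate_hz / fs)
  if (n_pulses == 0) return(out)
  centers <- sort(stats::runif(n_pulses, 1, n))
  t <- seq_len(n)
  for (c0 in centers) {
    amp <- stats::runif(1, amp_range[1], amp_range[2]) * sample(c(-1, 1), 1)
    w <- stats::runif(1, width_range[1], width_range[2]) * fs
    lo <- max(1, floor(c0 - 4 * w)); hi <- min(n, ceiling(c0 + 4 * w))
    out[lo:hi] <- out[lo:hi] + amp * exp(-((t[lo:hi] - c0)^2) / (2 * w^2))
  }
  out
}

.state_segment_signal <- function(state, n, fs, swing_factor) {
  p <- .state_params[[STATE_NAMES[state]]]
  acc <- sapply(1:3, function(i) p$acc_mean[i] + stats::rnorm(n, 0, p$acc_sd))
  gyr <- sapply(1:3, function(i) p$gyro_mean[i] + stats::rnorm(n, 0, p$gyro_sd))
  if (n == 1) { acc <- matrix(acc, 1); gyr <- matrix(gyr, 1) }
  if (STATE_NAMES[state] == "gait") {
    f <- p$swing_freq_hz * swing_factor
    t <- seq_len(n) / fs
    phase <- stats::runif(1, 0, 2 * pi)
    base <- sin(2 * pi * f * t + phase)
    harm <- 0.35 * sin(2 * pi * 2 * f * t + phase)
    for (i in 1:3) {
      gyr[, i] <- gyr[, i] + p$gyro_amp[i] * (base + harm)
      acc[, i] <- acc[, i] + p$acc_amp[i] * sin(2 * pi * 2 * f * t + phase + i)
    }
  } else if (STATE_NAMES[state] == "functional") {
    for (i in 1:3) {
      gyr[, i] <- gyr[, i] + .bell_pulses(n, fs, p$pulse_rate_hz,
                                          p$pulse_amp_gyro, p$pulse_width_s)
      acc[, i] <- acc[, i] + .bell_pulses(n, fs, p$pulse_rate_hz,
                                          p$pulse_amp_acc, p$pulse_width_s)
    }
  }
  cbind(acc, gyr)
}

.axis_rotation <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  k <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle_rad) * k + (1 - cos(angle_rad)) * (k %*% k)
}

# Per-subject device-mounting rotation: a strap rotation about the forearm
# (x) axis plus a small random-axis tilt. The same rotation applies to the
# accelerometer and gyroscope triads (they are rigidly mounted together).
.mount_rotation <- function(config) {
  strap <- stats::runif(1, -config$mount_rotation_deg,
                        config$mount_rotation_deg) * pi / 180
  tilt <- stats::rnorm(1, 0, config$mount_tilt_sd_deg) * pi / 180
  tilt_axis <- stats::rnorm(3)
  .axis_rotation(c(1, 0, 0), strap) %*% .axis_rotation(tilt_axis, tilt)
}

#' Generate one synthetic subject
#'
#' Draws a semi-Markov rest/gait/functional state sequence, synthesizes the
#' six IMU channels segment by segment, applies the subject's multiplicative
#' channel gains and gait-frequency idiosyncrasy, and records the true
#' per-sample state, FAABOS codes, and transition sample indices.
#'
#' @param config a [generator_config()].
#' @param subject_seed integer seed; the same seed reproduces the subject
#'   exactly.
#' @param subject_id identifier (default derived from the seed).
#' @param group `"control"` or `"amputee"` tag carried into evaluation.
#' @return list of class `synthetic_subject` with fields `series`
#'   ([imu_series()]), `states`, `codes` (per-sample true FAABOS),
#'   `transitions` (0-based sample indices of state changes),
#'   `true_fu_percent`, `group`, and the generating `config`.
#' @export
generate_subject <- function(config = generator_config(), subject_seed = 1L,
                             subject_id = NULL, group = "control") {
  stopifnot(inherits(config, "generator_config"))
  set.seed(subject_seed)
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  gains <- exp(stats::rnorm(6, 0, config$subject_gain_sd))
  rot <- .mount_rotation(config)
  swing_factor <- stats::runif(1, 0.85, 1.15)
  ss <- .sample_states(config, n)
  bounds <- c(0L, ss$transitions, n)
  x <- matrix(0, n, 6)
  for (k in seq_len(length(bounds) - 1)) {
    idx <- (bounds[k] + 1):bounds[k + 1]
    x[idx, ] <- .state_segment_signal(ss$states[idx[1]], length(idx), fs,
                                      swing_factor)
  }
  x[, 1:3] <- x[, 1:3] %*% t(rot)
  x[, 4:6] <- x[, 4:6] %*% t(rot)
  x <- sweep(x, 2, gains, `*`)
  colnames(x) <- IMU_CHANNELS
  if (is.null(subject_id)) subject_id <- paste0("synth", subject_seed)
  series <- imu_series(x, subject_id = subject_id,
                       limb = if (group == "amputee") "affected" else "nondominant",
                       sampling_rate_hz = fs)
  codes <- STATE_CODES[ss$states]
  structure(list(series = series, states = STATE_NAMES[ss$states],
                 codes = unname(codes), transitions = ss$transitions,
                 true_fu_percent = 100 * mean(ss$states == 3L),
                 group = group, config = config),
            class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> %s (%s): %d samples, %d transitions, true FU %.1f%%\n",
              x$series$subject_id, x$group, n_samples(x$series),
              length(x$transitions), x$true_fu_percent))
  invisible(x)
}

# Move each internal boundary of a run-length-encoded track by a random
# jitter, clamped so boundaries stay ordered.
.jitter_boundaries <- function(codes, jitter) {
  if (jitter == 0L) return(codes)
  r <- rle(codes)
  if (length(r$lengths) < 2L) return(codes)
  bounds <- cumsum(r$lengths)[-length(r$lengths)]
  shifted <- bounds + sample(-jitter:jitter, length(bounds), replace = TRUE)
  shifted <- pmin(pmax(shifted, 1L), length(codes) - 1L)
  shifted <- cummax(shifted)  # keep boundaries monotone
  out <- rep(r$values[length(r$values)], length(codes))
  prev <- 0L
  for (k in seq_along(shifted)) {
    if (shifted[k] > prev) out[(prev + 1):shifted[k]] <- r$values[k]
    prev <- shifted[k]
  }
  out
}

#' Simulate noisy video annotators for a synthetic subject
#'
#' Each annotator starts from the true FAABOS code of each video frame,
#' then independently (i) misplaces every state boundary by up to
#' `annotator_boundary_jitter_frames` frames and (ii) replaces each frame's
#' code with a uniformly random other code with probability
#' `annotator_error_rate`.
#'
#' @param subject a [generate_subject()] result.
#' @param config generator configuration (defaults to the subject's own).
#' @param seed RNG seed for the annotator noise.
#' @return an [annotator_set()] at `config$frame_rate_hz`.
#' @export
simulate_annotators <- function(subject, config = subject$config, seed = 1L) {
  stopifnot(inherits(subject, "synthetic_subject"))
  set.seed(seed)
  fs <- subject$series$sampling_rate_hz
  fr <- config$frame_rate_hz
  n <- n_samples(subject$series)
  n_frames <- floor(n / fs * fr)
  # true code at each frame midpoint
  mid <- pmin(n, floor(((seq_len(n_frames) - 0.5) / fr) * fs) + 1L)
  truth <- subject$codes[mid]
  tracks <- lapply(seq_len(config$n_annotators), function(a) {
    tr <- .jitter_boundaries(truth, config$annotator_boundary_jitter_frames)
    flip <- stats::runif(n_frames) < config$annotator_error_rate
    if (any(flip)) {
      tr[flip] <- vapply(tr[flip], function(code)
        sample(setdiff(FAABOS_CODES, code), 1L), integer(1))
    }
    tr
  })
  annotator_set(tracks, frame_rate_hz = fr)
}

#' Generate a reproducible cohort of synthetic subjects
#'
#' Subjects are independent draws with distinct per-subject channel gains
#' and gait frequencies (the source of the intra- vs inter-subject
#' generalization gap).
#'
#' @param config a [generator_config()].
#' @param n_subjects number of subjects (>= 1).
#' @param cohort_seed master seed; per-subject seeds are derived from it.
#' @param group group tag applied to all subjects.
#' @return list of `synthetic_subject` objects named by subject id.
#' @export
generate_cohort <- function(config = generator_config(), n_subjects = 4L,
                            cohort_seed = 42L, group = "control") {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  set.seed(cohort_seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, n_subjects)
  out <- lapply(seq_len(n_subjects), function(i)
    generate_subject(config, subject_seed = seeds[i],
                     subject_id = sprintf("synth%02d", i), group = group))
  names(out) <- vapply(out, function(s) s$series$subject_id, character(1))
  out
}

#' Bundle a subject's series with merged annotation ground truth
#'
#' Runs the annotation pipeline for one synthetic subject: simulate the
#' annotators, map frames to samples, merge by majority, and return the
#' dataset consumed by segmentation and classification.
#'
#' @param subject a [generate_subject()] result.
#' @param annotator_seed seed for the simulated annotators.
#' @param offset_s video-to-sensor offset passed to [align_annotations()].
#' @return list of class `subject_dataset` with `series`, `merged_codes`
#'   (per-sample FAABOS after majority fusion), `binary` (collapsed
#'   labels), `group`, and the underlying `subject`.
#' @export
subject_dataset <- function(subject, annotator_seed = 1L, offset_s = 0) {
  ann <- simulate_annotators(subject, seed = annotator_seed)
  per_sample <- align_annotations(ann, subject$series, offset_s = offset_s)
  merged <- merge_annotators(per_sample)
  structure(list(series = subject$series, merged_codes = merged,
                 binary = collapse_binary(merged), group = subject$group,
                 subject = subject),
            class = "subject_dataset")
}
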