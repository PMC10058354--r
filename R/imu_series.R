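#' Six-channel inertial recording for one subject and limb
#'
#' Container for a fixed-rate wrist IMU stream: three linear-acceleration
#' channels (`ax`, `ay`, `az`) and three angular-velocity channels
#' (`gx`, `gy`, `gz`), in device units. Sampling is assumed uniform; a time
#' column in source files is used for validation only.
#'
#' @param channels numeric matrix or data frame with n_samples rows and the
#'   six columns `ax, ay, az, gx, gy, gz` (order enforced).
#' @param subject_id character scalar identifying the subject.
#' @param limb `"affected"` (prosthesis users) or `"nondominant"` (controls).
#' @param sampling_rate_hz positive sampling rate, default 200.
#' @return an object of class `imu_series`.
#' @export
imu_series <- function(channels, subject_id = "s1",
                       limb = c("affected", "nondominant"),
                       sampling_rate_hz = 200) {
  limb <- match.arg(limb)
  if (is.data.frame(channels)) channels <- as.matrix(channels)
  if (!is.matrix(channels) || !is.numeric(channels))
    stop("`channels` must be a numeric matrix or data frame")
  if (ncol(channels) != 6L)
    stop("`channels` must have exactly 6 columns (ax, ay, az, gx, gy, gz)")
  if (is.null(colnames(channels))) {
    colnames(channels) <- IMU_CHANNELS
  } else if (!identical(colnames(channels), IMU_CHANNELS)) {
    if (!setequal(colnames(channels), IMU_CHANNELS))
      stop("channel columns must be named ", paste(IMU_CHANNELS, collapse = ", "))
    channels <- channels[, IMU_CHANNELS, drop = FALSE]
  }
  if (nrow(channels) < 1L) stop("series must contain at least one sample")
  if (anyNA(channels) || any(!is.finite(channels)))
    stop("channels contain non-finite values")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0)
    stop("`sampling_rate_hz` must be a positive scalar")
  structure(
    list(subject_id = as.character(subject_id), limb = limb,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         channels = channels),
    class = "imu_series")
}

#' Number of samples in an IMU series
#' @param series an [imu_series()].
#' @return integer sample count.
#' @export
n_samples <- function(series) {
  stopifnot(inherits(series, "imu_series"))
  nrow(series$channels)
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> subject %s (%s limb): %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$limb, n_samples(x), x$sampling_rate_hz,
              n_samples(x) / x$sampling_rate_hz))
  invisible(x)
}

#' Read an IMU stream from CSV
#'
#' Expects a header row naming exactly the seven columns
#' `t, ax, ay, az, gx, gy, gz` and a numeric body. The `t` column must be
#' strictly increasing (rows are never reordered silently); it is validated
#' and then discarded, since downstream analysis assumes a uniform rate.
#'
#' @param path path to the CSV file.
#' @param sampling_rate_hz sampling rate of the stream, default 200.
#' @inheritParams imu_series
#' @return an [imu_series()].
#' @export
read_imu_csv <- function(path, sampling_rate_hz = 200, subject_id = NULL,
                         limb = "affected") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- c("t", IMU_CHANNELS)
  if (anyDuplicated(names(df)))
    stop("format error: duplicate columns in ", path)
  if (!setequal(names(df), expected))
    stop("format error: header must name columns ",
         paste(expected, collapse = ","), "; got ",
         paste(names(df), collapse = ","))
  df <- df[, expected]
  for (nm in expected) {
    v <- df[[nm]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("parse error: non-numeric value in column '%s', row %d",
                   nm, if (is.na(bad)) 1L else bad))
    }
    if (anyNA(v)) stop(sprintf("parse error: missing value in column '%s', row %d",
                               nm, which(is.na(v))[1]))
  }
  if (nrow(df) > 1L && any(diff(df$t) <= 0))
    stop("alignment error: column 't' is not strictly increasing")
  if (is.null(subject_id))
    subject_id <- sub("\\.csv$", "", basename(path))
  imu_series(as.matrix(df[, IMU_CHANNELS]), subject_id = subject_id,
             limb = limb, sampling_rate_hz = sampling_rate_hz)
}

#' Write an IMU stream to CSV
#'
#' Inverse of [read_imu_csv()]: emits the `t,ax,ay,az,gx,gy,gz` header with
#' `t = (0:(n-1)) / sampling_rate_hz`. Round-trips preserve channel values to
#' float-printing precision.
#'
#' @param series an [imu_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(series, path) {
  stopifnot(inherits(series, "imu_series"))
  n <- n_samples(series)
  df <- data.frame(t = (seq_len(n) - 1) / series$sampling_rate_hz,
                   series$channels, check.names = FALSE)
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-frame annotation tracks from up to three video annotators
#'
#' Each track holds one five-level FAABOS code per video frame:
#' -1 unknown (arm out of view), 0 no activity, 1 nonfunctional movement,
#' 2 nontask-related functional, 3 task-related functional.
#'
#' @param tracks list of 1 to 3 equal-length integer vectors of codes.
#' @param frame_rate_hz positive video frame rate.
#' @return an object of class `annotator_set`.
#' @export
annotator_set <- function(tracks, frame_rate_hz = 30) {
  if (!is.list(tracks) || length(tracks) < 1L || length(tracks) > 3L)
    stop("`tracks` must be a list of 1-3 code vectors")
  lens <- vapply(tracks, length, integer(1))
  if (length(unique(lens)) != 1L) stop("shape error: tracks have unequal lengths")
  if (lens[1] < 1L) stop("empty-input error: tracks contain no frames")
  tracks <- lapply(tracks, function(tr) {
    tr <- as.integer(tr)
    if (anyNA(tr) || !all(tr %in% FAABOS_CODES))
      stop("domain error: codes must lie in {-1, 0, 1, 2, 3}")
    tr
  })
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("`frame_rate_hz` must be positive")
  structure(list(tracks = tracks, frame_rate_hz = as.numeric(frame_rate_hz)),
            class = "annotator_set")
}

#' @export
print.annotator_set <- function(x, ...) {
  cat(sprintf("<annotator_set> %d annotator(s), %d frames @ %g Hz\n",
              length(x$tracks), length(x$tracks[[1]]), x$frame_rate_hz))
  invisible(x)
}

#' Read annotation tracks from CSV
#'
#' Expects a header `frame,code_a1[,code_a2,code_a3]`; missing annotator
#' columns are allowed (single-annotator files are legal).
#'
#' @param path path to the CSV file.
#' @param frame_rate_hz video frame rate.
#' @return an [annotator_set()].
#' @export
read_annotation_csv <- function(path, frame_rate_hz = 30) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  code_cols <- intersect(c("code_a1", "code_a2", "code_a3"), names(df))
  if (!"frame" %in% names(df) || length(code_cols) == 0L)
    stop("format error: header must be frame,code_a1[,code_a2,code_a3]")
  annotator_set(unname(lapply(df[code_cols], as.integer)), frame_rate_hz)
}

#' Write annotation tracks to CSV
#' @param ann an [annotator_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_csv <- function(ann, path) {
  stopifnot(inherits(ann, "annotator_set"))
  df <- data.frame(frame = seq_along(ann$tracks[[1]]) - 1L)
  for (i in seq_along(ann$tracks)) df[[paste0("code_a", i)]] <- ann$tracks[[i]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map video-frame codes onto sensor samples
#'
#' Sample `i` (0-based) occurs at sensor time `i / sampling_rate_hz`; its
#' video time is that minus `offset_s`. Frame `j` covers the left-closed
#' interval `[j, j+1) / frame_rate_hz`, so a sample exactly on a frame
#' boundary takes the later frame's code. Samples falling before the first
#' or after the last frame are coded -1 (unknown).
#'
#' @param ann an [annotator_set()].
#' @param series the [imu_series()] the annotations describe.
#' @param offset_s sensor time (seconds) at which video time zero occurs.
#' @return integer matrix, `n_samples(series)` rows by one column per
#'   annotator, of per-sample FAABOS codes.
#' @export
align_annotations <- function(ann, series, offset_s = 0) {
  stopifnot(inherits(ann, "annotator_set"), inherits(series, "imu_series"))
  if (ann$frame_rate_hz > series$sampling_rate_hz)
    stop("frame rate must not exceed the sampling rate")
  n <- n_samples(series)
  nf <- length(ann$tracks[[1]])
  video_t <- (seq_len(n) - 1) / series$sampling_rate_hz - offset_s
  idx <- floor(video_t * ann$frame_rate_hz + 1e-9) + 1  # 1-based frame index
  idx[video_t < -1e-9] <- NA
  idx[idx > nf] <- NA
  out <- vapply(ann$tracks, function(tr) {
    codes <- tr[idx]
    codes[is.na(codes)] <- -1L
    codes
  }, integer(n))
  matrix(out, nrow = n,
         dimnames = list(NULL, paste0("a", seq_along(ann$tracks))))
}
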