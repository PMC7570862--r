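# Sliding-window segmentation of recordings into flattened instances.

#' Flatten a six-channel window into one feature vector
#'
#' Concatenates the six length-n channel blocks in the fixed order
#' acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z, producing a length-6n vector.
#' At the default 512-sample window this gives the 3072-feature instance
#' layout used throughout the package.
#'
#' @param acc_window,gyr_window Numeric matrices n x 3 (columns x, y, z).
#' @return Numeric vector of length 6n.
#' @seealso [unflatten_instance()]
#' @export
#' @examples
#' flatten_window(matrix(1:6, 2), matrix(7:12, 2))
flatten_window <- function(acc_window, gyr_window) {
  acc_window <- as.matrix(acc_window); gyr_window <- as.matrix(gyr_window)
  if (ncol(acc_window) != 3 || ncol(gyr_window) != 3 ||
      nrow(acc_window) != nrow(gyr_window)) {
    stop_invalid("acc and gyr windows must both be n x 3")
  }
  c(acc_window, gyr_window) # column-major: x, y, z blocks in order
}

#' Recover the six channel blocks from a flattened instance
#'
#' @param x Numeric vector of length 6n.
#' @return List with n x 3 matrices `acc` and `gyr`.
#' @export
unflatten_instance <- function(x) {
  if (length(x) %% 6 != 0) stop_invalid("length must be divisible by 6")
  n <- length(x) / 6
  list(
    acc = matrix(x[1:(3 * n)], n, 3, dimnames = list(NULL, c("acc_x", "acc_y", "acc_z"))),
    gyr = matrix(x[(3 * n + 1):(6 * n)], n, 3, dimnames = list(NULL, c("gyr_x", "gyr_y", "gyr_z")))
  )
}

#' Segment a recording with a sliding window
#'
#' Windows of `window_size` samples start at 0, step, 2*step, ... (step =
#' `round(window_size * (1 - overlap))`, half-away-from-zero rounding) while
#' the full window fits; the trailing partial window is discarded. Each
#' window is flattened with [flatten_window()] and inherits the recording's
#' label. Windows never span recordings.
#'
#' @param recording A [sensor_recording()].
#' @param window_size Window length in samples (default 512, i.e. 5 s at
#'   102.4 Hz).
#' @param overlap Fractional overlap in `[0, 1)` between consecutive windows
#'   (default 0.5).
#' @return An [instance_set()] (possibly empty) with 6 * `window_size`
#'   features per instance.
#' @export
#' @examples
#' rec <- generate_recording(default_activity_models()$standing,
#'                           duration_s = 10, sampling_rate = 102.4, seed = 1)
#' length(segment(rec)) # 3 windows: starts 0, 256, 512
segment <- function(recording, window_size = 512, overlap = 0.5) {
  stopifnot(inherits(recording, "sensor_recording"))
  if (window_size < 1) stop_invalid("window_size must be >= 1")
  if (overlap < 0 || overlap >= 1) stop_invalid("overlap must be in [0, 1)")
  step <- round_half_up(window_size * (1 - overlap))
  if (step < 1) stop_invalid("window_size and overlap give a step < 1")
  n_samples <- nrow(recording$acc)
  starts <- if (n_samples >= window_size) {
    seq(0, n_samples - window_size, by = step)
  } else {
    integer(0)
  }
  X <- matrix(0, length(starts), 6 * window_size)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1):(starts[i] + window_size)
    X[i, ] <- flatten_window(recording$acc[idx, , drop = FALSE],
                             recording$gyr[idx, , drop = FALSE])
  }
  instance_set(
    X,
    rep(recording$activity, length(starts)),
    data.frame(
      subject_id = rep(recording$subject_id, length(starts)),
      bout = rep(recording$bout, length(starts)),
      start = as.integer(starts)
    )
  )
}

## round() in R is half-to-even; window stepping uses half-away-from-zero.
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Segment a list of recordings into one instance set
#'
#' @param recordings List of [sensor_recording()] objects.
#' @inheritParams segment
#' @return The row-bound [instance_set()] over all recordings.
#' @export
segment_recordings <- function(recordings, window_size = 512, overlap = 0.5) {
  sets <- lapply(recordings, segment, window_size = window_size, overlap = overlap)
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  if (!length(sets)) {
    return(instance_set(matrix(0, 0, 6 * window_size), character(0)))
  }
  bind_instances(sets)
}
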