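# Synthetic study generator: labelled six-axis recordings emulating a
# multi-subject lab protocol.

#' Construct a sensor recording
#'
#' One continuous labelled six-channel stream for a single subject/activity
#' bout: tri-axial accelerometer (g) and tri-axial gyroscope (deg/s) sampled
#' at a common rate.
#'
#' @param subject_id Character subject identifier.
#' @param activity One of [activity_labels()].
#' @param sampling_rate Samples per second (> 0).
#' @param acc,gyr Numeric matrices with 3 columns (x, y, z) and one row per
#'   sample; both must have the same number of rows.
#' @param bout Integer bout (repeat) index, used to keep rows of distinct
#'   bouts of the same activity separate in CSV files.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(subject_id, activity, sampling_rate, acc, gyr,
                             bout = 1L) {
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  if (ncol(acc) != 3 || ncol(gyr) != 3) {
    stop_invalid("acc and gyr must each have 3 columns")
  }
  if (nrow(acc) != nrow(gyr)) {
    stop_invalid("acc and gyr must have the same number of samples")
  }
  if (!activity %in% activity_labels()) {
    stop_invalid("unknown activity label: ", activity)
  }
  if (sampling_rate <= 0) stop_invalid("sampling_rate must be > 0")
  colnames(acc) <- c("acc_x", "acc_y", "acc_z")
  colnames(gyr) <- c("gyr_x", "gyr_y", "gyr_z")
  structure(
    list(
      subject_id = as.character(subject_id), activity = activity,
      bout = as.integer(bout), sampling_rate = sampling_rate,
      acc = acc, gyr = gyr
    ),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf(
    "<sensor_recording> subject %s, %s (bout %d): %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$activity, x$bout, nrow(x$acc), x$sampling_rate,
    nrow(x$acc) / x$sampling_rate
  ))
  invisible(x)
}

#' Number of samples in a recording
#' @param x A `sensor_recording`.
#' @param ... Unused.
#' @export
length.sensor_recording <- function(x) nrow(x$acc)

## Logistic ramp weight in [0,1], centred mid-bout, rising over `ramp_s`
## seconds. Scaled so the 2%..98% rise spans the ramp duration.
logistic_ramp <- function(t, duration_s, ramp_s) {
  centre <- duration_s / 2
  rate <- 2 * log(49) / ramp_s
  stats::plogis(rate * (t - centre))
}

#' Generate one synthetic recording
#'
#' Simulates a single activity bout from its [activity_model()]: static
#' activities are baseline offset plus Gaussian noise; dynamic activities add
#' a per-channel sinusoid with a random common phase; transitional activities
#' follow a smooth logistic ramp from the start posture to the end posture
#' over the model's ramp duration, centred in the bout, plus noise.
#' Deterministic under `seed`.
#'
#' @param model An [activity_model()].
#' @param duration_s Bout duration in seconds (> 0).
#' @param sampling_rate Sampling rate in Hz (> 0); `round(duration_s *
#'   sampling_rate)` samples are produced.
#' @param seed Integer seed.
#' @param subject_id,bout Provenance fields stored on the recording.
#' @return A [sensor_recording()].
#' @export
#' @examples
#' rec <- generate_recording(default_activity_models()$walking,
#'                           duration_s = 5, sampling_rate = 102.4, seed = 1)
#' length(rec) # 512 samples
generate_recording <- function(model, duration_s, sampling_rate, seed,
                               subject_id = "S01", bout = 1L) {
  if (!inherits(model, "activity_model")) stop_invalid("model must be an activity_model")
  if (duration_s <= 0) stop_invalid("duration_s must be > 0")
  if (sampling_rate <= 0) stop_invalid("sampling_rate must be > 0")
  n <- round(duration_s * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  x <- matrix(0, n, 6)
  with_seed(seed, {
    if (model$group == "transitional") {
      w <- logistic_ramp(t, duration_s, model$ramp_s)
      for (j in 1:6) {
        x[, j] <- model$baseline[j] + w * (model$end_baseline[j] - model$baseline[j])
      }
    } else {
      x <- matrix(model$baseline, n, 6, byrow = TRUE)
      if (model$group == "dynamic" && model$freq_hz > 0) {
        phase <- stats::runif(1, 0, 2 * pi)
        carrier <- sin(2 * pi * model$freq_hz * t + phase)
        for (j in 1:6) x[, j] <- x[, j] + model$amplitude[j] * carrier
      }
    }
    for (j in 1:6) {
      if (model$noise_sd[j] > 0) x[, j] <- x[, j] + stats::rnorm(n, 0, model$noise_sd[j])
    }
  })
  sensor_recording(subject_id, model$activity, sampling_rate,
                   acc = x[, 1:3, drop = FALSE], gyr = x[, 4:6, drop = FALSE],
                   bout = bout)
}

#' Define a study protocol
#'
#' The acquisition schedule the synthetic study follows: how many subjects,
#' how long each continuous (static/dynamic) bout lasts, how long each
#' transitional bout lasts and how often it is repeated, the sampling rate,
#' and the master seed from which all per-recording seeds are derived.
#'
#' Defaults emulate a wrist-sensor lab protocol: 10 subjects, one 300 s bout
#' per continuous activity, and 12 repeats of an 8 s hold–ramp–hold bout per
#' transitional activity. With the default 512-sample / 50%-overlap windows
#' this yields roughly a 5:1 instance imbalance between continuous and
#' transitional classes (about 1190 vs 240 windows per class).
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param continuous_duration_s Continuous bout duration, seconds (> 0).
#' @param transitional_duration_s Transitional bout duration, seconds (> 0).
#' @param continuous_repeats,transitional_repeats Bouts per subject and
#'   activity (>= 1).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param seed Master seed; per-recording seeds are spawned from it
#'   deterministically, so studies of any size are reproducible.
#' @return An object of class `study_protocol`.
#' @export
study_protocol <- function(n_subjects = 10,
                           continuous_duration_s = 300,
                           transitional_duration_s = 8,
                           continuous_repeats = 1,
                           transitional_repeats = 12,
                           sampling_rate = 102.4,
                           seed = 20200905) {
  if (continuous_duration_s <= 0 || transitional_duration_s <= 0) {
    stop_invalid("bout durations must be > 0")
  }
  if (continuous_repeats < 1 || transitional_repeats < 1) {
    stop_invalid("repeats must be >= 1")
  }
  if (sampling_rate <= 0) stop_invalid("sampling_rate must be > 0")
  if (n_subjects < 0) stop_invalid("n_subjects must be >= 0")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      continuous_duration_s = continuous_duration_s,
      transitional_duration_s = transitional_duration_s,
      continuous_repeats = as.integer(continuous_repeats),
      transitional_repeats = as.integer(transitional_repeats),
      sampling_rate = sampling_rate,
      seed = as.integer(seed)
    ),
    class = "study_protocol"
  )
}

#' Generate a full synthetic study
#'
#' Emits one [sensor_recording()] per (subject, activity, repeat) under the
#' protocol: continuous activities (static and dynamic groups) get long
#' bouts, transitional activities short repeated bouts. Each recording's seed
#' is derived deterministically from the protocol's master seed and the
#' subject/activity/repeat indices.
#'
#' @param protocol A [study_protocol()].
#' @param models Named list covering all 12 activities, as from
#'   [default_activity_models()].
#' @return List of [sensor_recording()] objects.
#' @export
#' @examples
#' tiny <- study_protocol(n_subjects = 1, continuous_duration_s = 10,
#'                        transitional_repeats = 2)
#' length(generate_study(tiny, default_activity_models()))
generate_study <- function(protocol, models = default_activity_models()) {
  stopifnot(inherits(protocol, "study_protocol"))
  missing <- setdiff(activity_labels(), names(models))
  if (length(missing)) {
    stop_invalid("missing activity model(s): ", paste(missing, collapse = ", "))
  }
  recs <- list()
  labels <- activity_labels()
  for (s in seq_len(protocol$n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (a in seq_along(labels)) {
      model <- models[[labels[a]]]
      transitional <- model$group == "transitional"
      duration <- if (transitional) protocol$transitional_duration_s else protocol$continuous_duration_s
      repeats <- if (transitional) protocol$transitional_repeats else protocol$continuous_repeats
      for (r in seq_len(repeats)) {
        recs[[length(recs) + 1L]] <- generate_recording(
          model, duration, protocol$sampling_rate,
          seed = child_seed(protocol$seed, s, a, r),
          subject_id = sid, bout = r
        )
      }
    }
  }
  recs
}
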