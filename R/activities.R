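# Activity vocabulary and per-activity signal models for the synthetic
# six-axis generator.

#' The twelve daily-activity labels
#'
#' The recognised activity vocabulary: three static postures, three dynamic
#' (rhythmic) activities and six postural transitions. All labelling,
#' segmentation and classification in the package uses this ordering.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' activity_labels()
activity_labels <- function() {
  c(
    "standing", "sleeping", "watching_tv",
    "walking", "running", "sweeping",
    "stand_to_sit", "sit_to_stand", "stand_to_walk",
    "walk_to_stand", "lie_to_sit", "sit_to_lie"
  )
}

#' Activity group (static, dynamic or transitional) for each label
#'
#' @param activity Character vector of activity labels.
#' @return Character vector of groups, one of `"static"`, `"dynamic"`,
#'   `"transitional"`.
#' @export
#' @examples
#' activity_group(c("standing", "running", "sit_to_lie"))
activity_group <- function(activity) {
  groups <- c(rep("static", 3), rep("dynamic", 3), rep("transitional", 6))
  names(groups) <- activity_labels()
  unknown <- setdiff(activity, activity_labels())
  if (length(unknown)) {
    stop_invalid("unknown activity label(s): ", paste(unknown, collapse = ", "))
  }
  unname(groups[activity])
}

channel_names <- function() {
  c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
}

#' Construct a per-activity signal model
#'
#' An `activity_model` is the statistical recipe the synthetic generator uses
#' for one activity: a per-channel baseline offset plus Gaussian noise, with a
#' sinusoidal component for dynamic activities and a logistic ramp between two
#' posture offsets for transitional activities. Channels are ordered
#' `acc_x, acc_y, acc_z` (in g) then `gyr_x, gyr_y, gyr_z` (in deg/s).
#'
#' @param activity One of [activity_labels()].
#' @param group `"static"`, `"dynamic"` or `"transitional"`.
#' @param baseline Numeric length-6 per-channel offset. For transitional
#'   models this is the start posture.
#' @param noise_sd Numeric length-6 nonnegative per-channel noise standard
#'   deviation.
#' @param freq_hz Oscillation frequency in Hz (dynamic models; 0 otherwise).
#' @param amplitude Numeric length-6 oscillation amplitude (dynamic models;
#'   must be all zero for static models).
#' @param end_baseline Numeric length-6 end posture (transitional models).
#' @param ramp_s Ramp duration in seconds (transitional models; > 0).
#' @return An object of class `activity_model`.
#' @seealso [default_activity_models()], [generate_recording()]
#' @export
activity_model <- function(activity,
                           group = activity_group(activity),
                           baseline = numeric(6),
                           noise_sd = rep(0.01, 6),
                           freq_hz = 0,
                           amplitude = numeric(6),
                           end_baseline = NULL,
                           ramp_s = NULL) {
  group <- match.arg(group, c("static", "dynamic", "transitional"))
  stopifnot(
    length(baseline) == 6, length(noise_sd) == 6, length(amplitude) == 6
  )
  if (any(noise_sd < 0)) stop_invalid("noise_sd must be nonnegative")
  if (group == "static" && any(amplitude != 0)) {
    stop_invalid("static models must have zero oscillation amplitude")
  }
  if (group == "transitional") {
    if (is.null(end_baseline) || length(end_baseline) != 6) {
      stop_invalid("transitional models need a length-6 end_baseline")
    }
    if (is.null(ramp_s) || ramp_s <= 0) {
      stop_invalid("transitional models need ramp_s > 0")
    }
  }
  structure(
    list(
      activity = activity, group = group,
      baseline = as.numeric(baseline), noise_sd = as.numeric(noise_sd),
      freq_hz = freq_hz, amplitude = as.numeric(amplitude),
      end_baseline = if (!is.null(end_baseline)) as.numeric(end_baseline),
      ramp_s = ramp_s
    ),
    class = "activity_model"
  )
}

## Canonical wrist-posture accelerometer offsets (g). Gravity sits on one
## axis for upright postures and rotates toward x when lying.
posture_acc <- function(which) {
  switch(which,
    stand = c(0, 0, 1),
    sit = c(0, 0.60, 0.80),
    lie = c(1, 0, 0),
    walk = c(0, 0.25, 0.90)
  )
}

#' Default signal models for the twelve activities
#'
#' Defaults emulate a wrist-worn sensor at an amplitude range of about
#' \eqn{\pm 2} g: static postures are a gravity-dominated offset plus small
#' noise, dynamic activities add a class-specific sinusoid on both sensors,
#' and transitions ramp smoothly between two postures over 3 s. Noise levels
#' order the groups so that per-window signal variance ranks
#' static < transitional plateau < dynamic.
#'
#' @return Named list of 12 [activity_model()] objects.
#' @export
#' @examples
#' names(default_activity_models())
default_activity_models <- function() {
  m <- list(
    standing = activity_model("standing",
      baseline = c(posture_acc("stand"), 0, 0, 0),
      noise_sd = c(rep(0.02, 3), rep(1.5, 3))
    ),
    sleeping = activity_model("sleeping",
      baseline = c(posture_acc("lie"), 0, 0, 0),
      noise_sd = c(rep(0.03, 3), rep(2, 3))
    ),
    watching_tv = activity_model("watching_tv",
      baseline = c(posture_acc("sit"), 0, 0, 0),
      noise_sd = c(rep(0.05, 3), rep(4, 3))
    ),
    walking = activity_model("walking",
      baseline = c(posture_acc("stand"), 0, 0, 0),
      noise_sd = c(rep(0.05, 3), rep(5, 3)),
      freq_hz = 2.0, amplitude = c(0.25, 0.25, 0.35, 60, 40, 30)
    ),
    running = activity_model("running",
      baseline = c(posture_acc("stand"), 0, 0, 0),
      noise_sd = c(rep(0.10, 3), rep(10, 3)),
      freq_hz = 2.8, amplitude = c(0.8, 0.6, 1.0, 150, 100, 80)
    ),
    sweeping = activity_model("sweeping",
      baseline = c(0, 0.30, 0.95, 0, 0, 0),
      noise_sd = c(rep(0.06, 3), rep(6, 3)),
      freq_hz = 0.9, amplitude = c(0.35, 0.20, 0.15, 70, 50, 25)
    )
  )
  transitions <- list(
    stand_to_sit = c("stand", "sit"),
    sit_to_stand = c("sit", "stand"),
    stand_to_walk = c("stand", "walk"),
    walk_to_stand = c("walk", "stand"),
    lie_to_sit = c("lie", "sit"),
    sit_to_lie = c("sit", "lie")
  )
  for (act in names(transitions)) {
    ends <- transitions[[act]]
    m[[act]] <- activity_model(act,
      baseline = c(posture_acc(ends[1]), 0, 0, 0),
      end_baseline = c(posture_acc(ends[2]), 0, 0, 0),
      noise_sd = c(rep(0.04, 3), rep(5, 3)),
      ramp_s = 3
    )
  }
  m[activity_labels()]
}

#' @export
print.activity_model <- function(x, ...) {
  cat("<activity_model>", x$activity, sprintf("(%s)\n", x$group))
  cat("  baseline:", paste(signif(x$baseline, 3), collapse = " "), "\n")
  if (x$group == "dynamic") {
    cat("  oscillation:", x$freq_hz, "Hz, amplitude",
        paste(signif(x$amplitude, 3), collapse = " "), "\n")
  }
  if (x$group == "transitional") {
    cat("  ramp:", x$ramp_s, "s to",
        paste(signif(x$end_baseline, 3), collapse = " "), "\n")
  }
  invisible(x)
}
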