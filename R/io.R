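# CSV interchange for sensor recordings and segmented instance tables.

.datatable.aware <- TRUE

SENSOR_CSV_COLUMNS <- c(
  "subject_id", "activity", "bout", "t",
  "acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z"
)

#' Write sensor recordings to CSV
#'
#' One row per sample with columns `subject_id, activity, bout, t, acc_x,
#' acc_y, acc_z, gyr_x, gyr_y, gyr_z`; a recording occupies contiguous rows
#' sharing (subject_id, activity, bout). Values are written with full double
#' precision (15 significant digits), so [read_sensor_csv()] round-trips the
#' recordings.
#'
#' @param recordings A `sensor_recording` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(recordings, path) {
  if (inherits(recordings, "sensor_recording")) recordings <- list(recordings)
  tabs <- lapply(recordings, function(r) {
    n <- nrow(r$acc)
    data.table::data.table(
      subject_id = rep(r$subject_id, n),
      activity = rep(r$activity, n),
      bout = rep(r$bout, n),
      t = (seq_len(n) - 1) / r$sampling_rate,
      r$acc, r$gyr
    )
  })
  tab <- if (length(tabs)) data.table::rbindlist(tabs) else {
    empty <- as.list(rep(NA_real_, 10)); names(empty) <- SENSOR_CSV_COLUMNS
    data.table::as.data.table(empty)[0]
  }
  data.table::fwrite(tab, path)
  invisible(path)
}

#' Read sensor recordings from CSV
#'
#' Inverse of [write_sensor_csv()]. Rows are grouped into recordings by
#' contiguous (subject_id, activity, bout); the sampling rate is either given
#' or recovered from the median spacing of the `t` column.
#'
#' @param path CSV file path.
#' @param sampling_rate Sampling rate in Hz, or `NULL` to infer from `t`.
#' @return List of [sensor_recording()] objects (empty list for a file with a
#'   valid header and no rows).
#' @export
read_sensor_csv <- function(path, sampling_rate = NULL) {
  tab <- data.table::fread(path, header = TRUE, colClasses = list(
    character = "subject_id"
  ))
  if (!identical(names(tab), SENSOR_CSV_COLUMNS)) {
    stop_invalid(
      "malformed header in ", path, ": expected columns ",
      paste(SENSOR_CSV_COLUMNS, collapse = ", "), " but found ",
      paste(names(tab), collapse = ", ")
    )
  }
  if (nrow(tab) == 0) return(list())
  bad <- which(!tab$activity %in% activity_labels())
  if (length(bad)) {
    stop_invalid(
      "unknown activity label '", tab$activity[bad[1]],
      "' at data row ", bad[1], " of ", path
    )
  }
  num_cols <- SENSOR_CSV_COLUMNS[4:10]
  for (cn in num_cols) {
    v <- tab[[cn]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad)) {
        stop_invalid(
          "non-numeric value '", v[bad[1]], "' in column ", cn,
          " at data row ", bad[1], " of ", path
        )
      }
      data.table::set(tab, j = cn, value = conv)
    }
  }
  ## contiguous runs of (subject_id, activity, bout) are recordings
  key <- paste(tab$subject_id, tab$activity, tab$bout, sep = "\r")
  run <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  lapply(split(seq_len(nrow(tab)), run), function(idx) {
    part <- tab[idx]
    rate <- sampling_rate
    if (is.null(rate)) {
      rate <- if (nrow(part) > 1) 1 / stats::median(diff(part$t)) else 1
    }
    sensor_recording(
      part$subject_id[1], part$activity[1], rate,
      acc = as.matrix(part[, c("acc_x", "acc_y", "acc_z")]),
      gyr = as.matrix(part[, c("gyr_x", "gyr_y", "gyr_z")]),
      bout = part$bout[1]
    )
  }) |> unname()
}

#' Write an instance set to CSV
#'
#' Feature columns `f0000...` (zero-padded index), then `label`, `subject_id`,
#' `bout` and `start` provenance columns.
#'
#' @param set An [instance_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instances_csv <- function(set, path) {
  stopifnot(inherits(set, "instance_set"))
  X <- set$X
  colnames(X) <- sprintf("f%04d", seq_len(ncol(X)) - 1)
  tab <- data.table::data.table(
    X,
    label = as.character(set$label),
    subject_id = set$source$subject_id,
    bout = set$source$bout,
    start = set$source$start
  )
  data.table::fwrite(tab, path)
  invisible(path)
}

#' Read an instance set from CSV
#'
#' @param path CSV file written by [write_instances_csv()].
#' @return An [instance_set()].
#' @export
read_instances_csv <- function(path) {
  tab <- data.table::fread(path, header = TRUE)
  feat <- grep("^f[0-9]+$", names(tab), value = TRUE)
  need <- c("label", "subject_id", "bout", "start")
  if (!length(feat) || !all(need %in% names(tab))) {
    stop_invalid("malformed instance CSV: ", path)
  }
  instance_set(
    X = as.matrix(tab[, feat, with = FALSE]),
    label = tab$label,
    source = data.frame(
      subject_id = as.character(tab$subject_id),
      bout = tab$bout, start = tab$start
    )
  )
}
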