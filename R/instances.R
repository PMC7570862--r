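# Instance sets: labelled collections of flattened windows.

#' Construct an instance set
#'
#' The unit of resampling, splitting and training: a numeric feature matrix
#' with one row per segmented window, a class label per row, and provenance
#' (subject, bout, window start sample) per row.
#'
#' @param X Numeric matrix, instances in rows.
#' @param label Character or factor of per-row activity labels; coerced to a
#'   factor over [activity_labels()] plus any extra levels present.
#' @param source Data frame with columns `subject_id`, `bout`, `start`
#'   (0-based window start sample), or `NULL` for an empty default.
#' @return An object of class `instance_set`.
#' @export
instance_set <- function(X, label, source = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(label)) {
    stop_invalid("label length must equal number of instance rows")
  }
  if (is.factor(label)) {
    lev <- levels(label)
  } else {
    lev <- union(activity_labels(), unique(label))
    lev <- lev[lev %in% c(activity_labels(), unique(as.character(label)))]
  }
  label <- factor(as.character(label), levels = lev)
  if (anyNA(label)) stop_invalid("labels outside the factor levels")
  if (is.null(source)) {
    source <- data.frame(
      subject_id = rep(NA_character_, nrow(X)),
      bout = rep(NA_integer_, nrow(X)),
      start = rep(NA_integer_, nrow(X))
    )
  }
  stopifnot(nrow(source) == nrow(X))
  dimnames(X) <- NULL
  structure(
    list(X = X, label = label, source = source),
    class = "instance_set"
  )
}

#' Number of instances
#' @param x An `instance_set`.
#' @export
length.instance_set <- function(x) nrow(x$X)

#' Per-class instance counts
#'
#' @param set An [instance_set()].
#' @param drop_empty Drop classes with zero instances.
#' @return Named integer vector in class-level order.
#' @export
#' @examples
#' s <- instance_set(matrix(0, 3, 2), c("standing", "standing", "running"))
#' class_counts(s, drop_empty = TRUE)
class_counts <- function(set, drop_empty = FALSE) {
  counts <- table(set$label)
  out <- as.integer(counts); names(out) <- names(counts)
  if (drop_empty) out <- out[out > 0]
  out
}

#' Subset an instance set by row index
#'
#' @param set An [instance_set()].
#' @param idx Integer row indices (may repeat, for resampling).
#' @return An [instance_set()] with the selected rows, label levels kept.
#' @export
subset_instances <- function(set, idx) {
  instance_set(
    set$X[idx, , drop = FALSE],
    set$label[idx],
    set$source[idx, , drop = FALSE]
  )
}

#' Concatenate instance sets
#'
#' @param ... `instance_set` objects with identical feature width and levels.
#' @return The row-bound [instance_set()].
#' @export
bind_instances <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "instance_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1)
  widths <- vapply(sets, function(s) ncol(s$X), integer(1))
  if (length(unique(widths)) != 1) stop_invalid("feature widths differ")
  instance_set(
    do.call(rbind, lapply(sets, function(s) s$X)),
    factor(unlist(lapply(sets, function(s) as.character(s$label))),
           levels = levels(sets[[1]]$label)),
    do.call(rbind, lapply(sets, function(s) s$source))
  )
}

#' Restrict instances to one sensor's channel blocks
#'
#' Instances are flattened as six contiguous per-channel blocks
#' (acc x/y/z then gyr x/y/z). `"acc"` keeps the first three blocks,
#' `"gyr"` the last three, `"acc+gyr"` all six, so the instance length drops
#' from 6n to 3n for a single sensor.
#'
#' @param set An [instance_set()] with feature count divisible by 6.
#' @param channels `"acc+gyr"`, `"acc"` or `"gyr"`.
#' @return An [instance_set()].
#' @export
select_channels <- function(set, channels = c("acc+gyr", "acc", "gyr")) {
  channels <- match.arg(channels)
  if (channels == "acc+gyr") return(set)
  d <- ncol(set$X)
  if (d %% 6 != 0) stop_invalid("feature count is not divisible by 6")
  n <- d / 6
  keep <- if (channels == "acc") 1:(3 * n) else (3 * n + 1):d
  instance_set(set$X[, keep, drop = FALSE], set$label, set$source)
}

#' @export
print.instance_set <- function(x, ...) {
  cat(sprintf(
    "<instance_set> %d instances x %d features, %d classes\n",
    nrow(x$X), ncol(x$X), sum(class_counts(x) > 0)
  ))
  counts <- class_counts(x, drop_empty = TRUE)
  if (length(counts)) print(counts)
  invisible(x)
}
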