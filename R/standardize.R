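# Feature standardization: per-feature z-score, then rescale to [0, 1].

#' Fit standardization parameters on a training set
#'
#' Per feature, records the training mean and standard deviation, and the
#' min/max of the z-scored training values. [apply_standardizer()] z-scores
#' with these statistics and affinely rescales the z-values into `[0, 1]`
#' (the domain the autoencoder's cross-entropy reconstruction loss requires),
#' clipping out-of-range validation/test values. Features with zero training
#' variance map to the midpoint 0.5.
#'
#' @param train A non-empty [instance_set()].
#' @return An object of class `standardizer`.
#' @export
fit_standardizer <- function(train) {
  stopifnot(inherits(train, "instance_set"))
  if (nrow(train$X) == 0) stop_invalid("cannot fit a standardizer on an empty set")
  mu <- colMeans(train$X)
  ## population sd (divisor n), consistent with treating the train set as the
  ## reference distribution
  sigma <- sqrt(colMeans(train$X^2) - mu^2)
  sigma[sigma < 0] <- 0 # guard tiny negative round-off
  ok <- sigma > 0
  z_min <- rep(0, length(mu)); z_max <- rep(0, length(mu))
  if (any(ok)) {
    Z <- sweep(sweep(train$X[, ok, drop = FALSE], 2, mu[ok]), 2, sigma[ok], "/")
    z_min[ok] <- apply(Z, 2, min)
    z_max[ok] <- apply(Z, 2, max)
  }
  structure(
    list(mean = mu, sd = sigma, z_min = z_min, z_max = z_max),
    class = "standardizer"
  )
}

#' Apply (or invert) a fitted standardizer
#'
#' @param params A `standardizer` from [fit_standardizer()].
#' @param set An [instance_set()] with the same feature count.
#' @return An [instance_set()] with all features in `[0, 1]`.
#' @export
apply_standardizer <- function(params, set) {
  stopifnot(inherits(params, "standardizer"), inherits(set, "instance_set"))
  if (ncol(set$X) != length(params$mean)) {
    stop_invalid(
      "standardizer was fitted on ", length(params$mean),
      " features but the set has ", ncol(set$X)
    )
  }
  X <- set$X
  out <- matrix(0.5, nrow(X), ncol(X))
  ok <- params$sd > 0 & (params$z_max - params$z_min) > 0
  if (any(ok)) {
    Z <- sweep(sweep(X[, ok, drop = FALSE], 2, params$mean[ok]), 2, params$sd[ok], "/")
    R <- sweep(sweep(Z, 2, params$z_min[ok]), 2,
               (params$z_max - params$z_min)[ok], "/")
    out[, ok] <- clip01(R)
  }
  instance_set(out, set$label, set$source)
}

#' Invert the standardizer on standardized values
#'
#' Maps `[0, 1]` features back to the original scale (exact for training
#' values, since those are never clipped). Zero-variance features recover
#' their constant training value.
#'
#' @inheritParams apply_standardizer
#' @return An [instance_set()] on the original feature scale.
#' @export
invert_standardizer <- function(params, set) {
  stopifnot(inherits(params, "standardizer"), inherits(set, "instance_set"))
  X <- set$X
  out <- matrix(rep(params$mean, each = nrow(X)), nrow(X))
  ok <- params$sd > 0 & (params$z_max - params$z_min) > 0
  if (any(ok)) {
    Z <- sweep(X[, ok, drop = FALSE], 2, (params$z_max - params$z_min)[ok], "*")
    Z <- sweep(Z, 2, params$z_min[ok], "+")
    out[, ok] <- sweep(sweep(Z, 2, params$sd[ok], "*"), 2, params$mean[ok], "+")
  }
  instance_set(out, set$label, set$source)
}

#' Random 6:2:2 train/validation/test split
#'
#' Permutes the instances under `seed` and cuts at `round(r1 * N)` and
#' `round((r1 + r2) * N)`. In stratified mode the same cuts are applied
#' class by class, keeping every class's proportions.
#'
#' @param set An [instance_set()].
#' @param ratios Positive length-3 vector summing to 1 (default
#'   `c(0.6, 0.2, 0.2)`).
#' @param seed Integer seed.
#' @param stratified Split each class separately (default `FALSE`).
#' @return List of class `split_set` with elements `train`, `validation`,
#'   `test` (instance sets) and `ratios`.
#' @export
#' @examples
#' s <- instance_set(matrix(rnorm(20), 10), rep(c("standing", "running"), 5))
#' sapply(split_instances(s, seed = 1)[1:3], length) # 6, 2, 2
split_instances <- function(set, ratios = c(0.6, 0.2, 0.2), seed = NULL,
                            stratified = FALSE) {
  stopifnot(inherits(set, "instance_set"))
  if (length(ratios) != 3 || any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-8) {
    stop_invalid("ratios must be 3 positive numbers summing to 1")
  }
  cut_indices <- function(n, perm) {
    c1 <- round(ratios[1] * n)
    c2 <- round((ratios[1] + ratios[2]) * n)
    list(
      train = perm[seq_len(c1)],
      validation = if (c2 > c1) perm[(c1 + 1):c2] else integer(0),
      test = if (n > c2) perm[(c2 + 1):n] else integer(0)
    )
  }
  parts <- with_seed(seed, {
    if (stratified) {
      per_class <- lapply(split(seq_len(length(set)), set$label), function(idx) {
        if (!length(idx)) {
          return(list(train = integer(0), validation = integer(0), test = integer(0)))
        }
        cut_indices(length(idx), idx[sample.int(length(idx))])
      })
      list(
        train = unlist(lapply(per_class, `[[`, "train"), use.names = FALSE),
        validation = unlist(lapply(per_class, `[[`, "validation"), use.names = FALSE),
        test = unlist(lapply(per_class, `[[`, "test"), use.names = FALSE)
      )
    } else {
      cut_indices(length(set), sample.int(length(set)))
    }
  })
  structure(
    list(
      train = subset_instances(set, parts$train),
      validation = subset_instances(set, parts$validation),
      test = subset_instances(set, parts$test),
      ratios = ratios
    ),
    class = "split_set"
  )
}

#' @export
print.split_set <- function(x, ...) {
  cat(sprintf(
    "<split_set> train %d / validation %d / test %d (ratios %s)\n",
    length(x$train), length(x$validation), length(x$test),
    paste(x$ratios, collapse = ":")
  ))
  invisible(x)
}
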