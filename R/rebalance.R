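# Class rebalancing: random over/under-sampling and SMOTE.

#' Describe a resampling plan
#'
#' @param method `"none"`, `"oversample"`, `"undersample"` or `"smote"`.
#' @param target Per-class target count, or `NULL` for the default (the
#'   largest class count for oversample/SMOTE, the smallest for undersample).
#' @param smote_k Number of nearest same-class neighbours SMOTE interpolates
#'   toward (default 5; capped at class size − 1 at run time).
#' @param seed Integer seed.
#' @param interpolation SMOTE synthesis rule: `"componentwise"` (default)
#'   emits `x + r * (xn − x)`; `"literal"` adds the scalar Euclidean distance
#'   times r to every component, for fidelity experiments.
#' @return An object of class `resample_plan`.
#' @export
resample_plan <- function(method = c("none", "oversample", "undersample", "smote"),
                          target = NULL, smote_k = 5, seed = NULL,
                          interpolation = c("componentwise", "literal")) {
  method <- match.arg(method)
  interpolation <- match.arg(interpolation)
  if (!is.null(target) && target < 1) stop_invalid("target must be >= 1")
  if (smote_k < 1) stop_invalid("smote_k must be >= 1")
  structure(
    list(method = method, target = target, smote_k = smote_k, seed = seed,
         interpolation = interpolation),
    class = "resample_plan"
  )
}

present_counts <- function(set) class_counts(set, drop_empty = TRUE)

#' Random oversampling to equal class counts
#'
#' Every class is brought to the target count (the largest class count by
#' default) by duplicating uniformly-with-replacement chosen instances; all
#' originals are retained.
#'
#' @param set An [instance_set()] with no empty class among its observed
#'   labels.
#' @param plan A [resample_plan()]; its `target` and `seed` are honoured.
#' @return A balanced [instance_set()].
#' @export
random_oversample <- function(set, plan = resample_plan("oversample")) {
  counts <- present_counts(set)
  if (!length(counts)) return(set)
  target <- plan$target %||% max(counts)
  idx_by_class <- split(seq_len(length(set)), set$label, drop = TRUE)
  extra <- with_seed(plan$seed, {
    unlist(lapply(names(idx_by_class), function(cl) {
      idx <- idx_by_class[[cl]]
      need <- target - length(idx)
      if (need < 0) {
        stop_invalid("class ", cl, " exceeds the oversampling target")
      }
      if (need == 0) return(integer(0))
      idx[sample.int(length(idx), need, replace = TRUE)]
    }), use.names = FALSE)
  })
  subset_instances(set, c(seq_len(length(set)), extra))
}

#' Random undersampling to equal class counts
#'
#' Every class is reduced to the target count (the smallest class count by
#' default) by keeping a uniform without-replacement subset.
#'
#' @inheritParams random_oversample
#' @return A balanced [instance_set()] contained in the input.
#' @export
random_undersample <- function(set, plan = resample_plan("undersample")) {
  counts <- present_counts(set)
  if (!length(counts)) return(set)
  target <- plan$target %||% min(counts)
  idx_by_class <- split(seq_len(length(set)), set$label, drop = TRUE)
  keep <- with_seed(plan$seed, {
    unlist(lapply(names(idx_by_class), function(cl) {
      idx <- idx_by_class[[cl]]
      if (target > length(idx)) {
        stop_invalid("undersampling target ", target,
                     " exceeds the size of class ", cl)
      }
      sort(idx[sample.int(length(idx), target)])
    }), use.names = FALSE)
  })
  subset_instances(set, sort(keep))
}

#' SMOTE oversampling to equal class counts
#'
#' For each class below the target, synthetic instances are created by
#' choosing a class member `x` uniformly, one of its `smote_k` nearest
#' same-class neighbours `xn` (Euclidean distance) uniformly, and a single
#' `r` uniform on `[0, 1)`, emitting `x + r * (xn − x)` — a point on the
#' segment between the two parents. All originals are retained.
#'
#' @inheritParams random_oversample
#' @return A balanced [instance_set()]; synthetic rows carry the base
#'   instance's provenance.
#' @export
smote <- function(set, plan = resample_plan("smote")) {
  counts <- present_counts(set)
  if (!length(counts)) return(set)
  target <- plan$target %||% max(counts)
  idx_by_class <- split(seq_len(length(set)), set$label, drop = TRUE)
  pieces <- with_seed(plan$seed, {
    lapply(names(idx_by_class), function(cl) {
      idx <- idx_by_class[[cl]]
      need <- target - length(idx)
      if (need <= 0) return(NULL)
      if (length(idx) < 2) {
        stop_invalid("SMOTE needs >= 2 instances in class ", cl)
      }
      Xc <- set$X[idx, , drop = FALSE]
      k <- min(plan$smote_k, length(idx) - 1)
      D <- as.matrix(stats::dist(Xc))
      diag(D) <- Inf
      nn <- t(matrix(apply(D, 1, function(row) order(row)[seq_len(k)]), nrow = k))
      base <- sample.int(length(idx), need, replace = TRUE)
      pick <- nn[cbind(base, sample.int(k, need, replace = TRUE))]
      r <- stats::runif(need)
      Xs <- if (plan$interpolation == "componentwise") {
        Xc[base, , drop = FALSE] + r * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      } else {
        d_euc <- sqrt(rowSums((Xc[base, , drop = FALSE] - Xc[pick, , drop = FALSE])^2))
        Xc[base, , drop = FALSE] + matrix(r * d_euc, need, ncol(Xc))
      }
      list(X = Xs, label = rep(cl, need), source = set$source[idx[base], , drop = FALSE])
    })
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces)) return(set)
  synth <- instance_set(
    do.call(rbind, lapply(pieces, `[[`, "X")),
    factor(unlist(lapply(pieces, `[[`, "label")), levels = levels(set$label)),
    do.call(rbind, lapply(pieces, `[[`, "source"))
  )
  bind_instances(set, synth)
}

#' Rebalance an instance set according to a plan
#'
#' Dispatches to [random_oversample()], [random_undersample()] or [smote()];
#' `"none"` returns the set unchanged.
#'
#' @inheritParams random_oversample
#' @return An [instance_set()].
#' @export
rebalance <- function(set, plan) {
  stopifnot(inherits(plan, "resample_plan"))
  switch(plan$method,
    none = set,
    oversample = random_oversample(set, plan),
    undersample = random_undersample(set, plan),
    smote = smote(set, plan)
  )
}
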