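# Fixture builders.

## Gaussian instance set with given per-class counts (named vector) and
## feature dimension; class centres spread apart so toys are separable.
make_instances <- function(counts, d = 6, seed = 1, spread = 3) {
  set.seed(seed)
  X <- NULL; label <- character(0)
  for (i in seq_along(counts)) {
    n <- counts[[i]]
    centre <- rnorm(d) * spread
    X <- rbind(X, matrix(rnorm(n * d), n, d, byrow = TRUE) +
                 matrix(centre, n, d, byrow = TRUE))
    label <- c(label, rep(names(counts)[i], n))
  }
  instance_set(X, label)
}

## The twelve post-segmentation class counts used in rebalancing checks.
segmented_counts <- function() {
  stats::setNames(
    c(1198, 1200, 1196, 1174, 1151, 1179, 239, 238, 242, 242, 240, 242),
    activity_labels()
  )
}

tiny_protocol <- function(seed = 7) {
  study_protocol(
    n_subjects = 2, continuous_duration_s = 60,
    transitional_repeats = 3, seed = seed
  )
}

tiny_train_config <- function(...) {
  train_config(
    hidden_sizes = c(30, 30), pretrain_epochs = 2, finetune_epochs = 8,
    finetune_lr = 0.5, batch_size = 32, seed = 5, ...
  )
}
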