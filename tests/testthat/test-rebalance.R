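test_that("oversampling the post-segmentation counts equalises at 1200", {
  set <- make_instances(segmented_counts(), d = 4, seed = 1)
  out <- random_oversample(set, resample_plan("oversample", seed = 2))
  expect_true(all(class_counts(out) == 1200))
  expect_equal(length(out), 12 * 1200)
})

test_that("undersampling the post-segmentation counts equalises at 238", {
  set <- make_instances(segmented_counts(), d = 4, seed = 1)
  out <- random_undersample(set, resample_plan("undersample", seed = 2))
  expect_true(all(class_counts(out) == 238))
})

test_that("SMOTE brings the post-segmentation counts to 1200", {
  set <- make_instances(segmented_counts(), d = 4, seed = 1)
  out <- smote(set, resample_plan("smote", seed = 2))
  expect_true(all(class_counts(out) == 1200))
})

test_that("already balanced sets pass through unchanged", {
  set <- make_instances(c(standing = 5, running = 5), d = 3, seed = 3)
  expect_identical(random_oversample(set, resample_plan("oversample"))$X, set$X)
  expect_identical(
    random_undersample(set, resample_plan("undersample", target = 5, seed = 1))$X,
    set$X
  )
  expect_identical(smote(set, resample_plan("smote"))$X, set$X)
  expect_identical(rebalance(set, resample_plan("none")), set)
})

test_that("oversampling duplicates the single minority instance", {
  set <- instance_set(matrix(c(1, 2, 3, 9), 4, 1),
                      c("standing", "standing", "standing", "running"))
  out <- random_oversample(set, resample_plan("oversample", seed = 1))
  expect_equal(unname(class_counts(out)[c("standing", "running")]), c(3, 3))
  expect_true(all(out$X[out$label == "running", 1] == 9))
  ## originals are a prefix of the output
  expect_equal(out$X[1:4, , drop = FALSE], set$X)
})

test_that("oversample/SMOTE contain the input; undersample is contained in it", {
  set <- make_instances(c(standing = 12, running = 5, sweeping = 8), d = 3, seed = 4)
  key <- function(X) apply(round(X, 10), 1, paste, collapse = "|")
  over <- random_oversample(set, resample_plan("oversample", seed = 7))
  sm <- smote(set, resample_plan("smote", seed = 7))
  under <- random_undersample(set, resample_plan("undersample", seed = 7))
  expect_equal(over$X[seq_len(length(set)), ], set$X)
  expect_equal(sm$X[seq_len(length(set)), ], set$X)
  expect_true(all(key(under$X) %in% key(set$X)))
  ## undersample keeps per-class multiplicities within the originals
  expect_true(all(table(key(under$X)) <= table(key(set$X))[names(table(key(under$X)))]))
})

test_that("every SMOTE synthetic point lies between its two parents", {
  for (seed in 1:5) {
    set <- make_instances(c(standing = 40, running = 6), d = 5, seed = seed)
    out <- smote(set, resample_plan("smote", seed = seed))
    synth <- out$X[(length(set) + 1):length(out), , drop = FALSE]
    ## componentwise betweenness implies inside the class bounding box
    box <- apply(set$X[set$label == "running", ], 2, range)
    for (i in seq_len(nrow(synth))) {
      expect_true(all(synth[i, ] >= box[1, ] - 1e-12))
      expect_true(all(synth[i, ] <= box[2, ] + 1e-12))
    }
  }
})

test_that("SMOTE with r = 0 reproduces the base point (literal and default agree)", {
  ## 1-D class {0, 1}: any synthetic point must lie in [0, 1] on that segment
  set <- instance_set(matrix(c(0, 1, 5, 6, 7), 5, 1),
                      c("standing", "standing", "running", "running", "running"))
  out <- smote(set, resample_plan("smote", target = 5, seed = 3))
  synth <- out$X[which(as.character(out$label) == "standing")[-(1:2)], 1]
  expect_true(all(synth >= 0 & synth <= 1))
})

test_that("literal-mode SMOTE adds the scalar distance times r to all components", {
  set <- instance_set(rbind(c(0, 0), c(3, 4), c(9, 9), c(8, 8), c(7, 7)),
                      c("standing", "standing", "running", "running", "running"))
  plan <- resample_plan("smote", target = 5, seed = 11, interpolation = "literal")
  out <- smote(set, plan)
  synth <- out$X[which(as.character(out$label) == "standing")[-(1:2)], ,
                 drop = FALSE]
  expect_equal(nrow(synth), 3)
  ## parents are (0,0) and (3,4) at Euclidean distance 5: literal mode adds
  ## the same r * 5 offset to every component of the base point
  for (i in seq_len(nrow(synth))) {
    gap <- synth[i, 1] - synth[i, 2] # 0 for base (0,0), -1 for base (3,4)
    expect_true(abs(gap) < 1e-12 || abs(gap + 1) < 1e-12)
    base <- if (abs(gap) < 1e-12) c(0, 0) else c(3, 4)
    d <- synth[i, ] - base
    expect_equal(unname(d[1]), unname(d[2]), tolerance = 1e-12)
    expect_true(d[1] >= 0 && d[1] < 5)
  }
})

test_that("resampling is deterministic under a fixed seed", {
  set <- make_instances(c(standing = 9, running = 4), d = 3, seed = 5)
  for (method in c("oversample", "undersample", "smote")) {
    a <- rebalance(set, resample_plan(method, seed = 21))
    b <- rebalance(set, resample_plan(method, seed = 21))
    expect_identical(a$X, b$X)
    expect_identical(a$label, b$label)
  }
})

test_that("degenerate classes raise informative errors", {
  lone <- instance_set(matrix(c(1, 2, 3), 3, 1),
                       c("standing", "standing", "running"))
  expect_error(smote(lone, resample_plan("smote")), "running")
  expect_error(
    random_undersample(lone, resample_plan("undersample", target = 2)),
    "running"
  )
  expect_error(
    random_oversample(lone, resample_plan("oversample", target = 1)),
    "exceeds"
  )
  expect_error(resample_plan("smote", smote_k = 0), "smote_k")
  expect_error(resample_plan("oversample", target = 0), "target")
})

test_that("fuzzed class profiles always balance to the target", {
  for (seed in 1:8) {
    set.seed(seed)
    k <- sample(2:5, 1)
    counts <- stats::setNames(sample(2:30, k), sample(activity_labels(), k))
    set <- make_instances(counts, d = sample(2:6, 1), seed = seed + 100)
    for (method in c("oversample", "undersample", "smote")) {
      out <- rebalance(set, resample_plan(method, seed = seed))
      cc <- class_counts(out, drop_empty = TRUE)
      target <- if (method == "undersample") min(counts) else max(counts)
      expect_true(all(cc == target),
                  info = sprintf("seed %d method %s", seed, method))
    }
  }
})
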