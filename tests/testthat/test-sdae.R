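test_that("masking corruption keeps, zeroes and hits its expected rate", {
  x <- runif(100)
  expect_identical(corrupt(x, 0, seed = 1), x)
  expect_equal(corrupt(x, 1, seed = 1), rep(0, 100))
  zeroed <- sapply(1:20, function(s) {
    x <- rep(1, 1e4)
    mean(corrupt(x, 0.5, seed = s) == 0)
  })
  expect_true(all(abs(zeroed - 0.5) < 0.02))
  expect_identical(corrupt(x, 0.3, seed = 9), corrupt(x, 0.3, seed = 9))
  expect_error(corrupt(x, 1.5), "probability")
})

test_that("encode/decode are sigmoid affine maps with outputs in (0, 1)", {
  layer <- dae_layer(3, 2, corruption = 0, seed = 1)
  layer$W1[] <- 0; layer$b1[] <- 0
  expect_equal(encode(layer, c(1, 2, 3)), matrix(0.5, 1, 2))

  one_d <- dae_layer(1, 1, seed = 2)
  one_d$W1[] <- 2; one_d$b1[] <- 0
  expect_equal(encode(one_d, 1)[1, 1], plogis(2), tolerance = 1e-12)

  big <- dae_layer(10, 7, seed = 3)
  h <- encode(big, matrix(rnorm(50, sd = 10), 5))
  z <- decode(big, h)
  expect_true(all(h > 0 & h < 1))
  expect_true(all(z > 0 & z < 1))
  expect_error(encode(big, matrix(0, 2, 9)), "expected 10")
})

test_that("cross-entropy reconstruction loss matches hand values", {
  expect_equal(recon_loss(1, 0.5), -log(0.5), tolerance = 1e-12)
  expect_equal(recon_loss(0, 0.5), -log(0.5), tolerance = 1e-12)
  x <- c(0, 1, 1, 0)
  expect_lt(recon_loss(x, x), 1e-10) # perfect reconstruction, clipped logs
  expect_gt(recon_loss(c(1, 0), c(0.1, 0.9)), 0)
  expect_error(recon_loss(c(1, 0), 1), "shape")
})

test_that("analytic pretraining gradients match central finite differences", {
  set.seed(31)
  d_in <- 5; d_hid <- 4; m <- 3
  layer <- dae_layer(d_in, d_hid, corruption = 0.5, seed = 8)
  X <- matrix(runif(m * d_in), m)
  Xc <- X * (matrix(runif(m * d_in), m) >= 0.5)
  ana <- sdaehar:::dae_gradients(layer, X, Xc)
  loss_at <- function(param, value) {
    mod <- layer
    mod[[param]][] <- value
    recon_loss(X, decode(mod, encode(mod, Xc)))
  }
  for (param in c("W1", "b1", "W2", "b2")) {
    num <- numeric_gradient(function(v) loss_at(param, v), as.numeric(layer[[param]]))
    expect_lt(rel_err(as.numeric(ana[[param]]), num), 1e-5)
  }
})

test_that("analytic fine-tuning gradients match central finite differences", {
  set.seed(32)
  m <- 4
  model <- pretrain_stack(
    matrix(runif(m * 6), m),
    train_config(hidden_sizes = c(5, 3), corruption = 0,
                 pretrain_epochs = 1, batch_size = 2, seed = 9)
  )
  model$head <- list(W = matrix(rnorm(3 * 2, sd = 0.3), 3), b = rnorm(2))
  X <- matrix(runif(m * 6), m)
  Y <- sdaehar:::one_hot(sample(1:2, m, replace = TRUE), 2)
  ana <- sdaehar:::finetune_gradients(model, X, Y)
  loss_with <- function(mod) sdaehar:::finetune_gradients(mod, X, Y)$loss
  check <- function(get, set_fun, analytic) {
    num <- numeric_gradient(function(v) {
      loss_with(set_fun(model, v))
    }, as.numeric(get(model)))
    expect_lt(rel_err(as.numeric(analytic), num), 1e-5)
  }
  check(function(m) m$head$W,
        function(m, v) { m$head$W[] <- v; m }, ana$head_W)
  check(function(m) m$head$b,
        function(m, v) { m$head$b[] <- v; m }, ana$head_b)
  for (l in 1:2) {
    check(function(m) m$layers[[l]]$W1,
          function(m, v) { m$layers[[l]]$W1[] <- v; m }, ana$layers[[l]]$W1)
    check(function(m) m$layers[[l]]$b1,
          function(m, v) { m$layers[[l]]$b1[] <- v; m }, ana$layers[[l]]$b1)
  }
})

test_that("a vanishing learning rate leaves parameters unchanged", {
  layer <- dae_layer(4, 3, corruption = 0.5, seed = 2)
  X <- matrix(runif(20), 5)
  cfg <- train_config(hidden_sizes = 3, corruption = 0.5,
                      pretrain_lr = 1e-300, pretrain_epochs = 3,
                      batch_size = 2, seed = 3)
  out <- pretrain_layer(X, layer, cfg)
  expect_identical(out$layer$W1, layer$W1)
  expect_identical(out$layer$W2, layer$W2)
})

test_that("pretraining reduces the reconstruction loss on a fixed batch", {
  set.seed(12)
  X <- matrix(runif(40 * 8), 40)
  layer <- dae_layer(8, 6, corruption = 0.3, seed = 4)
  cfg <- train_config(hidden_sizes = 6, corruption = 0.3, pretrain_lr = 0.5,
                      pretrain_epochs = 200, batch_size = 10, seed = 5)
  out <- pretrain_layer(X, layer, cfg)
  expect_lte(out$loss_trace[200], out$loss_trace[1])
  expect_length(out$loss_trace, 200)
})

test_that("zero-corruption pretraining equals an independent plain autoencoder", {
  set.seed(13)
  X <- matrix(runif(30 * 7), 30)
  layer <- dae_layer(7, 4, corruption = 0, seed = 6)
  cfg <- train_config(hidden_sizes = 4, corruption = 0, pretrain_lr = 0.1,
                      pretrain_epochs = 15, batch_size = 8, seed = 77)
  ours <- pretrain_layer(X, layer, cfg)
  ref <- oracle_plain_ae(X, layer$W1, layer$b1, layer$W2, layer$b2,
                         lr = 0.1, epochs = 15, batch_size = 8, seed = 77)
  expect_equal(ours$loss_trace, ref$trace, tolerance = 1e-10)
  expect_equal(ours$layer$W1, ref$W1, tolerance = 1e-10)
  expect_equal(ours$layer$W2, ref$W2, tolerance = 1e-10)
})

test_that("greedy stacking chains layer shapes and matches a lone layer", {
  X <- matrix(runif(20 * 10), 20)
  cfg <- train_config(hidden_sizes = c(6, 3), corruption = 0.4,
                      pretrain_lr = 0.05, pretrain_epochs = 4,
                      batch_size = 5, seed = 21)
  model <- pretrain_stack(X, cfg)
  expect_equal(dim(model$layers[[1]]$W1), c(10, 6))
  expect_equal(dim(model$layers[[2]]$W1), c(6, 3))
  expect_equal(dim(model$layers[[2]]$W2), c(3, 6))

  ## a single-layer stack is exactly one pretrain_layer call under the
  ## stack's per-layer seed derivation
  cfg1 <- train_config(hidden_sizes = 6, corruption = 0.4, pretrain_lr = 0.05,
                       pretrain_epochs = 4, batch_size = 5, seed = 21)
  stack1 <- pretrain_stack(X, cfg1)
  lone <- pretrain_layer(
    X,
    dae_layer(10, 6, 0.4, seed = sdaehar:::child_seed(21, 101, 1)),
    sdaehar:::replace_seed(cfg1, sdaehar:::child_seed(21, 202, 1))
  )
  expect_identical(stack1$layers[[1]]$W1, lone$layer$W1)
  expect_error(pretrain_stack(X * 3, cfg), "\\[0, 1\\]")
})

test_that("training is deterministic: same data, config and seed, same weights", {
  set <- make_instances(c(standing = 25, running = 25), d = 8, seed = 14)
  params <- fit_standardizer(set)
  scaled <- apply_standardizer(params, set)
  cfg <- train_config(hidden_sizes = c(6, 4), corruption = 0.5,
                      pretrain_lr = 0.01, pretrain_epochs = 3,
                      finetune_epochs = 5, finetune_lr = 0.3,
                      batch_size = 8, seed = 33)
  run_once <- function() fine_tune(pretrain_stack(scaled, cfg), scaled, NULL, cfg)
  a <- run_once(); b <- run_once()
  expect_identical(a$layers[[1]]$W1, b$layers[[1]]$W1)
  expect_identical(a$head$W, b$head$W)
  expect_identical(a$finetune_trace$train_loss, b$finetune_trace$train_loss)
})

test_that("fine-tuning separates two linearly separable classes fully", {
  set.seed(15)
  n <- 40
  X <- rbind(matrix(runif(n * 4, 0, 0.35), n), matrix(runif(n * 4, 0.65, 1), n))
  toy <- instance_set(X, rep(c("standing", "running"), each = n))
  cfg <- train_config(hidden_sizes = c(8, 8), corruption = 0.2,
                      pretrain_lr = 0.01, pretrain_epochs = 3,
                      finetune_epochs = 200, finetune_lr = 0.5,
                      batch_size = 16, seed = 44)
  model <- fine_tune(pretrain_stack(toy, cfg), toy, toy, cfg)
  pred <- predict(model, toy, type = "class")
  expect_equal(as.character(pred), as.character(toy$label))
  expect_equal(tail(model$finetune_trace$val_accuracy, 1), 1)
})

test_that("softmax probabilities are normalised; zero head gives uniform + first class", {
  toy <- make_instances(c(standing = 6, running = 6), d = 5, seed = 16)
  scaled <- apply_standardizer(fit_standardizer(toy), toy)
  cfg <- train_config(hidden_sizes = 4, corruption = 0, pretrain_epochs = 1,
                      finetune_epochs = 1, batch_size = 4, seed = 17)
  model <- fine_tune(pretrain_stack(scaled, cfg), scaled, NULL, cfg)
  P <- predict(model, scaled, type = "prob")
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, 12), tolerance = 1e-9)

  model$head$W[] <- 0; model$head$b[] <- 0
  P0 <- predict(model, scaled, type = "prob")
  expect_equal(unname(P0), matrix(1 / ncol(P0), nrow(P0), ncol(P0)),
               tolerance = 1e-12)
  expect_true(all(predict(model, scaled, type = "class") == model$classes[1]))
})

test_that("labels outside the class set and unheaded prediction error", {
  toy <- make_instances(c(standing = 4, running = 4), d = 3, seed = 18)
  cfg <- tiny_train_config()
  model <- pretrain_stack(apply_standardizer(fit_standardizer(toy), toy), cfg)
  expect_error(predict(model, toy), "no softmax head")
  expect_error(
    fine_tune(model, toy, NULL, cfg, classes = c("walking", "running")),
    "outside the configured class set"
  )
})
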