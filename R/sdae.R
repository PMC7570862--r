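# Denoising-autoencoder layers and greedy layer-wise pretraining.
#
# A layer holds encoder (W1, b1) and decoder (W2, b2) parameters; both maps
# are sigmoid. Pretraining corrupts the input with masking noise (each
# component zeroed independently with probability a), reconstructs, and
# minimises the summed binary cross-entropy against the *clean* input by
# mini-batch gradient descent.

#' Training configuration
#'
#' Hyperparameters for pretraining and fine-tuning. The defaults are the
#' pipeline's reference operating point: two hidden layers of 500 units on
#' 3072-feature instances, masking probability 0.5, pretraining learning
#' rate 1e-7, fine-tuning learning rate 0.01, 200 epochs, batch size 64.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param corruption Masking probability `a` in `[0, 1]`.
#' @param pretrain_lr,finetune_lr Positive learning rates.
#' @param pretrain_epochs,finetune_epochs Epoch counts (>= 1); an epoch is
#'   one full pass over the training set.
#' @param batch_size Mini-batch size (>= 1).
#' @param seed Integer seed governing initialization, shuffling and
#'   corruption.
#' @return An object of class `train_config`.
#' @export
train_config <- function(hidden_sizes = c(500, 500),
                         corruption = 0.5,
                         pretrain_lr = 1e-7,
                         finetune_lr = 0.01,
                         pretrain_epochs = 200,
                         finetune_epochs = 200,
                         batch_size = 64,
                         seed = 1) {
  if (pretrain_lr <= 0 || finetune_lr <= 0) stop_invalid("learning rates must be > 0")
  if (pretrain_epochs < 1 || finetune_epochs < 1) stop_invalid("epochs must be >= 1")
  if (corruption < 0 || corruption > 1) stop_invalid("corruption must be in [0, 1]")
  if (batch_size < 1) stop_invalid("batch_size must be >= 1")
  if (!length(hidden_sizes) || any(hidden_sizes < 1)) {
    stop_invalid("hidden_sizes must be positive")
  }
  structure(
    list(
      hidden_sizes = as.integer(hidden_sizes), corruption = corruption,
      pretrain_lr = pretrain_lr, finetune_lr = finetune_lr,
      pretrain_epochs = as.integer(pretrain_epochs),
      finetune_epochs = as.integer(finetune_epochs),
      batch_size = as.integer(batch_size), seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

sigmoid <- function(x) stats::plogis(x)

## Glorot-style uniform init for sigmoid layers; biases start at zero.
init_weights <- function(d_in, d_out) {
  limit <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -limit, limit), d_in, d_out)
}

#' Create an untrained denoising-autoencoder layer
#'
#' Encoder weights are drawn uniform in ±sqrt(6 / (d_in + d_hidden)) (and
#' correspondingly for the decoder); biases start at zero.
#'
#' @param d_in,d_hidden Input and hidden dimensions.
#' @param corruption Masking probability `a` in `[0, 1]`.
#' @param seed Integer seed for the weight draw.
#' @return An object of class `dae_layer` with fields `W1` (d_in x d_hidden),
#'   `b1`, `W2` (d_hidden x d_in), `b2`, `corruption`.
#' @export
dae_layer <- function(d_in, d_hidden, corruption = 0.5, seed = NULL) {
  if (corruption < 0 || corruption > 1) stop_invalid("corruption must be in [0, 1]")
  with_seed(seed, {
    structure(
      list(
        W1 = init_weights(d_in, d_hidden), b1 = numeric(d_hidden),
        W2 = init_weights(d_hidden, d_in), b2 = numeric(d_in),
        corruption = corruption
      ),
      class = "dae_layer"
    )
  })
}

#' Masking corruption
#'
#' Independently zeroes each component with probability `a` (the denoising
#' factor); at `a = 0` the input is returned unchanged, at `a = 1` the
#' output is all zeros. Deterministic under `seed`.
#'
#' @param x Numeric vector or matrix (rows = instances).
#' @param a Masking probability in `[0, 1]`.
#' @param seed Integer seed (optional; omit to draw from the current RNG
#'   stream, as the training loop does).
#' @return Object of the same shape as `x`.
#' @export
corrupt <- function(x, a, seed = NULL) {
  if (a < 0 || a > 1) stop_invalid("corruption probability must be in [0, 1]")
  if (a == 0) return(x)
  with_seed(seed, x * (stats::runif(length(x)) >= a))
}

#' Encode / decode through a layer
#'
#' `encode()` maps inputs to the hidden representation
#' `sigmoid(x %*% W1 + b1)`; `decode()` maps hidden codes back to a
#' reconstruction `sigmoid(y %*% W2 + b2)`. Outputs are strictly inside
#' (0, 1).
#'
#' @param layer A [dae_layer()].
#' @param x,y Numeric vector or matrix (rows = instances) of the layer's
#'   input/hidden dimension.
#' @return Matrix of hidden codes (n x d_hidden) or reconstructions
#'   (n x d_in); a vector input yields a 1-row matrix.
#' @export
encode <- function(layer, x) {
  x <- matrix_input(x, nrow(layer$W1), "encode")
  sigmoid(sweep(x %*% layer$W1, 2, layer$b1, "+"))
}

#' @rdname encode
#' @export
decode <- function(layer, y) {
  y <- matrix_input(y, nrow(layer$W2), "decode")
  sigmoid(sweep(y %*% layer$W2, 2, layer$b2, "+"))
}

matrix_input <- function(x, d, what) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (ncol(x) != d) {
    stop_invalid(what, ": input has ", ncol(x), " columns, expected ", d)
  }
  x
}

#' Cross-entropy reconstruction loss
#'
#' Element-wise binary cross-entropy of a reconstruction `z` against the
#' clean input `x`, summed over components (and averaged over rows if given
#' matrices): `-(x log z + (1 - x) log(1 - z))`, with `z` clipped to
#' `[1e-12, 1 - 1e-12]` so the logs stay finite.
#'
#' @param x Clean input, values in `[0, 1]`.
#' @param z Reconstruction of the same shape.
#' @return Nonnegative scalar (mean over instances of the per-instance sum).
#' @export
#' @examples
#' recon_loss(1, 0.5) # -log(0.5)
recon_loss <- function(x, z) {
  if (length(x) != length(z)) stop_invalid("x and z must have the same shape")
  zc <- clip_unit(z)
  total <- -sum(x * log(zc) + (1 - x) * log(1 - zc))
  n_rows <- if (is.null(dim(x))) 1 else nrow(x)
  total / n_rows
}

## Analytic gradients of the mean (over batch rows) reconstruction loss.
## Xc = corrupted input actually fed to the encoder, X = clean target.
dae_gradients <- function(layer, X, Xc) {
  m <- nrow(X)
  H <- encode(layer, Xc)
  Z <- decode(layer, H)
  dZpre <- (Z - X) / m                      # d(meanloss)/d(pre-sigmoid output)
  dH <- (dZpre %*% t(layer$W2)) * H * (1 - H)
  list(
    W1 = t(Xc) %*% dH, b1 = colSums(dH),
    W2 = t(H) %*% dZpre, b2 = colSums(dZpre),
    loss = recon_loss(X, Z)
  )
}

#' Pretrain one denoising-autoencoder layer
#'
#' Runs `pretrain_epochs` epochs of mini-batch gradient descent: each epoch
#' shuffles the rows, corrupts every mini-batch afresh with masking
#' probability `layer$corruption`, reconstructs through encode/decode, and
#' minimises the cross-entropy against the clean batch at
#' `config$pretrain_lr`. The RNG is seeded once from `config$seed`; at zero
#' corruption no masking draws are made, so the schedule reduces exactly to
#' plain autoencoder training.
#'
#' @param data Numeric matrix (rows = instances, values in `[0, 1]`) or an
#'   [instance_set()].
#' @param layer A [dae_layer()]; its `corruption` field is used.
#' @param config A [train_config()].
#' @return List with the trained `layer` and `loss_trace` (per-epoch mean of
#'   the clean-input reconstruction loss over mini-batches).
#' @export
pretrain_layer <- function(data, layer, config) {
  X <- if (inherits(data, "instance_set")) data$X else as.matrix(data)
  if (nrow(X) == 0) stop_invalid("pretraining data is empty")
  if (ncol(X) != nrow(layer$W1)) {
    stop_invalid("data width ", ncol(X), " does not match layer input ", nrow(layer$W1))
  }
  n <- nrow(X)
  a <- layer$corruption
  trace <- numeric(config$pretrain_epochs)
  with_seed(config$seed, {
    for (epoch in seq_len(config$pretrain_epochs)) {
      perm <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        Xc <- if (a > 0) Xb * (matrix(stats::runif(length(Xb)), nrow(Xb)) >= a) else Xb
        g <- dae_gradients(layer, Xb, Xc)
        if (!is.finite(g$loss)) {
          stop_invalid(
            "non-finite reconstruction loss at epoch ", epoch,
            "; the pretraining learning rate ", config$pretrain_lr,
            " is likely too high for these data"
          )
        }
        layer$W1 <- layer$W1 - config$pretrain_lr * g$W1
        layer$b1 <- layer$b1 - config$pretrain_lr * g$b1
        layer$W2 <- layer$W2 - config$pretrain_lr * g$W2
        layer$b2 <- layer$b2 - config$pretrain_lr * g$b2
        batch_losses <- c(batch_losses, g$loss)
      }
      trace[epoch] <- mean(batch_losses)
    }
  })
  list(layer = layer, loss_trace = trace)
}

#' Greedy layer-wise pretraining of the full stack
#'
#' Trains the layers in order: layer 1 on the standardized instances, each
#' subsequent layer on the *clean* (uncorrupted) encodings of its
#' predecessor's inputs. Corruption is applied afresh inside each layer's own
#' training. Returns a headless stacked model ready for [fine_tune()].
#'
#' @param train An [instance_set()] standardized to `[0, 1]`, or a numeric
#'   matrix.
#' @param config A [train_config()]; `hidden_sizes` fixes the stack shape.
#' @return An object of class `sdae` with `layers`, `config`, per-layer
#'   `pretrain_traces`, and no head yet.
#' @export
pretrain_stack <- function(train, config) {
  X <- if (inherits(train, "instance_set")) train$X else as.matrix(train)
  if (any(X < 0 | X > 1)) stop_invalid("pretraining inputs must lie in [0, 1]")
  layers <- list()
  traces <- list()
  input <- X
  for (l in seq_along(config$hidden_sizes)) {
    layer <- dae_layer(
      ncol(input), config$hidden_sizes[l], config$corruption,
      seed = child_seed(config$seed, 101, l)
    )
    fit <- pretrain_layer(input, layer, replace_seed(config, child_seed(config$seed, 202, l)))
    layers[[l]] <- fit$layer
    traces[[l]] <- fit$loss_trace
    input <- encode(fit$layer, input)
  }
  structure(
    list(
      layers = layers, head = NULL,
      classes = if (inherits(train, "instance_set")) levels(train$label),
      config = config, pretrain_traces = traces, finetune_trace = NULL
    ),
    class = "sdae"
  )
}

replace_seed <- function(config, seed) {
  config$seed <- as.integer(seed)
  config
}

#' @export
print.sdae <- function(x, ...) {
  dims <- c(nrow(x$layers[[1]]$W1), vapply(x$layers, function(l) ncol(l$W1), integer(1)))
  cat("<sdae>", paste(dims, collapse = " -> "))
  if (!is.null(x$head)) cat(" -> softmax(", ncol(x$head$W), ")", sep = "")
  cat(if (is.null(x$head)) " [pretrained, no head]" else " [fine-tuned]", "\n")
  invisible(x)
}
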