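# Supervised fine-tuning: softmax head on top of the encoder stack, trained
# end-to-end as a plain multilayer perceptron (decoders frozen, no
# corruption).

softmax_rows <- function(logits) {
  shifted <- logits - apply(logits, 1, max)
  e <- exp(shifted)
  e / rowSums(e)
}

## Forward pass through all encoders; returns hidden activations per layer.
encoder_forward <- function(model, X) {
  acts <- vector("list", length(model$layers))
  h <- X
  for (l in seq_along(model$layers)) {
    h <- encode(model$layers[[l]], h)
    acts[[l]] <- h
  }
  acts
}

## One-hot matrix for integer class indices.
one_hot <- function(idx, n_classes) {
  Y <- matrix(0, length(idx), n_classes)
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

## Analytic gradients of the mean categorical cross-entropy w.r.t. the head
## and every encoder's (W1, b1). Returns loss as a by-product.
finetune_gradients <- function(model, X, Y) {
  m <- nrow(X)
  acts <- encoder_forward(model, X)
  top <- acts[[length(acts)]]
  logits <- sweep(top %*% model$head$W, 2, model$head$b, "+")
  P <- softmax_rows(logits)
  dlogits <- (P - Y) / m
  grads <- list(
    head_W = t(top) %*% dlogits,
    head_b = colSums(dlogits),
    layers = vector("list", length(model$layers))
  )
  dh <- dlogits %*% t(model$head$W)
  for (l in rev(seq_along(model$layers))) {
    H <- acts[[l]]
    dpre <- dh * H * (1 - H)
    below <- if (l == 1) X else acts[[l - 1]]
    grads$layers[[l]] <- list(W1 = t(below) %*% dpre, b1 = colSums(dpre))
    if (l > 1) dh <- dpre %*% t(model$layers[[l]]$W1)
  }
  Pc <- clip_unit(P)
  grads$loss <- -sum(Y * log(Pc)) / m
  grads
}

#' Fine-tune a pretrained stack with a softmax head
#'
#' Appends a softmax classification layer on top of the last hidden layer
#' and trains the whole encoder stack plus head by mini-batch gradient
#' descent on categorical cross-entropy for `finetune_epochs` epochs at
#' `finetune_lr`. No corruption is applied, and decoder parameters are left
#' untouched. Per-epoch mean training loss and validation accuracy are
#' recorded.
#'
#' @param model A pretrained `sdae` from [pretrain_stack()].
#' @param train Labelled [instance_set()] standardized to `[0, 1]`.
#' @param validation Optional labelled [instance_set()] for the accuracy
#'   trace (may be `NULL`).
#' @param config A [train_config()]; `finetune_lr`, `finetune_epochs`,
#'   `batch_size` and `seed` are used.
#' @param classes Class-label ordering for the head; defaults to the levels
#'   of the training labels.
#' @return The fine-tuned `sdae` with a `head`, plus `finetune_trace` (data
#'   frame of epoch, train_loss, val_accuracy).
#' @export
fine_tune <- function(model, train, validation = NULL, config = model$config,
                      classes = levels(train$label)) {
  stopifnot(inherits(model, "sdae"), inherits(train, "instance_set"))
  if (!all(as.character(train$label) %in% classes)) {
    stop_invalid("training labels outside the configured class set")
  }
  if (!is.null(validation) && length(validation) > 0 &&
      !all(as.character(validation$label) %in% classes)) {
    stop_invalid("validation labels outside the configured class set")
  }
  X <- train$X
  n <- nrow(X)
  if (n == 0) stop_invalid("fine-tuning data is empty")
  d_top <- ncol(model$layers[[length(model$layers)]]$W1)
  y_idx <- match(as.character(train$label), classes)
  Y <- one_hot(y_idx, length(classes))
  trace <- data.frame(
    epoch = seq_len(config$finetune_epochs),
    train_loss = NA_real_, val_accuracy = NA_real_
  )
  with_seed(child_seed(config$seed, 303), {
    model$head <- list(
      W = init_weights(d_top, length(classes)),
      b = numeric(length(classes))
    )
    for (epoch in seq_len(config$finetune_epochs)) {
      perm <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1, n)]
        g <- finetune_gradients(model, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
        if (!is.finite(g$loss)) {
          stop_invalid("non-finite classification loss at epoch ", epoch,
                       "; the fine-tuning learning rate is likely too high")
        }
        model$head$W <- model$head$W - config$finetune_lr * g$head_W
        model$head$b <- model$head$b - config$finetune_lr * g$head_b
        for (l in seq_along(model$layers)) {
          model$layers[[l]]$W1 <- model$layers[[l]]$W1 - config$finetune_lr * g$layers[[l]]$W1
          model$layers[[l]]$b1 <- model$layers[[l]]$b1 - config$finetune_lr * g$layers[[l]]$b1
        }
        batch_losses <- c(batch_losses, g$loss)
      }
      trace$train_loss[epoch] <- mean(batch_losses)
      if (!is.null(validation) && length(validation) > 0) {
        pred <- predict(model, validation, type = "class")
        trace$val_accuracy[epoch] <-
          mean(as.character(pred) == as.character(validation$label))
      }
    }
  })
  model$classes <- classes
  model$config <- config
  model$finetune_trace <- trace
  model
}

#' Predict activity classes with a fine-tuned model
#'
#' Runs the encoder stack and softmax head. Probabilities are nonnegative
#' and sum to 1 per instance; the predicted label is the argmax, with ties
#' broken toward the lowest class index.
#'
#' @param object A fine-tuned `sdae`.
#' @param newdata An [instance_set()] or numeric matrix standardized to
#'   `[0, 1]`.
#' @param type `"class"` for a factor of labels, `"prob"` for the n x C
#'   probability matrix.
#' @param ... Unused.
#' @return Factor of predicted labels, or a probability matrix with class
#'   columns.
#' @export
predict.sdae <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(object$head)) stop_invalid("model has no softmax head; run fine_tune() first")
  X <- if (inherits(newdata, "instance_set")) newdata$X else as.matrix(newdata)
  if (ncol(X) != nrow(object$layers[[1]]$W1)) {
    stop_invalid("newdata width ", ncol(X), " does not match model input ",
                 nrow(object$layers[[1]]$W1))
  }
  acts <- encoder_forward(object, X)
  logits <- sweep(acts[[length(acts)]] %*% object$head$W, 2, object$head$b, "+")
  P <- softmax_rows(logits)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")], levels = object$classes)
}
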