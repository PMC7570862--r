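# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

## Brute-force sliding-window start enumeration.
oracle_window_starts <- function(n_samples, window, step) {
  starts <- integer(0)
  s <- 0
  while (s + window <= n_samples) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}

## Central finite differences of a scalar function at x.
numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    up <- x; up[i] <- up[i] + eps
    dn <- x; dn[i] <- dn[i] - eps
    g[i] <- (f(up) - f(dn)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(a)), max(abs(b)), 1e-8)
}

## Reference plain (non-denoising) autoencoder trainer: sigmoid encoder and
## decoder, summed binary cross-entropy averaged over the batch, mini-batch
## gradient descent. Mirrors the documented RNG protocol (one set.seed, one
## permutation draw per epoch, no corruption draws) but is written
## independently of the package's training code.
oracle_plain_ae <- function(X, W1, b1, W2, b2, lr, epochs, batch_size, seed) {
  sig <- function(v) 1 / (1 + exp(-v))
  n <- nrow(X)
  trace <- numeric(epochs)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    losses <- c()
    for (s0 in seq(1, n, by = batch_size)) {
      idx <- perm[s0:min(s0 + batch_size - 1, n)]
      B <- X[idx, , drop = FALSE]
      m <- nrow(B)
      H <- sig(sweep(B %*% W1, 2, b1, "+"))
      Z <- sig(sweep(H %*% W2, 2, b2, "+"))
      Zc <- pmin(pmax(Z, 1e-12), 1 - 1e-12)
      losses <- c(losses, -sum(B * log(Zc) + (1 - B) * log(1 - Zc)) / m)
      dZ <- (Z - B) / m
      dH <- (dZ %*% t(W2)) * H * (1 - H)
      W2 <- W2 - lr * (t(H) %*% dZ)
      b2 <- b2 - lr * colSums(dZ)
      W1 <- W1 - lr * (t(B) %*% dH)
      b1 <- b1 - lr * colSums(dH)
    }
    trace[ep] <- mean(losses)
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, trace = trace)
}

## Direct recount of one-vs-rest TP/FP/FN from raw label vectors.
oracle_ovr_counts <- function(y_true, y_pred, cls) {
  tp <- sum(y_true == cls & y_pred == cls)
  fp <- sum(y_true != cls & y_pred == cls)
  fn <- sum(y_true == cls & y_pred != cls)
  c(tp = tp, fp = fp, fn = fn)
}

## Random confusion matrix with the package's class structure.
random_confusion <- function(n_classes, max_count = 30) {
  cm <- matrix(sample.int(max_count + 1, n_classes^2, replace = TRUE) - 1L,
               n_classes)
  labels <- paste0("c", seq_len(n_classes))
  y_true <- rep(rep(labels, each = n_classes), as.vector(t(cm)))
  y_pred <- rep(rep(labels, times = n_classes), as.vector(t(cm)))
  list(y_true = y_true, y_pred = y_pred, labels = labels, counts = cm)
}
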