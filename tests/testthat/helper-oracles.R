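# Independent oracles used across test files. These deliberately avoid the
# package's own computational paths.

# Naive two-pass RMSE loop.
naive_rmse <- function(pred, truth) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (pred[i] - truth[i])^2
  sqrt(s / length(pred))
}

# Pure-R reference implementation of mini-batch Adam on the softmax-MSE
# objective, written independently of the compiled training loop.
ref_train_softmax <- function(W, b, x, y, cfg, perms) {
  K <- nrow(W)
  n <- nrow(x)
  th <- c(W, b)
  m <- v <- numeric(3 * K)
  t <- 0
  for (ep in seq_len(ncol(perms))) {
    ord <- perms[, ep]
    for (s in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1, n)]
      Wc <- matrix(th[1:(2 * K)], K)
      bc <- th[2 * K + 1:K]
      z <- x[idx, , drop = FALSE] %*% t(Wc) +
        matrix(bc, length(idx), K, byrow = TRUE)
      z <- z - apply(z, 1, max)
      e <- exp(z)
      p <- e / rowSums(e)
      g <- 2 * (p - y[idx, , drop = FALSE]) / (K * length(idx))
      dz <- p * (g - rowSums(g * p))
      grad <- c(t(dz) %*% x[idx, , drop = FALSE], colSums(dz))
      t <- t + 1
      m <- cfg$beta1 * m + (1 - cfg$beta1) * grad
      v <- cfg$beta2 * v + (1 - cfg$beta2) * grad^2
      th <- th - cfg$learning_rate * (m / (1 - cfg$beta1^t)) /
        (sqrt(v / (1 - cfg$beta2^t)) + cfg$eps)
    }
  }
  list(W = matrix(th[1:(2 * K)], K), b = unname(th[2 * K + 1:K]))
}

# Central finite differences of the training loss over all 3K parameters.
numeric_net_gradient <- function(net, x, y, h = 1e-6) {
  loss_at <- function(W, b) {
    n2 <- net
    n2$W <- W
    n2$b <- b
    mean((forward_net(n2, x) - y)^2)
  }
  K <- nrow(net$W)
  dW <- matrix(0, K, 2)
  for (i in seq_len(K)) {
    for (j in 1:2) {
      Wp <- net$W; Wp[i, j] <- Wp[i, j] + h
      Wm <- net$W; Wm[i, j] <- Wm[i, j] - h
      dW[i, j] <- (loss_at(Wp, net$b) - loss_at(Wm, net$b)) / (2 * h)
    }
  }
  db <- numeric(K)
  for (i in seq_len(K)) {
    bp <- net$b; bp[i] <- bp[i] + h
    bm <- net$b; bm[i] <- bm[i] - h
    db[i] <- (loss_at(net$W, bp) - loss_at(net$W, bm)) / (2 * h)
  }
  list(dW = dW, db = db)
}
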