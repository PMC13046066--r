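#' Per-element ordinary least squares decomposition model
#'
#' Fits, independently for each element, the affine model
#' `w_hat = beta0 + beta1 * x1 + beta2 * x2` on standardized attenuation
#' features by closed-form least squares (QR). Each element contributes 3
#' coefficients, so the model carries `3K` parameters: 12 for soft tissue
#' (K = 4) and 15 for bone (K = 5). Predictions are unconstrained real
#' numbers and may fall outside `[0, 1]`.
#'
#' @param x n x 2 matrix of standardized features.
#' @param y n x K matrix of target mass fractions (columns named by
#'   element).
#' @return A `dect_lm`: list with `coef` (3 x K matrix, rows
#'   `(Intercept)`, `x1`, `x2`), `elements`, `residual_rms` (per-element
#'   RMS of training residuals) and `n_train`.
#' @export
fit_linear_ols <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows")
  if (nrow(x) < 3) stop("at least 3 training samples are required")
  design <- cbind(`(Intercept)` = 1, x1 = x[, 1], x2 = x[, 2])
  fit <- lm.fit(design, y)
  if (fit$rank < 3) stop("rank-deficient design: features are collinear")
  coef <- as.matrix(fit$coefficients)
  colnames(coef) <- colnames(y)
  res <- as.matrix(fit$residuals)
  structure(
    list(coef = coef,
         elements = colnames(y),
         residual_rms = sqrt(colMeans(res^2)),
         n_train = nrow(x)),
    class = "dect_lm"
  )
}

#' @export
print.dect_lm <- function(x, ...) {
  cat("<dect_lm>", length(x$elements), "elements,",
      3 * length(x$elements), "parameters\n")
  print(round(x$coef, 5))
  invisible(x)
}

#' Predict mass fractions with the linear model
#'
#' @param model A `dect_lm`.
#' @param x n x 2 matrix (or length-2 vector) of standardized features.
#' @return n x K matrix of predicted mass fractions (unbounded).
#' @export
predict_linear <- function(model, x) {
  stopifnot(inherits(model, "dect_lm"))
  x <- if (is.null(dim(x))) matrix(x, ncol = 2) else as.matrix(x)
  cbind(1, x) %*% model$coef
}

#' Number of trainable parameters of a decomposition model
#'
#' @param model A `dect_lm` or `dect_net`.
#' @return Integer parameter count (`3K` for both model families).
#' @export
n_parameters <- function(model) {
  UseMethod("n_parameters")
}

#' @export
n_parameters.dect_lm <- function(model) length(model$coef)

#' @export
n_parameters.dect_net <- function(model) length(model$W) + length(model$b)

#' Training configuration for the softmax network
#'
#' Defaults follow the study protocol: MSE loss, Adam with learning rate
#' 0.001, batch size 16, 80 epochs, and the canonical Adam constants
#' `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`. No early stopping,
#' learning-rate schedule, weight decay or gradient clipping is applied;
#' the validation set is used for monitoring only.
#'
#' @param learning_rate,batch_size,epochs,beta1,beta2,eps Positive
#'   optimizer constants.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 16L,
                         epochs = 80L, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, eps > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

#' Initialize a single-layer softmax network
#'
#' The network maps the two standardized attenuation features through one
#' affine layer (`z = W x + b`, `W` of shape K x 2) and a softmax, giving
#' `K(2 + 1)` trainable parameters. Weights are drawn uniformly over
#' `+/- 1/sqrt(2)` (fan-in scaling); biases start at zero.
#'
#' @param K Output count: 4 (soft tissue) or 5 (bone).
#' @param seed Optional replicate master seed (uses the `"init"` stream).
#' @param elements Optional element names for the outputs.
#' @return A `dect_net`: list with `W` (K x 2), `b` (K), `elements`.
#' @export
init_net <- function(K, seed = NULL, elements = NULL) {
  if (!K %in% c(4L, 5L)) stop("K must be 4 (soft) or 5 (bone)")
  if (is.null(elements)) elements <- if (K == 4) SOFT_ELEMENTS else BONE_ELEMENTS
  stopifnot(length(elements) == K)
  lim <- 1 / sqrt(2)  # fan_in = 2 input features
  W <- with_stream(seed, "init",
                   expr = matrix(runif(2 * K, -lim, lim), nrow = K))
  structure(list(W = W, b = rep(0, K), elements = elements,
                 history = NULL, config = NULL),
            class = "dect_net")
}

#' @export
print.dect_net <- function(x, ...) {
  K <- nrow(x$W)
  cat("<dect_net>", K, "outputs,", 3 * K, "parameters",
      if (is.null(x$history)) "(untrained)" else "(trained)", "\n")
  invisible(x)
}

#' Softmax network forward pass
#'
#' `z = W x + b`; `w_hat_i = exp(z_i) / sum_j exp(z_j)`, computed with
#' max-subtraction for overflow safety. Outputs are strictly positive and
#' sum to one, enforcing physically plausible mass fractions by
#' construction.
#'
#' @param net A `dect_net`.
#' @param x n x 2 matrix (or length-2 vector) of standardized features.
#' @return n x K matrix of predictions on the K-simplex.
#' @export
forward_net <- function(net, x) {
  stopifnot(inherits(net, "dect_net"))
  x <- if (is.null(dim(x))) matrix(x, ncol = 2) else as.matrix(x)
  z <- x %*% t(net$W) + matrix(net$b, nrow(x), length(net$b), byrow = TRUE)
  z <- z - apply(z, 1, max)
  e <- exp(z)
  out <- e / rowSums(e)
  colnames(out) <- net$elements
  out
}

#' @rdname forward_net
#' @export
predict_net <- function(net, x) forward_net(net, x)

# MSE loss (mean over samples and channels) of the softmax net and its
# analytic gradient. Used by the optimizer and by gradient-check tests.
net_loss_grad <- function(net, x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  K <- nrow(net$W)
  what <- forward_net(net, x)
  r <- what - y
  g <- 2 * r / (K * n)
  gdot <- rowSums(g * what)           # length n
  dz <- what * (g - gdot)             # n x K
  list(
    loss = mean(r^2),
    dW = t(dz) %*% x,                 # K x 2
    db = colSums(dz)
  )
}

#' Train the softmax network with mini-batch Adam
#'
#' Minimizes the MSE between softmax outputs and target mass fractions by
#' mini-batch gradient descent with Adam updates. Batches are reshuffled
#' every epoch (last incomplete batch included); training always runs the
#' configured number of epochs, with the validation set used only to
#' record monitoring metrics.
#'
#' @param net An initialized `dect_net`.
#' @param x,y Training features (n x 2, standardized) and targets (n x K,
#'   in `[0, 1]`).
#' @param xval,yval Optional validation features/targets for monitoring.
#' @param config A [train_config()].
#' @param seed Optional replicate master seed; the per-epoch batch
#'   permutations are drawn from the `"batches"` stream.
#' @return The trained `dect_net`, with `history` (tibble of per-epoch
#'   `train_mse`, `train_mae`, `val_mse`, `val_mae`) and `config` attached.
#' @export
train_net <- function(net, x, y, xval = NULL, yval = NULL,
                      config = train_config(), seed = NULL) {
  stopifnot(inherits(net, "dect_net"), inherits(config, "train_config"))
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows")
  if (any(y < 0 | y > 1)) stop("targets must lie in [0, 1]")
  n <- nrow(x)
  perms <- with_stream(seed, "batches", expr = {
    vapply(seq_len(config$epochs), function(i) sample.int(n), integer(n))
  })
  fit <- train_softmax_adam_cpp(
    x, y, net$W, net$b, perms,
    config$learning_rate, config$batch_size,
    config$beta1, config$beta2, config$eps,
    if (is.null(xval)) NULL else as.matrix(xval),
    if (is.null(yval)) NULL else as.matrix(yval)
  )
  net$W <- fit$W
  net$b <- fit$b
  net$history <- tibble::tibble(
    epoch = seq_len(config$epochs),
    train_mse = fit$history[, 1], train_mae = fit$history[, 2],
    val_mse = fit$history[, 3], val_mae = fit$history[, 4]
  )
  net$config <- config
  net
}

#' Model serialization
#'
#' Writes a fitted model (either family) as JSON holding the element
#' order, coefficients or weights, configuration and loss history;
#' `read_model()` reconstructs the object.
#'
#' @param model A `dect_lm` or `dect_net`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "dect_lm")) {
    obj <- list(type = "lm", elements = model$elements,
                coef = model$coef, residual_rms = model$residual_rms,
                n_train = model$n_train)
  } else if (inherits(model, "dect_net")) {
    obj <- list(type = "nn", elements = model$elements,
                W = model$W, b = model$b,
                config = unclass(model$config), history = model$history)
  } else {
    stop("unsupported model class")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "lm")) {
    coef <- as.matrix(obj$coef)
    dimnames(coef) <- list(c("(Intercept)", "x1", "x2"), obj$elements)
    rms <- as.numeric(unlist(obj$residual_rms))
    names(rms) <- obj$elements
    structure(list(coef = coef, elements = obj$elements,
                   residual_rms = rms,
                   n_train = obj$n_train),
              class = "dect_lm")
  } else if (identical(obj$type, "nn")) {
    structure(list(W = as.matrix(obj$W), b = as.numeric(obj$b),
                   elements = obj$elements,
                   history = if (is.null(obj$history)) NULL
                             else tibble::as_tibble(obj$history),
                   config = if (is.null(obj$config)) NULL
                            else do.call(train_config, as.list(obj$config))),
              class = "dect_net")
  } else {
    stop("unrecognized model file: ", path)
  }
}
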