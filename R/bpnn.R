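#' Single-hidden-layer backpropagation network
#'
#' A fully-connected feedforward regression network `n - h - 1` with
#' logistic hidden units and a linear output, trained by
#' Levenberg-Marquardt (damped Gauss-Newton on the residual Jacobian) or
#' plain batch gradient descent.  Inputs and target are min-max scaled to
#' [0,1] before training and predictions are mapped back to the original
#' target scale.
#'
#' @name bpnn
NULL

#' Hidden-layer size candidates
#'
#' The conventional sizing rule for a single hidden layer:
#' `h = ceil(sqrt(n + m) + a)` for integer `a` in 1..10, where `n` and `m`
#' are the input and output layer sizes.  For the 41-input, 1-output
#' hospital surrogate this yields candidates 8 through 17.
#'
#' @param n number of input neurons.
#' @param m number of output neurons.
#' @return increasing integer vector of candidate hidden sizes.
#' @export
hidden_size_candidates <- function(n, m) {
  stopifnot(n >= 1, m >= 1)
  sort(unique(as.integer(ceiling(sqrt(n + m) + 1:10))))
}

#' Min-max scaling to [0,1]
#'
#' Per-feature `(x - min)/(max - min)`.  A constant feature cannot be
#' rescaled and maps to 0.5 (flagged with a warning); [inverse_scale()]
#' restores such a feature to its constant value.
#'
#' @param X numeric matrix (or vector, treated as one feature).
#' @return list with `scaled` matrix and `scaler = list(min, max)`.
#' @export
minmax_scale <- function(X) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  stopifnot(is.numeric(X), nrow(X) >= 1, all(is.finite(X)))
  mn <- apply(X, 2, min); mx <- apply(X, 2, max)
  rng <- mx - mn
  const <- rng == 0
  if (any(const)) {
    warning("constant feature(s) mapped to 0.5: ",
            paste(which(const), collapse = ", "))
  }
  S <- X
  for (j in seq_len(ncol(X))) {
    S[, j] <- if (const[j]) rep(0.5, nrow(X)) else (X[, j] - mn[j]) / rng[j]
  }
  list(scaled = S, scaler = list(min = mn, max = mx))
}

#' Apply a fitted min-max scaler to new data
#' @param X numeric matrix/vector on the original scale.
#' @param scaler `list(min, max)` from [minmax_scale()].
#' @return scaled matrix (constant features map to 0.5).
#' @export
apply_scale <- function(X, scaler) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  rng <- scaler$max - scaler$min
  S <- X
  for (j in seq_len(ncol(X))) {
    S[, j] <- if (rng[j] == 0) rep(0.5, nrow(X))
              else (X[, j] - scaler$min[j]) / rng[j]
  }
  S
}

#' Invert a min-max scaler
#' @param S scaled matrix/vector.
#' @param scaler `list(min, max)` from [minmax_scale()].
#' @return matrix on the original scale.
#' @export
inverse_scale <- function(S, scaler) {
  if (is.vector(S)) S <- matrix(S, ncol = 1)
  rng <- scaler$max - scaler$min
  X <- S
  for (j in seq_len(ncol(S))) {
    X[, j] <- if (rng[j] == 0) rep(scaler$min[j], nrow(S))
              else S[, j] * rng[j] + scaler$min[j]
  }
  X
}

#' Training configuration
#'
#' Defaults follow the published MATLAB setup: learning speed 0.05 (under
#' LM interpreted as the initial damping parameter `mu`), at most 3000
#' epochs, MSE goal `1e-5`, minimum gradient `1e-5`.  Training stops at the
#' first condition met.
#'
#' @param lr learning speed: initial LM damping `mu0`, or the gradient-descent
#'   step size when `algorithm = "gd"`.
#' @param max_epochs maximum number of epochs (accepted parameter updates).
#' @param goal target mean squared error on the scaled data.
#' @param min_grad minimum infinity-norm of the MSE gradient.
#' @param algorithm `"lm"` (Levenberg-Marquardt) or `"gd"` (batch gradient
#'   descent).
#' @param seed integer seed for weight initialization (required: training is
#'   deterministic given the seed).
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.05, max_epochs = 3000, goal = 1e-5,
                         min_grad = 1e-5, algorithm = c("lm", "gd"),
                         seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(lr > 0, max_epochs >= 0, goal > 0, min_grad > 0,
            is.numeric(seed), length(seed) == 1)
  structure(list(lr = lr, max_epochs = as.integer(max_epochs), goal = goal,
                 min_grad = min_grad, algorithm = algorithm,
                 seed = as.integer(seed)),
            class = "train_config")
}

# evaluate expr with a temporary RNG seed, restoring global state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# pack/unpack parameters <-> flat vector (order: W by column, bh, V, bo)
.bpnn_pack <- function(p) c(as.vector(p$W), p$bh, p$V, p$bo)
.bpnn_unpack <- function(theta, n, h) {
  W <- matrix(theta[seq_len(h * n)], nrow = h)
  off <- h * n
  list(W = W, bh = theta[off + seq_len(h)], V = theta[off + h + seq_len(h)],
       bo = theta[off + 2 * h + 1], n = n, h = h)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass on scaled inputs; returns yhat (scaled) and hidden activations
.bpnn_forward <- function(p, X) {
  Z <- .sigmoid(X %*% t(p$W) + matrix(p$bh, nrow(X), p$h, byrow = TRUE))
  list(yhat = as.vector(Z %*% p$V + p$bo), Z = Z)
}

# Jacobian d yhat_i / d theta, N x (h*(n+2)+1), column order matching .bpnn_pack
.bpnn_jacobian <- function(p, X) {
  fw <- .bpnn_forward(p, X)
  Z <- fw$Z
  N <- nrow(X); n <- p$n; h <- p$h
  D <- Z * (1 - Z)                              # N x h, sigmoid derivative
  VD <- sweep(D, 2, p$V, `*`)                   # N x h, d yhat / d (Wx+bh)_k
  J <- matrix(0, N, h * (n + 2) + 1)
  for (j in seq_len(n)) {                       # d/dW[, j] block (column j of W)
    J[, (j - 1) * h + seq_len(h)] <- VD * X[, j]
  }
  J[, h * n + seq_len(h)] <- VD                 # d/d bh
  J[, h * n + h + seq_len(h)] <- Z              # d/d V
  J[, h * (n + 2) + 1] <- 1                     # d/d bo
  J
}

#' Initialize a network
#'
#' Weights and biases drawn uniform(-0.5, 0.5) from a seeded generator; the
#' global RNG state is left untouched.
#'
#' @param n input size.
#' @param hidden hidden-layer size.
#' @param seed integer seed.
#' @return parameter list `W (h x n), bh, V, bo, n, h`.
#' @export
bpnn_init <- function(n, hidden, seed) {
  npar <- hidden * (n + 2) + 1
  theta <- .with_seed(seed, stats::runif(npar, -0.5, 0.5))
  .bpnn_unpack(theta, n, hidden)
}

# one LM training run on scaled data; returns params + trace + stop reason
.bpnn_train_lm <- function(p, X, y, cfg) {
  theta <- .bpnn_pack(p)
  n <- p$n; h <- p$h; N <- nrow(X)
  mu <- cfg$lr
  mse_of <- function(th) {
    e <- y - .bpnn_forward(.bpnn_unpack(th, n, h), X)$yhat
    mean(e^2)
  }
  mse <- mse_of(theta)
  trace <- data.frame(epoch = 0L, mse = mse)
  stop_reason <- "max_epochs"
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    if (mse <= cfg$goal) { stop_reason <- "goal"; break }
    pcur <- .bpnn_unpack(theta, n, h)
    e <- y - .bpnn_forward(pcur, X)$yhat
    J <- .bpnn_jacobian(pcur, X)
    g <- as.vector(crossprod(J, e))             # gradient of SSE/2 (sign-flipped)
    if (max(abs(2 * g / N)) <= cfg$min_grad) { stop_reason <- "min_grad"; break }
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (!accepted && mu <= 1e10) {
      delta <- tryCatch(
        solve(JtJ + diag(mu, ncol(J)), g),
        error = function(err) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.vector(delta)
        mse_new <- mse_of(cand)
        if (is.finite(mse_new) && mse_new < mse) {
          theta <- cand; mse <- mse_new
          mu <- max(mu / 10, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!accepted) { stop_reason <- "mu_cap"; break }
    epoch <- epoch + 1L
    trace <- rbind(trace, data.frame(epoch = epoch, mse = mse))
  }
  if (mse <= cfg$goal && stop_reason == "max_epochs") stop_reason <- "goal"
  if (!is.finite(mse)) stop("training diverged: non-finite loss", call. = FALSE)
  list(params = .bpnn_unpack(theta, n, h), trace = trace,
       stop_reason = stop_reason)
}

.bpnn_train_gd <- function(p, X, y, cfg) {
  theta <- .bpnn_pack(p)
  n <- p$n; h <- p$h; N <- nrow(X)
  fw <- .bpnn_forward(p, X)
  mse <- mean((y - fw$yhat)^2)
  trace <- data.frame(epoch = 0L, mse = mse)
  stop_reason <- "max_epochs"
  for (epoch in seq_len(cfg$max_epochs)) {
    if (mse <= cfg$goal) { stop_reason <- "goal"; break }
    pcur <- .bpnn_unpack(theta, n, h)
    e <- y - .bpnn_forward(pcur, X)$yhat
    J <- .bpnn_jacobian(pcur, X)
    grad <- -2 * as.vector(crossprod(J, e)) / N   # gradient of MSE
    if (max(abs(grad)) <= cfg$min_grad) { stop_reason <- "min_grad"; break }
    theta <- theta - cfg$lr * grad
    mse <- mean((y - .bpnn_forward(.bpnn_unpack(theta, n, h), X)$yhat)^2)
    if (!is.finite(mse)) stop("training diverged: non-finite loss", call. = FALSE)
    trace <- rbind(trace, data.frame(epoch = epoch, mse = mse))
  }
  if (mse <= cfg$goal && stop_reason == "max_epochs") stop_reason <- "goal"
  list(params = .bpnn_unpack(theta, n, h), trace = trace,
       stop_reason = stop_reason)
}

#' Fit a backpropagation network
#'
#' Scales `X` and `y` to [0,1], initializes weights from `cfg$seed` and
#' trains until the MSE goal, the epoch cap or the minimum gradient is
#' reached.  With the LM backend a step is accepted only if it lowers the
#' MSE (damping `mu` shrinks tenfold on acceptance, grows tenfold on
#' rejection, capped at 1e10), so the recorded trace is non-increasing.
#'
#' @param X numeric feature matrix (hospitals x indicators), original scale.
#' @param y numeric target vector, original scale.
#' @param hidden hidden-layer size.
#' @param cfg a [train_config()].
#' @return a `bpnn` model: parameters, scalers, config, training `trace`
#'   (`epoch`, `mse` on the scaled data) and `stop_reason`.
#' @export
bpnn_fit <- function(X, y, hidden, cfg = train_config()) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  stopifnot(is.numeric(X), is.numeric(y), nrow(X) == length(y), hidden >= 1,
            inherits(cfg, "train_config"))
  sx <- minmax_scale(X)
  sy <- minmax_scale(y)
  p0 <- bpnn_init(ncol(X), hidden, cfg$seed)
  fit <- if (cfg$algorithm == "lm") .bpnn_train_lm(p0, sx$scaled, as.vector(sy$scaled), cfg)
         else .bpnn_train_gd(p0, sx$scaled, as.vector(sy$scaled), cfg)
  structure(list(params = fit$params, x_scaler = sx$scaler, y_scaler = sy$scaler,
                 hidden = hidden, n_inputs = ncol(X), config = cfg,
                 trace = fit$trace, stop_reason = fit$stop_reason),
            class = "bpnn")
}

#' Predict from a fitted network
#'
#' Forward pass `yhat = V . sigmoid(W x + b_h) + b_o` on min-max-scaled
#' inputs, inverse-scaled back to the original target units.
#'
#' @param object a `bpnn` model.
#' @param newdata numeric matrix with `n_inputs` columns.
#' @param ... unused.
#' @return numeric prediction vector.
#' @export
predict.bpnn <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_inputs) {
    stop("feature count mismatch: model expects ", object$n_inputs,
         " inputs, got ", ncol(newdata), call. = FALSE)
  }
  S <- apply_scale(newdata, object$x_scaler)
  yhat_s <- .bpnn_forward(object$params, S)$yhat
  as.vector(inverse_scale(yhat_s, object$y_scaler))
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("bpnn %d-%d-1, %s backend, stopped on '%s' after %d epochs (MSE %.3g)\n",
              x$n_inputs, x$hidden, x$config$algorithm, x$stop_reason,
              max(x$trace$epoch), x$trace$mse[nrow(x$trace)]))
  invisible(x)
}

#' Regression metrics
#'
#' `MSE = mean((y - yhat)^2)`, `RMSE = sqrt(MSE)`,
#' `R^2 = 1 - SSres/SStot` (optionally the squared Pearson correlation), and
#' `MAPE = (100/N) sum |y - yhat| / |y|`.  Pairs with `y = 0` are excluded
#' from MAPE with a warning (the term is undefined).
#'
#' @param y observed values, length >= 2.
#' @param yhat predicted values, same length.
#' @param r2_method `"one_minus_ratio"` (default) or `"squared_cor"`.
#' @return list `mse, rmse, r2, mape` (MAPE in percent) plus the pairs.
#' @export
metrics <- function(y, yhat, r2_method = c("one_minus_ratio", "squared_cor")) {
  r2_method <- match.arg(r2_method)
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  e <- y - yhat
  mse <- mean(e^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (r2_method == "squared_cor") stats::cor(y, yhat)^2
        else 1 - sum(e^2) / sstot
  nz <- y != 0
  if (!all(nz)) warning(sum(!nz), " observation(s) equal to 0 excluded from MAPE")
  mape <- 100 * mean(abs(e[nz] / y[nz]))
  list(mse = mse, rmse = sqrt(mse), r2 = r2, mape = mape, y = y, yhat = yhat)
}

#' Serialize a fitted network to JSON
#' @param model a `bpnn`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
bpnn_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "bpnn"))
  doc <- list(
    n_inputs = model$n_inputs, hidden = model$hidden,
    W = model$params$W, bh = model$params$bh, V = model$params$V,
    bo = model$params$bo,
    x_scaler = model$x_scaler, y_scaler = model$y_scaler,
    config = unclass(model$config), trace = model$trace,
    stop_reason = model$stop_reason)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Restore a network serialized with [bpnn_to_json()]
#' @param path JSON path or string.
#' @return a `bpnn` model.
#' @export
bpnn_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  cfg <- do.call(train_config, doc$config[c("lr", "max_epochs", "goal",
                                            "min_grad", "algorithm", "seed")])
  h <- doc$hidden; n <- doc$n_inputs
  structure(list(
    params = list(W = matrix(doc$W, nrow = h), bh = as.numeric(doc$bh),
                  V = as.numeric(doc$V), bo = as.numeric(doc$bo), n = n, h = h),
    x_scaler = list(min = as.numeric(doc$x_scaler$min),
                    max = as.numeric(doc$x_scaler$max)),
    y_scaler = list(min = as.numeric(doc$y_scaler$min),
                    max = as.numeric(doc$y_scaler$max)),
    hidden = h, n_inputs = n, config = cfg,
    trace = as.data.frame(doc$trace), stop_reason = doc$stop_reason),
    class = "bpnn")
}
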