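#' Model evaluation: LOOCV, hidden-size selection, PLSR baseline
#'
#' With only N ~ 14 hospitals, generalization is estimated by leave-one-out
#' cross-validation: the model is trained N times, each time holding out one
#' hospital, and accuracy is measured on the concatenated held-out
#' predictions.  The same driver selects the hidden-layer size and
#' benchmarks the network against a partial least-squares regression
#' baseline.
#'
#' @name evaluation
NULL

#' Leave-one-out cross-validation of the network surrogate
#'
#' Trains `N` networks, each on `N - 1` hospitals, and predicts the held-out
#' one.  Fold `i` is seeded with `cfg$seed + i` so the whole report is
#' deterministic given `cfg$seed`.  Pooled metrics (via [metrics()]) on the
#' concatenated held-out pairs are primary; because a fold holds out a
#' single sample, per-fold averaging is only meaningful for the absolute
#' error, reported as `rmse_fold_avg = mean(|y_i - yhat_i|)`.
#'
#' @param X feature matrix (N x p), `N >= 3`.
#' @param y target vector.
#' @param hidden hidden-layer size.
#' @param cfg a [train_config()].
#' @return a `cv_report`: `folds` data.frame (`held_out`, `observed`,
#'   `predicted`, `stop_reason`), pooled `rmse`, `r2`, `mape`,
#'   `rmse_fold_avg`, `hidden`, `seed`, `complete` flag.
#' @export
loocv <- function(X, y, hidden, cfg = train_config()) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  N <- nrow(X)
  stopifnot(N >= 3, length(y) == N)
  ids <- rownames(X) %||% as.character(seq_len(N))
  pred <- rep(NA_real_, N)
  reason <- character(N)
  for (i in seq_len(N)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    fit <- tryCatch(bpnn_fit(X[-i, , drop = FALSE], y[-i], hidden, cfg_i),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      reason[i] <- paste("failed:", conditionMessage(fit))
      next
    }
    pred[i] <- predict(fit, X[i, , drop = FALSE])
    reason[i] <- fit$stop_reason
  }
  ok <- !is.na(pred)
  mt <- metrics(y[ok], pred[ok])
  structure(list(
    folds = data.frame(held_out = ids, observed = y, predicted = pred,
                       stop_reason = reason, stringsAsFactors = FALSE),
    rmse = mt$rmse, r2 = mt$r2, mape = mt$mape,
    rmse_fold_avg = mean(abs(y[ok] - pred[ok])),
    hidden = hidden, seed = cfg$seed, complete = all(ok)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("LOOCV (%d folds, hidden = %d, seed = %d)%s\n",
              nrow(x$folds), x$hidden, x$seed,
              if (x$complete) "" else " [INCOMPLETE: failed folds]"))
  cat(sprintf("  pooled R2 = %.4f, RMSE = %.4f, MAPE = %.4f%%\n",
              x$r2, x$rmse, x$mape))
  invisible(x)
}

#' Select the hidden-layer size by LOOCV
#'
#' Runs [loocv()] for each candidate size and picks the best: highest pooled
#' R-squared, ties broken by lowest RMSE, then by the smaller size.
#'
#' @param X feature matrix.
#' @param y target vector.
#' @param candidates integer vector of hidden sizes (e.g.
#'   [hidden_size_candidates()]).
#' @param cfg a [train_config()].
#' @return list with `best` (integer), `table` (data.frame `neurons, r2,
#'   rmse, mape, complete`) and `reports` (the per-size `cv_report`s).
#' @export
select_hidden_size <- function(X, y, candidates, cfg = train_config()) {
  stopifnot(length(candidates) >= 1)
  reports <- lapply(candidates, function(hh) loocv(X, y, hh, cfg))
  tab <- data.frame(
    neurons = as.integer(candidates),
    r2 = vapply(reports, `[[`, 0, "r2"),
    rmse = vapply(reports, `[[`, 0, "rmse"),
    mape = vapply(reports, `[[`, 0, "mape"),
    complete = vapply(reports, `[[`, TRUE, "complete"))
  ord <- order(-tab$r2, tab$rmse, tab$neurons)
  list(best = tab$neurons[ord[1]], table = tab, reports = reports)
}

#' Partial least-squares regression (PLS1, NIPALS)
#'
#' Univariate-response PLSR fitted by the NIPALS algorithm with deflation:
#' after centring, component `a` takes weights `w_a = X'y / |X'y|`, scores
#' `t_a = X w_a`, loadings `p_a = X't_a / t'_a t_a`, `q_a = y't_a / t'_a
#' t_a`, then deflates `X` and `y`.  `components = 0` yields the mean
#' predictor.
#'
#' @param X feature matrix (N x p).
#' @param y response vector, non-constant.
#' @param components number of latent components,
#'   `0 <= components <= min(N - 1, p)`.
#' @return a `plsr_model` with regression coefficients on the original scale.
#' @export
plsr_fit <- function(X, y, components) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  N <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == N, components >= 0, components <= min(N - 1, p))
  if (stats::var(y) == 0) stop("zero-variance response: PLSR undefined", call. = FALSE)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean
  A <- as.integer(components)
  W <- P <- matrix(0, p, A); Q <- numeric(A); TT <- matrix(0, N, A)
  a <- 0L
  while (a < A) {
    s <- as.vector(crossprod(Xc, yc))
    nrm <- sqrt(sum(s^2))
    if (nrm < 1e-12) break                      # X carries no more covariance with y
    w <- s / nrm
    t_ <- as.vector(Xc %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-24) break
    p_ <- as.vector(crossprod(Xc, t_)) / tt
    q_ <- sum(yc * t_) / tt
    a <- a + 1L
    W[, a] <- w; P[, a] <- p_; Q[a] <- q_; TT[, a] <- t_
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - t_ * q_
  }
  if (a < A) {
    W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
    Q <- Q[seq_len(a)]; TT <- TT[, seq_len(a), drop = FALSE]
  }
  beta <- if (a == 0L) rep(0, p)
          else as.vector(W %*% solve(crossprod(P, W), Q))
  structure(list(coef = beta, x_mean = x_mean, y_mean = y_mean,
                 components = a, weights = W, loadings = P, q = Q,
                 scores = TT),
            class = "plsr_model")
}

#' Predict from a PLSR model
#' @param object a `plsr_model`.
#' @param newdata feature matrix on the original scale.
#' @param ... unused.
#' @return numeric prediction vector.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  as.vector(sweep(newdata, 2, object$x_mean) %*% object$coef) + object$y_mean
}

#' Leave-one-out cross-validation of the PLSR baseline
#'
#' Mirrors [loocv()] for the linear baseline.  When `components = NULL` the
#' count is chosen by LOOCV pooled R-squared over `1..min(N - 2, p, 10)`
#' (N - 2 so every training fold of size N - 1 supports the count).
#'
#' @param X feature matrix.
#' @param y response vector.
#' @param components fixed component count, or `NULL` to select by LOOCV.
#' @return a `cv_report` (with `hidden = NA`) plus `components`; when
#'   selecting, `selection` holds the per-count pooled R-squared.
#' @export
plsr_loocv <- function(X, y, components = NULL) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  N <- nrow(X)
  stopifnot(N >= 3, length(y) == N)
  run <- function(A) {
    pred <- vapply(seq_len(N), function(i) {
      fit <- plsr_fit(X[-i, , drop = FALSE], y[-i], A)
      predict(fit, X[i, , drop = FALSE])
    }, 0)
    pred
  }
  selection <- NULL
  if (is.null(components)) {
    cand <- seq_len(min(N - 2, ncol(X), 10))
    r2s <- vapply(cand, function(A) metrics(y, run(A))$r2, 0)
    selection <- data.frame(components = cand, r2 = r2s)
    components <- cand[which.max(r2s)]
  }
  pred <- run(components)
  mt <- metrics(y, pred)
  structure(list(
    folds = data.frame(held_out = rownames(X) %||% as.character(seq_len(N)),
                       observed = y, predicted = pred,
                       stop_reason = "plsr", stringsAsFactors = FALSE),
    rmse = mt$rmse, r2 = mt$r2, mape = mt$mape,
    rmse_fold_avg = mean(abs(y - pred)),
    hidden = NA_integer_, seed = NA_integer_, complete = TRUE,
    components = components, selection = selection),
    class = "cv_report")
}

#' Per-hospital error analysis
#'
#' For each hospital the absolute error `observed - predicted` and the
#' relative error `100 |observed - predicted| / observed` (percent), with an
#' R-squared footer (`1 - SSres/SStot`).  Values are kept at full precision;
#' the print method rounds absolute errors to 4 and relative errors to 2
#' decimals.  Rows with `observed = 0` get `NA` relative error and a warning.
#'
#' @param observed numeric vector.
#' @param predicted numeric vector, same length.
#' @param ids optional row labels.
#' @return an `error_table` data.frame (`hospital_id, observed, predicted,
#'   absolute_error, relative_error`) with attribute `r2`.
#' @export
error_table <- function(observed, predicted, ids = NULL) {
  stopifnot(length(observed) == length(predicted))
  ids <- ids %||% paste0("S", seq_along(observed))
  abs_err <- observed - predicted
  rel_err <- ifelse(observed == 0, NA_real_, 100 * abs(abs_err) / observed)
  if (anyNA(rel_err)) warning("relative error undefined where observed = 0")
  out <- data.frame(hospital_id = as.character(ids), observed = observed,
                    predicted = predicted, absolute_error = abs_err,
                    relative_error = rel_err, stringsAsFactors = FALSE)
  attr(out, "r2") <- 1 - sum(abs_err^2) / sum((observed - mean(observed))^2)
  class(out) <- c("error_table", "data.frame")
  out
}

#' @export
print.error_table <- function(x, ...) {
  disp <- as.data.frame(x)
  disp$absolute_error <- round(disp$absolute_error, 4)
  disp$relative_error <- round(disp$relative_error, 2)
  print(disp, row.names = FALSE)
  cat(sprintf("R2 = %.4f\n", attr(x, "r2")))
  invisible(x)
}
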