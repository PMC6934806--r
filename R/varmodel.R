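#' Fit a multivariate autoregressive (MVAR) model
#'
#' Ordinary multivariate least squares over concatenated epochs, with
#' regressor windows that cross epoch boundaries excluded, so each epoch
#' contributes only lags from within itself. The innovation covariance is
#' estimated from the residuals with a degrees-of-freedom correction, and
#' stability (companion spectral radius < 1) is evaluated and recorded. When
#' the regressor cross-product matrix is numerically singular a small ridge
#' penalty is added and recorded.
#'
#' The returned object keeps the inverse regressor cross-product matrix,
#' which downstream renormalized-PDC computations need for the
#' coefficient-estimator covariance.
#'
#' @param signals sources x samples matrix, a sources x samples x epochs
#'   array, or a `pooled_sources` object.
#' @param order lag order p (>= 1).
#' @return object of class `mvar` with elements `order`, `A` (list of d x d
#'   coefficient matrices), `Sigma` (innovation covariance), `n_obs`,
#'   `stable`, `xtx_inv`, `residuals`, `ridge`.
#' @export
fit_var <- function(signals, order) {
  x <- as_signal_array(signals)
  d <- dim(x)[1L]; n <- dim(x)[2L]; ne <- dim(x)[3L]
  p <- as.integer(order)
  if (p < 1L) stop("'order' must be >= 1")
  if (n <= p * d + d) stop("epochs too short for the requested order")
  reg <- build_var_regression(x, p)
  fit <- var_ls(reg$X, reg$Y, d, p)
  A <- fit$A
  comp_sr <- spectral_radius(A)
  structure(list(order = p, A = A, Sigma = fit$Sigma, n_obs = nrow(reg$X),
                 stable = comp_sr < 1, spectral_radius = comp_sr,
                 xtx_inv = fit$xtx_inv, residuals = fit$resid,
                 ridge = fit$ridge, d = d, fs = attr(signals, "fs")),
            class = "mvar")
}

as_signal_array <- function(signals) {
  if (inherits(signals, "pooled_sources")) {
    out <- signals$signals
    attr(out, "fs") <- signals$fs
    return(out)
  }
  if (is.matrix(signals)) return(array(signals, dim = c(dim(signals), 1L)))
  if (is.array(signals) && length(dim(signals)) == 3L) return(signals)
  stop("'signals' must be a matrix, 3-d array or pooled_sources object")
}

# Stacked lagged regression over epochs, excluding boundary-crossing windows.
build_var_regression <- function(x, p, start = p + 1L) {
  d <- dim(x)[1L]; n <- dim(x)[2L]; ne <- dim(x)[3L]
  rows_per_epoch <- n - start + 1L
  X <- matrix(0, rows_per_epoch * ne, d * p)
  Y <- matrix(0, rows_per_epoch * ne, d)
  for (e in seq_len(ne)) {
    xe <- x[, , e, drop = FALSE][, , 1L, drop = FALSE]
    dim(xe) <- dim(x)[1:2]
    rows <- (e - 1L) * rows_per_epoch + seq_len(rows_per_epoch)
    Y[rows, ] <- t(xe[, start:n, drop = FALSE])
    for (k in seq_len(p))
      X[rows, (k - 1L) * d + seq_len(d)] <- t(xe[, (start - k):(n - k), drop = FALSE])
  }
  list(X = X, Y = Y)
}

var_ls <- function(X, Y, d, p) {
  xtx <- crossprod(X)
  ridge <- 0
  xtx_inv <- tryCatch(solve(xtx), error = function(e) NULL)
  if (is.null(xtx_inv) || kappa(xtx, exact = FALSE) > 1e12) {
    ridge <- 1e-6 * mean(diag(xtx))
    xtx_inv <- tryCatch(solve(xtx + ridge * diag(ncol(X))),
                        error = function(e) stop("regressor matrix singular even after ridge"))
  }
  B <- xtx_inv %*% crossprod(X, Y)          # (d p) x d
  resid <- Y - X %*% B
  dof <- max(nrow(X) - ncol(X), 1L)
  Sigma <- crossprod(resid) / dof
  A <- lapply(seq_len(p), function(k) t(B[(k - 1L) * d + seq_len(d), , drop = FALSE]))
  list(A = A, Sigma = Sigma, resid = resid, xtx_inv = xtx_inv, ridge = ridge)
}

#' @export
print.mvar <- function(x, ...) {
  cat(sprintf("MVAR(%d) fit: %d signals, %d observations, %sstable (spectral radius %.3f)%s\n",
              x$order, x$d, x$n_obs, if (x$stable) "" else "NOT ",
              x$spectral_radius,
              if (x$ridge > 0) sprintf(", ridge %.2g", x$ridge) else ""))
  invisible(x)
}

#' @export
summary.mvar <- function(object, ...) {
  cat(sprintf("MVAR(%d), d = %d, n_obs = %d\n", object$order, object$d, object$n_obs))
  for (k in seq_along(object$A)) {
    cat(sprintf("A%d:\n", k)); print(round(object$A[[k]], 4))
  }
  cat("Innovation covariance:\n"); print(round(object$Sigma, 5))
  invisible(object)
}

#' @export
coef.mvar <- function(object, ...) object$A

#' @export
residuals.mvar <- function(object, ...) object$residuals

#' Simulate from a fitted MVAR model
#'
#' @param object an `mvar` fit.
#' @param nsim number of samples to generate.
#' @param seed optional integer seed.
#' @param burn burn-in samples discarded at the start.
#' @param ... unused.
#' @return sources x nsim matrix.
#' @export
simulate.mvar <- function(object, nsim = 1000L, seed = NULL, burn = 200L, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$d; p <- object$order
  L <- chol(object$Sigma + 1e-12 * diag(d))
  n <- nsim + burn
  eps <- t(matrix(stats::rnorm(n * d), n, d) %*% L)
  y <- matrix(0, d, n)
  for (t in (p + 1L):n) {
    acc <- eps[, t]
    for (k in seq_len(p)) acc <- acc + object$A[[k]] %*% y[, t - k]
    y[, t] <- acc
  }
  y[, (burn + 1L):n, drop = FALSE]
}

#' One-step-ahead predictions from an MVAR fit
#'
#' @param object an `mvar` fit.
#' @param newdata sources x samples matrix.
#' @param ... unused.
#' @return sources x samples matrix of predictions (first `order` columns NA).
#' @export
predict.mvar <- function(object, newdata, ...) {
  x <- as_signal_array(newdata)[, , 1L]
  p <- object$order
  out <- matrix(NA_real_, nrow(x), ncol(x))
  for (t in (p + 1L):ncol(x)) {
    acc <- numeric(nrow(x))
    for (k in seq_len(p)) acc <- acc + object$A[[k]] %*% x[, t - k]
    out[, t] <- acc
  }
  out
}

#' MVAR order selection by the Akaike information criterion
#'
#' `AIC(p) = log det(Sigma_hat(p)) + 2 p d^2 / T`, where all candidate
#' orders are fitted on a common effective sample (regressions start at
#' `max_order + 1` in every epoch) so the criterion values are comparable.
#' Ties are broken towards the smaller order.
#'
#' @param signals as in [fit_var()].
#' @param max_order largest candidate order (default 20).
#' @return list with `order` (selected), `aic` (criterion curve) and
#'   `orders` (candidate grid).
#' @export
select_order_aic <- function(signals, max_order = 20L) {
  x <- as_signal_array(signals)
  d <- dim(x)[1L]
  max_order <- as.integer(max_order)
  if (max_order < 1L) stop("'max_order' must be >= 1")
  if (dim(x)[2L] <= max_order + d * max_order)
    stop("'max_order' infeasible for this epoch length")
  aic <- numeric(max_order)
  for (p in seq_len(max_order)) {
    reg <- build_var_regression(x, p, start = max_order + 1L)
    fit <- var_ls(reg$X, reg$Y, d, p)
    Tn <- nrow(reg$X)
    ldet <- determinant(fit$Sigma, logarithm = TRUE)
    aic[p] <- as.numeric(ldet$modulus) + 2 * p * d^2 / Tn
  }
  if (all(!is.finite(aic))) stop("AIC non-finite at every candidate order")
  list(order = which.min(aic), aic = aic, orders = seq_len(max_order))
}
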