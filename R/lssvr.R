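# Least-squares support-vector regression. The equality-constrained SVR
# primal reduces, through its KKT conditions, to one dense linear solve of
# the (n+1) x (n+1) saddle system
#     [ 0   1^T        ] [ b ]   [ 0 ]
#     [ 1   K + I/J    ] [ a ] = [ y ]
# after which prediction is yhat(x) = sum_i a_i K(x, x_i) + b. The feature
# map behind the kernel is never materialised.

#' RBF kernel
#'
#' k(x, x') = exp(-||x - x'||^2 / sigma2). Note the width parameterisation:
#' sigma2 divides the squared distance directly (no factor 2), so it is
#' equivalent to the textbook 2*sigma^2 form up to reparameterisation.
#'
#' @param x,y Numeric matrices (rows are points) or vectors; \code{y = NULL}
#'   computes the kernel of \code{x} with itself.
#' @param sigma2 Kernel width (> 0).
#' @return Kernel matrix of similarities in (0, 1].
#' @export
rbf_kernel <- function(x, y = NULL, sigma2 = 1) {
  assert_number(sigma2, "sigma2", lower = 0, strict_lower = TRUE)
  x <- as.matrix(x)
  y <- if (is.null(y)) x else as.matrix(y)
  if (ncol(x) != ncol(y)) stop("dimension mismatch between point sets")
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma2)
}

#' Least-squares support-vector regression
#'
#' Fits an RBF-kernel LSSVR by solving the dual KKT system in one dense
#' linear solve (no quadratic programming). \code{J} weights the squared
#' slack penalty (larger J fits the training data more tightly); the dual
#' coefficients satisfy sum(a) = 0 by construction. Inputs are standardized
#' with training mean/SD before kernel evaluation, so the width
#' \code{sigma2} is expressed on a common scale.
#'
#' @param x Numeric matrix or vector of inputs (rows are observations), or
#'   a formula.
#' @param y Numeric response vector.
#' @param J Regularization weight (> 0, default 100).
#' @param sigma2 RBF kernel width (> 0, default 1).
#' @param scale Standardize inputs by training mean/SD (default TRUE).
#' @param data,... For the formula method: the data frame holding the model
#'   variables, and arguments passed on.
#' @return Object of class \code{"lssvr"} with dual coefficients
#'   \code{alpha}, bias \code{b}, kernel parameters, and the (scaled)
#'   training inputs.
#' @examples
#' x <- seq(0, 1, length.out = 20)
#' fit <- lssvr(x, sin(2 * pi * x), J = 1000, sigma2 = 0.5)
#' predict(fit, c(0.25, 0.75))
#' @export
lssvr <- function(x, ...) UseMethod("lssvr")

#' @rdname lssvr
#' @export
lssvr.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- lssvr.default(X, stats::model.response(mf), ...)
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit
}

#' @rdname lssvr
#' @export
lssvr.default <- function(x, y, J = 100, sigma2 = 1, scale = TRUE, ...) {
  assert_number(J, "J", lower = 0, strict_lower = TRUE)
  assert_number(sigma2, "sigma2", lower = 0, strict_lower = TRUE)
  X <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) stop("nrow(x) must equal length(y)")
  if (n < 1L) stop("need at least one training point")
  if (anyNA(X) || anyNA(y)) stop("missing values in training data")
  center <- if (scale) colMeans(X) else rep(0, ncol(X))
  scl <- if (scale) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")
  K <- rbf_kernel(Xs, sigma2 = sigma2)
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / J))
  sol <- tryCatch(solve(M, c(0, y)), error = function(e)
    stop(sprintf("dual KKT system is singular (rcond = %.3g): %s",
                 1 / kappa(M), conditionMessage(e)), call. = FALSE))
  b <- sol[1L]
  a <- sol[-1L]
  resid_sys <- max(abs(M %*% sol - c(0, y)))
  if (resid_sys > 1e-6)
    warning(sprintf("KKT system residual %.3g; solution may be inaccurate",
                    resid_sys))
  fit <- structure(list(alpha = a, b = b, J = J, sigma2 = sigma2,
                        x_scaled = Xs, x_center = center, x_scale = scl,
                        y = y, system_residual = resid_sys,
                        call = match.call()),
                   class = "lssvr")
  fit$fitted <- predict(fit, X)
  fit
}

scale_query <- function(object, newdata) {
  X <- as.matrix(newdata)
  if (ncol(X) == 1L && ncol(object$x_scaled) != 1L) X <- t(X)
  if (ncol(X) != ncol(object$x_scaled))
    stop("query dimension does not match training inputs")
  sweep(sweep(X, 2L, object$x_center), 2L, object$x_scale, "/")
}

#' @export
predict.lssvr <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    mf <- stats::model.frame(stats::delete.response(object$terms), newdata)
    newdata <- stats::model.matrix(stats::delete.response(object$terms), mf)
    newdata <- newdata[, colnames(newdata) != "(Intercept)", drop = FALSE]
  }
  Q <- scale_query(object, newdata)
  drop(rbf_kernel(Q, object$x_scaled, sigma2 = object$sigma2) %*%
         object$alpha) + object$b
}

#' @export
print.lssvr <- function(x, ...) {
  cat(sprintf("LSSVR (RBF kernel): n = %d, J = %g, sigma2 = %g\n",
              length(x$alpha), x$J, x$sigma2))
  cat(sprintf("  bias b = %.4f, sum(alpha) = %.2e, training RMSE = %.4f\n",
              x$b, sum(x$alpha),
              sqrt(mean((x$y - x$fitted)^2))))
  invisible(x)
}

#' @export
summary.lssvr <- function(object, ...) {
  r <- object$y - object$fitted
  structure(list(n = length(object$alpha), J = object$J,
                 sigma2 = object$sigma2, b = object$b,
                 train_rmse = sqrt(mean(r^2)), train_mae = mean(abs(r)),
                 system_residual = object$system_residual),
            class = "summary.lssvr")
}

#' @export
print.summary.lssvr <- function(x, ...) {
  cat(sprintf(paste0("LSSVR fit: n = %d, J = %g, sigma2 = %g\n",
                     "  bias %.4f, training RMSE %.4f, MAE %.4f, ",
                     "KKT residual %.2e\n"),
              x$n, x$J, x$sigma2, x$b, x$train_rmse, x$train_mae,
              x$system_residual))
  invisible(x)
}

#' @export
coef.lssvr <- function(object, ...) {
  c(b = object$b, stats::setNames(object$alpha,
                                  paste0("a", seq_along(object$alpha))))
}

#' @export
fitted.lssvr <- function(object, ...) object$fitted

#' @export
residuals.lssvr <- function(object, ...) object$y - object$fitted

#' Exact leave-one-out residuals of an LSSVR fit
#'
#' Computes the n leave-one-out prediction residuals from a single solve of
#' the dual KKT system: with saddle matrix M and dual solution a, the
#' residual of point i under the model refitted without it is
#' a_i / (M^-1)_ii. This evaluates hyperparameters at the full training
#' size, so near-interpolating (unstable) settings are penalised exactly.
#'
#' @param x Inputs (rows are observations).
#' @param y Response vector.
#' @param J,sigma2,scale As in \code{lssvr}.
#' @return Numeric vector of leave-one-out residuals y_i - yhat_(-i)(x_i).
#' @export
lssvr_loo_residuals <- function(x, y, J = 100, sigma2 = 1, scale = TRUE) {
  assert_number(J, "J", lower = 0, strict_lower = TRUE)
  assert_number(sigma2, "sigma2", lower = 0, strict_lower = TRUE)
  X <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2L) stop("leave-one-out needs at least two points")
  if (scale) {
    scl <- apply(X, 2L, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    X <- sweep(sweep(X, 2L, colMeans(X)), 2L, scl, "/")
  }
  K <- rbf_kernel(X, sigma2 = sigma2)
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / J))
  Minv <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Minv)) return(rep(Inf, n))
  sol <- Minv %*% c(0, y)
  drop(sol[-1L] / diag(Minv)[-1L])
}

#' Serialize an LSSVR model to JSON
#'
#' Stores dual coefficients, bias, kernel parameters, scaling and the
#' scaled training inputs at full precision, enough to reproduce
#' predictions exactly.
#'
#' @param object A fitted \code{lssvr}.
#' @param path JSON file path.
#' @export
write_lssvr_json <- function(object, path) {
  stopifnot(inherits(object, "lssvr"))
  jsonlite::write_json(list(alpha = object$alpha, b = object$b, J = object$J,
                            sigma2 = object$sigma2,
                            x_scaled = object$x_scaled,
                            x_center = object$x_center,
                            x_scale = object$x_scale, y = object$y),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lssvr_json
#' @export
read_lssvr_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- structure(list(alpha = o$alpha, b = o$b, J = o$J,
                        sigma2 = o$sigma2,
                        x_scaled = as.matrix(o$x_scaled),
                        x_center = o$x_center, x_scale = o$x_scale,
                        y = o$y, system_residual = NA_real_,
                        call = quote(read_lssvr_json())),
                   class = "lssvr")
  fit$fitted <- drop(rbf_kernel(fit$x_scaled, sigma2 = fit$sigma2) %*%
                       fit$alpha) + fit$b
  fit
}
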