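#' Squared-exponential kernel specification
#'
#' Defines the covariance function of the Gaussian-process (maximum-entropy)
#' prior on the regression function.  The squared-exponential form is
#' \deqn{\kappa(x_i, x_j) = u_0 \exp\{-(w_0/2)\,\|x_i - x_j\|^2\},}
#' where \code{u0} is the global scale (the prior marginal variance of the
#' regression function) and \code{w0} the smoothing rate (inverse squared
#' length-scale).  A small jitter ridge is added to the diagonal of every Gram
#' matrix because squared-exponential Gram matrices on dense one-dimensional
#' designs are numerically singular.
#'
#' @param u0 positive global scale of the covariance.
#' @param w0 positive smoothing rate.
#' @param jitter nonnegative ridge added to the diagonal of Gram matrices;
#'   defaults to \code{1e-8 * u0}.
#' @param form \code{"squared_exponential"} or \code{"user_supplied"}.
#' @param fun for \code{form = "user_supplied"}, a function
#'   \code{f(X1, X2)} returning the cross-covariance matrix.
#' @return an object of class \code{"rsgpr_kernel"}.
#' @export
kernel_spec <- function(u0 = 400, w0 = 200, jitter = 1e-8 * u0,
                        form = c("squared_exponential", "user_supplied"),
                        fun = NULL) {
  form <- match.arg(form)
  if (!is.numeric(u0) || length(u0) != 1L || !is.finite(u0) || u0 <= 0)
    stop("'u0' must be a positive scalar")
  if (!is.numeric(w0) || length(w0) != 1L || !is.finite(w0) || w0 <= 0)
    stop("'w0' must be a positive scalar")
  if (jitter < 0) stop("'jitter' must be nonnegative")
  if (form == "user_supplied" && !is.function(fun))
    stop("'fun' must be a function for a user-supplied kernel")
  structure(list(form = form, u0 = u0, w0 = w0, jitter = jitter, fun = fun),
            class = "rsgpr_kernel")
}

#' @export
print.rsgpr_kernel <- function(x, ...) {
  cat(sprintf("<rsgpr_kernel> %s: u0 = %g, w0 = %g, jitter = %g\n",
              x$form, x$u0, x$w0, x$jitter))
  invisible(x)
}

as_design_matrix <- function(X) {
  if (is.null(dim(X))) X <- matrix(as.numeric(X), ncol = 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X)))
    stop("design matrix contains non-finite entries")
  X
}

#' Kernel Gram and cross-covariance matrices
#'
#' \code{kernel_matrix} evaluates the kernel on all pairs of rows of \code{X}
#' (adding the jitter ridge to the diagonal); \code{kernel_cross} evaluates it
#' between rows of two designs (no jitter).
#'
#' @param X,X1,X2 numeric design matrices (rows are points); vectors are taken
#'   as a single column.
#' @param spec a [kernel_spec()].
#' @return a covariance matrix.
#' @export
kernel_matrix <- function(X, spec) {
  X <- as_design_matrix(X)
  K <- kernel_cross(X, X, spec)
  K <- (K + t(K)) / 2
  diag(K) <- diag(K) + spec$jitter
  K
}

#' @rdname kernel_matrix
#' @export
kernel_cross <- function(X1, X2, spec) {
  stopifnot(inherits(spec, "rsgpr_kernel"))
  X1 <- as_design_matrix(X1); X2 <- as_design_matrix(X2)
  if (ncol(X1) != ncol(X2)) stop("designs have different numbers of columns")
  if (spec$form == "user_supplied") return(spec$fun(X1, X2))
  ## squared distances via the usual expansion
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  spec$u0 * exp(-(spec$w0 / 2) * d2)
}

chol_or_stop <- function(K, what = "covariance matrix") {
  R <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(R))
    stop(sprintf("%s is not positive definite; the maximum-entropy prior is undefined", what))
  R
}

#' Log-density of the maximum-entropy (Gaussian process) prior
#'
#' The maximum-entropy prior of a regression-function vector with stated mean
#' \code{m} and covariance \code{K} is multivariate normal; this evaluates its
#' log density at \code{eta}.  \code{K} must be symmetric positive definite
#' (checked through its Cholesky factorization); otherwise the differential
#' entropy, and hence the prior, is undefined.
#'
#' @param eta numeric vector at which to evaluate.
#' @param m prior mean vector.
#' @param K prior covariance matrix.
#' @return the log density (scalar).
#' @export
maxent_log_prior <- function(eta, m, K) {
  n <- length(eta)
  if (length(m) != n || !all(dim(K) == c(n, n)))
    stop("dimension mismatch between 'eta', 'm' and 'K'")
  R <- chol_or_stop(K, "prior covariance 'K'")
  u <- backsolve(R, eta - m, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(u^2)
}

#' Closed-form Gaussian process regression posterior
#'
#' For fully observed Gaussian data \code{y = eta + e}, \code{e ~ N(0,
#' sigma2 I)}, with prior \code{eta ~ N(m, K)}, the conditional posterior of
#' the regression-function vector is normal with
#' \deqn{E = K(K+\sigma^2 I)^{-1} y + \sigma^2 (K+\sigma^2 I)^{-1} m, \quad
#'       V = \sigma^2 K (K+\sigma^2 I)^{-1}.}
#' All solves go through a Cholesky factorization of \code{K + sigma2 I};
#' no explicit inverse is formed.
#'
#' @param y observed response vector.
#' @param m prior mean vector.
#' @param K prior covariance matrix.
#' @param sigma2 nonnegative error variance.
#' @return list with elements \code{mean} and \code{cov}.
#' @export
gpr_posterior <- function(y, m, K, sigma2) {
  n <- length(y)
  if (length(m) != n || !all(dim(K) == c(n, n)))
    stop("dimension mismatch between 'y', 'm' and 'K'")
  if (sigma2 < 0) stop("'sigma2' must be nonnegative")
  if (sigma2 == 0) return(list(mean = as.numeric(y), cov = matrix(0, n, n)))
  A <- K + diag(sigma2, n)
  R <- chol_or_stop(A, "K + sigma2*I")
  ## solve A x = y and A x = m via the factor
  solveA <- function(b) backsolve(R, backsolve(R, b, transpose = TRUE))
  mean <- drop(K %*% solveA(y)) + sigma2 * drop(solveA(m))
  cov <- sigma2 * (K %*% apply(diag(1, n), 2L, solveA))
  cov <- (cov + t(cov)) / 2
  list(mean = mean, cov = cov)
}
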