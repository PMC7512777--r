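#' Conditional draw of the regression function at test points
#'
#' Given a draw of the regression function at the training points, the
#' Gaussian-process prior conditions to
#' \deqn{\eta_2 \mid \eta_1 \sim N\big(m_2 + K_{21}K_{11}^{-1}(\eta_1 - m_1),
#'   \; K_{22} - K_{21}K_{11}^{-1}K_{12}\big),}
#' the predictive law used to augment each retained MCMC iteration.  The
#' conditional covariance is clipped to positive semidefinite through an
#' eigendecomposition before drawing.
#'
#' @param eta1 draw of the regression function at the training points.
#' @param X1,X2 training and test designs.
#' @param spec a [kernel_spec()].
#' @param m1,m2 prior mean vectors (default zero).
#' @param moments return \code{list(mean, cov)} instead of a draw.
#' @return an n2-vector draw, or the conditional moments.
#' @export
conditional_eta2 <- function(eta1, X1, X2, spec, m1 = NULL, m2 = NULL,
                             moments = FALSE) {
  X1 <- as_design_matrix(X1); X2 <- as_design_matrix(X2)
  n1 <- nrow(X1); n2 <- nrow(X2)
  if (length(eta1) != n1) stop("'eta1' must match the training design")
  if (is.null(m1)) m1 <- numeric(n1)
  if (is.null(m2)) m2 <- numeric(n2)
  K11 <- kernel_matrix(X1, spec)
  K21 <- kernel_cross(X2, X1, spec)
  K22 <- kernel_matrix(X2, spec)
  A <- K21 %*% chol2inv(chol_or_stop(K11, "K11"))
  mu <- m2 + drop(A %*% (eta1 - m1))
  V <- K22 - A %*% t(K21)
  V <- (V + t(V)) / 2
  if (moments) return(list(mean = mu, cov = V))
  ev <- eigen(V, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n2)
  mu + drop(L %*% stats::rnorm(n2))
}

#' Predictive outcome draw at test points
#'
#' Adds scale-mixed observation noise to a regression-function draw:
#' \code{y2 = eta2 + sqrt(sigma2 * delta(omega2)) * e}, with fresh mixing
#' draws \code{omega2 ~ G} at the test indices (these latents are not
#' identified by the data and are sampled from the mixing law).
#'
#' @param eta2 regression-function draw at the test points.
#' @param sigma2 outcome error variance.
#' @param spec mixing law.
#' @return an n2-vector outcome draw.
#' @export
predictive_y2 <- function(eta2, sigma2, spec = mixing_normal()) {
  n2 <- length(eta2)
  om <- spec$sampler(n2)
  eta2 + sqrt(sigma2 * spec$delta(om)) * stats::rnorm(n2)
}

#' Pointwise posterior summaries of predicted curves
#'
#' Monte-Carlo means and percentile bands (2.5/97.5 by default, the linear
#' order-statistic interpolation of [stats::quantile()] type 7) per
#' coordinate of a draws matrix.
#'
#' @param draws matrix of retained draws (iterations x coordinates).
#' @param x optional coordinate labels (e.g. the test inputs).
#' @param probs band probabilities.
#' @return data frame with columns \code{x}, \code{mean}, \code{lo},
#'   \code{hi}.
#' @export
summarize_prediction <- function(draws, x = NULL, probs = c(0.025, 0.975)) {
  draws <- as.matrix(draws)
  if (is.null(x)) x <- seq_len(ncol(draws))
  qs <- apply(draws, 2L, stats::quantile, probs = probs, names = FALSE)
  data.frame(x = x, mean = colMeans(draws), lo = qs[1L, ], hi = qs[2L, ])
}

#' Predicted regression function and outcomes from a fitted chain
#'
#' Summarizes the bias-corrected predictive draws stored by [rsgpr_gibbs()]
#' when test points were supplied.
#'
#' @param object an \code{rsgpr_chains} object fitted with
#'   \code{predict_at}.
#' @param what \code{"eta"} (regression function) or \code{"y"} (new
#'   outcomes).
#' @param ... passed to [summarize_prediction()].
#' @return data frame of pointwise summaries.
#' @export
predict.rsgpr_chains <- function(object, what = c("eta", "y"), ...) {
  what <- match.arg(what)
  if (is.null(object$predict_at))
    stop("the chain was run without test points; refit with 'predict_at'")
  draws <- if (what == "eta") object$draws$eta2 else object$draws$y2
  summarize_prediction(draws, x = object$predict_at[, 1L], ...)
}
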