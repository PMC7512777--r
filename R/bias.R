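#' Sample a selected observation from its two-stage representation
#'
#' A selected outcome admits the stochastic representation
#' \deqn{y \mid \omega, s=1 \;=\; \eta + \rho\sigma Z_C +
#'   \sigma\sqrt{1-\rho^2}\, U,}
#' with \eqn{\omega \sim G}, \eqn{U \sim N(0, \delta(\omega))} and
#' \eqn{Z_C \sim TN_{(\alpha,\infty)}(0, \delta(\omega))} independent given
#' \eqn{\omega}.  Its distribution coincides with the skew-SMN density
#' [skew_smn_logpdf()]; the two routes cross-validate each other.
#'
#' @param n_draws number of draws.
#' @param eta regression-function value.
#' @param sigma,rho outcome error scale and selection correlation.
#' @param alpha selection threshold.
#' @param spec mixing law.
#' @return numeric vector of outcome draws.
#' @export
lemma2_sample <- function(n_draws, eta, sigma, rho, alpha,
                          spec = mixing_normal()) {
  om <- spec$sampler(n_draws)
  d <- spec$delta(om)
  zc <- rtnorm(n_draws, 0, sqrt(d), lower = alpha)
  u <- stats::rnorm(n_draws, 0, sqrt(d))
  eta + rho * sigma * zc + sigma * sqrt(1 - rho^2) * u
}

#' Mean of a one-sided truncated centred normal
#'
#' \eqn{\xi_i = \sqrt{\omega^*_{ii}}\,\phi(\beta_i/\sqrt{\omega^*_{ii}})
#'   \,/\,\{1-\Phi(\beta_i/\sqrt{\omega^*_{ii}})\}}: the mean of a
#' \eqn{N(0, \omega^*_{ii})} variable truncated to \eqn{(\beta_i, \infty)}.
#' Strictly positive, never below \eqn{\beta_i}, increasing in \eqn{\beta_i};
#' evaluated through log-scale Mills ratios so that large thresholds stay
#' stable.
#'
#' @param beta truncation thresholds (vector).
#' @param omega_diag variances \eqn{\omega^*_{ii}} (recycled).
#' @return vector of truncated means.
#' @export
trunc_mean_xi <- function(beta, omega_diag = 1) {
  omega_diag <- rep_len(omega_diag, length(beta))
  sd <- sqrt(omega_diag)
  a <- beta / sd
  sd * exp(stats::dnorm(a, log = TRUE) -
           stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
}

## operator blocks of the conditional-posterior representation (delta = 1)
bias_operators <- function(K11, sigma, rho, delta = 1) {
  n1 <- nrow(K11)
  H <- K11 + diag(delta * sigma^2, n1)
  Hc <- chol_or_stop(H, "K11 + delta*sigma^2*I")
  Omega1 <- delta * sigma^2 * (K11 %*% chol2inv(Hc))
  Omega1 <- (Omega1 + t(Omega1)) / 2
  Omega2 <- diag(delta * (1 - rho^2), n1) + rho^2 * Omega1 / sigma^2
  Omega2 <- (Omega2 + t(Omega2)) / 2
  Gamma <- -rho * Omega1 / sigma
  list(H = H, Hchol = Hc, Omega1 = Omega1, Omega2 = Omega2, Gamma = Gamma)
}

## Exact mean of N(0, a*I + b*11') truncated to all coordinates > beta,
## via the one-factor decomposition W_i = sqrt(b) Z0 + sqrt(a) E_i.
equicorr_trunc_mean <- function(a, b, beta, subdiv = 400L) {
  n1 <- length(beta)
  if (b <= 1e-12) return(trunc_mean_xi(beta, a))   # diagonal case is exact
  sa <- sqrt(a); sb <- sqrt(b)
  ## P(all > beta | z0) = prod Phi-bar((beta_i - sb z0)/sa); integrate over z0
  lw <- function(z0) {
    lp <- stats::dnorm(z0, log = TRUE)
    for (i in seq_len(n1))
      lp <- lp + stats::pnorm((beta[i] - sb * z0) / sa, lower.tail = FALSE,
                              log.p = TRUE)
    lp
  }
  zs <- seq(-9, 9, length.out = subdiv + 1L)
  lz <- vapply(zs, lw, numeric(1L))
  w <- exp(lz - max(lz)); w <- w / sum(w)
  ## conditional mean of W_i given z0 and truncation of coordinate i only
  xi <- numeric(n1)
  for (i in seq_len(n1)) {
    mcond <- sb * zs + sa * vapply(zs, function(z0)
      exp(stats::dnorm((beta[i] - sb * z0) / sa, log = TRUE) -
          stats::pnorm((beta[i] - sb * z0) / sa, lower.tail = FALSE,
                       log.p = TRUE)), numeric(1L))
    xi[i] <- sum(w * mcond)
  }
  xi
}

is_equicorrelated <- function(M, tol = 1e-8) {
  n <- nrow(M)
  if (n == 1L) return(TRUE)
  offd <- M[upper.tri(M)]
  dg <- diag(M)
  max(abs(dg - dg[1L])) < tol * max(abs(dg)) &&
    (length(offd) == 0L || max(abs(offd - offd[1L])) < tol * max(abs(dg)))
}

#' Analytic selection bias of the naive Gaussian process posterior mean
#'
#' When the plain GP regression model is fit to selected-only data generated
#' under the normal-error selection model, its conditional posterior mean of
#' the regression function is biased.  Conditioning the joint normal law of
#' (regression function, selection errors) on the observed outcomes and on
#' selection gives the gap
#' \deqn{E[\eta \mid y, \Psi] - E[\eta \mid y, \sigma^2]
#'   = \Gamma\,\Omega_2^{*-1}\, E[W_{1C_\beta}],}
#' where \eqn{\Gamma = -\rho\Omega_1^*/\sigma},
#' \eqn{\Omega_1^* = \sigma^2 K_{11}(K_{11}+\sigma^2 I)^{-1}},
#' \eqn{\Omega_2^* = (1-\rho^2)I + \rho^2\Omega_1^*/\sigma^2},
#' \eqn{W_{1C_\beta}} is a \eqn{N(0, \Omega_2^*)} vector truncated to all
#' coordinates above \eqn{\beta_i = \alpha_i - \rho(y_i - \theta_{1i})/\sigma},
#' and \eqn{\theta_1} is the smoothed (GPR) posterior mean.  The bias is
#' identically zero at \eqn{\rho = 0} and its sign is opposite to that of
#' \eqn{\rho}; its magnitude grows with \eqn{|\rho|} and with the thresholds.
#'
#' The truncated mean is computed exactly by a one-factor quadrature when
#' \eqn{\Omega_2^*} is equicorrelated (the intra-class illustration setting)
#' and by the componentwise marginal formula [trunc_mean_xi()] otherwise
#' (exact for diagonal \eqn{\Omega_2^*}, an approximation when truncation
#' correlation is appreciable).
#'
#' @param y_obs observed (selected) outcomes.
#' @param K11 prior covariance at the selected points.
#' @param m1 prior mean vector.
#' @param sigma,rho error scale and selection correlation.
#' @param alphas selection thresholds \eqn{\alpha_i} (recycled).
#' @param beta optional: supply the truncation thresholds directly (overrides
#'   the \code{y_obs}-based computation; used for bias curves over a grid of
#'   thresholds).
#' @param xi_method \code{"auto"} (one-factor quadrature when equicorrelated,
#'   marginal otherwise), \code{"marginal"}, or \code{"factor"}.
#' @return bias vector (length n1).
#' @export
selection_bias <- function(y_obs, K11, m1 = NULL, sigma, rho, alphas,
                           beta = NULL,
                           xi_method = c("auto", "marginal", "factor")) {
  xi_method <- match.arg(xi_method)
  if (abs(rho) >= 1) stop("'rho' must lie strictly inside (-1, 1)")
  n1 <- nrow(K11)
  if (is.null(m1)) m1 <- numeric(n1)
  if (rho == 0) return(numeric(n1))
  op <- bias_operators(K11, sigma, rho)
  if (is.null(beta)) {
    alphas <- rep_len(alphas, n1)
    theta1 <- drop(K11 %*% backsolve(op$Hchol,
                 backsolve(op$Hchol, y_obs, transpose = TRUE))) +
      sigma^2 * backsolve(op$Hchol,
                 backsolve(op$Hchol, m1, transpose = TRUE))
    beta <- alphas - rho * (y_obs - theta1) / sigma
  } else beta <- rep_len(beta, n1)
  use_factor <- switch(xi_method,
    auto = is_equicorrelated(op$Omega2),
    marginal = FALSE, factor = TRUE)
  xi <- if (use_factor) {
    dg <- diag(op$Omega2)[1L]
    off <- if (n1 > 1L) op$Omega2[1L, 2L] else 0
    equicorr_trunc_mean(dg - off, max(off, 0), beta)
  } else trunc_mean_xi(beta, diag(op$Omega2))
  drop(op$Gamma %*% solve(op$Omega2, xi))
}

#' Monte-Carlo selection bias from the conditional-posterior representation
#'
#' Samples the truncated component of the stochastic representation
#' (rejection sampling of \eqn{N(0,\Omega_2^*)} restricted to the box) and
#' averages; the independent oracle for [selection_bias()].
#'
#' @inheritParams selection_bias
#' @param n_draws accepted-draw target for the truncated normal vector.
#' @return \code{list(bias, se)}: the MC bias estimate and its elementwise
#'   standard error.
#' @export
selection_bias_mc <- function(y_obs, K11, m1 = NULL, sigma, rho, alphas,
                              beta = NULL, n_draws = 1e5) {
  n1 <- nrow(K11)
  if (is.null(m1)) m1 <- numeric(n1)
  if (rho == 0) return(list(bias = numeric(n1), se = numeric(n1)))
  op <- bias_operators(K11, sigma, rho)
  if (is.null(beta)) {
    alphas <- rep_len(alphas, n1)
    theta1 <- drop(K11 %*% backsolve(op$Hchol,
                 backsolve(op$Hchol, y_obs, transpose = TRUE))) +
      sigma^2 * backsolve(op$Hchol,
                 backsolve(op$Hchol, m1, transpose = TRUE))
    beta <- alphas - rho * (y_obs - theta1) / sigma
  } else beta <- rep_len(beta, n1)
  L <- chol(op$Omega2)
  acc <- matrix(NA_real_, 0L, n1)
  tries <- 0L
  while (nrow(acc) < n_draws && tries < 400L) {
    tries <- tries + 1L
    W <- matrix(stats::rnorm(n1 * 1e5), ncol = n1) %*% L
    keep <- rowSums(sweep(W, 2L, beta, ">")) == n1
    acc <- rbind(acc, W[keep, , drop = FALSE])
  }
  if (nrow(acc) < 100L) stop("truncation region too improbable for rejection sampling")
  xi <- colMeans(acc)
  A <- op$Gamma %*% solve(op$Omega2)
  se_xi <- apply(acc, 2L, stats::sd) / sqrt(nrow(acc))
  list(bias = drop(A %*% xi),
       se = sqrt(drop((A^2) %*% se_xi^2)))
}

#' Marginal-effect difference between selection-aware and naive models
#'
#' When a covariate \eqn{x_k} appears in both the outcome and the selection
#' equation (\eqn{v_k = x_k}), the derivative of \eqn{E[y \mid s=1]} with
#' respect to \eqn{x_k} picks up a selection term that the naive model
#' misses.  Writing the conditional selection-error mean as
#' \eqn{T(\alpha) = N(\alpha)/D(\alpha)} with
#' \eqn{N = \int \sqrt{\delta}\,\phi(\alpha/\sqrt{\delta})\,dG} and
#' \eqn{D = \int \bar\Phi(\alpha/\sqrt{\delta})\,dG}, the difference is
#' \deqn{-\gamma_k\,\rho\sigma\, T'(\alpha), \qquad
#'   T' = \frac{N'D - N D'}{D^2},}
#' which for degenerate mixing reduces to
#' \eqn{\gamma_k\rho\sigma\,(b_2 - b_1^2)} with the Mills-ratio terms
#' \eqn{b_1 = \phi(\alpha)/\bar\Phi(\alpha)}, \eqn{b_2 = \alpha b_1}.  The
#' selection tilt of the mixing law is accounted for exactly; the expression
#' vanishes at \eqn{\rho = 0} or \eqn{\gamma_k = 0} and has sign opposite to
#' \eqn{\rho} when \eqn{\gamma_k > 0}.
#'
#' @param gamma_k coefficient of the shared covariate in the selection
#'   equation.
#' @param sigma,rho error scale and selection correlation.
#' @param alpha selection threshold \eqn{-v^\top\gamma} (vectorized).
#' @param spec mixing law.
#' @return the marginal-effect difference (same length as \code{alpha}).
#' @export
marginal_effect_diff <- function(gamma_k, sigma, rho, alpha,
                                 spec = mixing_normal()) {
  if (abs(rho) >= 1) stop("'rho' must lie strictly inside (-1, 1)")
  if (rho == 0 || gamma_k == 0) return(numeric(length(alpha)) )
  if (spec$kind == "degenerate") {
    lam <- exp(stats::dnorm(alpha, log = TRUE) -
               stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
    return(gamma_k * rho * sigma * (alpha * lam - lam^2))
  }
  d <- spec$delta(spec$qnodes)
  w <- exp(spec$qlw)
  out <- vapply(alpha, function(al) {
    a <- al / sqrt(d)
    ph <- stats::dnorm(a)
    Pb <- stats::pnorm(a, lower.tail = FALSE)
    N <- sum(w * sqrt(d) * ph)      # E[eps 1(eps>al) | omega] = sqrt(d) phi(a)
    D <- sum(w * Pb)
    Np <- -al * sum(w * ph / sqrt(d))
    Dp <- -sum(w * ph / sqrt(d))
    -gamma_k * rho * sigma * (Np / D - N * Dp / D^2)
  }, numeric(1L))
  out
}

#' Bias-curve grid for the intra-class illustration
#'
#' Evaluates the first component of the analytic selection bias over a grid
#' of thresholds and correlations in the standard illustration setting
#' (\eqn{\sigma = 1}, intra-class \eqn{K_{11} = 0.5 I + 0.5\,11^\top/n_1},
#' common threshold \eqn{\beta}), and the marginal-effect difference over a
#' matching \eqn{(\alpha, \rho)} grid with \eqn{\gamma_k = 1}.
#'
#' @param beta_grid,alpha_grid threshold grids.
#' @param rho_grid correlation grid.
#' @param n1 number of selected points in the intra-class instance.
#' @param spec mixing law for the marginal-effect panel.
#' @return \code{list(bias, marginal)}: two long-format data frames with
#'   columns (threshold, rho, value).
#' @export
bias_curves <- function(beta_grid = seq(-2, 2, by = 0.25),
                        rho_grid = c(-0.75, -0.5, -0.25, 0.25, 0.5, 0.75),
                        alpha_grid = seq(-2, 2, by = 0.25),
                        n1 = 10, spec = mixing_normal()) {
  K11 <- 0.5 * diag(n1) + 0.5 * matrix(1, n1, n1) / n1
  bias <- do.call(rbind, lapply(rho_grid, function(r) {
    v <- vapply(beta_grid, function(b)
      selection_bias(NULL, K11, sigma = 1, rho = r, alphas = NULL,
                     beta = rep(b, n1))[1L], numeric(1L))
    data.frame(threshold = beta_grid, rho = r, value = v)
  }))
  marg <- do.call(rbind, lapply(rho_grid, function(r) {
    data.frame(threshold = alpha_grid, rho = r,
               value = marginal_effect_diff(1, 1, r, alpha_grid, spec))
  }))
  list(bias = bias, marginal = marg)
}
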