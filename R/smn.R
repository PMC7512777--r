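#' Scale-mixture-of-normals error laws
#'
#' The model's bivariate errors are a scale mixture of normals: conditional on
#' a mixing draw \code{omega ~ G}, both error components are normal with their
#' covariance multiplied by \code{delta(omega)}.  Three laws are provided:
#' \describe{
#'   \item{\code{mixing_normal()}}{\code{G} degenerate at
#'     \code{delta(omega) = 1}; plain bivariate normal errors (the normal-error
#'     selection model).}
#'   \item{\code{mixing_t(nu)}}{\code{omega ~ Gamma(nu/2, nu/2)} (mean 1) with
#'     \code{delta(omega) = 1/omega}; marginally Student-t errors with
#'     \code{nu} degrees of freedom (the t-error selection model).}
#'   \item{\code{mixing_custom()}}{any user-supplied mixing law through its
#'     scale function, density and sampler; mixing integrals then use
#'     Monte-Carlo quadrature and the sampler falls back to
#'     Metropolis-Hastings updates of \code{omega}.}
#' }
#' Mixing integrals for the t law use fixed-order generalized Gauss-Laguerre
#' quadrature on the \code{omega} scale (default 64 nodes), exact for the
#' closed-form tail probabilities and accurate to near machine precision for
#' the smooth integrands that arise here.
#'
#' @param nu degrees of freedom (positive).
#' @param nodes quadrature order for mixing integrals.
#' @param delta scale function \code{delta(omega) > 0}.
#' @param log_g log-density of \code{omega}.
#' @param sampler function \code{(n)} returning \code{n} draws of
#'   \code{omega}.
#' @param mc_nodes number of Monte-Carlo quadrature draws for a custom law.
#' @return an object of class \code{"rsgpr_mixing"}.
#' @name mixing
NULL

#' @rdname mixing
#' @export
mixing_normal <- function() {
  structure(list(kind = "degenerate", nu = NULL,
                 delta = function(omega) rep_len(1, length(omega)),
                 log_g = NULL, sampler = function(n) rep_len(1, n),
                 qnodes = NULL, qlw = NULL),
            class = "rsgpr_mixing")
}

#' @rdname mixing
#' @export
mixing_t <- function(nu, nodes = 64L) {
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0)
    stop("'nu' must be a positive scalar")
  ## \int f(w) dG(w), G = Gamma(nu/2, nu/2), by Gauss-Legendre on the
  ## probability scale: w = G^{-1}(p), p in (0, 1); robust for any nu
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  qnodes <- stats::qgamma(gl$x, nu / 2, nu / 2)
  qlw <- log(gl$w)
  structure(list(kind = "gamma_t", nu = nu,
                 delta = function(omega) 1 / omega,
                 log_g = function(omega) stats::dgamma(omega, nu / 2, nu / 2, log = TRUE),
                 sampler = function(n) stats::rgamma(n, nu / 2, nu / 2),
                 qnodes = qnodes, qlw = qlw),
            class = "rsgpr_mixing")
}

#' @rdname mixing
#' @export
mixing_custom <- function(delta, log_g, sampler, mc_nodes = 4096L) {
  stopifnot(is.function(delta), is.function(sampler))
  ## Monte-Carlo quadrature grid, frozen at construction for reproducibility
  om <- sampler(mc_nodes)
  if (any(delta(om) <= 0)) stop("'delta' must be positive on the support of omega")
  structure(list(kind = "custom", nu = NULL, delta = delta, log_g = log_g,
                 sampler = sampler, qnodes = om,
                 qlw = rep_len(-log(mc_nodes), mc_nodes)),
            class = "rsgpr_mixing")
}

#' @export
print.rsgpr_mixing <- function(x, ...) {
  lab <- switch(x$kind,
    degenerate = "degenerate at delta(omega) = 1 (normal errors)",
    gamma_t = sprintf("Gamma(%g/2, %g/2) mixing, delta = 1/omega (t%g errors)",
                      x$nu, x$nu, x$nu),
    custom = "custom mixing law")
  cat("<rsgpr_mixing>", lab, "\n")
  invisible(x)
}

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

## row-wise logsumexp of a matrix plus a log-weight vector over columns
row_logsumexp <- function(L, lw) {
  L <- sweep(L, 2L, lw, "+")
  m <- apply(L, 1L, max)
  ok <- is.finite(m)
  out <- m
  out[ok] <- m[ok] + log(rowSums(exp(L[ok, , drop = FALSE] - m[ok])))
  out
}

#' Mixed upper-tail selection probability
#'
#' The discrete component of the model is driven by
#' \deqn{\bar F(C_i; d, \tau) = \int \bar\Phi(C_i; d, \delta(\omega)\tau)\,
#'   dG(\omega),}
#' the probability that a scale-mixed normal with mean \code{d} and base
#' variance \code{tau} exceeds the selection threshold \code{alpha}.  For
#' degenerate mixing this is a normal upper tail; for Gamma mixing it is a
#' closed-form Student-t tail; custom laws use the stored quadrature grid.
#'
#' @param alpha lower endpoint of the selection interval \code{(alpha, Inf)};
#'   vectorized.
#' @param d mean of the mixed normal.
#' @param tau base variance (positive).
#' @param spec a mixing law from [mixing_normal()], [mixing_t()] or
#'   [mixing_custom()].
#' @param log_p return log probabilities.
#' @param lower_tail if \code{TRUE} return the complement
#'   \code{1 - Fbar} (the probability of non-selection), computed on its own
#'   stable tail.
#' @return probabilities in \code{[0, 1]} (or their logs).
#' @export
fbar <- function(alpha, d = 0, tau = 1, spec = mixing_normal(),
                 log_p = FALSE, lower_tail = FALSE) {
  if (tau <= 0) stop("'tau' must be positive")
  z <- (alpha - d) / sqrt(tau)
  lp <- switch(spec$kind,
    degenerate = stats::pnorm(z, lower.tail = lower_tail, log.p = TRUE),
    gamma_t = stats::pt(z, df = spec$nu, lower.tail = lower_tail, log.p = TRUE),
    {
      sdv <- sqrt(spec$delta(spec$qnodes))
      L <- stats::pnorm(outer(z, sdv, "/"), lower.tail = lower_tail, log.p = TRUE)
      row_logsumexp(L, spec$qlw)
    })
  if (log_p) lp else exp(lp)
}

#' Selection-indicator probability mass
#'
#' \code{Fbar(C;0,1)^s (1 - Fbar(C;0,1))^(1-s)}: the marginal probability of
#' observing selection indicator \code{s} at threshold \code{alpha}.
#'
#' @param s 0/1 indicator (vectorized with \code{alpha}).
#' @inheritParams fbar
#' @export
selection_pmf <- function(s, alpha, spec = mixing_normal()) {
  if (!all(s %in% c(0, 1))) stop("'s' must be binary (0/1)")
  n <- max(length(s), length(alpha))
  s <- rep_len(s, n)
  p1 <- rep_len(fbar(alpha, spec = spec), n)
  ifelse(s == 1, p1, 1 - p1)
}

#' Density of a selected observation (skew scale mixture of normals)
#'
#' The continuous component of the model: the log density of an outcome given
#' that its record was selected,
#' \deqn{h(y \mid s=1) = \frac{\int \phi(y;\eta,\delta(\omega)\sigma^2)\,
#'   \bar\Phi(C;\theta_{e|y},\delta(\omega)(1-\rho^2))\, dG(\omega)}
#'   {\bar F(C;0,1)},}
#' with \eqn{\theta_{e|y} = \rho(y-\eta)/\sigma}.  Selection with
#' \eqn{\rho \ne 0} tilts the error law: the density is a skew scale mixture
#' of normals.  Everything is computed in log space so that thresholds
#' \code{alpha} of magnitude up to about 8 remain stable.
#'
#' @param y outcome value(s).
#' @param eta regression-function value(s) \eqn{\eta(x_i)}.
#' @param sigma outcome error scale (\eqn{\sigma > 0}).
#' @param rho selection correlation, \eqn{|\rho| < 1}.
#' @param alpha selection threshold \eqn{\alpha_i = -v_i^\top\gamma}.
#' @inheritParams fbar
#' @return log density, vectorized over \code{y}/\code{eta}/\code{alpha}.
#' @export
skew_smn_logpdf <- function(y, eta, sigma, rho, alpha, spec = mixing_normal()) {
  if (abs(rho) >= 1) stop("'rho' must lie strictly inside (-1, 1)")
  if (sigma <= 0) stop("'sigma' must be positive")
  theta <- rho * (y - eta) / sigma
  s2cond <- 1 - rho^2
  lden <- fbar(alpha, 0, 1, spec, log_p = TRUE)
  if (spec$kind == "degenerate") {
    lnum <- stats::dnorm(y, eta, sigma, log = TRUE) +
      stats::pnorm((alpha - theta) / sqrt(s2cond), lower.tail = FALSE, log.p = TRUE)
    return(lnum - lden)
  }
  dl <- spec$delta(spec$qnodes)
  ## rows: observations, cols: quadrature nodes
  L <- stats::dnorm(outer(y - eta, sqrt(dl) * sigma, "/"), log = TRUE) -
    log(sigma) - rep(0.5 * log(dl), each = length(y)) +
    stats::pnorm(outer(alpha - theta, sqrt(dl * s2cond), "/"),
                 lower.tail = FALSE, log.p = TRUE)
  row_logsumexp(L, spec$qlw) - lden
}

#' Observed-data log-likelihood of the selection model
#'
#' Sums, over all records, the log selection-probability of the indicator and,
#' for selected records, the log skew-SMN density of the outcome:
#' \deqn{\ell = \sum_i s_i\{\ln \bar F(C_i;0,1) + \ln h(y_i|s_i=1)\}
#'   + (1-s_i)\ln\{1-\bar F(C_i;0,1)\}.}
#' This is the likelihood with all latent variables (selection scores and
#' mixing draws) integrated out; it is the deviance used for DIC.
#'
#' @param eta1 regression-function values at the selected records
#'   (length \code{n1}).
#' @param gamma selection coefficient vector (length \code{q}).
#' @param sigma,rho outcome error scale and selection correlation.
#' @param data an [rsgpr_data()] object (selected-first order).
#' @inheritParams fbar
#' @return scalar log-likelihood.
#' @export
observed_loglik <- function(eta1, gamma, sigma, rho, data,
                            spec = mixing_normal()) {
  stopifnot(inherits(data, "rsgpr_data"))
  if (data$n == 0L) return(0)
  if (length(eta1) != data$n1)
    stop("'eta1' must have one value per selected record")
  alpha <- -drop(data$v %*% gamma)
  lsel <- fbar(alpha, 0, 1, spec, log_p = TRUE)
  lmiss <- fbar(alpha, 0, 1, spec, log_p = TRUE, lower_tail = TRUE)
  ll <- sum(lmiss[data$s == 0L]) + sum(lsel[data$s == 1L])
  if (data$n1 > 0L) {
    i1 <- seq_len(data$n1)
    ll <- ll + sum(skew_smn_logpdf(data$y[i1], eta1, sigma, rho,
                                   alpha[i1], spec))
  }
  ll
}
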