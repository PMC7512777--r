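#' Truncated-normal draws and moments
#'
#' Vectorized exact sampling from one-sided truncated normal distributions,
#' used for the latent selection scores and the stochastic representation of
#' a selected observation.  Draws use the inverse-CDF method evaluated in log
#' probability space, which stays exact far into the tails (standardized
#' truncation points beyond +/- 30) without clipping or rejection loops.
#'
#' @param n number of draws (recycled against the parameter vectors).
#' @param mean,sd location and scale of the parent normal.
#' @param lower,upper truncation bounds; exactly one of them may be finite
#'   per element (one-sided truncation) or both infinite.
#' @return numeric vector of draws, each inside its interval.
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(lower >= upper)) stop("'lower' must be below 'upper'")
  u <- stats::runif(n)
  x <- numeric(n)
  a <- (lower - mean) / sd        # standardized bounds
  b <- (upper - mean) / sd
  lo <- is.finite(a) & !is.finite(b)   # (a, Inf)
  hi <- !is.finite(a) & is.finite(b)   # (-Inf, b)
  no <- !is.finite(a) & !is.finite(b)
  two <- is.finite(a) & is.finite(b)
  if (any(no)) x[no] <- stats::qnorm(u[no])
  if (any(lo)) {
    ## P(Z > z) = u * P(Z > a): work on the log survival scale
    lp <- stats::pnorm(a[lo], lower.tail = FALSE, log.p = TRUE) + log(u[lo])
    x[lo] <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
    x[lo] <- pmax(x[lo], a[lo])  # guard against qnorm rounding at the bound
  }
  if (any(hi)) {
    lp <- stats::pnorm(b[hi], log.p = TRUE) + log(u[hi])
    x[hi] <- stats::qnorm(lp, log.p = TRUE)
    x[hi] <- pmin(x[hi], b[hi])
  }
  if (any(two)) {
    pa <- stats::pnorm(a[two]); pb <- stats::pnorm(b[two])
    x[two] <- stats::qnorm(pa + u[two] * (pb - pa))
    x[two] <- pmin(pmax(x[two], a[two]), b[two])
  }
  mean + sd * x
}

#' @rdname rtnorm
#' @details \code{tnorm_moments} returns the exact mean and variance of a
#'   normal distribution truncated to a one-sided interval, via numerically
#'   stable log-scale Mills ratios.
#' @export
tnorm_moments <- function(mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (is.finite(lower) && is.finite(upper))
    stop("only one-sided truncation is supported")
  if (!is.finite(lower) && !is.finite(upper))
    return(list(mean = mean, var = sd^2))
  flip <- is.finite(upper)
  a <- if (flip) (mean - upper) / sd else (lower - mean) / sd
  ## lambda(a) = phi(a) / (1 - Phi(a)), computed in log space
  lam <- exp(stats::dnorm(a, log = TRUE) -
             stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  mu_z <- lam
  var_z <- 1 + a * lam - lam^2
  m <- if (flip) mean - sd * mu_z else mean + sd * mu_z
  list(mean = m, var = sd^2 * var_z)
}
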