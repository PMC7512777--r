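## Small builders shared across test files.

## fully observed Gaussian dataset (every record selected)
make_observed_data <- function(n = 30, sigma = 2, seed = 1) {
  set.seed(seed)
  x <- seq(0.02, 0.98, length.out = n)
  y <- true_function(x) + rnorm(n, 0, sigma)
  rsgpr_data(x = x, s = rep(1L, n), y = y)
}

## intra-class covariance aI + b 11'/n
intra_class <- function(n1, a = 0.5, b = 0.5) {
  a * diag(n1) + b * matrix(1, n1, n1) / n1
}

## multivariate normal log-density over rows of X
mvn_logd <- function(X, m, K) {
  R <- chol(K)
  U <- backsolve(R, t(sweep(X, 2L, m)), transpose = TRUE)
  -0.5 * ncol(X) * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(U^2)
}

## numeric CDF of the selected-outcome density on a grid
skew_cdf_grid <- function(eta, sigma, rho, alpha, spec, lim, m = 8001L) {
  ys <- seq(-lim, lim, length.out = m)
  dens <- exp(skew_smn_logpdf(ys, eta, sigma, rho, alpha, spec))
  cdf <- cumsum((dens[-1L] + dens[-m]) / 2 * diff(ys))
  cdf <- c(0, cdf / cdf[m - 1L])
  list(x = ys, cdf = cdf)
}

## two-sided KS distance of draws against a gridded CDF
ks_distance <- function(draws, grid) {
  Fx <- stats::approx(grid$x, grid$cdf, xout = sort(draws), rule = 2L)$y
  n <- length(draws)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1L) / n
  max(abs(Fx - emp_hi), abs(Fx - emp_lo))
}
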