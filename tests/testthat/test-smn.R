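test_that("truncated normal sampler and moments are exact", {
  set.seed(2)
  x <- rtnorm(2e5, 0, 1, lower = 0)
  expect_true(all(x > 0))
  expect_equal(mean(x), sqrt(2 / pi), tolerance = 5e-3)

  ## closed-form moments across random one-sided parameterizations
  for (r in 1:5) {
    mu <- rnorm(1); sd <- runif(1, 0.5, 2); a <- rnorm(1)
    mom <- tnorm_moments(mu, sd, lower = a)
    z <- rtnorm(2e5, mu, sd, lower = a)
    expect_true(all(z > a))
    expect_equal(mean(z), mom$mean, tolerance = 4 * sqrt(mom$var / 2e5) + 1e-4)
    expect_equal(var(z), mom$var, tolerance = 0.05 * mom$var)
  }

  ## deep-tail draws stay exact, never clipped to the bound
  y <- rtnorm(1e4, 0, 1, lower = 8)
  expect_true(all(y > 8))
  expect_gt(var(y), 0)
  expect_equal(mean(y), tnorm_moments(0, 1, lower = 8)$mean, tolerance = 2e-3)
})

test_that("mixed tail probability matches normal and Student-t closed forms", {
  expect_equal(fbar(0), 0.5)
  expect_equal(fbar(-1.6449), 0.950, tolerance = 1e-3)
  expect_equal(fbar(0, spec = mixing_t(10)), 0.5)
  ## complementarity at arbitrary thresholds
  a <- c(-2.3, 0.4, 1.7)
  expect_equal(selection_pmf(1, a) + selection_pmf(0, a), rep(1, 3))
  expect_equal(selection_pmf(1, a, mixing_t(5)) + selection_pmf(0, a, mixing_t(5)),
               rep(1, 3))
  ## gamma mixing agrees with a Monte-Carlo average of normal tails
  set.seed(8)
  om <- rgamma(2e5, 5, 5)
  mc <- mean(pnorm(-1 / sqrt(1 / om), lower.tail = FALSE))
  se <- sd(pnorm(-1 / sqrt(1 / om), lower.tail = FALSE)) / sqrt(2e5)
  expect_equal(fbar(-1, spec = mixing_t(10)), mc, tolerance = 3 * se)
  ## custom-law quadrature reproduces the t closed form
  cus <- mixing_custom(function(w) 1 / w,
                       function(w) dgamma(w, 5, 5, log = TRUE),
                       function(n) rgamma(n, 5, 5), mc_nodes = 2e5)
  expect_equal(fbar(-1, spec = cus), fbar(-1, spec = mixing_t(10)),
               tolerance = 5e-3)
})

test_that("selected-outcome density normalizes, shifts, and nests the normal", {
  ## rho = 0 reduces to the plain normal at its mode
  expect_equal(skew_smn_logpdf(0, 0, 1, 0, 0), dnorm(0, log = TRUE))

  for (spec in list(mixing_normal(), mixing_t(10))) {
    f <- function(y) exp(skew_smn_logpdf(y, 0, 3, 0.5, 0, spec))
    expect_equal(integrate(f, -60, 60)$value, 1, tolerance = 1e-6)
    ## location equivariance
    expect_equal(skew_smn_logpdf(2.2 + 1, 0.7 + 1, 3, 0.5, -0.3, spec),
                 skew_smn_logpdf(2.2, 0.7, 3, 0.5, -0.3, spec))
  }

  ## extreme thresholds stay finite in log space
  expect_true(is.finite(skew_smn_logpdf(1, 0, 3, 0.5, 8)))
  expect_true(is.finite(skew_smn_logpdf(1, 0, 3, 0.5, -8)))
  expect_error(skew_smn_logpdf(1, 0, 3, 1.2, 0), "rho")
})

test_that("large-df gamma mixing collapses to the degenerate law", {
  sp <- mixing_t(1e6)
  a <- c(-1.2, 0.3, 2.1)
  expect_equal(fbar(a, spec = sp), fbar(a), tolerance = 1e-4)
  y <- c(-2, 0.5, 4)
  expect_equal(skew_smn_logpdf(y, 0.2, 2, 0.4, 0.5, sp),
               skew_smn_logpdf(y, 0.2, 2, 0.4, 0.5), tolerance = 1e-4)
})

test_that("draws from the two-stage representation match the density", {
  set.seed(5)
  for (spec in list(mixing_normal(), mixing_t(10))) {
    dr <- lemma2_sample(4e4, 1, 3, 0.5, 0, spec)
    grid <- skew_cdf_grid(1, 3, 0.5, 0, spec, lim = 45)
    ## 1% critical value of the Kolmogorov statistic
    expect_lt(ks_distance(dr, grid), 1.628 / sqrt(4e4))
  }
  ## rho = 0: no selection effect on the mean
  set.seed(6)
  expect_equal(mean(lemma2_sample(2e5, 0.7, 3, 0, 0)), 0.7, tolerance = 0.03)
  ## closed-form selected mean at rho = 0.5, sigma = 3, alpha = 0
  set.seed(7)
  expect_equal(mean(lemma2_sample(4e5, 0, 3, 0.5, 0)),
               1.5 * sqrt(2 / pi), tolerance = 0.02)
})

test_that("observed-data log-likelihood splits, vanishes, and matches quadrature", {
  ## empty dataset
  d0 <- rsgpr_data(x = numeric(0), s = integer(0), y = numeric(0))
  expect_equal(observed_loglik(numeric(0), 0, 1, 0, d0), 0)

  ## rho = 0, degenerate: independent normal + Bernoulli pieces
  set.seed(9)
  x <- runif(6); s <- c(1L, 1L, 1L, 0L, 0L, 1L)
  y <- ifelse(s == 1, true_function(x) + rnorm(6), NA)
  dat <- rsgpr_data(x = x, s = s, y = y)
  eta1 <- true_function(dat$x[seq_len(dat$n1), 1])
  gam <- 0.3
  ll <- observed_loglik(eta1, gam, 2, 0, dat)
  alpha <- -gam
  split <- sum(dnorm(dat$y[seq_len(dat$n1)], eta1, 2, log = TRUE)) +
    dat$n1 * pnorm(alpha, lower.tail = FALSE, log.p = TRUE) +
    (dat$n - dat$n1) * pnorm(alpha, log.p = TRUE)
  expect_equal(ll, split, tolerance = 1e-10)

  ## 3-record toy instance against term-by-term quadrature of the density
  d3 <- rsgpr_data(x = c(0.2, 0.5, 0.9), s = c(1L, 1L, 0L),
                   y = c(1.1, -0.4, NA))
  eta <- c(0.6, -0.1)
  for (spec in list(mixing_normal(), mixing_t(7))) {
    hq <- vapply(1:2, function(i) {
      dens <- integrate(function(y) exp(skew_smn_logpdf(y, eta[i], 1.5, 0.4,
                                                        -0.25, spec)),
                        -40, 40)$value
      expect_equal(dens, 1, tolerance = 1e-5)   # proper density
      skew_smn_logpdf(d3$y[i], eta[i], 1.5, 0.4, -0.25, spec)
    }, numeric(1))
    expected <- sum(hq) + 2 * fbar(-0.25, spec = spec, log_p = TRUE) +
      log(fbar(-0.25, spec = spec, lower_tail = TRUE))
    expect_equal(observed_loglik(eta, 0.25, 1.5, 0.4, d3, spec), expected,
                 tolerance = 1e-8)
  }

  ## tail monotonicity: moving a selected outcome away from eta lowers it
  lls <- vapply(seq(0, 12, by = 2), function(shift) {
    y2 <- d3$y; y2[1] <- y2[1] + shift
    d <- rsgpr_data(d3$x, d3$v, d3$s, y2)
    observed_loglik(eta, 0.25, 1.5, 0.4, d)
  }, numeric(1))
  expect_true(all(diff(lls) < 0))

  expect_error(rsgpr_data(x = c(1, 2), s = c(1L, 0L), y = c(NA, NA)),
               "missing")
})
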