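test_that("regression-function conditional matches grid and closed-form limits", {
  ## single-record grid oracle
  y1 <- 1.4; zC1 <- 0.6; zeta <- 0.7; tau2 <- 1.3; delta1 <- 1.1
  K11 <- matrix(2.0, 1, 1); m1 <- 0.3
  lp <- function(e) dnorm(y1, e + zeta * zC1, sqrt(delta1 * tau2), log = TRUE) +
    dnorm(e, m1, sqrt(2), log = TRUE)
  es <- seq(-8, 10, length.out = 40001)
  w <- exp(vapply(es, lp, numeric(1))); w <- w / sum(w)
  mom <- cond_eta(y1, zC1, zeta, tau2, delta1, K11, m1, moments = TRUE)
  expect_equal(mom$mean, sum(es * w), tolerance = 1e-6)
  expect_equal(drop(mom$cov), sum(es^2 * w) - sum(es * w)^2, tolerance = 1e-6)

  ## two-record grid oracle with unequal mixing scales
  set.seed(3)
  K2 <- kernel_matrix(c(0.2, 0.6), kernel_spec(u0 = 1.5, w0 = 4))
  y2 <- c(0.8, -0.5); zC2 <- c(0.4, -1.1); d2 <- c(0.7, 1.8)
  g <- seq(-5, 5, length.out = 251)
  gr <- as.matrix(expand.grid(g, g))
  lpost <- mvn_logd(gr, c(0, 0), K2) +
    dnorm(y2[1], gr[, 1] + 0.5 * zC2[1], sqrt(d2[1] * 0.9), log = TRUE) +
    dnorm(y2[2], gr[, 2] + 0.5 * zC2[2], sqrt(d2[2] * 0.9), log = TRUE)
  wt <- exp(lpost - max(lpost)); wt <- wt / sum(wt)
  mom2 <- cond_eta(y2, zC2, 0.5, 0.9, d2, K2, moments = TRUE)
  expect_equal(unname(drop(wt %*% gr)), mom2$mean, tolerance = 1e-3)

  ## no-data limit: the conditional collapses to the prior
  momP <- cond_eta(y2, zC2, 0.5, 1e12, d2, K2, moments = TRUE)
  expect_equal(momP$mean, c(0, 0), tolerance = 1e-6)
  expect_equal(momP$cov, K2, tolerance = 1e-6)

  ## zeta = 0, unit mixing: coincides with the closed-form GPR posterior
  momG <- cond_eta(y2, zC2, 0, 0.9, c(1, 1), K2, moments = TRUE)
  gp <- gpr_posterior(y2, c(0, 0), K2, 0.9)
  expect_equal(momG$mean, gp$mean, tolerance = 1e-9)
  expect_equal(momG$cov, gp$cov, tolerance = 1e-9)
})

test_that("tau-squared conditional has the stated inverse-gamma parameters", {
  pri <- rsgpr_priors(theta0 = 0.3, sigma0 = 0.5, c = 4, d = 6)
  ## zero residuals and zeta at its prior mean: data terms vanish
  p0 <- cond_tau2(rep(0, 5), rep(1, 5), 0.3, pri, moments = TRUE)
  expect_equal(p0$shape, 4 + 6 / 2)
  expect_equal(p0$rate, 6)
  ## no selected records: prior plus the zeta coupling only
  p1 <- cond_tau2(numeric(0), numeric(0), 0.7, pri, moments = TRUE)
  expect_equal(p1$shape, 4 + 0.5)
  expect_equal(p1$rate, 6 + (0.7 - 0.3)^2 / (2 * 0.5))
  ## single-record grid oracle for the full conditional
  delta1 <- 1.1
  mt <- cond_tau2(0.9, delta1, 0.7, pri, moments = TRUE)
  lpt <- function(t2) dnorm(0.9, 0, sqrt(delta1 * t2), log = TRUE) +
    dnorm(0.7, 0.3, sqrt(0.5 * t2), log = TRUE) +
    4 * log(6) - lgamma(4) - 5 * log(t2) - 6 / t2
  ts <- seq(5e-4, 300, length.out = 200001)
  wt <- exp(vapply(ts, lpt, numeric(1))); wt <- wt / sum(wt)
  expect_equal(sum(ts * wt), mt$rate / (mt$shape - 1), tolerance = 1e-3)
  ## draw histogram against the named density
  set.seed(12)
  dr <- replicate(4e4, cond_tau2(0.9, delta1, 0.7, pri))
  expect_equal(mean(1 / dr), mt$shape / mt$rate, tolerance = 0.02)
})

test_that("zeta conditional recovers its prior and matches a 1-D grid", {
  pri <- rsgpr_priors(theta0 = 0.3, sigma0 = 0.5)
  ## all centred scores zero: prior recovery
  m0 <- cond_zeta(c(1, -2), c(0, 0), c(1, 1), 1.3, pri, moments = TRUE)
  expect_equal(m0$mean, 0.3)
  expect_equal(m0$var, 0.5 * 1.3)
  ## single-record grid
  mz <- cond_zeta(1.4 - 0.5, 0.6, 1.1, 1.3, pri, moments = TRUE)
  lpz <- function(zt) dnorm(1.4, 0.5 + zt * 0.6, sqrt(1.1 * 1.3), log = TRUE) +
    dnorm(zt, 0.3, sqrt(0.5 * 1.3), log = TRUE)
  zs <- seq(-10, 12, length.out = 40001)
  wz <- exp(vapply(zs, lpz, numeric(1))); wz <- wz / sum(wz)
  expect_equal(mz$mean, sum(zs * wz), tolerance = 1e-6)
  expect_equal(mz$var, sum(zs^2 * wz) - sum(zs * wz)^2, tolerance = 1e-6)
  ## information monotonicity: variance shrinks as records accrue
  v <- vapply(1:6, function(k)
    cond_zeta(rep(0.5, k), rep(0.8, k), rep(1, k), 1.3, pri,
              moments = TRUE)$var, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("latent-score conditional respects signs and truncated-normal moments", {
  set.seed(13)
  vg <- c(0.24, -0.8); s <- c(1L, 0L)
  ## zeta = 0 reduction for a selected record
  zz <- replicate(4e4, cond_z(vg, s, 0.9, 0, 1.3, c(1.4, 1))[1])
  m <- tnorm_moments(vg[1], sqrt(1.4), lower = 0)
  expect_equal(mean(zz), m$mean, tolerance = 4 * sqrt(m$var / 4e4))

  ## grid oracle with outcome coupling
  zeta <- 0.7; tau2 <- 1.3; d1 <- 1.1; yr <- 0.9
  lpz <- function(z) dnorm(yr, zeta * (z - vg[1]), sqrt(d1 * tau2), log = TRUE) +
    dnorm(z, vg[1], sqrt(d1), log = TRUE)
  zs <- seq(0, 10, length.out = 40001)
  wz <- exp(vapply(zs, lpz, numeric(1))); wz <- wz / sum(wz)
  set.seed(14)
  zd <- replicate(4e4, cond_z(vg, s, yr - 0, zeta, tau2, c(d1, 1)))
  expect_equal(mean(zd[1, ]), sum(zs * wz), tolerance = 0.01)
  ## hard sign constraint on both sides
  expect_true(all(zd[1, ] > 0))
  expect_true(all(zd[2, ] < 0))
  ## unselected mean: E[TN(-inf,0)(0,1)] = -sqrt(2/pi) at vg = 0
  set.seed(15)
  z0 <- replicate(2e5, cond_z(c(0, 0), c(1L, 0L), 0, 0, 1, c(1, 1))[2])
  expect_equal(mean(z0), -sqrt(2 / pi), tolerance = 5e-3)
})

test_that("selection-coefficient conditional matches prior recovery and a grid", {
  pri <- rsgpr_priors(gamma0 = 0.2, Omega0 = 0.7)
  ## no records: prior
  g0 <- cond_gamma(numeric(0), matrix(numeric(0), 0, 1), numeric(0), 0.5, 1,
                   numeric(0), numeric(0), pri, moments = TRUE)
  expect_equal(g0$mean, 0.2)
  expect_equal(drop(g0$cov), 0.7)
  ## two-record grid oracle (one selected)
  v <- matrix(c(0.8, -1.2), 2, 1)
  z <- c(0.6, -0.9); y1 <- 1.4; eta1 <- 0.5
  zeta <- 0.7; tau2 <- 1.3; delta <- c(1.1, 0.8)
  lp <- function(g) dnorm(z[1], v[1] * g, sqrt(delta[1]), log = TRUE) +
    dnorm(z[2], v[2] * g, sqrt(delta[2]), log = TRUE) +
    dnorm(y1, eta1 + zeta * (z[1] - v[1] * g), sqrt(delta[1] * tau2), log = TRUE) +
    dnorm(g, 0.2, sqrt(0.7), log = TRUE)
  gs <- seq(-6, 6, length.out = 20001)
  w <- exp(vapply(gs, lp, numeric(1))); w <- w / sum(w)
  mom <- cond_gamma(z, v, delta, zeta, tau2, eta1, y1, pri, moments = TRUE)
  expect_equal(drop(mom$mean), sum(gs * w), tolerance = 1e-6)
  expect_equal(drop(mom$cov), sum(gs^2 * w) - sum(gs * w)^2, tolerance = 1e-6)
  ## the conditional covariance is symmetric pd for arbitrary data
  set.seed(16)
  v2 <- matrix(rnorm(12), 6, 2)
  mom2 <- cond_gamma(rnorm(6), v2, runif(6, 0.5, 2), -0.4, 0.8,
                     rnorm(3), rnorm(3), rsgpr_priors(), moments = TRUE)
  expect_true(isSymmetric(mom2$cov, tol = 1e-12))
  expect_true(all(eigen(mom2$cov, only.values = TRUE)$values > 0))
})

test_that("mixing-variable conditional uses the conjugate gamma parameters", {
  ## plug-in parameters: selected record
  set.seed(17); draw1 <- cond_omega(1, zC = 1, resid = 1, tau2 = 1,
                                    spec = mixing_t(10))$omega
  set.seed(17); ref1 <- rgamma(1, 6, rate = 6)
  expect_equal(draw1, ref1)
  ## unselected record: shape (nu+1)/2, rate nu/2 + zC^2/2, mean one
  set.seed(18); draw0 <- cond_omega(c(1, 1), zC = c(1, 1), resid = 1, tau2 = 1,
                                    spec = mixing_t(10))$omega
  set.seed(18); ref0 <- rgamma(2, c(6, 5.5), rate = c(6, 5.5))
  expect_equal(draw0, ref0)
  ## degenerate: a no-op at delta = 1
  o <- cond_omega(rep(1, 4), rnorm(4), rnorm(2), 1, mixing_normal())
  expect_equal(o$omega, rep(1, 4))
  ## custom Metropolis step targets the same conditional as the conjugate law
  cus <- mixing_custom(function(w) 1 / w,
                       function(w) dgamma(w, 5, 5, log = TRUE),
                       function(n) rgamma(n, 5, 5))
  set.seed(19)
  om <- rep(1, 2)
  acc <- 0L
  draws <- matrix(NA_real_, 4000, 2)
  for (i in 1:4000) {
    st <- cond_omega(om, zC = c(0.5, -1), resid = 0.8, tau2 = 1.2, spec = cus)
    om <- st$omega
    draws[i, ] <- om
  }
  sh <- c((10 + 2) / 2, (10 + 1) / 2)
  rt <- c(5 + 0.5^2 / 2 + 0.8^2 / 2.4, 5 + 1 / 2)
  expect_equal(colMeans(draws[-(1:200), ]), sh / rt, tolerance = 0.05)
})

test_that("kernel-hyperparameter update is conjugate in u0 and can be fixed", {
  set.seed(20)
  x <- seq(0.1, 0.9, length.out = 6)
  d2 <- outer(x, x, "-")^2
  pri <- rsgpr_priors(a = 3, b = 2, sample_kernel = TRUE)
  ## eta at the prior mean: the quadratic form vanishes
  set.seed(21)
  kh <- cond_kernel_hyper(rep(0, 6), rep(0, 6), 1.5, 4, d2, 1e-8, pri)
  set.seed(21)
  ref <- 1 / rgamma(1, 3 + 3, rate = 2)
  expect_equal(kh$u0, ref)
  ## the proposal chain stays positive and the draw respects the IG form
  set.seed(22)
  eta <- rnorm(6)
  R <- exp(-(4 / 2) * d2) + diag(1e-8, 6)
  Q <- drop(t(eta) %*% solve(R, eta))
  us <- replicate(3e4, cond_kernel_hyper(eta, rep(0, 6), 1.5, 4, d2, 1e-8,
                                         pri, prop_sd = 0)$u0)
  expect_equal(mean(1 / us), (3 + 3) / (2 + Q / 2), tolerance = 0.02)
})

test_that("the Gibbs driver is deterministic and sized as configured", {
  set.seed(30)
  dat <- generate_selection_data(sim_design(1, n = 60, seed = 5))
  cfg <- rsgpr_config(n_burn = 50, n_iter = 100, thin = 5, seed = 99)
  f1 <- rsgpr_gibbs(dat, config = cfg)
  f2 <- rsgpr_gibbs(dat, config = cfg)
  expect_equal(f1$n_keep, 20)
  expect_identical(f1$draws, f2$draws)          # bitwise determinism
  expect_equal(nrow(f1$draws$eta1), 20)
  expect_equal(ncol(f1$draws$eta1), dat$n1)
  ## derived parameters always inside their supports
  expect_true(all(abs(f1$draws$rho) < 1))
  expect_true(all(f1$draws$sigma2 > 0))
  ## default plan retains 3000 draws
  expect_equal(rsgpr_config()$n_iter %/% rsgpr_config()$thin, 3000)
})

test_that("baseline mode with fixed variance reproduces the closed-form posterior", {
  dat <- make_observed_data(n = 12, sigma = 1.5, seed = 31)
  ker <- kernel_spec(u0 = 50, w0 = 30)
  cfg <- rsgpr_config(n_burn = 100, n_iter = 4000, thin = 1, seed = 7)
  fit <- rsgpr_gibbs(dat, kernel = ker, config = cfg, mode = "baseline",
                     fix_sigma2 = 2.25)
  gp <- gpr_posterior(dat$y, numeric(12), kernel_matrix(dat$x, ker), 2.25)
  est <- colMeans(fit$draws$eta1)
  se <- apply(fit$draws$eta1, 2, sd) / sqrt(4000)   # iid draws here
  expect_true(all(abs(est - gp$mean) < 4 * se))
  expect_equal(apply(fit$draws$eta1, 2, var), diag(gp$cov), tolerance = 0.15)
})
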