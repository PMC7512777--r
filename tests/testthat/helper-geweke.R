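## Joint-distribution ("getting it right") harness for the full Gibbs cycle:
## the marginal-conditional simulator draws (parameters, data) iid from the
## prior and the model; the successive-conditional simulator alternates the
## package's full conditional updates with data regeneration.  If every
## conditional is correct the two simulators share a stationary law, so
## moments of any statistic must agree.
geweke_max_z <- function(spec, n = 12, R = 25000, seed = 1, n_batch = 50) {
  set.seed(seed)
  x <- seq(0.05, 0.95, length.out = n)
  v <- matrix(1, n, 1)
  K <- kernel_matrix(x, kernel_spec(u0 = 2, w0 = 5))
  Kc <- chol(K)
  ## proper test priors: the diffuse defaults have barely-finite moments
  pri <- rsgpr_priors(theta0 = 0.3, sigma0 = 0.5, c = 6, d = 8,
                      gamma0 = 0.2, Omega0 = 0.7)
  draw_prior <- function() {
    tau2 <- 1 / rgamma(1, pri$c, rate = pri$d)
    list(eta = drop(crossprod(Kc, rnorm(n))), tau2 = tau2,
         zeta = rnorm(1, pri$theta0, sqrt(pri$sigma0 * tau2)),
         gamma = rnorm(1, pri$gamma0, sqrt(pri$Omega0)),
         omega = spec$sampler(n))
  }
  draw_data <- function(th) {
    d <- spec$delta(th$omega)
    z <- rnorm(n, th$gamma * v[, 1], sqrt(d))
    s <- as.integer(z >= 0)
    y <- th$eta + th$zeta * (z - th$gamma * v[, 1]) + rnorm(n, 0, sqrt(d * th$tau2))
    y[s == 0] <- NA
    list(y = y, s = s, z = z)
  }
  stat <- function(th) c(th$zeta, th$tau2, th$gamma, th$eta[1], mean(th$eta))

  M1 <- t(replicate(R, stat(draw_prior())))
  th <- draw_prior(); da <- draw_data(th)
  M2 <- matrix(NA_real_, R, ncol(M1))
  for (r in seq_len(R)) {
    n1 <- sum(da$s)
    ord <- order(1L - da$s)
    sel <- ord[seq_len(n1)]
    uns <- if (n1 < n) ord[(n1 + 1L):n] else integer(0)
    d <- spec$delta(th$omega)
    zC <- da$z - th$gamma * v[, 1]
    if (n1 >= 1) {
      K11 <- K[sel, sel, drop = FALSE]
      th$eta[sel] <- cond_eta(da$y[sel], zC[sel], th$zeta, th$tau2, d[sel],
                              K11, numeric(n1))
      if (length(uns)) {
        A <- K[uns, sel, drop = FALSE] %*% chol2inv(chol(K11))
        V <- K[uns, uns] - A %*% K[sel, uns, drop = FALSE]
        V <- (V + t(V)) / 2
        ev <- eigen(V, symmetric = TRUE)
        L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(uns))
        th$eta[uns] <- drop(A %*% th$eta[sel]) + drop(L %*% rnorm(length(uns)))
      }
    } else th$eta <- drop(crossprod(Kc, rnorm(n)))
    resid <- da$y[sel] - th$eta[sel] - th$zeta * zC[sel]
    th$tau2 <- cond_tau2(resid, d[sel], th$zeta, pri)
    th$zeta <- cond_zeta(da$y[sel] - th$eta[sel], zC[sel], d[sel], th$tau2, pri)
    sord <- c(sel, uns)
    da$z[sord] <- cond_z(th$gamma * v[sord, 1], da$s[sord],
                         da$y[sel] - th$eta[sel], th$zeta, th$tau2, d[sord])
    th$gamma <- cond_gamma(da$z[sord], v[sord, , drop = FALSE], d[sord],
                           th$zeta, th$tau2, th$eta[sel], da$y[sel], pri)
    zC <- da$z - th$gamma * v[, 1]
    resid <- da$y[sel] - th$eta[sel] - th$zeta * zC[sel]
    th$omega[sord] <- cond_omega(th$omega[sord], zC[sord], resid, th$tau2,
                                 spec)$omega
    da <- draw_data(th)
    M2[r, ] <- stat(th)
  }
  batch_se <- function(xv) {
    m <- length(xv) %/% n_batch
    bm <- colMeans(matrix(xv[seq_len(m * n_batch)], nrow = m))
    sd(bm) / sqrt(n_batch)
  }
  zs <- vapply(seq_len(ncol(M1)), function(j) {
    z1 <- (mean(M1[, j]) - mean(M2[, j])) /
      sqrt(var(M1[, j]) / R + batch_se(M2[, j])^2)
    z2 <- (mean(M1[, j]^2) - mean(M2[, j]^2)) /
      sqrt(var(M1[, j]^2) / R + batch_se(M2[, j]^2)^2)
    max(abs(z1), abs(z2))
  }, numeric(1))
  max(zs)
}
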