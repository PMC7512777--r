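#' Prior specification for the hierarchical selection model
#'
#' Hyperparameters of the Bayesian hierarchy.  In the estimation
#' parameterization the error block is \eqn{(\zeta, \tau^2)} with
#' \eqn{\zeta = \rho\sigma} and \eqn{\tau^2 = \sigma^2(1-\rho^2)}; the inverse
#' map \eqn{\sigma^2 = \zeta^2 + \tau^2}, \eqn{\rho = \zeta/\sqrt{\zeta^2 +
#' \tau^2}} keeps \eqn{|\rho| < 1} automatically and makes every full
#' conditional conjugate.  Defaults are the diffuse choices used throughout
#' the package's simulation studies: \code{theta0 = 0}, \code{sigma0 = 10},
#' \code{c = d = 0.001}, \code{gamma0 = 0}, \code{Omega0 = 10 I}.
#'
#' @param theta0,sigma0 prior mean and relative variance of \code{zeta}
#'   (\code{zeta | tau2 ~ N(theta0, sigma0 * tau2)}).
#' @param c,d inverse-gamma shape and scale for \code{tau2}.
#' @param gamma0 prior mean of the selection coefficients (scalar recycled).
#' @param Omega0 prior covariance of the selection coefficients (scalar
#'   \code{k} means \code{k I}).
#' @param a,b inverse-gamma shape/scale for the kernel global scale \code{u0}
#'   (used only when the kernel hyperparameters are sampled).
#' @param cw,dw half-Cauchy location and scale for the kernel smoothing rate
#'   \code{w0}.
#' @param sample_kernel sample \code{(u0, w0)} inside the Gibbs cycle instead
#'   of keeping them fixed at the kernel specification's values.
#' @return object of class \code{"rsgpr_priors"}.
#' @export
rsgpr_priors <- function(theta0 = 0, sigma0 = 10, c = 0.001, d = 0.001,
                         gamma0 = 0, Omega0 = 10, a = 2, b = 1,
                         cw = 0, dw = 5, sample_kernel = FALSE) {
  stopifnot(sigma0 > 0, c > 0, d > 0, b > 0, dw > 0)
  structure(list(theta0 = theta0, sigma0 = sigma0, c = c, d = d,
                 gamma0 = gamma0, Omega0 = Omega0, a = a, b = b,
                 cw = cw, dw = dw, sample_kernel = isTRUE(sample_kernel)),
            class = "rsgpr_priors")
}

#' Markov chain configuration
#'
#' Defaults follow the package's standard sampling plan: 5000 burn-in
#' iterations, then 15000 iterations thinned by 5, retaining 3000 draws.
#'
#' @param n_burn burn-in iterations (discarded).
#' @param n_iter post-burn-in iterations.
#' @param thin thinning period; \code{n_iter/thin} draws are retained.
#' @param seed integer seed for the chain (optional; the caller's RNG state
#'   is used when \code{NULL}).
#' @param w0_prop_sd,omega_prop_sd initial log-scale random-walk proposal
#'   standard deviations for the Metropolis steps (kernel smoothing rate and
#'   custom mixing draws).
#' @param adapt adapt Metropolis proposal scales toward 20--50\% acceptance
#'   during burn-in (frozen afterwards).
#' @return object of class \code{"rsgpr_config"}.
#' @export
rsgpr_config <- function(n_burn = 5000, n_iter = 15000, thin = 5,
                         seed = NULL, w0_prop_sd = 0.3, omega_prop_sd = 0.5,
                         adapt = TRUE) {
  stopifnot(n_burn >= 0, n_iter >= 1, thin >= 1, n_iter %% thin == 0)
  structure(list(n_burn = as.integer(n_burn), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), seed = seed,
                 w0_prop_sd = w0_prop_sd, omega_prop_sd = omega_prop_sd,
                 adapt = isTRUE(adapt)),
            class = "rsgpr_config")
}

expand_gamma_prior <- function(priors, q) {
  g0 <- rep_len(priors$gamma0, q)
  O0 <- priors$Omega0
  if (is.null(dim(O0))) O0 <- diag(rep_len(O0, q), q)
  list(gamma0 = g0, Omega0 = O0, Omega0_inv = chol2inv(chol(O0)))
}

## ---- full conditional posteriors -------------------------------------------

#' Full conditional draw of the regression-function values
#'
#' Conditional on everything else, the regression-function vector at the
#' selected points is normal with
#' \eqn{\Sigma_\eta = (K_{11}^{-1} + D_1^{-1}/\tau^2)^{-1}} and mean
#' \eqn{\Sigma_\eta\{K_{11}^{-1} m_1 + D_1^{-1}(y - \zeta z_C)/\tau^2\}},
#' where \eqn{D_1 = \mathrm{diag}\{\delta(\omega_i)\}} over selected records
#' and \eqn{z_C = z - V\gamma}.
#'
#' @param y1 outcomes at selected records.
#' @param zC1 centred latent selection scores \code{z - V gamma} at selected
#'   records.
#' @param zeta,tau2 current error-block parameters.
#' @param delta1 \code{delta(omega)} at selected records.
#' @param K11 prior covariance of \code{eta1} (Gram matrix).
#' @param m1 prior mean of \code{eta1}.
#' @param moments return the conditional mean and covariance instead of a
#'   draw.
#' @return a draw (vector), or \code{list(mean, cov)} when
#'   \code{moments = TRUE}.
#' @export
cond_eta <- function(y1, zC1, zeta, tau2, delta1, K11, m1 = NULL,
                     moments = FALSE) {
  n1 <- length(y1)
  if (is.null(m1)) m1 <- numeric(n1)
  Kinv <- chol2inv(chol_or_stop(K11, "K11"))
  A <- Kinv
  diag(A) <- diag(A) + 1 / (delta1 * tau2)
  R <- chol(A)
  rhs <- drop(Kinv %*% m1) + (y1 - zeta * zC1) / (delta1 * tau2)
  mu <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
  if (moments) {
    S <- chol2inv(R)
    return(list(mean = mu, cov = (S + t(S)) / 2))
  }
  mu + backsolve(R, stats::rnorm(n1))
}

#' Full conditional draw of tau-squared
#'
#' Inverse gamma with shape \code{c + (n1+1)/2} and rate
#' \code{d + 0.5 * sum(resid^2/delta) + (zeta-theta0)^2/(2 sigma0)}, where
#' \code{resid = y - eta - zeta*zC}.  With \code{include_zeta = FALSE} (the
#' zero-correlation baseline, which has no \code{zeta} block) the shape is
#' \code{c + n1/2} and the coupling term is dropped.
#'
#' @param resid residual vector at selected records.
#' @param delta1 \code{delta(omega)} at selected records.
#' @param zeta current value of \code{zeta}.
#' @param priors an [rsgpr_priors()].
#' @param include_zeta include the \code{zeta} prior-coupling term.
#' @param moments return \code{list(shape, rate)} instead of a draw.
#' @return a positive draw, or the inverse-gamma parameters.
#' @export
cond_tau2 <- function(resid, delta1, zeta, priors, include_zeta = TRUE,
                      moments = FALSE) {
  n1 <- length(resid)
  shape <- priors$c + (n1 + include_zeta) / 2
  rate <- priors$d + 0.5 * sum(resid^2 / delta1)
  if (include_zeta)
    rate <- rate + (zeta - priors$theta0)^2 / (2 * priors$sigma0)
  if (moments) return(list(shape = shape, rate = rate))
  1 / stats::rgamma(1L, shape, rate = rate)
}

#' Full conditional draw of zeta
#'
#' Normal with mean
#' \eqn{\{\theta_0/\sigma_0 + \sum (y_i-\eta_i) z_{Ci}/\delta_i\} /
#'      \{1/\sigma_0 + \sum z_{Ci}^2/\delta_i\}}
#' and variance
#' \eqn{\{1/(\sigma_0\tau^2) + \sum z_{Ci}^2/(\delta_i\tau^2)\}^{-1}}.
#'
#' @param yresid \code{y - eta} at selected records.
#' @param zC1 centred latent scores at selected records.
#' @param delta1 \code{delta(omega)} at selected records.
#' @param tau2 current value of \code{tau2}.
#' @param priors an [rsgpr_priors()].
#' @param moments return \code{list(mean, var)} instead of a draw.
#' @export
cond_zeta <- function(yresid, zC1, delta1, tau2, priors, moments = FALSE) {
  s1 <- sum(zC1^2 / delta1)
  mu <- (priors$theta0 / priors$sigma0 + sum(yresid * zC1 / delta1)) /
    (1 / priors$sigma0 + s1)
  v <- 1 / (1 / (priors$sigma0 * tau2) + s1 / tau2)
  if (moments) return(list(mean = mu, var = v))
  stats::rnorm(1L, mu, sqrt(v))
}

#' Full conditional draw of the latent selection scores
#'
#' Independent one-sided truncated normals: for unselected records,
#' \eqn{TN_{(-\infty,0)}(v_i^\top\gamma, \delta_i)}; for selected records,
#' \eqn{TN_{(0,\infty)}(\theta_{zi}, \sigma_{zi}^2)} with
#' \eqn{\theta_{zi} = v_i^\top\gamma + \zeta(y_i-\eta_i)/(\zeta^2+\tau^2)}
#' and \eqn{\sigma_{zi}^2 = \delta_i\tau^2/(\zeta^2+\tau^2)}.  Every draw
#' satisfies the sign constraint \code{z >= 0 <=> s = 1} exactly.
#'
#' @param vg linear predictor \code{V gamma} (length n, selected-first).
#' @param s selection indicators (selected-first).
#' @param yresid \code{y - eta} at selected records (length n1).
#' @param zeta,tau2 current error-block parameters.
#' @param delta \code{delta(omega)} for all records.
#' @return an n-vector of draws.
#' @export
cond_z <- function(vg, s, yresid, zeta, tau2, delta) {
  n <- length(vg)
  n1 <- sum(s == 1L)
  z <- numeric(n)
  if (n1 > 0L) {
    i1 <- seq_len(n1)
    mz <- vg[i1] + zeta * yresid / (zeta^2 + tau2)
    sz <- sqrt(delta[i1] * tau2 / (zeta^2 + tau2))
    z[i1] <- rtnorm(n1, mz, sz, lower = 0)
  }
  if (n1 < n) {
    i0 <- (n1 + 1L):n
    z[i0] <- rtnorm(n - n1, vg[i0], sqrt(delta[i0]), upper = 0)
  }
  z
}

#' Full conditional draw of the selection coefficients
#'
#' Multivariate normal with precision
#' \eqn{\Omega_0^{-1} + \sum_i v_i v_i^\top/\delta_i +
#'      \sum_{i \le n_1} \zeta^2 v_i v_i^\top/(\tau^2\delta_i)}
#' (first sum over all records) and matching mean; see the model's full
#' conditional for \eqn{\gamma}.
#'
#' @param z latent scores (length n, selected-first).
#' @param v selection design matrix (n x q).
#' @param delta \code{delta(omega)} for all records.
#' @param zeta,tau2 current error-block parameters.
#' @param eta1,y1 regression-function values and outcomes at selected records.
#' @param priors an [rsgpr_priors()].
#' @param moments return \code{list(mean, cov)} instead of a draw.
#' @export
cond_gamma <- function(z, v, delta, zeta, tau2, eta1, y1, priors,
                       moments = FALSE) {
  q <- ncol(v)
  n1 <- length(y1)
  gp <- expand_gamma_prior(priors, q)
  w <- 1 / delta
  P <- gp$Omega0_inv + crossprod(v * sqrt(w))
  b <- drop(crossprod(v, z * w)) + drop(gp$Omega0_inv %*% gp$gamma0)
  if (n1 > 0L) {
    i1 <- seq_len(n1)
    w1 <- zeta^2 / (tau2 * delta[i1])
    v1 <- v[i1, , drop = FALSE]
    P <- P + crossprod(v1 * sqrt(w1))
    b <- b + drop(crossprod(v1, zeta * (zeta * z[i1] + eta1 - y1) /
                                  (tau2 * delta[i1])))
  }
  R <- chol((P + t(P)) / 2)
  mu <- backsolve(R, backsolve(R, b, transpose = TRUE))
  if (moments) {
    S <- chol2inv(R)
    return(list(mean = mu, cov = (S + t(S)) / 2))
  }
  mu + backsolve(R, stats::rnorm(q))
}

#' Full conditional draw of the mixing variables
#'
#' Degenerate mixing is a no-op (\code{omega = 1}).  Gamma mixing with
#' \code{delta = 1/omega} is conjugate: for selected records
#' \code{Gamma((nu+2)/2, nu/2 + zC^2/2 + resid^2/(2 tau2))}, for unselected
#' records \code{Gamma((nu+1)/2, nu/2 + zC^2/2)}.  A custom law takes one
#' Metropolis-Hastings step per record with a log-normal random-walk
#' proposal targeting the exact conditional density.
#'
#' @param omega current mixing draws (length n).
#' @param zC centred latent scores (length n).
#' @param resid \code{y - eta - zeta*zC} at selected records (length n1).
#' @param tau2 current value of \code{tau2}.
#' @param spec mixing law.
#' @param prop_sd log-scale proposal sd for the custom Metropolis step.
#' @param include_z include the latent-score likelihood factor; the
#'   zero-correlation baseline has no selection scores, so its mixing
#'   conditional carries only the outcome residual term.
#' @return \code{list(omega, accepts)}; \code{accepts} counts accepted
#'   Metropolis proposals (\code{NA} for conjugate updates).
#' @export
cond_omega <- function(omega, zC, resid, tau2, spec, prop_sd = 0.5,
                       include_z = TRUE) {
  n <- length(omega); n1 <- length(resid)
  if (spec$kind == "degenerate")
    return(list(omega = rep_len(1, n), accepts = NA_integer_))
  if (spec$kind == "gamma_t") {
    nu <- spec$nu
    shape <- rep(c((nu + 1 + include_z) / 2, (nu + 1) / 2), c(n1, n - n1))
    rate <- rep_len(nu / 2, n) + if (include_z) zC^2 / 2 else 0
    if (n1 > 0L) rate[seq_len(n1)] <- rate[seq_len(n1)] + resid^2 / (2 * tau2)
    return(list(omega = stats::rgamma(n, shape, rate = rate),
                accepts = NA_integer_))
  }
  ## custom law: elementwise MH with log-normal random walk
  logtarget <- function(om, i) {
    d <- spec$delta(om)
    lt <- spec$log_g(om)
    if (include_z) lt <- lt + stats::dnorm(zC[i], 0, sqrt(d), log = TRUE)
    if (length(i) && any(i <= n1)) {
      sel <- i <= n1
      lt[sel] <- lt[sel] + stats::dnorm(resid[i[sel]], 0,
                                        sqrt(d[sel] * tau2), log = TRUE)
    }
    lt
  }
  idx <- seq_len(n)
  prop <- omega * exp(stats::rnorm(n, 0, prop_sd))
  lr <- logtarget(prop, idx) - logtarget(omega, idx) + log(prop) - log(omega)
  acc <- log(stats::runif(n)) < lr
  omega[acc] <- prop[acc]
  list(omega = omega, accepts = sum(acc))
}

#' Full conditional update of the kernel hyperparameters
#'
#' Writing \eqn{K_{11} = u_0 R(w_0)}, the global scale has the conjugate
#' inverse-gamma conditional \eqn{IG(a + n_1/2,\; b + Q/2)} with
#' \eqn{Q = (\eta - m_1)^\top R(w_0)^{-1}(\eta - m_1)}; the smoothing rate is
#' updated by one Metropolis-Hastings step on \eqn{\log w_0} targeting the
#' Gaussian-process prior density of \eqn{\eta} times its half-Cauchy prior.
#'
#' @param eta1,m1 current regression-function values and their prior mean.
#' @param u0,w0 current kernel hyperparameters.
#' @param d2 matrix of squared distances between selected design points.
#' @param jitter_rel relative jitter (added as \code{jitter_rel * I} to
#'   \code{R(w0)}).
#' @param priors an [rsgpr_priors()].
#' @param prop_sd log-scale proposal sd for the \code{w0} step.
#' @return \code{list(u0, w0, accept)}.
#' @export
cond_kernel_hyper <- function(eta1, m1, u0, w0, d2, jitter_rel, priors,
                              prop_sd = 0.3) {
  n1 <- length(eta1)
  Rmat <- function(w) {
    M <- exp(-(w / 2) * d2)
    diag(M) <- diag(M) + jitter_rel
    M
  }
  e <- eta1 - m1
  quad_and_logdet <- function(w) {
    Rw <- chol(Rmat(w))
    u <- backsolve(Rw, e, transpose = TRUE)
    list(Q = sum(u^2), logdet = 2 * sum(log(diag(Rw))))
  }
  cur <- quad_and_logdet(w0)
  u0_new <- 1 / stats::rgamma(1L, priors$a + n1 / 2,
                              rate = priors$b + cur$Q / 2)
  ## half-Cauchy log prior on (cw, Inf)
  lhc <- function(w) {
    if (w <= priors$cw) return(-Inf)
    stats::dcauchy(w, priors$cw, priors$dw, log = TRUE) + log(2)
  }
  logpost <- function(w, qd)
    -0.5 * qd$logdet - qd$Q / (2 * u0_new) - (n1 / 2) * log(u0_new) + lhc(w)
  w0_new <- w0
  accept <- FALSE
  wprop <- w0 * exp(stats::rnorm(1L, 0, prop_sd))
  qd_prop <- tryCatch(quad_and_logdet(wprop), error = function(e) NULL)
  if (!is.null(qd_prop)) {
    lr <- logpost(wprop, qd_prop) - logpost(w0, cur) + log(wprop) - log(w0)
    if (is.finite(lr) && log(stats::runif(1L)) < lr) {
      w0_new <- wprop
      accept <- TRUE
    }
  }
  list(u0 = u0_new, w0 = w0_new, accept = accept)
}

## ---- Gibbs driver ----------------------------------------------------------

rho_sigma_from <- function(zeta, tau2)
  list(rho = zeta / sqrt(zeta^2 + tau2), sigma2 = zeta^2 + tau2)

#' Fit the sample-selection Gaussian process regression model by Gibbs sampling
#'
#' Runs the data-augmentation Gibbs/Metropolis sampler over the blocks
#' regression function, \code{tau2}, \code{zeta}, latent scores \code{z},
#' selection coefficients \code{gamma}, mixing draws \code{omega}, and
#' (optionally) the kernel hyperparameters, in that order.  Mode
#' \code{"selection"} fits the full selection model; mode \code{"baseline"}
#' pins the selection correlation at zero and fits the plain (scale-mixture)
#' Gaussian process regression to the selected records only, which is the
#' model a selection-naive analysis would use.
#'
#' @param data an [rsgpr_data()] object.
#' @param kernel a [kernel_spec()]; its \code{u0}, \code{w0} are fixed unless
#'   \code{priors$sample_kernel} is set.
#' @param mixing a mixing law ([mixing_normal()], [mixing_t()],
#'   [mixing_custom()]).
#' @param priors an [rsgpr_priors()].
#' @param config an [rsgpr_config()].
#' @param mode \code{"selection"} or \code{"baseline"}.
#' @param predict_at optional design matrix of test points; each retained
#'   iteration is augmented with a draw of the regression function and of a
#'   new outcome at these points (bias-corrected prediction).
#' @param fix_sigma2 optionally fix the outcome error variance (baseline mode
#'   only); used to compare against the closed-form conditional posterior.
#' @param mean_fun optional mean function mapping a design matrix to a mean
#'   vector (default zero).
#' @return object of class \code{"rsgpr_chains"}: retained draws of all
#'   parameters (\code{eta1}, \code{zeta}, \code{tau2}, \code{rho},
#'   \code{sigma2}, \code{gamma}, \code{u0}, \code{w0}, and \code{eta2},
#'   \code{y2} when predicting) plus the run configuration.
#' @export
rsgpr_gibbs <- function(data, kernel = kernel_spec(), mixing = mixing_normal(),
                        priors = rsgpr_priors(), config = rsgpr_config(),
                        mode = c("selection", "baseline"), predict_at = NULL,
                        fix_sigma2 = NULL, mean_fun = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "rsgpr_data"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n1 <- data$n1
  if (n1 < 2L) stop("need at least two selected records")
  n <- if (mode == "selection") data$n else n1
  x1 <- data$x[seq_len(n1), , drop = FALSE]
  y1 <- data$y[seq_len(n1)]
  v <- data$v
  q <- ncol(v)
  m1 <- if (is.null(mean_fun)) numeric(n1) else drop(mean_fun(x1))

  ## kernel pieces on the selected design
  u0 <- kernel$u0; w0 <- kernel$w0
  jitter_rel <- kernel$jitter / kernel$u0
  d2_11 <- if (kernel$form == "squared_exponential") {
    X <- as_design_matrix(x1)
    d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
    d2[d2 < 0] <- 0
    d2
  } else NULL
  make_K11 <- function(u0, w0) {
    if (kernel$form == "squared_exponential") {
      K <- u0 * exp(-(w0 / 2) * d2_11)
      diag(K) <- diag(K) + jitter_rel * u0
      K
    } else kernel_matrix(x1, kernel)
  }
  K11 <- make_K11(u0, w0)
  K11_chol <- chol_or_stop(K11, "K11")
  K11_inv <- chol2inv(K11_chol)
  degen <- mixing$kind == "degenerate"
  if (degen) {
    ei <- eigen(K11, symmetric = TRUE)
    Ulam <- ei$vectors
    lam <- pmax(ei$values, 1e-12)
  }

  ## prediction blocks (kernel fixed => precompute)
  do_pred <- !is.null(predict_at) && !priors$sample_kernel
  if (!is.null(predict_at) && priors$sample_kernel)
    stop("prediction with sampled kernel hyperparameters is not supported")
  if (do_pred) {
    X2 <- as_design_matrix(predict_at)
    n2 <- nrow(X2)
    K21 <- kernel_cross(X2, x1, kernel)
    K22 <- kernel_matrix(X2, kernel)
    m2 <- if (is.null(mean_fun)) numeric(n2) else drop(mean_fun(X2))
    A21 <- K21 %*% K11_inv                     # n2 x n1
    V22 <- K22 - A21 %*% t(K21)
    V22 <- (V22 + t(V22)) / 2
    ev <- eigen(V22, symmetric = TRUE)
    L2 <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n2)
  }

  ## ---- initialization (probit-style LS for gamma; closed-form GP for eta)
  s <- if (mode == "selection") data$s else rep(1L, n1)
  vv <- v[seq_len(n), , drop = FALSE]
  fit_s <- stats::lm.fit(vv, s)
  phat <- pmin(pmax(fit_s$fitted.values, 0.01), 0.99)
  gamma <- drop(qr.coef(qr(vv), stats::qnorm(phat)))
  gamma[is.na(gamma)] <- 0
  vary <- stats::var(y1)
  eta1 <- gpr_posterior(y1, m1, K11, vary)$mean
  zeta <- 0
  tau2 <- if (is.null(fix_sigma2)) vary else fix_sigma2
  omega <- rep(1, n)
  zlat <- numeric(n)

  fixed_tau2 <- !is.null(fix_sigma2)
  if (fixed_tau2 && mode != "baseline")
    stop("'fix_sigma2' is only meaningful in baseline mode")

  n_keep <- config$n_iter %/% config$thin
  draws <- list(
    eta1 = matrix(NA_real_, n_keep, n1),
    zeta = numeric(n_keep), tau2 = numeric(n_keep),
    rho = numeric(n_keep), sigma2 = numeric(n_keep),
    gamma = matrix(NA_real_, n_keep, q),
    u0 = numeric(n_keep), w0 = numeric(n_keep))
  if (do_pred) {
    draws$eta2 <- matrix(NA_real_, n_keep, n2)
    draws$y2 <- matrix(NA_real_, n_keep, n2)
  }
  i1 <- seq_len(n1)
  acc_w0 <- 0L; try_w0 <- 0L
  acc_om <- 0L; try_om <- 0L
  w0_sd <- config$w0_prop_sd; om_sd <- config$omega_prop_sd
  total <- config$n_burn + config$n_iter
  kept <- 0L

  for (it in seq_len(total)) {
    delta <- mixing$delta(omega)
    delta1 <- delta[i1]
    vg <- drop(vv %*% gamma)
    zC <- zlat - vg

    ## eta | rest
    rhs <- drop(K11_inv %*% m1) + (y1 - zeta * zC[i1]) / (delta1 * tau2)
    if (degen) {
      pvar <- 1 / (1 / lam + 1 / (delta1[1L] * tau2))
      wv <- drop(crossprod(Ulam, rhs))
      eta1 <- drop(Ulam %*% (pvar * wv + sqrt(pvar) * stats::rnorm(n1)))
    } else {
      A <- K11_inv
      diag(A) <- diag(A) + 1 / (delta1 * tau2)
      Rc <- chol(A)
      mu <- backsolve(Rc, backsolve(Rc, rhs, transpose = TRUE))
      eta1 <- mu + backsolve(Rc, stats::rnorm(n1))
    }

    resid <- y1 - eta1 - zeta * zC[i1]
    ## tau2 | rest
    if (!fixed_tau2)
      tau2 <- cond_tau2(resid, delta1, zeta, priors,
                        include_zeta = (mode == "selection"))
    ## zeta | rest
    if (mode == "selection") {
      zeta <- cond_zeta(y1 - eta1, zC[i1], delta1, tau2, priors)
      ## z | rest
      zlat <- cond_z(vg, s, y1 - eta1, zeta, tau2, delta)
      ## gamma | rest
      gamma <- cond_gamma(zlat, vv, delta, zeta, tau2, eta1, y1, priors)
      zC <- zlat - drop(vv %*% gamma)
    }
    ## omega | rest
    if (mixing$kind != "degenerate") {
      resid <- y1 - eta1 - zeta * zC[i1]
      ou <- cond_omega(omega, zC, resid, tau2, mixing, prop_sd = om_sd,
                       include_z = (mode == "selection"))
      omega <- ou$omega
      if (!is.na(ou$accepts)) {
        acc_om <- acc_om + ou$accepts; try_om <- try_om + n
        if (config$adapt && it <= config$n_burn && it %% 50L == 0L) {
          r <- acc_om / max(try_om, 1L)
          om_sd <- om_sd * exp(r - 0.35)
          acc_om <- 0L; try_om <- 0L
        }
      }
    }
    ## kernel hyperparameters | rest
    if (priors$sample_kernel) {
      if (kernel$form != "squared_exponential")
        stop("kernel hyperparameter sampling requires the squared-exponential form")
      kh <- cond_kernel_hyper(eta1, m1, u0, w0, d2_11, jitter_rel, priors,
                              prop_sd = w0_sd)
      u0 <- kh$u0; w0 <- kh$w0
      try_w0 <- try_w0 + 1L; acc_w0 <- acc_w0 + kh$accept
      if (config$adapt && it <= config$n_burn && it %% 50L == 0L) {
        r <- acc_w0 / max(try_w0, 1L)
        w0_sd <- w0_sd * exp(r - 0.35)
        acc_w0 <- 0L; try_w0 <- 0L
      }
      K11 <- make_K11(u0, w0)
      K11_inv <- chol2inv(chol_or_stop(K11, "K11"))
      if (degen) {
        ei <- eigen(K11, symmetric = TRUE)
        Ulam <- ei$vectors
        lam <- pmax(ei$values, 1e-12)
      }
    }

    if (!all(is.finite(eta1)) || !is.finite(tau2) || !is.finite(zeta) ||
        !all(is.finite(gamma)))
      stop(sprintf(
        "non-finite sampler state at iteration %d (tau2 = %g, zeta = %g)",
        it, tau2, zeta))

    if (it > config$n_burn && (it - config$n_burn) %% config$thin == 0L) {
      kept <- kept + 1L
      draws$eta1[kept, ] <- eta1
      draws$zeta[kept] <- zeta
      draws$tau2[kept] <- tau2
      rs <- rho_sigma_from(zeta, tau2)
      draws$rho[kept] <- rs$rho
      draws$sigma2[kept] <- rs$sigma2
      draws$gamma[kept, ] <- gamma
      draws$u0[kept] <- u0
      draws$w0[kept] <- w0
      if (do_pred) {
        e2 <- m2 + drop(A21 %*% (eta1 - m1)) + drop(L2 %*% stats::rnorm(n2))
        om2 <- mixing$sampler(n2)
        y2 <- e2 + sqrt(rs$sigma2 * mixing$delta(om2)) * stats::rnorm(n2)
        draws$eta2[kept, ] <- e2
        draws$y2[kept, ] <- y2
      }
    }
  }

  structure(list(
    draws = draws, n_keep = n_keep, mode = mode, mixing = mixing,
    kernel = kernel, priors = priors, config = config,
    data = data, predict_at = if (do_pred) X2 else NULL,
    mean_fun = mean_fun,
    acceptance = list(w0 = if (try_w0 > 0) acc_w0 / try_w0 else NA,
                      omega = if (try_om > 0) acc_om / try_om else NA)),
    class = "rsgpr_chains")
}

#' @export
print.rsgpr_chains <- function(x, ...) {
  cat(sprintf("<rsgpr_chains> %s model (%s mixing): %d retained draws\n",
              if (x$mode == "selection") "selection" else "baseline",
              x$mixing$kind, x$n_keep))
  cat(sprintf("  posterior means: sigma = %.3f, rho = %.3f\n",
              mean(sqrt(x$draws$sigma2)), mean(x$draws$rho)))
  invisible(x)
}

#' Posterior summary of a fitted chain
#'
#' @param object an \code{rsgpr_chains} object.
#' @param probs interval probabilities.
#' @param ... unused.
#' @return data frame of posterior means, standard deviations and quantiles
#'   for the scalar parameters.
#' @export
summary.rsgpr_chains <- function(object, probs = c(0.025, 0.975), ...) {
  d <- object$draws
  pars <- list(sigma = sqrt(d$sigma2), rho = d$rho, zeta = d$zeta,
               tau2 = d$tau2)
  for (j in seq_len(ncol(d$gamma)))
    pars[[paste0("gamma", j)]] <- d$gamma[, j]
  if (object$mode == "baseline") pars$rho <- pars$zeta <- NULL
  out <- do.call(rbind, lapply(names(pars), function(nm) {
    v <- pars[[nm]]
    qs <- stats::quantile(v, probs, names = FALSE)
    data.frame(parameter = nm, mean = mean(v), sd = stats::sd(v),
               lo = qs[1], hi = qs[2])
  }))
  names(out)[4:5] <- paste0("q", format(100 * probs, trim = TRUE))
  out
}
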