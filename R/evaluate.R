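#' Replication-study accuracy metrics
#'
#' Mean absolute bias and root mean square error over replicated estimates,
#' exactly in the element-sum convention
#' \deqn{MAB = \frac{1}{M}\sum_{k=1}^M\sum_{\ell=1}^p |\hat\theta_{k\ell} -
#'   \theta_\ell|, \qquad
#'   RMSE = \Big\{\frac{1}{M}\sum_{k=1}^M\sum_{\ell=1}^p (\hat\theta_{k\ell}
#'   - \theta_\ell)^2\Big\}^{1/2}:}
#' the sums run over all elements, the division is by the replicate count
#' only.
#'
#' @param estimates M x p matrix of per-replicate estimates (a vector is a
#'   single column).
#' @param truth length-p vector of true values.
#' @return scalar metric.
#' @export
mab <- function(estimates, truth) {
  E <- as.matrix(estimates)
  if (length(truth) != ncol(E)) stop("'truth' must have one value per column")
  sum(abs(sweep(E, 2L, truth))) / nrow(E)
}

#' @rdname mab
#' @export
rmse <- function(estimates, truth) {
  E <- as.matrix(estimates)
  if (length(truth) != ncol(E)) stop("'truth' must have one value per column")
  sqrt(sum(sweep(E, 2L, truth)^2) / nrow(E))
}

#' Batch-means Monte Carlo standard error
#'
#' Standard error of the posterior-mean estimate from an autocorrelated
#' chain: the chain is split into \code{batches} consecutive batches and the
#' standard deviation of the batch means is scaled by \code{1/sqrt(batches)}.
#'
#' @param chain numeric vector of retained draws.
#' @param batches number of batches (default 30).
#' @return scalar MC error.
#' @export
mc_error <- function(chain, batches = 30L) {
  n <- length(chain)
  if (n < 2L * batches) batches <- max(2L, n %/% 2L)
  m <- n %/% batches
  bm <- colMeans(matrix(chain[seq_len(m * batches)], nrow = m))
  stats::sd(bm) / sqrt(batches)
}

#' Deviance information criterion from the observed-data likelihood
#'
#' The deviance is \code{-2} times the observed-data log-likelihood
#' [observed_loglik()] (latent selection scores and mixing draws integrated
#' out), evaluated at each retained draw of \code{(eta1, zeta, tau2, gamma)}.
#' \code{DIC = Dbar + pD} with \code{pD = Dbar - D(thetabar)}, where
#' \code{thetabar} collects the posterior means of the parameter blocks.
#' The augmented-data deviance is deliberately not used: it is ill-defined
#' under data augmentation.
#'
#' @param chains an \code{rsgpr_chains} fit (selection mode).
#' @param data the [rsgpr_data()] the model was fit to.
#' @param max_draws cap on the number of draws used for \code{Dbar}
#'   (evenly spaced subsample; 0 means all).
#' @return \code{list(DIC, pD, Dbar)}.
#' @export
dic <- function(chains, data = chains$data, max_draws = 0L) {
  stopifnot(inherits(chains, "rsgpr_chains"))
  if (chains$mode != "selection")
    stop("DIC is defined here for the selection model fit")
  d <- chains$draws
  R <- chains$n_keep
  idx <- if (max_draws > 0L && max_draws < R)
    unique(round(seq(1L, R, length.out = max_draws))) else seq_len(R)
  spec <- chains$mixing
  dev_at <- function(eta1, zeta, tau2, gamma) {
    s2 <- zeta^2 + tau2
    -2 * observed_loglik(eta1, gamma, sqrt(s2), zeta / sqrt(s2), data, spec)
  }
  devs <- vapply(idx, function(r)
    dev_at(d$eta1[r, ], d$zeta[r], d$tau2[r], d$gamma[r, ]), numeric(1L))
  Dbar <- mean(devs)
  Dhat <- dev_at(colMeans(d$eta1), mean(d$zeta), mean(d$tau2),
                 colMeans(d$gamma))
  pD <- Dbar - Dhat
  list(DIC = Dbar + pD, pD = pD, Dbar = Dbar)
}

#' Replication study over simulated selection datasets
#'
#' Generates \code{M} seeded replicate datasets from a [sim_design()], fits
#' each requested model, records the per-replicate posterior means of
#' \code{sigma} and \code{rho}, and aggregates mean, across-replicate
#' standard deviation, RMSE, MAB and the average within-chain MC error per
#' model.  The reported s.d. is the root mean squared deviation about the
#' replicate mean (divides by \code{M}), so that
#' \code{RMSE^2 = (mean - truth)^2 + sd^2} holds exactly.
#'
#' @param design a [sim_design()].
#' @param models character vector; any of \code{"sgprn"}, \code{"sgprt"},
#'   \code{"gpr"}, \code{"gprt"} (the t variants use \code{nu}).
#' @param M number of replicates.
#' @param config an [rsgpr_config()] (its seed is ignored; replicate seeds
#'   derive from \code{seed}).
#' @param kernel a [kernel_spec()].
#' @param priors an [rsgpr_priors()].
#' @param nu degrees of freedom of the t-error models.
#' @param seed master seed; replicate k uses \code{seed + k} for data and
#'   fitting.
#' @param cache_dir optional directory of per-replicate CSV records; present
#'   records are reused, so an interrupted study resumes where it stopped.
#' @return object of class \code{"rsgpr_study"}: \code{replicates} (long
#'   data frame) and \code{summary} (one row per model and parameter).
#' @export
run_study <- function(design, models = c("sgprn", "gpr"), M = 20,
                      config = rsgpr_config(n_burn = 1000, n_iter = 3000,
                                            thin = 5),
                      kernel = kernel_spec(), priors = rsgpr_priors(),
                      nu = 10, seed = 1, cache_dir = NULL) {
  stopifnot(all(models %in% c("sgprn", "sgprt", "gpr", "gprt")))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  rows <- list()
  for (k in seq_len(M)) {
    cache <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("replicate_%04d.csv", k)) else NULL
    if (!is.null(cache) && file.exists(cache)) {
      rows[[k]] <- utils::read.csv(cache)
      next
    }
    des_k <- design
    des_k$seed <- seed + k
    dat <- generate_selection_data(des_k)
    rec <- do.call(rbind, lapply(models, function(mod) {
      cfg <- config
      cfg$seed <- seed + k
      mx <- if (mod %in% c("sgprt", "gprt")) mixing_t(nu) else mixing_normal()
      md <- if (mod %in% c("sgprn", "sgprt")) "selection" else "baseline"
      fit <- rsgpr_gibbs(dat, kernel = kernel, mixing = mx, priors = priors,
                         config = cfg, mode = md)
      sig <- sqrt(fit$draws$sigma2)
      data.frame(replicate = k, model = mod,
                 sigma_hat = mean(sig), rho_hat = mean(fit$draws$rho),
                 sigma_psd = stats::sd(sig), rho_psd = stats::sd(fit$draws$rho),
                 sigma_mc = mc_error(sig), rho_mc = mc_error(fit$draws$rho))
    }))
    if (!is.null(cache)) utils::write.csv(rec, cache, row.names = FALSE)
    rows[[k]] <- rec
  }
  reps <- do.call(rbind, rows)
  truth <- c(sigma = design$sigma, rho = design$rho)
  summ <- do.call(rbind, lapply(unique(reps$model), function(mod) {
    r <- reps[reps$model == mod, ]
    sel_mode <- mod %in% c("sgprn", "sgprt")
    do.call(rbind, lapply(c("sigma", "rho"), function(par) {
      if (par == "rho" && !sel_mode) return(NULL)
      est <- r[[paste0(par, "_hat")]]
      tv <- truth[[par]]
      data.frame(model = mod, parameter = par, true = tv,
                 mean = mean(est),
                 sd = sqrt(mean((est - mean(est))^2)),
                 rmse = rmse(est, tv), mab = mab(est, tv),
                 mc_error = mean(r[[paste0(par, "_mc")]]),
                 M = nrow(r))
    }))
  }))
  structure(list(replicates = reps, summary = summ, design = design,
                 models = models, seed = seed),
            class = "rsgpr_study")
}

#' @export
print.rsgpr_study <- function(x, ...) {
  cat(sprintf("<rsgpr_study> Model %d design, M = %d replicates\n",
              x$design$model_id, max(x$replicates$replicate)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
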