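# rsgpr — robust sample-selection Gaussian process regression

`rsgpr` fits nonparametric Bayesian regressions in which the outcome is
observed only when a correlated latent selection score is positive —
incidental truncation, the classic missing-not-at-random design of
follow-up studies, income surveys and size-selective sampling.  Analyzing
the observed records alone biases both the fitted curve and the error-scale
estimate; `rsgpr` models the outcome and the selection mechanism jointly and
corrects the bias, with scale-mixture-of-normals errors for robustness to
heavy tails and outliers.

## The model

For record *i* with outcome covariates `x_i` and selection covariates `v_i`:

    y_i = eta(x_i) + eps_i        observed iff  s_i = 1
    z_i = v_i' gamma + e_i,       s_i = 1(z_i >= 0)
    (eps_i, e_i) | omega_i  ~  N2( 0,  delta(omega_i) * [[sigma^2, rho*sigma],
                                                         [rho*sigma, 1     ]] )
    omega_i ~ G,     eta ~ GP(m, kappa),
    kappa(x, x') = u0 * exp(-(w0/2) ||x - x'||^2)

The Gaussian-process prior is the maximum-entropy prior given a mean and
covariance specification.  Degenerate mixing (`mixing_normal()`) gives
normal errors; `mixing_t(nu)` gives Student-t errors; `mixing_custom()`
admits arbitrary laws.  Estimation is a data-augmentation Gibbs sampler in
the conjugate parameterization `zeta = rho*sigma`,
`tau^2 = sigma^2(1 - rho^2)`; every full conditional is exported and tested
against brute-force oracles.  Closed-form GP regression (the naive,
zero-correlation baseline), analytic selection-bias and marginal-effect
diagnostics, bias-corrected prediction, a synthetic-data generator and a
replication-study driver (MAB, RMSE, MC error, DIC) round out the package.
See the vignette (`vignettes/selection-gpr-methods.Rmd`) for the methods in
full.

## Worked example

Simulate a selection design (true curve `f(x) = 50x + 5 sin(10x)`,
`sigma = 3`, `rho = 0.5`, half the 300 records unobserved), fit the
selection model and the naive baseline, and predict:

```r
library(rsgpr)

dat <- generate_selection_data(sim_design(1, n = 300, exact_n1 = TRUE, seed = 42))
#> <rsgpr_data> n = 300 records (150 selected, 150 unselected), p = 1, q = 1

fit <- rsgpr_gibbs(dat,
  config = rsgpr_config(n_burn = 1000, n_iter = 3000, thin = 5, seed = 42),
  predict_at = matrix(seq(0.05, 0.95, by = 0.1), ncol = 1))
summary(fit)
#>   parameter     mean    sd   q2.5 q97.5
#> 1     sigma  2.88663 0.434  2.308 3.942
#> 2       rho -0.12170 0.549 -0.933 0.803
#> 3      zeta -0.43118 1.779 -3.584 2.719
#> 4      tau2  5.17523 1.400  1.829 7.375
#> 5    gamma1 -0.00213 0.073 -0.146 0.138

rsgpr_gibbs(dat, config = rsgpr_config(1000, 3000, 5, seed = 42),
            mode = "baseline")
#> <rsgpr_chains> baseline model (degenerate mixing): 600 retained draws
#>   posterior means: sigma = 2.516, rho = 0.000

head(predict(fit, "eta"), 4)
#>      x  mean    lo    hi      (truth)
#> 1 0.05  6.06  3.00  9.13       4.90
#> 2 0.15 12.90  9.78 15.92      12.49
#> 3 0.25 17.41 14.36 20.78      15.49
#> 4 0.35 17.65 14.35 21.29      15.75
```

Reading the output: the selection-aware fit recovers the error scale
(posterior mean `sigma` 2.89 against a truth of 3, with a wide interval —
the selection correlation is weakly identified from an intercept-only
selection equation, hence `rho`'s broad posterior), while the naive baseline
understates it (2.52): selection clips the error distribution and a model
that ignores it mistakes the clipped spread for the noise level.  The
95% bands of the bias-corrected prediction cover the true curve at all ten
test points.

The analytic bias diagnostic quantifies the naive model's error without any
MCMC — e.g. on a 3-point intra-class instance:

```r
K11 <- 0.5 * diag(3) + 0.5 * matrix(1, 3, 3) / 3
selection_bias(c(0.4, -0.2, 0.9), K11, sigma = 1, rho = 0.5, alphas = 0)
#> [1] -0.1948 -0.2198 -0.1754     # negative: opposite sign to rho
```

A thin command-line interface wraps the same functions:

```sh
exec/rsgpr simulate --model-id 1 --n 300 --exact-n1 150 --seed 7 --out data.csv
exec/rsgpr fit --data data.csv --model sgprn --out fitdir/ --predict-grid 50
exec/rsgpr study --model-id 1 --models sgprn,gpr --M 20 --seed 1 --out studydir/
exec/rsgpr bias-curves --out curves/
```

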