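#' True regression function of the simulation designs
#'
#' \code{f(x) = 50 x + 5 sin(10 x)}: a steep linear trend with a smooth
#' oscillation, evaluated on \code{x} in (0, 1).
#'
#' @param x numeric vector.
#' @return \code{f(x)}.
#' @export
true_function <- function(x) 50 * x + 5 * sin(10 * x)

#' Simulation design for sample-selection data
#'
#' The three study designs share the outcome equation
#' \code{y = f(x) + e1}, the selection equation \code{z = gamma + e2} with
#' \code{s = 1(z >= 0)}, and jointly drawn errors \code{(e1, e2)} with
#' outcome scale \code{sigma}, unit selection scale and correlation
#' \code{rho}:
#' \describe{
#'   \item{Model 1}{bivariate normal errors.}
#'   \item{Model 2}{bivariate Student-t-type scale mixture: one shared
#'     \code{omega ~ Gamma(nu/2, nu/2)} per record scales both components by
#'     \code{1/sqrt(omega)} (default \code{nu = 10}).}
#'   \item{Model 3}{five-component bivariate normal mixture with weights
#'     (0.4, 0.2, 0.2, 0.1, 0.1) over scale factors k = 1, 2, 4, 8, 16,
#'     where component k replaces \code{sigma^2} by \code{9k} (unit selection
#'     variance throughout); a heavy contamination mixture.}
#' }
#' Defaults are the package's standard study conditions: n = 300, expected
#' half selected (\code{gamma = 0}), \code{rho = 0.5}, \code{sigma = 3}.
#'
#' @param model_id 1, 2 or 3.
#' @param n number of records.
#' @param gamma intercept of the selection equation.
#' @param rho,sigma error correlation and outcome error scale.
#' @param nu degrees of freedom for Model 2.
#' @param target_n1 selected count enforced when \code{exact_n1 = TRUE}.
#' @param exact_n1 regenerate whole datasets until exactly \code{target_n1}
#'   records are selected (whole-dataset rejection preserves the model law).
#' @param x_mode covariates drawn uniformly on (0, 1) (\code{"uniform"}) or
#'   placed on an equally spaced grid (\code{"grid"}).
#' @param seed optional integer seed.
#' @return object of class \code{"rsgpr_design"}.
#' @export
sim_design <- function(model_id = 1, n = 300, gamma = 0, rho = 0.5,
                       sigma = 3, nu = 10, target_n1 = 150,
                       exact_n1 = FALSE, x_mode = c("uniform", "grid"),
                       seed = NULL) {
  x_mode <- match.arg(x_mode)
  stopifnot(model_id %in% 1:3, n >= 2, abs(rho) < 1, sigma > 0, nu > 0)
  structure(list(model_id = model_id, n = as.integer(n), gamma = gamma,
                 rho = rho, sigma = sigma, nu = nu,
                 target_n1 = as.integer(target_n1),
                 exact_n1 = isTRUE(exact_n1), x_mode = x_mode, seed = seed),
            class = "rsgpr_design")
}

#' @export
print.rsgpr_design <- function(x, ...) {
  cat(sprintf(
    "<rsgpr_design> Model %d: n = %d, gamma = %g, rho = %g, sigma = %g%s\n",
    x$model_id, x$n, x$gamma, x$rho, x$sigma,
    if (x$exact_n1) sprintf(", exact n1 = %d", x$target_n1) else ""))
  invisible(x)
}

#' Draw bivariate selection-model errors
#'
#' Returns an n x 2 matrix of (outcome error, selection error) pairs under
#' one of the three error laws of [sim_design()].
#'
#' @param n number of pairs.
#' @param sigma,rho outcome error scale and correlation.
#' @param model_id error law (1 normal, 2 shared-scale Student-t mixture,
#'   3 five-component normal contamination mixture).
#' @param nu degrees of freedom for \code{model_id = 2}.
#' @return matrix with columns \code{eps_y} (outcome) and \code{eps_z}
#'   (selection).
#' @export
draw_errors <- function(n, sigma, rho, model_id = 1, nu = 10) {
  ## N(0, [[s^2, rho s],[rho s, 1]]) via the Cholesky of the unit-correlation
  ## pair, then per-model scaling
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  e_y_unit <- z1
  e_z_unit <- rho * z1 + sqrt(1 - rho^2) * z2
  if (model_id == 1) {
    ey <- sigma * e_y_unit; ez <- e_z_unit
  } else if (model_id == 2) {
    omega <- stats::rgamma(n, nu / 2, nu / 2)
    sc <- 1 / sqrt(omega)         # shared scale for both components
    ey <- sigma * e_y_unit * sc; ez <- e_z_unit * sc
  } else if (model_id == 3) {
    k <- sample(c(1, 2, 4, 8, 16), n, replace = TRUE,
                prob = c(0.4, 0.2, 0.2, 0.1, 0.1))
    ## component k has outcome variance 9k and unit selection variance
    ey <- sqrt(9 * k) * e_y_unit; ez <- e_z_unit
  } else stop("unknown model_id")
  cbind(eps_y = ey, eps_z = ez)
}

#' Generate a sample-selection dataset
#'
#' Draws covariates, errors, latent selection scores and outcomes from a
#' [sim_design()], masks outcomes of unselected records and returns the
#' records selected-first as an [rsgpr_data()] object.  The realized design
#' is attached as attribute \code{"design"}.
#'
#' @param design an [rsgpr_design()].
#' @param max_tries retry limit for \code{exact_n1} regeneration.
#' @return an [rsgpr_data()] object.
#' @export
generate_selection_data <- function(design, max_tries = 10000L) {
  stopifnot(inherits(design, "rsgpr_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  one <- function() {
    x <- if (design$x_mode == "grid")
      seq(1 / (2 * design$n), 1 - 1 / (2 * design$n), length.out = design$n)
    else stats::runif(design$n)
    ## Model 3 uses sigma^2 = 9 in its base component regardless of design$sigma
    e <- draw_errors(design$n, design$sigma, design$rho, design$model_id,
                     design$nu)
    z <- design$gamma + e[, "eps_z"]
    s <- as.integer(z >= 0)
    y <- true_function(x) + e[, "eps_y"]
    y[s == 0L] <- NA_real_
    rsgpr_data(x = x, s = s, y = y)
  }
  dat <- one()
  if (design$exact_n1) {
    tries <- 1L
    while (dat$n1 != design$target_n1) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not reach the target selected count within the retry limit")
      dat <- one()
    }
  }
  attr(dat, "design") <- design
  dat
}
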