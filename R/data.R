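#' Selection-regression dataset
#'
#' Container for partially observed sample-selection data: outcome covariates
#' \code{x}, selection covariates \code{v}, a binary selection indicator
#' \code{s}, and the outcome \code{y}, observed only where \code{s = 1}
#' (missing not at random).  Records are stored selected-first, the ordering
#' every model-fitting routine in the package assumes; the permutation that
#' maps back to the input order is kept in the \code{order_map} attribute.
#'
#' @param x outcome design matrix (n x p) or vector.
#' @param v selection design matrix (n x q); defaults to an intercept-only
#'   column of ones.
#' @param s binary selection indicator (0/1 or logical).
#' @param y outcome vector; must be non-missing exactly where \code{s = 1}.
#' @return object of class \code{"rsgpr_data"}: a list with elements
#'   \code{x}, \code{v}, \code{s}, \code{y}, \code{n}, \code{n1}.
#' @export
rsgpr_data <- function(x, v = NULL, s, y) {
  x <- as_design_matrix(x)
  n <- nrow(x)
  if (is.null(v)) v <- matrix(1, n, 1L, dimnames = list(NULL, "v1"))
  v <- as_design_matrix(v)
  if (is.logical(s)) s <- as.integer(s)
  if (!all(s %in% c(0L, 1L))) stop("'s' must be binary (0/1)")
  s <- as.integer(s)
  y <- as.numeric(y)
  if (nrow(v) != n || length(s) != n || length(y) != n)
    stop("'x', 'v', 's' and 'y' must have the same number of records")
  if (anyNA(y[s == 1L])) stop("outcome 'y' missing for a selected record (s = 1)")
  y[s == 0L] <- NA_real_
  ord <- order(1L - s)   # stable: selected rows first, original order within
  out <- list(x = x[ord, , drop = FALSE], v = v[ord, , drop = FALSE],
              s = s[ord], y = y[ord], n = n, n1 = sum(s))
  attr(out, "order_map") <- ord
  class(out) <- "rsgpr_data"
  out
}

#' @export
print.rsgpr_data <- function(x, ...) {
  cat(sprintf(
    "<rsgpr_data> n = %d records (%d selected, %d unselected), p = %d, q = %d\n",
    x$n, x$n1, x$n - x$n1, ncol(x$x), ncol(x$v)))
  invisible(x)
}

#' @export
as.data.frame.rsgpr_data <- function(x, row.names = NULL, optional = FALSE, ...) {
  X <- x$x; colnames(X) <- paste0("x", seq_len(ncol(X)))
  V <- x$v; colnames(V) <- paste0("v", seq_len(ncol(V)))
  data.frame(X, V, s = x$s, y = x$y)
}
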