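#' Read and write selection datasets as CSV
#'
#' The on-disk schema has columns \code{x1..xp}, \code{v1..vq}, \code{s},
#' \code{y}, with \code{y} empty for unselected records (\code{s = 0});
#' header mandatory, decimal point, comma separator.  Reading reorders
#' selected-first (the in-memory invariant) and validates the schema.
#'
#' @param data an [rsgpr_data()] object.
#' @param path CSV file path.
#' @return \code{read_selection_csv} returns an [rsgpr_data()];
#'   \code{write_selection_csv} returns \code{path} invisibly.
#' @export
write_selection_csv <- function(data, path) {
  stopifnot(inherits(data, "rsgpr_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_selection_csv
#' @export
read_selection_csv <- function(path) {
  df <- utils::read.csv(path)
  xc <- grep("^x[0-9]+$", names(df), value = TRUE)
  vc <- grep("^v[0-9]+$", names(df), value = TRUE)
  if (length(xc) == 0L || !"s" %in% names(df) || !"y" %in% names(df))
    stop("CSV schema must provide columns x1..xp, (v1..vq), s, y")
  if (!all(df$s %in% c(0L, 1L))) stop("'s' column must be binary (0/1)")
  if (anyNA(df$y[df$s == 1L]))
    stop("'y' missing for a selected record (s = 1)")
  rsgpr_data(x = as.matrix(df[xc]),
             v = if (length(vc)) as.matrix(df[vc]) else NULL,
             s = df$s, y = df$y)
}

#' Write chain tables and a reproducibility manifest
#'
#' Serializes a fitted chain as one CSV per parameter block (scalars
#' combined into \code{parameters.csv}) plus \code{manifest.json} recording
#' the configuration, priors, kernel, mixing law, data fingerprint and
#' package version — enough to reproduce the run exactly.
#'
#' @param chains an \code{rsgpr_chains} object.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_chains <- function(chains, dir) {
  stopifnot(inherits(chains, "rsgpr_chains"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- chains$draws
  scal <- data.frame(iteration = seq_len(chains$n_keep), zeta = d$zeta,
                     tau2 = d$tau2, rho = d$rho, sigma2 = d$sigma2,
                     u0 = d$u0, w0 = d$w0)
  utils::write.csv(scal, file.path(dir, "parameters.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(d$eta1), file.path(dir, "eta1.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(d$gamma), file.path(dir, "gamma.csv"),
                   row.names = FALSE)
  if (!is.null(d$eta2)) {
    utils::write.csv(as.data.frame(d$eta2), file.path(dir, "eta2.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(d$y2), file.path(dir, "y2.csv"),
                     row.names = FALSE)
  }
  df <- as.data.frame(chains$data)
  manifest <- list(
    package = "rsgpr",
    version = as.character(utils::packageVersion("rsgpr")),
    mode = chains$mode,
    mixing = list(kind = chains$mixing$kind, nu = chains$mixing$nu),
    kernel = chains$kernel[c("form", "u0", "w0", "jitter")],
    priors = unclass(chains$priors),
    config = unclass(chains$config),
    n = chains$data$n, n1 = chains$data$n1,
    data_digest = sprintf("sum:%.10e;sumsq:%.10e",
                          sum(df[!is.na(df)]), sum(df[!is.na(df)]^2)),
    acceptance = chains$acceptance)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' Write study outputs
#'
#' Emits the per-replicate records, the aggregate table (one row per model
#' and parameter: mean, s.d., RMSE, MAB, MC error), and a JSON manifest.
#'
#' @param study an \code{rsgpr_study} object.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "rsgpr_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$replicates, file.path(dir, "replicates.csv"),
                   row.names = FALSE)
  utils::write.csv(study$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(package = "rsgpr",
         version = as.character(utils::packageVersion("rsgpr")),
         design = unclass(study$design), models = study$models,
         seed = study$seed),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(dir)
}
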