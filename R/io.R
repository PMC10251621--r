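# Labelled-matrix CSV I/O and scenario configuration files.

#' Read a labelled square matrix from CSV
#'
#' The expected dialect is the one used by the packaged fixtures: first
#' cell empty, header row of trait labels, one row per trait with the
#' label in the first column, '.' as decimal separator, UTF-8. Symmetric
#' matrices may be stored as an upper triangle; missing lower-triangle
#' entries are then filled by mirroring.
#'
#' @param path file path.
#' @param symmetric if `TRUE`, missing entries are mirrored from the
#'   opposite triangle and the matrix is checked for symmetry.
#' @return Numeric matrix with identical row and column labels.
#' @export
read_labeled_matrix <- function(path, symmetric = FALSE) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M))
    stop("matrix in ", path, " is not square")
  if (!identical(rownames(M), colnames(M)))
    stop("row and column labels differ in ", path)
  if (symmetric) {
    up <- is.na(M) & !is.na(t(M))
    M[up] <- t(M)[up]
    if (anyNA(M)) stop("matrix in ", path, " has unpaired missing entries")
    .check_symmetric(M, paste0("matrix in ", path))
    M <- (M + t(M)) / 2
  } else if (anyNA(M)) {
    stop("matrix in ", path, " has missing entries")
  }
  M
}

#' Write a labelled square matrix to CSV
#'
#' @param M labelled numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(M, path) {
  utils::write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}

#' Read a scenario from a configuration file
#'
#' A scenario bundles the genetic parameters, the index definition and the
#' residual model. The configuration is YAML (or JSON); fields:
#'
#' \describe{
#'   \item{`scenario`}{name of a packaged scenario (`"holstein_old"` or
#'     `"holstein_new"`); all other fields are then ignored.}
#'   \item{`traits`}{list of records with `name`, `genetic_sd`,
#'     `heritability`, `reliability`.}
#'   \item{`genetic_correlations`}{path to a labelled CSV (upper triangle
#'     accepted), relative paths resolved against the config file.}
#'   \item{`index`}{record with `traits` and `weights`.}
#'   \item{`residual`}{either the string `"reliability_diagonal"`, or a
#'     record with `type: file` and `path` to a labelled covariance CSV,
#'     or `type: ebv_correlations` with `path` to an EBV correlation CSV
#'     that is de-regressed into a residual covariance.}
#'   \item{`intensity`, `theta`, `seed`}{optional scalars.}
#' }
#'
#' @param path path to the YAML or JSON configuration.
#' @return A scenario: list with `params`, `index_def`, `residual`,
#'   `intensity`, `theta`, `seed`.
#' @export
read_scenario_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)

  if (!is.null(cfg$scenario)) {
    sc <- switch(cfg$scenario,
                 holstein_old = holstein_old(),
                 holstein_new = holstein_new(),
                 stop("unknown packaged scenario: ", cfg$scenario))
  } else {
    for (field in c("traits", "genetic_correlations", "index"))
      if (is.null(cfg[[field]]))
        stop("config field missing: ", field)
    tr <- do.call(rbind, lapply(cfg$traits, function(x)
      data.frame(name = x$name, genetic_sd = x$genetic_sd,
                 heritability = x$heritability,
                 reliability = if (is.null(x$reliability)) NA_real_
                               else x$reliability)))
    K <- read_labeled_matrix(.resolve_path(cfg$genetic_correlations, path),
                             symmetric = TRUE)
    if (!identical(rownames(K), tr$name))
      stop("genetic_correlations labels do not match config traits")
    params <- genetic_parameters(tr$name, K, tr$genetic_sd,
                                 tr$heritability, tr$reliability)
    if (is.null(cfg$index$traits) || is.null(cfg$index$weights))
      stop("config field missing: index.traits / index.weights")
    index_def <- index_definition(unlist(cfg$index$traits),
                                  unlist(cfg$index$weights))
    res_cfg <- cfg$residual
    if (is.null(res_cfg) || identical(res_cfg, "reliability_diagonal")) {
      residual <- diagonal_error_covariance(params, index_def)
    } else if (identical(res_cfg$type, "file")) {
      M <- read_labeled_matrix(.resolve_path(res_cfg$path, path),
                               symmetric = TRUE)
      residual <- residual_model(M, "user_supplied")
    } else if (identical(res_cfg$type, "ebv_correlations")) {
      M <- read_labeled_matrix(.resolve_path(res_cfg$path, path),
                               symmetric = TRUE)
      H <- ebv_covariance_from_correlations(M, params, index_def)
      residual <- estimate_residual_covariance(H, params, index_def)
    } else {
      stop("unknown residual specification in config")
    }
    sc <- list(params = params, index_def = index_def, residual = residual)
  }
  sc$intensity <- if (is.null(cfg$intensity)) 1 else cfg$intensity
  sc$theta <- if (is.null(cfg$theta)) 0.001 else cfg$theta
  sc$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  sc
}

.resolve_path <- function(p, config_path) {
  if (file.exists(p)) return(p)
  cand <- file.path(dirname(config_path), p)
  if (file.exists(cand)) return(cand)
  stop("referenced file not found: ", p)
}
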