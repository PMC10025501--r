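#' Read and write Likert response matrices as CSV
#'
#' Persons as rows, items as columns (\code{item1}, \code{item2}, ...).
#'
#' @param x integer persons x items matrix with entries in 1..5.
#' @param path file path.
#' @return \code{read_likert_csv} returns a validated integer matrix.
#' @export
write_likert_csv <- function(x, path) {
  x <- as.matrix(x)
  colnames(x) <- paste0("item", seq_len(ncol(x)))
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_likert_csv
#' @export
read_likert_csv <- function(path) {
  x <- as.matrix(read.csv(path, check.names = FALSE))
  storage.mode(x) <- "integer"
  decompose_responses(x)  # validation only: errors on out-of-range entries
  x
}

#' Read and write pseudo-item matrices as CSV
#'
#' Persons as rows; one column per item x node named
#' \code{item<i>_<M|A|E>}; structural missingness serialized as \code{NA}.
#'
#' @param codes an \code{mpp_pseudo_items} array.
#' @param path file path.
#' @return \code{read_pseudo_csv} returns an \code{mpp_pseudo_items} array.
#' @export
write_pseudo_csv <- function(codes, path) {
  arr <- unclass(codes)
  if (length(dim(arr)) != 3L || dim(arr)[3L] != 3L)
    stop("'codes' must be a persons x items x 3 array")
  n <- dim(arr)[1L]; J <- dim(arr)[2L]
  abbr <- c("M", "A", "E")
  flat <- matrix(NA_integer_, n, J * 3L)
  cn <- character(J * 3L)
  for (j in seq_len(J)) for (k in 1:3) {
    col <- (j - 1L) * 3L + k
    flat[, col] <- arr[, j, k]
    cn[col] <- paste0("item", j, "_", abbr[k])
  }
  colnames(flat) <- cn
  write.csv(flat, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_pseudo_csv
#' @export
read_pseudo_csv <- function(path) {
  flat <- as.matrix(read.csv(path, check.names = FALSE))
  storage.mode(flat) <- "integer"
  cn <- colnames(flat)
  m <- regmatches(cn, regexec("^item(\\d+)_([MAE])$", cn))
  if (any(lengths(m) != 3L))
    stop("pseudo-item CSV columns must be named item<i>_<M|A|E>")
  items <- as.integer(vapply(m, `[`, "", 2L))
  nodes <- match(vapply(m, `[`, "", 3L), c("M", "A", "E"))
  J <- max(items)
  arr <- array(NA_integer_, dim = c(nrow(flat), J, 3L),
               dimnames = list(NULL, paste0("item", seq_len(J)), MPP_NODES))
  for (col in seq_along(cn)) arr[, items[col], nodes[col]] <- flat[, col]
  codes <- structure(arr, class = "mpp_pseudo_items")
  recompose_responses(codes)  # validation: errors on illegal patterns
  codes
}

#' Write posterior summaries as CSV
#'
#' One row per parameter (alpha, b, d per node x item) with posterior mean,
#' sd, 95% interval bounds, split R-hat, effective sample size and the
#' convergence flag.
#'
#' @param fit an \code{mpp_fit} from \code{\link{fit_irtree_mcmc}}.
#' @param path file path.
#' @export
write_fit_summary <- function(fit, path) {
  stopifnot(inherits(fit, "mpp_fit"))
  write.csv(fit$summary, path, row.names = FALSE)
  invisible(path)
}

#' Read and write study configuration files
#'
#' Serializes the generating distributions, design grid, priors and chain
#' settings to YAML (\code{.yml}/\code{.yaml}) or JSON (\code{.json}),
#' chosen by file extension.
#'
#' @param config a list as produced by \code{\link{study_config}}.
#' @param path file path ending in .yaml, .yml or .json.
#' @return \code{read_study_config} returns a \code{\link{study_config}}.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "mpp_study_config"))
  plain <- list(
    nodes = lapply(unclass(config$node_config), as.numeric),
    grid = unclass(config$grid),
    priors = lapply(unclass(config$priors), as.numeric),
    chains = unclass(config$chains)[c("chains", "iterations", "burnin",
                                      "thin", "adapt_window", "target_accept",
                                      "rhat_threshold")],
    trait_cor = as.vector(config$trait_cor),
    refresh_items = config$refresh_items)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(plain, path)
  } else if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  } else stop("config extension must be .yaml, .yml or .json")
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  plain <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
           else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
           else stop("config extension must be .yaml, .yml or .json")
  study_config(
    node_config = do.call(node_distribution_config,
                          lapply(plain$nodes, as.numeric)),
    grid = design_grid(N = as.integer(plain$grid$N),
                       J = as.integer(plain$grid$J),
                       replicates = as.integer(plain$grid$replicates),
                       base_seed = as.integer(plain$grid$base_seed)),
    priors = do.call(prior_config, lapply(plain$priors, as.numeric)),
    chains = do.call(chain_config, plain$chains),
    trait_cor = matrix(as.numeric(plain$trait_cor), 3L, 3L),
    refresh_items = isTRUE(plain$refresh_items))
}
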