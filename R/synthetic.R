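#' Generating distributions for the node item parameters
#'
#' Defaults are the study's generating values. Discriminations are log-normal
#' with the given location (meanlog) and scale (sdlog); difficulties are
#' normal on the trait scale. The "mean/sd" of the log-normals are the
#' parameters of the underlying normal on the log scale, matching
#' \code{\link[stats]{rlnorm}} usage.
#'
#' @param alpha_meanlog,alpha_sdlog length-3 numeric (midpoint, agreement,
#'   extreme): log-normal location and scale of the discriminations.
#' @param b_mean,b_sd length-3 numeric: mean and sd of the normal difficulty
#'   distributions.
#' @return An object of class \code{mpp_node_config}.
#' @examples
#' node_distribution_config()  # the study defaults
#' @export
node_distribution_config <- function(alpha_meanlog = c(-0.5, 0.3, 0.5),
                                     alpha_sdlog = c(0.5, 0.2, 0.5),
                                     b_mean = c(-1, 0, 1),
                                     b_sd = c(0.5, 1, 0.5)) {
  for (v in list(alpha_meanlog, alpha_sdlog, b_mean, b_sd))
    if (length(v) != 3L || any(!is.finite(v)))
      stop("each field must be a finite length-3 numeric (one value per node)")
  if (any(alpha_sdlog < 0) || any(b_sd < 0))
    stop("scales and sds must be non-negative")
  cfg <- list(alpha_meanlog = stats::setNames(alpha_meanlog, MPP_NODES),
              alpha_sdlog = stats::setNames(alpha_sdlog, MPP_NODES),
              b_mean = stats::setNames(b_mean, MPP_NODES),
              b_sd = stats::setNames(b_sd, MPP_NODES))
  structure(cfg, class = "mpp_node_config")
}

#' @export
print.mpp_node_config <- function(x, ...) {
  cat("MPP node generating distributions\n")
  for (k in 1:3)
    cat(sprintf("  %-9s alpha ~ logN(%+.2f, %.2f)   b ~ N(%+.2f, %.2f)\n",
                MPP_NODES[k], x$alpha_meanlog[k], x$alpha_sdlog[k],
                x$b_mean[k], x$b_sd[k]))
  invisible(x)
}

#' Default latent trait correlation matrix
#'
#' The study's trait structure: a small negative midpoint-agreement
#' correlation (-0.10), a small positive agreement-extreme correlation
#' (0.10), and a moderate negative midpoint-extreme correlation (-0.50).
#'
#' @return A 3 x 3 correlation matrix with node dimnames.
#' @export
default_trait_cor <- function() {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- -0.10
  R[2, 3] <- R[3, 2] <- 0.10
  R[1, 3] <- R[3, 1] <- -0.50
  dimnames(R) <- list(MPP_NODES, MPP_NODES)
  R
}

#' Draw item parameters for a test of J items
#'
#' Discriminations are drawn i.i.d. per node from the configured log-normal
#' distributions and difficulties from the configured normals; the intercept
#' \code{d = alpha * b} is derived.
#'
#' @param J number of items (>= 1).
#' @param config an \code{\link{node_distribution_config}}.
#' @param seed optional integer seed for reproducibility.
#' @return An \code{\link{item_params}} object.
#' @export
draw_item_params <- function(J, config = node_distribution_config(),
                             seed = NULL) {
  if (!is.numeric(J) || length(J) != 1L || J < 1L)
    stop("'J' must be a positive item count")
  J <- as.integer(J)
  stopifnot(inherits(config, "mpp_node_config"))
  if (!is.null(seed)) set.seed(seed)
  alpha <- b <- matrix(NA_real_, 3L, J)
  for (k in 1:3) {
    alpha[k, ] <- rlnorm(J, config$alpha_meanlog[k], config$alpha_sdlog[k])
    b[k, ] <- rnorm(J, config$b_mean[k], config$b_sd[k])
  }
  item_params(alpha, b)
}

#' Draw correlated latent traits
#'
#' Person traits for the three nodes from a trivariate normal with zero
#' means, unit variances and correlation matrix \code{R}.
#'
#' @param n number of persons.
#' @param R 3 x 3 correlation matrix; default \code{\link{default_trait_cor}}.
#' @param seed optional integer seed.
#' @return A \code{\link{latent_traits}} object.
#' @export
draw_thetas <- function(n, R = default_trait_cor(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L)
    stop("'n' must be a positive person count")
  validate_cor_matrix(R)
  if (!is.null(seed)) set.seed(seed)
  theta <- MASS::mvrnorm(as.integer(n), mu = rep(0, 3), Sigma = R)
  if (n == 1L) theta <- matrix(theta, nrow = 1L)
  latent_traits(theta, R)
}

#' Simulate Likert responses from the MPP model
#'
#' Each person x item response is drawn from the five-category distribution
#' implied by the three node probabilities. Emits a warning when the
#' simulated matrix does not contain all five categories (expected to be
#' vanishingly rare at the study's default parameters and n >= 500).
#'
#' @param params an \code{\link{item_params}} object.
#' @param traits a \code{\link{latent_traits}} object (or n x 3 matrix).
#' @param seed optional integer seed.
#' @return Integer persons x items matrix with entries in 1..5.
#' @export
simulate_responses <- function(params, traits, seed = NULL) {
  stopifnot(inherits(params, "mpp_item_params"))
  th <- if (inherits(traits, "mpp_latent_traits")) traits$theta else as.matrix(traits)
  if (ncol(th) != 3L) stop("'traits' must have 3 trait columns")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(th); J <- params$J
  out <- matrix(NA_integer_, n, J,
                dimnames = list(NULL, colnames(params$alpha)))
  for (j in seq_len(J)) {
    P <- category_probabilities(params, th, item = j)
    cp <- P %*% upper.tri(matrix(0, 5, 5), diag = TRUE)  # row-wise cumsum
    u <- runif(n)
    out[, j] <- 1L + as.integer(rowSums(u > cp[, 1:4, drop = FALSE]))
  }
  present <- sort(unique(as.vector(out)))
  if (length(present) < 5L)
    warning(sprintf("simulated responses lack categor%s %s",
                    if (5L - length(present) > 1L) "ies" else "y",
                    paste(setdiff(1:5, present), collapse = ", ")))
  out
}

#' The study's design grid
#'
#' Crossed sample sizes and test lengths with a replicate count and a base
#' seed. Defaults are the full study design: N in \{500, 1000, 1500, 5000\},
#' J in \{10, 15, 20\}, 2000 replicates per cell. Smaller replicate counts
#' give a scaled-down study with identical structure.
#'
#' @param N integer vector of sample sizes.
#' @param J integer vector of test lengths.
#' @param replicates replicates per design cell.
#' @param base_seed integer base seed from which all cell/replicate seeds are
#'   derived.
#' @return An object of class \code{mpp_design_grid}.
#' @export
design_grid <- function(N = c(500L, 1000L, 1500L, 5000L),
                        J = c(10L, 15L, 20L),
                        replicates = 2000L,
                        base_seed = 1L) {
  if (!length(N) || !length(J)) stop("'N' and 'J' must be non-empty")
  if (any(N < 1) || any(J < 1)) stop("'N' and 'J' must be positive")
  if (replicates < 1) stop("'replicates' must be >= 1")
  structure(list(N = as.integer(sort(unique(N))),
                 J = as.integer(sort(unique(J))),
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "mpp_design_grid")
}

#' @export
print.mpp_design_grid <- function(x, ...) {
  cat(sprintf("MPP design grid: %d conditions (N: %s) x (J: %s), %d replicates/cell, base seed %d\n",
              length(x$N) * length(x$J),
              paste(x$N, collapse = ", "), paste(x$J, collapse = ", "),
              x$replicates, x$base_seed))
  invisible(x)
}

# Stable counter-based seed derivation: every (stream, index) pair maps to a
# distinct 31-bit seed regardless of execution order, so any replicate can be
# regenerated in isolation.
derive_seed <- function(base_seed, stream, index = 0L) {
  m <- 2147483647                       # 2^31 - 1
  s <- (as.double(base_seed) %% m) * 48271 %% m
  s <- (s + as.double(stream) * 1000003 + as.double(index) * 7919) %% m
  as.integer(s %% (m - 1) + 1)
}

#' Enumerate the design conditions
#'
#' Expands the grid into one descriptor per (N, J) condition with derived
#' seeds: an item-parameter seed shared by every condition with the same test
#' length (item parameters are drawn once per test length and held fixed
#' across sample sizes and replicates), and a per-condition replicate seed
#' stream.
#'
#' @param grid an \code{\link{design_grid}}.
#' @return A data.frame with one row per condition: \code{condition},
#'   \code{N}, \code{J}, \code{item_seed}, \code{seed_stream},
#'   \code{replicates}.
#' @export
build_design <- function(grid) {
  stopifnot(inherits(grid, "mpp_design_grid"))
  cells <- expand.grid(N = grid$N, J = grid$J, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$J, cells$N), , drop = FALSE]
  rownames(cells) <- NULL
  cells$condition <- seq_len(nrow(cells))
  cells$item_seed <- derive_seed(grid$base_seed, stream = 0L,
                                 index = match(cells$J, grid$J))
  cells$seed_stream <- cells$condition
  cells$replicates <- grid$replicates
  cells[, c("condition", "N", "J", "item_seed", "seed_stream", "replicates")]
}

# Seed for replicate r of a given condition stream.
replicate_seed <- function(grid, seed_stream, r) {
  derive_seed(grid$base_seed, stream = seed_stream, index = r)
}
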