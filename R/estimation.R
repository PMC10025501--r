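#' Prior configuration for the three-node fit
#'
#' Priors mirror the generating distributions by default: log-normal priors
#' on the discriminations with locations (-0.5, 0.3, 0.5) and normal priors
#' on the difficulties \code{b} with centers (-1, 0, 1) for the midpoint,
#' agreement and extreme nodes; spreads default to the generating scales.
#' Priors are placed on the difficulty scale \code{b}; the intercept
#' \code{d = alpha * b} is derived. Traits have a standard-normal prior per
#' node (independent unless a fixed correlation matrix is supplied to the
#' fitter).
#'
#' @param alpha_meanlog,alpha_sdlog length-3: log-normal prior location and
#'   scale for the discriminations.
#' @param b_mean,b_sd length-3: normal prior mean and sd for the
#'   difficulties.
#' @return An object of class \code{mpp_prior_config}.
#' @export
prior_config <- function(alpha_meanlog = c(-0.5, 0.3, 0.5),
                         alpha_sdlog = c(0.5, 0.2, 0.5),
                         b_mean = c(-1, 0, 1),
                         b_sd = c(0.5, 1, 0.5)) {
  for (v in list(alpha_meanlog, alpha_sdlog, b_mean, b_sd))
    if (length(v) != 3L || any(!is.finite(v)))
      stop("each prior field must be a finite length-3 numeric")
  if (any(alpha_sdlog <= 0) || any(b_sd <= 0))
    stop("prior scales must be positive")
  structure(list(alpha_meanlog = stats::setNames(alpha_meanlog, MPP_NODES),
                 alpha_sdlog = stats::setNames(alpha_sdlog, MPP_NODES),
                 b_mean = stats::setNames(b_mean, MPP_NODES),
                 b_sd = stats::setNames(b_sd, MPP_NODES)),
            class = "mpp_prior_config")
}

#' MCMC chain configuration
#'
#' @param chains number of chains (>= 2 recommended so that R-hat is
#'   defined; a single chain triggers a warning).
#' @param iterations total iterations per chain (including burn-in).
#' @param burnin burn-in iterations discarded per chain; proposal scales
#'   adapt only during burn-in.
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @param adapt_window iterations between proposal-scale adaptations.
#' @param target_accept target acceptance rate for the adaptive scales.
#' @param rhat_threshold flag parameters whose split R-hat exceeds this.
#' @param seed integer seed for the sampler (chain seeds are derived from
#'   it); \code{NULL} leaves the RNG state untouched.
#' @return An object of class \code{mpp_chain_config}.
#' @export
chain_config <- function(chains = 3L, iterations = 4000L, burnin = 2000L,
                         thin = 1L, adapt_window = 50L, target_accept = 0.3,
                         rhat_threshold = 1.1, seed = NULL) {
  chains <- as.integer(chains)
  if (chains < 1L) stop("'chains' must be >= 1")
  if (chains < 2L)
    warning("fewer than 2 chains: convergence diagnostics (R-hat) unavailable")
  iterations <- as.integer(iterations); burnin <- as.integer(burnin)
  if (burnin < 0L || iterations <= burnin)
    stop("'iterations' must exceed 'burnin' and 'burnin' must be >= 0")
  if (thin < 1L) stop("'thin' must be >= 1")
  if (target_accept <= 0 || target_accept >= 1)
    stop("'target_accept' must be in (0, 1)")
  structure(list(chains = chains, iterations = iterations, burnin = burnin,
                 thin = as.integer(thin), adapt_window = as.integer(adapt_window),
                 target_accept = target_accept,
                 rhat_threshold = rhat_threshold, seed = seed),
            class = "mpp_chain_config")
}

#' Fit the three-node MPP IRTree model by MCMC
#'
#' Adaptive random-walk Metropolis-within-Gibbs over person traits and
#' per-node item parameters, targeting the posterior implied by the node
#' 2PL sub-models on the observed pseudo-item cells plus the configured
#' priors. Discriminations are sampled on the log scale (hence constrained
#' positive); difficulties are sampled on the \code{b} scale with
#' \code{d = alpha * b} derived per draw.
#'
#' @param codes an \code{mpp_pseudo_items} array from
#'   \code{\link{decompose_responses}} (persons x items x 3).
#' @param priors a \code{\link{prior_config}}.
#' @param chains a \code{\link{chain_config}}.
#' @param traits optional n x 3 matrix (or \code{\link{latent_traits}}) of
#'   known trait values; with \code{update_traits = FALSE} they are held
#'   fixed, otherwise they serve as initial values.
#' @param update_traits sample the person traits (default) or condition on
#'   \code{traits}.
#' @param trait_cor optional fixed 3 x 3 trait correlation matrix used as
#'   the multivariate-normal trait prior; default identity (independent
#'   standard-normal traits; the correlation matrix is never estimated).
#' @param seed integer seed; overrides \code{chains$seed}.
#' @return An object of class \code{mpp_fit} with elements:
#'   \describe{
#'     \item{summary}{data.frame, one row per parameter (\code{alpha},
#'       \code{b}, \code{d} per node x item): posterior mean, sd, 2.5/97.5
#'       percentiles, split R-hat, effective sample size, convergence flag.}
#'     \item{draws}{list of per-chain matrices of pooled (alpha, b) draws.}
#'     \item{theta_mean, theta_sd}{posterior mean/sd of each person's traits
#'       (when traits are sampled).}
#'     \item{flags}{character vector of warnings: non-convergence, sparse or
#'       all-missing pseudo-items.}
#'   }
#' @export
fit_irtree_mcmc <- function(codes, priors = prior_config(),
                            chains = chain_config(), traits = NULL,
                            update_traits = TRUE, trait_cor = NULL,
                            seed = chains$seed) {
  stopifnot(inherits(priors, "mpp_prior_config"),
            inherits(chains, "mpp_chain_config"))
  arr <- unclass(codes)
  if (length(dim(arr)) != 3L || dim(arr)[3L] != 3L)
    stop("'codes' must be a persons x items x 3 array")
  n <- dim(arr)[1L]; J <- dim(arr)[2L]
  if (J > 64L) stop("at most 64 items are supported")
  if (J < 1L) stop("at least one item is required")

  ymats <- lapply(1:3, function(k) {
    y <- arr[, , k, drop = FALSE]
    dim(y) <- c(n, J)
    storage.mode(y) <- "integer"
    y
  })
  # legality: pattern must be one of the five pseudo-item rows
  if (n > 0L) {
    chk <- array(NA_integer_, dim = c(n, J, 3L))
    for (k in 1:3) chk[, , k] <- ymats[[k]]
    recompose_responses(chk)  # errors on illegal patterns
  }

  flags <- character(0)
  n_obs <- t(vapply(ymats, function(y) colSums(!is.na(y)), numeric(J)))
  if (J == 1L) n_obs <- matrix(n_obs, nrow = 3L)
  for (k in 1:3) {
    zero <- which(n_obs[k, ] == 0L)
    sparse <- which(n_obs[k, ] > 0L & n_obs[k, ] < 2L)
    if (length(zero))
      flags <- c(flags, sprintf(
        "%s pseudo-item %d has no observed values: posterior equals the prior",
        MPP_NODES[k], zero))
    if (length(sparse))
      flags <- c(flags, sprintf(
        "%s pseudo-item %d has fewer than 2 observed values", MPP_NODES[k], sparse))
  }

  if (!is.null(traits) && inherits(traits, "mpp_latent_traits"))
    traits <- traits$theta
  if (!update_traits && is.null(traits))
    stop("'traits' must be supplied when update_traits = FALSE")
  if (!is.null(traits)) {
    traits <- as.matrix(traits)
    if (nrow(traits) != n || ncol(traits) != 3L)
      stop("'traits' must be an n x 3 matrix matching 'codes'")
  }

  if (is.null(trait_cor)) {
    R_prec <- diag(3)
  } else {
    validate_cor_matrix(trait_cor)
    R_prec <- solve(trait_cor)
  }

  loga_init <- matrix(priors$alpha_meanlog, 3L, J)
  b_init <- matrix(priors$b_mean, 3L, J)

  chain_draws <- vector("list", chains$chains)
  theta_sum <- matrix(0, max(n, 1L), 3L)
  theta_sumsq <- matrix(0, max(n, 1L), 3L)
  accept <- vector("list", chains$chains)
  total_kept <- 0L

  for (ch in seq_len(chains$chains)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, stream = 900L + ch))
    theta_init <- if (!is.null(traits)) traits else
      matrix(rnorm(n * 3L, sd = 0.5), max(n, 0L), 3L)
    if (n == 0L) theta_init <- matrix(0, 0L, 3L)
    # overdisperse item-parameter starting points across chains
    jit <- if (chains$chains > 1L) (ch - (chains$chains + 1) / 2) * 0.2 else 0
    res <- mpp_mcmc_chain(
      ymats[[1L]], ymats[[2L]], ymats[[3L]],
      as.numeric(priors$alpha_meanlog), as.numeric(priors$alpha_sdlog),
      as.numeric(priors$b_mean), as.numeric(priors$b_sd),
      theta_init, loga_init + jit, b_init + jit, R_prec,
      chains$iterations, chains$burnin, chains$thin,
      update_traits, chains$adapt_window, chains$target_accept)
    chain_draws[[ch]] <- res$draws
    accept[[ch]] <- list(theta = res$accept_theta, item = res$accept_item)
    if (n > 0L && update_traits) {
      theta_sum <- theta_sum + res$theta_sum
      theta_sumsq <- theta_sumsq + res$theta_sumsq
    }
    total_kept <- total_kept + res$kept
  }

  par_names <- c(
    paste0("alpha[", rep(MPP_NODES, each = J), ",", rep(seq_len(J), 3L), "]"),
    paste0("b[", rep(MPP_NODES, each = J), ",", rep(seq_len(J), 3L), "]"))
  for (ch in seq_along(chain_draws)) colnames(chain_draws[[ch]]) <- par_names

  # d = alpha * b, per draw
  d_draws <- lapply(chain_draws, function(m) {
    dm <- m[, 1:(3 * J), drop = FALSE] * m[, 3 * J + 1:(3 * J), drop = FALSE]
    colnames(dm) <- sub("^b", "d", colnames(m)[3 * J + 1:(3 * J)])
    dm
  })
  all_draws <- Map(cbind, chain_draws, d_draws)

  pooled <- do.call(rbind, all_draws)
  summ <- summarize_posterior(pooled)

  if (chains$chains >= 2L) {
    rh <- vapply(colnames(pooled), function(p)
      rhat(sapply(all_draws, function(m) m[, p])), numeric(1))
    es <- vapply(colnames(pooled), function(p)
      ess(sapply(all_draws, function(m) m[, p])), numeric(1))
  } else {
    rh <- rep(NA_real_, ncol(pooled))
    es <- rep(NA_real_, ncol(pooled))
  }
  summ$rhat <- rh
  summ$ess <- es
  summ$converged <- is.na(rh) | rh <= chains$rhat_threshold
  if (any(!summ$converged, na.rm = TRUE))
    flags <- c(flags, sprintf(
      "%d parameter(s) with split R-hat > %.2f", sum(!summ$converged),
      chains$rhat_threshold))

  info <- strcapture("^(alpha|b|d)\\[(\\w+),(\\d+)\\]$", summ$parameter,
                     proto = data.frame(what = character(), node = character(),
                                        item = integer()))
  summ <- cbind(info, summ)
  summ$node <- factor(summ$node, levels = MPP_NODES)

  theta_mean <- theta_sd <- NULL
  if (n > 0L && update_traits && total_kept > 0L) {
    theta_mean <- theta_sum / total_kept
    theta_sd <- sqrt(pmax(theta_sumsq / total_kept - theta_mean^2, 0))
    colnames(theta_mean) <- colnames(theta_sd) <- MPP_NODES
  }

  structure(list(summary = summ, draws = all_draws,
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 flags = flags, accept = accept,
                 n = n, J = J, priors = priors, chains = chains),
            class = "mpp_fit")
}

#' @export
print.mpp_fit <- function(x, ...) {
  cat(sprintf("MPP IRTree fit: %d persons x %d items, %d chain(s) x %d draws kept\n",
              x$n, x$J, x$chains$chains,
              (x$chains$iterations - x$chains$burnin) %/% x$chains$thin))
  a <- subset(x$summary, x$summary$what == "alpha")
  cat("posterior mean alpha by node:",
      paste(sprintf("%s %.2f", MPP_NODES,
                    tapply(a$mean, a$node, mean)), collapse = ", "), "\n")
  if (length(x$flags)) cat("flags:\n", paste(" -", x$flags, collapse = "\n"), "\n")
  else cat("no convergence flags\n")
  invisible(x)
}

#' Split-chain Gelman-Rubin R-hat
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also registers. Chains with zero variance
#' everywhere return 1 by convention.
#'
#' @param draws iterations x chains matrix of draws for one parameter.
#' @return Scalar R-hat (>= 1 up to floating error).
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("R-hat requires at least 2 chains")
  if (nrow(draws) < 4L) stop("R-hat requires at least 4 draws per chain")
  half <- nrow(draws) %/% 2L
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[half + seq_len(half), , drop = FALSE])
  m <- ncol(split); n_it <- nrow(split)
  mu <- colMeans(split)
  W <- mean(apply(split, 2L, var))
  B <- n_it * var(mu)
  if (W == 0) return(1)  # zero-variance guard (identical constant chains)
  sqrt(((n_it - 1) / n_it * W + B / n_it) / W)
}

# Effective sample size from split chains: pooled-variance autocorrelation
# sum truncated at the first negative paired-lag sum (Geyer initial
# positive sequence).
ess <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L || nrow(draws) < 8L) return(NA_real_)
  half <- nrow(draws) %/% 2L
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[half + seq_len(half), , drop = FALSE])
  m <- ncol(split); n_it <- nrow(split)
  W <- mean(apply(split, 2L, var))
  B <- n_it * var(colMeans(split))
  varp <- (n_it - 1) / n_it * W + B / n_it
  if (varp == 0) return(m * n_it)
  max_lag <- min(n_it - 2L, 500L)
  acov <- vapply(seq_len(m), function(c_) {
    x <- split[, c_] - mean(split[, c_])
    stats::acf(x, lag.max = max_lag, plot = FALSE, type = "covariance",
               demean = FALSE)$acf[, 1, 1]
  }, numeric(max_lag + 1L))
  rho <- 1 - (W - rowMeans(acov)[-1L]) / varp
  # Geyer: sum consecutive pairs while positive
  tau <- 1
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  max(m * n_it / tau, 1)
}

#' Summarize posterior draws
#'
#' Mean, sd and central 95% interval per parameter. Percentiles use R's
#' default quantile definition (type 7).
#'
#' @param draws numeric vector or iterations x parameters matrix of pooled
#'   draws.
#' @return data.frame with columns \code{parameter}, \code{mean}, \code{sd},
#'   \code{q2.5}, \code{q97.5}.
#' @export
summarize_posterior <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1L,
                                           dimnames = list(NULL, "par"))
  draws <- as.matrix(draws)
  if (nrow(draws) < 1L) stop("no draws to summarize")
  q <- apply(draws, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(parameter = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
             mean = colMeans(draws),
             sd = apply(draws, 2L, sd),
             q2.5 = q[1L, ], q97.5 = q[2L, ],
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
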