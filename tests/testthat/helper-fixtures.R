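# Shared fixture builders. Everything is generated in code; seeds are fixed
# so failures are reproducible.

# item parameters with all node probabilities equal to 1/2 at theta = 0
half_prob_params <- function(J = 1L) {
  item_params(alpha = matrix(1, 3, J), b = matrix(0, 3, J))
}

# a small simulated dataset with known truth
small_dataset <- function(n = 50L, J = 4L, seed = 99L) {
  params <- draw_item_params(J, seed = derive_seed_fix(seed, 1L))
  traits <- draw_thetas(n, seed = derive_seed_fix(seed, 2L))
  responses <- suppressWarnings(
    simulate_responses(params, traits, seed = derive_seed_fix(seed, 3L)))
  list(params = params, traits = traits, responses = responses,
       codes = decompose_responses(responses))
}

derive_seed_fix <- function(seed, k) as.integer(seed * 131L + k)

# direct evaluation of the five category-probability formulas, written
# independently of the package internals (the test oracle)
oracle_category_probs <- function(alpha, d, theta) {
  pM <- 1 / (1 + exp(-(alpha[1] * theta[1] + d[1])))
  pA <- 1 / (1 + exp(-(alpha[2] * theta[2] + d[2])))
  pE <- 1 / (1 + exp(-(alpha[3] * theta[3] + d[3])))
  c((1 - pM) * (1 - pA) * pE,
    (1 - pM) * (1 - pA) * (1 - pE),
    pM,
    (1 - pM) * pA * (1 - pE),
    (1 - pM) * pA * pE)
}

# posterior means of (alpha, b) for a single item at one node by dense 2-D
# grid integration, conditioning on known traits -- the brute-force oracle
# for the MCMC sampler
grid_posterior_means <- function(y, theta, alpha_meanlog, alpha_sdlog,
                                 b_mean, b_sd, n_grid = 401L) {
  la <- seq(alpha_meanlog - 6 * alpha_sdlog, alpha_meanlog + 6 * alpha_sdlog,
            length.out = n_grid)
  bb <- seq(b_mean - 6 * b_sd, b_mean + 6 * b_sd, length.out = n_grid)
  obs <- !is.na(y)
  logpost <- outer(la, bb, function(lav, bv) {
    vapply(seq_along(lav), function(i) {
      a <- exp(lav[i])
      eta <- a * theta[obs] + a * bv[i]
      sum(ifelse(y[obs] == 1, -log1p(exp(-eta)), -log1p(exp(eta)))) +
        dnorm(lav[i], alpha_meanlog, alpha_sdlog, log = TRUE) +
        dnorm(bv[i], b_mean, b_sd, log = TRUE)
    }, numeric(1))
  })
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  list(alpha = sum(rowSums(w) * exp(la)),
       b = sum(colSums(w) * bb))
}
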