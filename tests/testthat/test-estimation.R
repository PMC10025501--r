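test_that("chain and prior configs validate their settings", {
  expect_error(chain_config(iterations = 100, burnin = 100), "exceed")
  expect_error(chain_config(chains = 0), ">= 1")
  expect_warning(chain_config(chains = 1), "diagnostics")
  expect_error(prior_config(alpha_sdlog = c(0, 0.2, 0.5)), "positive")
  pc <- prior_config()
  expect_equal(unname(pc$alpha_meanlog), c(-0.5, 0.3, 0.5))
  expect_equal(unname(pc$b_mean), c(-1, 0, 1))
})

test_that("split R-hat separates converged from divergent chains", {
  # identical constant chains: defined as 1 by the zero-variance guard
  expect_equal(rhat(matrix(2, 100, 3)), 1)

  # two chains from the same distribution sit near 1
  set.seed(101)
  expect_lt(rhat(matrix(rnorm(20000), 10000, 2)), 1.01)

  # chains centred 10 apart are flagrantly non-converged
  bad <- cbind(rnorm(1000), rnorm(1000, 10))
  expect_gt(rhat(bad), 1.1)
  expect_gt(rhat(bad), 5)

  expect_error(rhat(matrix(1, 100, 1)), "2 chains")
  expect_error(rhat(matrix(1, 2, 2)), "4 draws")
})

test_that("posterior summaries follow the documented percentile rule", {
  s <- summarize_posterior(rep(3.5, 50))
  expect_equal(s$mean, 3.5)
  expect_equal(s$sd, 0)
  expect_equal(s$q2.5, 3.5)
  expect_equal(s$q97.5, 3.5)

  s2 <- summarize_posterior(1:100)
  expect_equal(s2$mean, 50.5)
  expect_equal(s2$q2.5, unname(quantile(1:100, 0.025)))  # type-7 rule
  expect_equal(s2$q97.5, unname(quantile(1:100, 0.975)))

  # invariant to chain concatenation order
  set.seed(102)
  x <- rnorm(500)
  expect_equal(summarize_posterior(x), summarize_posterior(rev(x)))
  expect_error(summarize_posterior(numeric(0)), "no draws")
})

test_that("with no data the sampler reproduces the prior", {
  empty <- structure(array(NA_integer_, c(0, 2, 3)), class = "mpp_pseudo_items")
  fit <- fit_irtree_mcmc(empty,
                         chains = chain_config(chains = 2, iterations = 4000,
                                               burnin = 1000),
                         seed = 7)
  pc <- prior_config()
  for (k in 1:3) {
    prior_mean <- exp(pc$alpha_meanlog[k] + pc$alpha_sdlog[k]^2 / 2)
    a <- fit$summary[fit$summary$what == "alpha" &
                       fit$summary$node == mpp_nodes()[k], ]
    expect_equal(mean(a$mean), unname(prior_mean), tolerance = 0.08)
    b <- fit$summary[fit$summary$what == "b" &
                       fit$summary$node == mpp_nodes()[k], ]
    expect_equal(mean(b$mean), unname(pc$b_mean[k]), tolerance = 0.1)
  }
})

test_that("identical seeds give bit-identical draws", {
  sim <- small_dataset(n = 40, J = 3)
  cc <- suppressWarnings(chain_config(chains = 2, iterations = 200,
                                      burnin = 100))
  f1 <- fit_irtree_mcmc(sim$codes, chains = cc, seed = 31)
  f2 <- fit_irtree_mcmc(sim$codes, chains = cc, seed = 31)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_irtree_mcmc(sim$codes, chains = cc, seed = 32)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("structural missingness is monotone down the decision hierarchy", {
  sim <- small_dataset(n = 300, J = 6)
  arr <- unclass(sim$codes)
  n_obs <- apply(!is.na(arr), 3, sum)
  expect_lte(n_obs["extreme"], n_obs["agreement"])
  expect_lte(n_obs["agreement"], n_obs["midpoint"])
  expect_equal(unname(n_obs["midpoint"]), 300L * 6L)
})

test_that("an all-missing pseudo-item is flagged and falls back to the prior", {
  # one item answered with the midpoint by everyone: its agreement and
  # extreme pseudo-items carry no data
  sim <- small_dataset(n = 80, J = 3)
  y <- sim$responses
  y[, 2] <- 3L
  fit <- fit_irtree_mcmc(decompose_responses(y),
                         chains = chain_config(chains = 2, iterations = 1500,
                                               burnin = 500), seed = 41)
  expect_true(any(grepl("no observed values", fit$flags)))
  pc <- prior_config()
  a2 <- fit$summary[fit$summary$what == "alpha" &
                      fit$summary$node == "agreement" &
                      fit$summary$item == 2L, ]
  expect_equal(a2$mean, unname(exp(pc$alpha_meanlog[2] + pc$alpha_sdlog[2]^2 / 2)),
               tolerance = 0.12)
})

test_that("posterior intervals are ordered and discriminations positive", {
  sim <- small_dataset(n = 120, J = 4)
  fit <- fit_irtree_mcmc(sim$codes,
                         chains = chain_config(chains = 2, iterations = 600,
                                               burnin = 300), seed = 51)
  s <- fit$summary
  expect_true(all(s$q2.5 < s$q97.5))
  expect_true(all(s$mean[s$what == "alpha"] > 0))
  expect_true(all(s$rhat >= 1 - 1e-8))
  # trait posterior means exist for every person and node
  expect_equal(dim(fit$theta_mean), c(120L, 3L))

  # summaries round-trip to CSV, one row per parameter
  f <- withr::local_tempfile(fileext = ".csv")
  write_fit_summary(fit, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(s))
  expect_equal(back$mean, s$mean)
})
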