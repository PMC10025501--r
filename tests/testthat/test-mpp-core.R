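test_that("node probability is the logistic of alpha*theta + d", {
  expect_equal(node_probability(1, 0, 0), 0.5)
  expect_equal(node_probability(2, -1, 1), plogis(1))
  expect_equal(node_probability(2, -1, 1), 0.7310586, tolerance = 1e-6)
  # strictly increasing in theta for any positive alpha
  set.seed(4)
  for (i in 1:20) {
    a <- rlnorm(1); d <- rnorm(1)
    th <- sort(rnorm(2))
    expect_lt(node_probability(a, d, th[1]), node_probability(a, d, th[2]))
  }
  expect_error(node_probability(0, 0, 0), "positive")
  expect_error(node_probability(-1, 0, 0), "positive")
})

test_that("item parameter container enforces its invariants", {
  p <- item_params(matrix(2, 3, 4), matrix(-1, 3, 4))
  expect_equal(p$d, p$alpha * p$b)
  expect_equal(p$J, 4L)
  expect_error(item_params(matrix(0, 3, 2), matrix(0, 3, 2)), "positive")
  expect_error(item_params(matrix(1, 2, 2), matrix(0, 2, 2)), "3 rows")
  expect_error(item_params(matrix(1, 3, 2), matrix(0, 3, 3)), "identical dim")
})

test_that("category probabilities follow the three-node product rules", {
  # all node probabilities 1/2: the midpoint takes half the mass, the four
  # directed categories split the rest evenly
  p <- half_prob_params()
  expect_equal(unname(category_probabilities(p, c(0, 0, 0))),
               c(0.125, 0.125, 0.5, 0.125, 0.125))

  # the midpoint node alone determines category 3, whatever A and E do
  pm <- 0.9
  for (seed in 1:5) {
    set.seed(seed)
    q <- item_params(alpha = matrix(c(1, rlnorm(2)), 3, 1),
                     b = matrix(c(qlogis(pm), rnorm(2)), 3, 1))
    expect_equal(unname(category_probabilities(q, c(0, 0, 0))[3]), pm)
  }

  # direct evaluation of the five formulas as an independent oracle
  q <- item_params(matrix(1, 3, 1), matrix(0, 3, 1))
  th <- c(1, -1, 0.5)
  expect_equal(unname(category_probabilities(q, th)),
               oracle_category_probs(c(1, 1, 1), c(0, 0, 0), th),
               tolerance = 1e-12)
  expect_equal(sum(category_probabilities(q, th)), 1, tolerance = 1e-12)
})

test_that("category probabilities sum to one over random draws", {
  set.seed(11)
  for (i in 1:1000) {
    p <- item_params(alpha = matrix(rlnorm(3, 0, 1), 3, 1),
                     b = matrix(rnorm(3, 0, 2), 3, 1))
    pr <- category_probabilities(p, rnorm(3, 0, 2))
    expect_true(abs(sum(pr) - 1) < 1e-12)
    expect_true(all(pr >= 0))
  }
})

test_that("a saturated midpoint node drives all mass to category 3", {
  p <- item_params(alpha = matrix(1, 3, 1), b = matrix(c(80, 0, 0), 3, 1))
  pr <- category_probabilities(p, c(0, 0, 0))
  expect_equal(unname(pr[3]), 1)
  expect_equal(unname(pr[-3]), rep(0, 4))
})

test_that("decomposition maps each category to its pseudo-item row", {
  x <- matrix(1:5, 1, 5)
  codes <- decompose_responses(x)
  expect_equal(unname(codes[1, 1, ]), c(0L, 0L, 1L))        # 1
  expect_equal(unname(codes[1, 2, ]), c(0L, 0L, 0L))        # 2
  expect_equal(unname(codes[1, 3, ]), c(1L, NA, NA))        # 3: tree stops
  expect_equal(unname(codes[1, 4, ]), c(0L, 1L, 0L))        # 4
  expect_equal(unname(codes[1, 5, ]), c(0L, 1L, 1L))        # 5
  # structural missingness iff midpoint
  expect_true(all(is.na(codes[, , 2]) == (codes[, , 1] == 1L)))

  bad <- matrix(c(1L, 6L, 2L, 3L), 2, 2)
  expect_error(decompose_responses(bad), "person 2, item 1")
  bad2 <- matrix(c(1L, 2L, NA, 3L), 2, 2)
  expect_error(decompose_responses(bad2), "person 1, item 2")
})

test_that("recompose inverts decompose and rejects illegal patterns", {
  codes <- decompose_responses(matrix(c(4L, 3L), 1, 2))
  expect_equal(unname(recompose_responses(codes)[1, ]), c(4L, 3L))

  set.seed(21)
  for (i in 1:10) {
    x <- matrix(sample(1:5, 60, replace = TRUE), 10, 6)
    expect_equal(unname(recompose_responses(decompose_responses(x))),
                 unname(x))
  }
  # decompose(recompose(c)) = c on legal codes
  legal <- decompose_responses(matrix(rep(1:5, 4), 4, 5))
  back <- decompose_responses(recompose_responses(legal))
  expect_identical(unclass(back)[, , ], unclass(legal)[, , ])

  # midpoint taken but agreement observed: no such branch exists
  ill <- unclass(decompose_responses(matrix(3L, 2, 2)))
  ill[1, 1, 2] <- 0L
  expect_error(recompose_responses(ill), "illegal.*person 1, item 1")
  # directed response with missing extreme code
  ill2 <- unclass(decompose_responses(matrix(4L, 2, 2)))
  ill2[2, 2, 3] <- NA
  expect_error(recompose_responses(ill2), "person 2, item 2")
})

test_that("log-likelihood counts only observed pseudo-item cells", {
  # all node probabilities 1/2: each observed cell contributes log(1/2)
  p <- half_prob_params(J = 3L)
  tr <- latent_traits(matrix(0, 4, 3))
  x <- matrix(c(1L, 3L, 5L, 2L, 3L, 3L, 4L, 1L, 2L, 5L, 3L, 4L), 4, 3)
  codes <- decompose_responses(x)
  k_obs <- sum(!is.na(unclass(codes)))
  expect_equal(mpp_loglik(p, tr, codes), k_obs * log(0.5))

  # a midpoint response contributes log(p_M) alone
  p1 <- item_params(matrix(c(1.2, 2, 0.5), 3, 1), matrix(c(0.4, -1, 1), 3, 1))
  th <- matrix(c(0.3, -0.2, 0.1), 1, 3)
  codes3 <- decompose_responses(matrix(3L, 1, 1))
  pM <- node_probability(1.2, 1.2 * 0.4, 0.3)
  expect_equal(mpp_loglik(p1, th, codes3), log(pM))
})

test_that("decomposed likelihood equals the category-probability likelihood", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(1:6, 1); J <- sample(1:4, 1)
    p <- item_params(alpha = matrix(rlnorm(3 * J, 0, 0.6), 3, J),
                     b = matrix(rnorm(3 * J), 3, J))
    th <- matrix(rnorm(3 * n), n, 3)
    x <- matrix(sample(1:5, n * J, replace = TRUE), n, J)
    ll_cat <- sum(vapply(seq_len(J), function(j) {
      pr <- category_probabilities(p, th, item = j)
      if (!is.matrix(pr)) pr <- matrix(pr, 1, 5)
      sum(log(pr[cbind(seq_len(n), x[, j])]))
    }, numeric(1)))
    expect_equal(mpp_loglik(p, th, decompose_responses(x)), ll_cat,
                 tolerance = 1e-10)
  }
})

test_that("log-likelihood stays finite at extreme linear predictors", {
  p <- item_params(matrix(c(3, 1, 1), 3, 1), matrix(c(10, 0, 0), 3, 1))
  th <- matrix(c(-20, 0, 0), 1, 3)  # eta_M = 3*(-20) + 30 = -30, y_M = 1
  codes <- decompose_responses(matrix(3L, 1, 1))
  ll <- mpp_loglik(p, th, codes)
  expect_true(is.finite(ll))
  expect_equal(ll, -30, tolerance = 1e-6)  # log p ~ eta for eta << 0
})
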