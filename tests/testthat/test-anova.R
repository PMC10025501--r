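# builds a minimal detail table directly; only the columns the ANOVA module
# reads are needed
mock_detail <- function(N, J, node, alpha_rmse, d_rmse = alpha_rmse) {
  data.frame(node = factor(node, levels = mpp_nodes()), N = N, J = J,
             item = seq_along(alpha_rmse),
             alpha_rmse = alpha_rmse, d_rmse = d_rmse)
}

# the full study layout: for every N x J cell, J items per node
full_design_detail <- function(fill = function(n) rep(0, n)) {
  do.call(rbind, lapply(c(500, 1000, 1500, 5000), function(N)
    do.call(rbind, lapply(c(10, 15, 20), function(J)
      do.call(rbind, lapply(mpp_nodes(), function(nd)
        mock_detail(N, J, nd, fill(J))))))))
}

test_that("constant responses give zero sums of squares and zero eta-squared", {
  det <- full_design_detail(function(n) rep(0.5, n))
  an <- factorial_anova(det, "alpha")
  expect_equal(an$table$sum_sq, rep(0, nrow(an$table)), tolerance = 1e-20)
  expect_equal(an$table$eta_sq_partial, rep(0, nrow(an$table)))
})

test_that("a hand-computed 2x2 design recovers its sums of squares", {
  # cell means 0,0,1,1: all variation is the N main effect; two items per
  # cell with zero within-cell spread, so the residual is exactly zero
  det <- rbind(mock_detail(100, 5, "midpoint", c(0, 0)),
               mock_detail(100, 10, "midpoint", c(0, 0)),
               mock_detail(200, 5, "midpoint", c(1, 1)),
               mock_detail(200, 10, "midpoint", c(1, 1)))
  expect_warning(an <- factorial_anova(det, "alpha"), "single level")
  tab <- an$table
  # hand computation: grand mean 1/2, SS_N = 8 * 0.25 = 2, SS_J = SS_NJ = 0
  expect_equal(tab$sum_sq[tab$effect == "N"], 2)
  expect_equal(tab$sum_sq[tab$effect == "J"], 0, tolerance = 1e-12)
  expect_equal(an$residual_ss, 0, tolerance = 1e-12)
  expect_equal(tab$eta_sq_partial[tab$effect == "N"], 1)
  expect_equal(tab$eta_sq_partial[tab$effect == "J"], 0)
})

test_that("sums of squares are conserved on balanced designs", {
  set.seed(88)
  for (i in 1:5) {
    det <- full_design_detail(function(n) rnorm(n))
    det <- det[det$J == 10 | det$J == 15 | det$J == 20, ]
    # balance item counts across J cells so Type II partitions exactly
    det_b <- do.call(rbind, lapply(split(det, list(det$N, det$J, det$node)),
                                   function(g) g[1:10, ]))
    an <- factorial_anova(det_b, "alpha")
    total <- sum((det_b$alpha_rmse - mean(det_b$alpha_rmse))^2)
    expect_equal(sum(an$table$sum_sq) + an$residual_ss, total,
                 tolerance = 1e-8)
    expect_true(all(an$table$eta_sq_partial >= 0 &
                      an$table$eta_sq_partial <= 1))
  }
})

test_that("partial eta-squared equals classical eta-squared with one factor", {
  set.seed(89)
  det <- mock_detail(100, 10, rep(mpp_nodes(), each = 10),
                     rnorm(30, rep(c(0, 1, 3), each = 10)))
  expect_warning(an <- factorial_anova(det, "alpha"), "single level")
  y <- det$alpha_rmse
  ss_between <- sum(tapply(y, det$node, function(g) length(g) * (mean(g) - mean(y))^2))
  ss_total <- sum((y - mean(y))^2)
  expect_equal(an$table$eta_sq_partial[an$table$effect == "node"],
               ss_between / ss_total, tolerance = 1e-10)
})

test_that("the full design yields 540 observations and 504 residual df", {
  set.seed(90)
  det <- full_design_detail(function(n) rnorm(n, sd = 0.1))
  expect_equal(nrow(det), 540L)
  an <- factorial_anova(det, "alpha")
  expect_equal(an$residual_df, 504L)
  expect_equal(sum(an$table$df), 35L)  # 36 cells - 1
})

test_that("pairwise node contrasts use the pooled residual variance", {
  det <- mock_detail(100, 10, rep(mpp_nodes(), each = 4),
                     c(0, 0, 0, 0, 1, 1, 1, 1, 2, 3, 2, 3))
  suppressWarnings({
    ctr <- pairwise_simple_effects(det, "alpha", "overall")
  })
  # residual SS = 1 (within extreme) on 9 df; t = -1 / sqrt((1/9)(1/2))
  expect_equal(ctr$df, rep(9, 3))
  expect_equal(ctr$t[ctr$contrast == "midpoint - agreement"],
               -1 / sqrt((1 / 9) * (1 / 4 + 1 / 4)), tolerance = 1e-10)
  # earlier-minus-later sign convention: growing error gives negative t
  expect_true(all(ctr$t < 0))

  # identical groups give t = 0
  det0 <- mock_detail(100, 10, rep(mpp_nodes(), each = 3),
                      rep(c(1, 2, 3), times = 3))
  suppressWarnings(ctr0 <- pairwise_simple_effects(det0, "alpha", "overall"))
  expect_equal(ctr0$t, rep(0, 3), tolerance = 1e-12)

  # adjusted p-values are never smaller than raw ones
  suppressWarnings({
    raw <- pairwise_simple_effects(det, "alpha", "overall", adjust = "none")
    bon <- pairwise_simple_effects(det, "alpha", "overall", adjust = "bonferroni")
  })
  expect_true(all(bon$p >= raw$p - 1e-15))
})

test_that("within-test-length contrasts are grouped by J", {
  set.seed(91)
  det <- do.call(rbind, lapply(c(10, 15), function(J)
    mock_detail(100, J, rep(mpp_nodes(), each = 5), rnorm(15, sd = 0.1))))
  suppressWarnings(ctr <- pairwise_simple_effects(det, "alpha", "J"))
  expect_equal(nrow(ctr), 6L)
  expect_setequal(unique(ctr$group), c("J=10", "J=15"))
})
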