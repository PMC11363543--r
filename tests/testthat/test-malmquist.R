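test_that("efficiency against an explicit reference set has closed-form toys", {
  # point (2,2) against {(1,2)}: input slack 1, no output slack
  expect_equal(efficiency_vs_reference(2, 2, matrix(1), matrix(2)), 0.5,
               tolerance = 1e-9)
  # membership in the reference set bounds the score by one
  set.seed(31)
  X <- matrix(runif(8, 1, 4), 2)
  Y <- matrix(runif(8, 1, 4), 2)
  for (j in 1:4)
    expect_lte(efficiency_vs_reference(X[, j], Y[, j], X, Y), 1 + 1e-9)
})

test_that("identical adjacent periods give unit Malmquist components", {
  g <- generate_dea_panel(n_units = 5, n_periods = 2, seed = 32)
  p <- g$panel
  p$inputs[, , 2] <- p$inputs[, , 1]
  p$outputs[, , 2] <- p$outputs[, , 1]
  res <- malmquist_chain(p)
  expect_equal(res$mi, rep(1, 5), tolerance = 1e-8)
  expect_equal(res$ec, rep(1, 5), tolerance = 1e-8)
  expect_equal(res$tc, rep(1, 5), tolerance = 1e-8)
})

test_that("uniform input inflation leaves catch-up at one and lowers MI", {
  # 1 input, 1 output; all inputs inflated 10% in period 2, outputs fixed.
  # Within-period frontiers are rescaled copies, so contemporaneous scores
  # (hence EC) are unchanged by units-invariance; against the pooled
  # frontier every period-2 unit is strictly worse.
  inputs <- array(c(1, 2, 3, 1.1, 2.2, 3.3), c(3, 1, 2))
  outputs <- array(c(1, 1.8, 2.2, 1, 1.8, 2.2), c(3, 1, 2))
  p <- panel_dataset(c("a", "b", "c"), 1:2, inputs, outputs)
  res <- malmquist_chain(p)
  expect_equal(res$ec, rep(1, 3), tolerance = 1e-8)
  expect_true(all(res$mi < 1))
  expect_equal(res$mi, res$tc, tolerance = 1e-9)
})

test_that("the index decomposes exactly and is transitive across periods", {
  g <- generate_dea_panel(n_units = 6, n_periods = 3, seed = 33)
  res <- malmquist_chain(g$panel)
  expect_true(all(res$mi > 0 & res$ec > 0 & res$tc > 0))
  expect_equal(res$mi, res$ec * res$tc, tolerance = 1e-12)
  # global-frontier circularity: MI(1->3) = MI(1->2) * MI(2->3)
  Eg <- attr(res, "global")
  for (j in seq_len(nrow(Eg))) {
    direct <- Eg[j, 3] / Eg[j, 1]
    chained <- (Eg[j, 2] / Eg[j, 1]) * (Eg[j, 3] / Eg[j, 2])
    expect_equal(direct, chained, tolerance = 1e-9)
  }
})

test_that("summaries use geometric per-unit and arithmetic national means", {
  res <- data.frame(unit = rep(c("a", "b"), each = 2),
                    mi = c(1, 1, 4, 1), ec = c(1, 1, 2, 1),
                    tc = c(1, 1, 2, 1))
  s <- summarize_malmquist(res)
  expect_equal(unname(s$per_unit["a", ]), c(1, 1, 1))
  expect_equal(unname(s$per_unit["b", "MI"]), 2)  # geometric mean of 4 and 1
  expect_equal(unname(s$national["MI"]), 1.5)     # arithmetic across units
  # geometric averaging preserves the multiplicative identity
  set.seed(34)
  mi <- runif(6, 0.5, 1.5)
  ec <- runif(6, 0.5, 1.5)
  d <- data.frame(unit = "u", mi = mi, ec = ec, tc = mi / ec)
  su <- summarize_malmquist(d)
  expect_equal(unname(su$per_unit[1, "MI"]),
               unname(su$per_unit[1, "EC"] * su$per_unit[1, "TC"]),
               tolerance = 1e-12)
  expect_error(summarize_malmquist(transform(d, mi = -mi)), "positive")
})
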