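test_that("toy frontier reproduces known SBM and super-SBM scores", {
  toy <- toy_abc()
  # C uses twice the input of A for the same output: half efficient
  expect_equal(sbm_score(dea_problem(toy$X, toy$Y, 3))$score, 0.5,
               tolerance = 1e-9)
  expect_equal(sbm_score(dea_problem(toy$X, toy$Y, 1))$score, 1,
               tolerance = 1e-9)
  # A re-scored against {B, C}: must move to x >= 4 while y <= 2
  sup <- super_sbm_score(dea_problem(toy$X, toy$Y, 1))
  expect_equal(sup$score, 2, tolerance = 1e-9)
  expect_true(sup$feasible)
  # a point reproducible as a convex combination of its reference scores 1
  expect_equal(super_sbm_score(dea_problem(matrix(c(2, 4, 3), 1),
                                           matrix(c(2, 4, 3), 1), 3))$score,
               1, tolerance = 1e-9)
  # a duplicated efficient unit makes the zero adjustment feasible
  X2 <- cbind(toy$X, 2)
  Y2 <- cbind(toy$Y, 2)
  expect_equal(super_sbm_score(dea_problem(X2, Y2, 1))$score, 1,
               tolerance = 1e-9)
})

test_that("a unit evaluated against itself alone is efficient with no slack", {
  sol <- sbm_score(dea_problem(matrix(2), matrix(3), 1))
  expect_equal(sol$score, 1, tolerance = 1e-9)
  expect_equal(sol$input_slacks, 0, tolerance = 1e-9)
  expect_equal(sol$output_slacks, 0, tolerance = 1e-9)
})

test_that("dominated units always score below one", {
  set.seed(101)
  for (r in 1:20) {
    m <- sample(1:2, 1)
    s <- sample(1:2, 1)
    n <- sample(3:5, 1)
    X <- matrix(runif(m * n, 1, 5), m)
    Y <- matrix(runif(s * n, 1, 5), s)
    # make unit n strictly dominated by unit 1
    X[, n] <- X[, 1] * runif(m, 1.1, 1.5)
    Y[, n] <- Y[, 1] * runif(s, 0.5, 0.9)
    expect_lt(sbm_score(dea_problem(X, Y, n))$score, 1)
  }
})

test_that("scores are invariant to rescaling any input or output dimension", {
  set.seed(102)
  X <- matrix(runif(2 * 5, 1, 5), 2)
  Y <- matrix(runif(2 * 5, 1, 5), 2)
  base_sbm <- sapply(1:5, function(j) sbm_score(dea_problem(X, Y, j))$score)
  base_sup <- sapply(1:5, function(j)
    super_sbm_score(dea_problem(X, Y, j))$score)
  for (r in 1:5) {
    cx <- runif(2, 0.01, 100)
    cy <- runif(2, 0.01, 100)
    Xs <- X * cx
    Ys <- Y * cy
    expect_equal(sapply(1:5, function(j)
      sbm_score(dea_problem(Xs, Ys, j))$score), base_sbm, tolerance = 1e-7)
    expect_equal(sapply(1:5, function(j)
      super_sbm_score(dea_problem(Xs, Ys, j))$score), base_sup,
      tolerance = 1e-7)
  }
})

test_that("inflating an inefficient unit's inputs never raises its score", {
  set.seed(103)
  for (r in 1:10) {
    X <- matrix(runif(2 * 4, 1, 5), 2)
    Y <- matrix(runif(2 * 4, 1, 5), 2)
    X[, 4] <- X[, 1] * 1.3
    Y[, 4] <- Y[, 1] * 0.8       # unit 4 inefficient by construction
    s0 <- sbm_score(dea_problem(X, Y, 4))$score
    X[, 4] <- X[, 4] * runif(2, 1.05, 1.5)
    s1 <- sbm_score(dea_problem(X, Y, 4))$score
    expect_lte(s1, s0 + 1e-9)
  }
})

test_that("certificates satisfy the envelopment constraints and objective", {
  set.seed(104)
  X <- matrix(runif(2 * 5, 1, 5), 2)
  Y <- matrix(runif(2 * 5, 1, 5), 2)
  for (j in 1:5) {
    sol <- sbm_score(dea_problem(X, Y, j))
    expect_equal(sum(sol$lambdas), 1, tolerance = 1e-6)
    expect_true(all(sol$lambdas >= -1e-8))
    expect_equal(as.vector(X %*% sol$lambdas + sol$input_slacks), X[, j],
                 tolerance = 1e-6)
    expect_equal(as.vector(Y %*% sol$lambdas - sol$output_slacks), Y[, j],
                 tolerance = 1e-6)
    obj <- (1 - mean(sol$input_slacks / X[, j])) /
      (1 + mean(sol$output_slacks / Y[, j]))
    expect_equal(obj, sol$score, tolerance = 1e-6)
  }
})

test_that("small instances agree with the lambda-simplex grid oracle", {
  set.seed(105)
  for (r in 1:10) {
    n <- sample(2:4, 1)
    ms <- sample(1:2, 1)
    X <- matrix(round(runif(ms * n, 0.5, 5), 2), ms)
    Y <- matrix(round(runif(ms * n, 0.5, 5), 2), ms)
    j0 <- sample(n, 1)
    expect_equal(sbm_score(dea_problem(X, Y, j0))$score,
                 sbm_grid_oracle(X, Y, j0), tolerance = 1e-3)
  }
})

test_that("the two-stage rule returns SBM output for inefficient units and
           super-efficiency for efficient ones", {
  toy <- toy_abc()
  ineff <- two_stage_score(dea_problem(toy$X, toy$Y, 3))
  expect_identical(ineff$stage, "sbm")
  expect_equal(ineff$score, 0.5, tolerance = 1e-9)
  eff <- two_stage_score(dea_problem(toy$X, toy$Y, 1))
  expect_identical(eff$stage, "super_sbm")
  expect_equal(eff$score, 2, tolerance = 1e-9)
})

test_that("panel scoring is deterministic and permutation-equivariant", {
  g <- generate_dea_panel(n_units = 6, n_periods = 2, seed = 21)
  et <- score_panel(g$panel)
  expect_equal(dim(et$scores), c(6L, 2L))
  # identical data in both periods of a copied panel -> identical columns
  p2 <- g$panel
  p2$inputs[, , 2] <- p2$inputs[, , 1]
  p2$outputs[, , 2] <- p2$outputs[, , 1]
  et2 <- score_panel(p2)
  expect_equal(et2$scores[, 1], et2$scores[, 2])
  # permuting units permutes scores identically
  perm <- c(3, 1, 6, 2, 5, 4)
  pp <- panel_dataset(g$panel$units[perm], g$panel$periods,
                      g$panel$inputs[perm, , , drop = FALSE],
                      g$panel$outputs[perm, , , drop = FALSE])
  etp <- score_panel(pp)
  expect_equal(unname(etp$scores), unname(et$scores[perm, ]),
               tolerance = 1e-8)
})

test_that("score table formatting appends arithmetic means", {
  sc <- matrix(1:6 / 10, 2, dimnames = list(c("a", "b"), 2001:2003))
  ft <- format_score_table(sc)
  expect_equal(dim(ft), c(3L, 4L))
  expect_equal(ft["Mean", "Mean"], round(mean(sc), 3))
  expect_equal(ft["a", "Mean"], round(mean(sc["a", ]), 3))
})
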