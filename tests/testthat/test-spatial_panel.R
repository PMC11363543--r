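test_that("the within transformation annihilates additive structure", {
  expect_equal(demean_two_way(matrix(5, 4, 3)), matrix(0, 4, 3))
  a <- rnorm(4)
  b <- rnorm(3)
  M <- outer(a, rep(1, 3)) + outer(rep(1, 4), b)
  expect_equal(demean_two_way(M), matrix(0, 4, 3), tolerance = 1e-12)
  set.seed(61)
  R <- demean_two_way(matrix(rnorm(12), 4, 3))
  expect_lt(max(abs(rowMeans(R))), 1e-12)
  expect_lt(max(abs(colMeans(R))), 1e-12)
  expect_error(demean_two_way(matrix(c(1, NA, 3, 4), 2)), "unbalanced")
})

test_that("with a null weight matrix all three models collapse to least
           squares", {
  set.seed(62)
  n <- 8; Tt <- 4; k <- 2
  y <- matrix(rnorm(n * Tt), n)
  X <- array(rnorm(n * Tt * k), c(n, Tt, k))
  W0 <- structure(list(labels = sprintf("u%d", 1:n),
                       binary = matrix(0, n, n),
                       row_standardized = matrix(0, n, n)),
                  class = "weight_matrix")
  yd <- demean_two_way(y)
  Zd <- sapply(1:k, function(j) as.vector(demean_two_way(X[, , j])))
  ols <- lm.fit(Zd, as.vector(yd))$coefficients
  for (mod in c("sdm", "sar", "sem")) {
    f <- fit_spatial_panel(y, X, W0, mod, "both")
    expect_equal(unname(f$beta), unname(ols), tolerance = 1e-8)
    expect_equal(f$rho, 0)
  }
})

test_that("a noiseless aspatial DGP is recovered exactly", {
  set.seed(63)
  sim <- generate_sdm_panel(rho = 0, theta = rep(0, 13), sigma = 1e-6,
                            seed = 64)
  f <- fit_spatial_panel(sim$y, sim$X, sim$W, "sar", "both")
  expect_equal(unname(f$beta), sim$params$beta, tolerance = 1e-4)
  expect_lt(abs(f$rho), 1e-3)
})

test_that("the concentrated likelihood optimum beats a parameter grid", {
  sim <- generate_sdm_panel(seed = 65)
  f <- fit_spatial_panel(sim$y, sim$X, sim$W, "sdm", "both")
  # independent profile-likelihood evaluation on demeaned data
  Wm <- sim$W$row_standardized
  n <- nrow(sim$y); Tt <- ncol(sim$y); k <- dim(sim$X)[3]
  Wy <- demean_two_way(apply(sim$y, 2, function(c) Wm %*% c))
  yd <- demean_two_way(sim$y)
  Z <- cbind(sapply(1:k, function(j) as.vector(demean_two_way(sim$X[, , j]))),
             sapply(1:k, function(j) as.vector(demean_two_way(
               apply(sim$X[, , j], 2, function(c) Wm %*% c)))))
  om <- Re(eigen(Wm, only.values = TRUE)$values)
  ll_at <- function(rho) {
    e <- lm.fit(Z, as.vector(yd) - rho * as.vector(Wy))$residuals
    s2 <- sum(e^2) / (n * Tt)
    -n * Tt / 2 * (log(2 * pi * s2) + 1) + Tt * sum(log(1 - rho * om))
  }
  grid <- seq(1 / min(om) + 0.01, 0.99, length.out = 100)
  expect_gte(f$loglik, max(sapply(grid, ll_at)) - 1e-6)
  expect_equal(f$loglik, ll_at(f$rho), tolerance = 1e-8)
})

test_that("fit diagnostics are well-formed", {
  sim <- generate_sdm_panel(seed = 66)
  f <- fit_spatial_panel(sim$y, sim$X, sim$W, "sdm", "both")
  expect_true(f$r2 >= 0 && f$r2 <= 1)
  expect_true(is.finite(f$loglik))
  ev <- eigen(f$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * max(ev))
  om <- Re(eigen(sim$W$row_standardized, only.values = TRUE)$values)
  expect_true(f$rho > 1 / min(om) && f$rho < 1)
})

test_that("LM statistics are nonnegative quadratic forms with valid p", {
  sim <- generate_sdm_panel(seed = 67)
  lt <- lm_tests(sim$y, sim$X, sim$W)
  expect_named(lt, c("lm_lag", "lm_error", "robust_lm_lag",
                     "robust_lm_error"))
  for (t in lt) {
    expect_gte(t$statistic, 0)
    expect_true(t$p_value >= 0 && t$p_value <= 1)
    expect_equal(t$df, 1L)
  }
})

test_that("robust LM-error dominates robust LM-lag under error
           autocorrelation", {
  W <- rook29_weights()
  A <- solve(diag(29) - 0.6 * W$row_standardized)
  beta <- c(0.4, -0.1)
  set.seed(68)
  wins <- replicate(40, {
    X <- array(rnorm(29 * 10 * 2), c(29, 10, 2))
    u <- sapply(1:10, function(t) A %*% rnorm(29, 0, 0.3))
    y <- sapply(1:10, function(t) matrix(X[, t, ], 29) %*% beta) + u
    lt <- lm_tests(y, X, W)
    c(err = lt$robust_lm_error$p_value < 0.05,
      lag = lt$robust_lm_lag$p_value < 0.05)
  })
  expect_gt(sum(wins["err", ]), sum(wins["lag", ]))
})

test_that("likelihood-ratio machinery is coherent", {
  sim <- generate_sdm_panel(seed = 69)
  f1 <- fit_spatial_panel(sim$y, sim$X, sim$W, "sdm", "both")
  f0 <- fit_spatial_panel(sim$y, sim$X, sim$W, "sar", "both")
  expect_equal(lr_test(f1, f1, df = 1)$statistic, 0)
  lr <- lr_test(f1, f0, df = 13)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$df, 13L)
  expect_error(lr_test(f0, f0), "not nested")
  # Durbin terms generated nonzero: degradation rejected by LR and Wald
  expect_lt(lr$p_value, 0.05)
  expect_lt(wald_degradation(f1, "sar")$p_value, 0.05)
  expect_lt(wald_degradation(f1, "sem")$p_value, 0.05)
  expect_error(wald_degradation(f0, "sar"), "SDM")
})

test_that("the Hausman statistic is degenerate at zero for identical fits", {
  sim <- generate_sdm_panel(seed = 70)
  f <- fit_spatial_panel(sim$y, sim$X, sim$W, "sdm", "both")
  h <- hausman_test(f, f)
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  re <- fit_spatial_panel(sim$y, sim$X, sim$W, "sdm", "random")
  h2 <- hausman_test(f, re)
  expect_gte(h2$statistic, 0)
  expect_true(h2$p_value >= 0 && h2$p_value <= 1)
})

test_that("effects decomposition matches a hand-inverted 3-node system", {
  labs <- c("a", "b", "c")
  W <- build_weights(rbind(c("a", "b"), c("b", "c")), labs)
  fit <- structure(list(model = "sar", delta = 1, beta = 1, theta = NULL,
                        rho = 0.5, k = 1L, xnames = "x",
                        vcov = diag(c(1e-6, 1e-6, 1e-6))),
                   class = "spatial_model_fit")
  eff <- decompose_effects(fit, W, draws = 50, seed = 1)
  S <- solve(diag(3) - 0.5 * W$row_standardized)
  expect_equal(eff$direct, mean(diag(S)), tolerance = 1e-8)
  expect_equal(eff$total, sum(S) / 3, tolerance = 1e-8)
  expect_equal(eff$indirect, sum(S) / 3 - mean(diag(S)), tolerance = 1e-8)
})

test_that("effects are purely direct when the spatial parameter is zero", {
  labs <- sprintf("u%d", 1:4)
  W <- ring_weights(4)
  fit <- structure(list(model = "sdm", delta = c(2, 0), beta = 2, theta = 0,
                        rho = 0, k = 1L, xnames = "x",
                        vcov = diag(1e-8, 4)),
                   class = "spatial_model_fit")
  eff <- decompose_effects(fit, W, draws = 50, seed = 2)
  expect_equal(eff$direct, 2, tolerance = 1e-9)
  expect_equal(eff$indirect, 0, tolerance = 1e-9)
  expect_equal(eff$total, eff$direct + eff$indirect)
})

test_that("effects decomposition is reproducible and label-equivariant", {
  sim <- generate_sdm_panel(seed = 71)
  f <- fit_spatial_panel(sim$y, sim$X, sim$W, "sdm", "both")
  e1 <- decompose_effects(f, sim$W, draws = 100, seed = 9)
  e2 <- decompose_effects(f, sim$W, draws = 100, seed = 9)
  expect_equal(e1, e2)
  expect_equal(e1$total, e1$direct + e1$indirect, tolerance = 1e-12)
  # permuting units leaves the averaged effects unchanged
  perm <- sample(29)
  Wp <- list(labels = sim$W$labels[perm],
             binary = sim$W$binary[perm, perm],
             row_standardized = sim$W$row_standardized[perm, perm])
  class(Wp) <- "weight_matrix"
  fp <- fit_spatial_panel(sim$y[perm, ], sim$X[perm, , ], Wp, "sdm", "both")
  ep <- decompose_effects(fp, Wp, draws = 100, seed = 9)
  expect_equal(ep$direct, e1$direct, tolerance = 1e-6)
  expect_equal(ep$indirect, e1$indirect, tolerance = 1e-6)
})
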