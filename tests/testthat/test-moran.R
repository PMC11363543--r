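test_that("weight construction is symmetric, standardized and validated", {
  W <- ring_weights(4)
  expect_true(isSymmetric(W$binary))
  expect_equal(diag(W$binary), rep(0, 4), ignore_attr = TRUE)
  # each ring row splits weight equally between its two neighbours
  expect_equal(sort(W$row_standardized[1, ]), c(0, 0, 0.5, 0.5),
               ignore_attr = TRUE)
  expect_error(build_weights(cbind("a", "zz"), c("a", "b")), "unknown label")
  expect_error(build_weights(cbind("a", "b"), c("a", "b", "c")), "isolated")
  expect_error(build_weights(cbind("a", "a"), c("a", "b")), "self-loop")
})

test_that("the packaged rook matrix matches the declared contiguity", {
  W <- rook29_weights()
  expect_equal(length(W$labels), 29L)
  expect_true(isSymmetric(W$binary))
  # Hainan is an island joined only to Guangdong
  hn <- W$binary["Hainan", ]
  expect_equal(sum(hn), 1)
  expect_equal(unname(hn["Guangdong"]), 1)
  expect_equal(rowSums(W$row_standardized), rep(1, 29), ignore_attr = TRUE)
})

test_that("alternating values on a 4-cycle give Moran's I of -1", {
  W <- ring_weights(4)
  m <- global_moran(c(1, -1, 1, -1), W)
  expect_equal(m$statistic, -1, tolerance = 1e-12)
  expect_equal(m$expectation, -1 / 3)
})

test_that("Moran's I is invariant to positive affine transformations", {
  W <- rook29_weights()
  x <- load_fixture("table1_efficiency")[, "2012"]
  base <- global_moran(x, W)$statistic
  expect_equal(global_moran(3.2 + 10 * x, W)$statistic, base,
               tolerance = 1e-12)
  expect_error(global_moran(rep(1, 29), W), "degenerate")
})

test_that("permutation variance agrees with the analytic randomization
           variance", {
  W <- rook29_weights()
  x <- load_fixture("table1_efficiency")[, "2012"]
  m <- global_moran(x, W, n_perm = 10000L, seed = 7L)
  expect_lt(abs(m$perm_var - m$variance) / m$variance, 0.05)
  expect_true(m$p_perm >= 0 && m$p_perm <= 1)
})

test_that("quadrant classification is a partition with sign-flip symmetry", {
  W <- rook29_weights()
  x <- load_fixture("table1_efficiency")[, "2012"]
  q <- moran_quadrants(x, W)
  expect_setequal(unique(q$quadrant), c("HH", "LL", "LH", "HL"))
  expect_equal(nrow(q), 29L)
  qn <- moran_quadrants(-x, W)
  map <- c(HH = "LL", LL = "HH", LH = "HL", HL = "LH")
  expect_identical(unname(map[q$quadrant]), qn$quadrant)
  expect_equal(attr(q, "share_agglomeration"),
               attr(qn, "share_agglomeration"))
})

test_that("a lone high unit among low neighbours is classified HL", {
  W <- ring_weights(4)
  q <- moran_quadrants(c(10, 1, 1, 1), W)
  expect_identical(q$quadrant[1], "HL")
  expect_identical(q$quadrant[3], "LL")  # opposite unit: low with low lag
})

test_that("strongly autocorrelated fields concentrate in HH and LL", {
  W <- rook29_weights()
  A <- solve(diag(29) - 0.6 * W$row_standardized)
  set.seed(55)
  shares <- replicate(20, {
    y <- as.vector(A %*% rnorm(29))
    attr(moran_quadrants(y, W), "share_agglomeration")
  })
  expect_gte(median(shares), 0.5)
})

test_that("cluster tables partition units per year and are deterministic", {
  W <- ring_weights(4)
  a1 <- moran_quadrants(c(5, 4, -3, -6), W)
  tab <- cluster_table(list(`2012` = a1, `2013` = a1))
  expect_equal(sum(tab$count[tab$year == "2012"]), 4L)
  expect_identical(tab[tab$year == "2012", -1], tab[tab$year == "2013", -1],
                   ignore_attr = TRUE)
  expect_error(cluster_table(list()), "no assignments")
})

test_that("yearly Moran tables cover every column of a score panel", {
  W <- rook29_weights()
  t1 <- load_fixture("table1_efficiency")
  tab <- moran_by_year(t1, W)
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$year, colnames(t1))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
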