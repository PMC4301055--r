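test_that("classification functions match a brute-force matrix-algebra oracle", {
  d <- toy_3group()
  m <- fit_dfa(d, vars = c("v1", "v2", "v3"))
  ## independent oracle: explicit per-group evaluation of the classification
  ## function formula from scratch
  X <- as.matrix(d[, c("v1", "v2", "v3")])
  g <- factor(d$individual_id)
  k <- nlevels(g); p <- ncol(X)
  W <- matrix(0, p, p)
  for (lev in levels(g)) {
    sub <- X[g == lev, , drop = FALSE]
    cs <- sweep(sub, 2, colMeans(sub))
    W <- W + t(cs) %*% cs
  }
  W <- W / (nrow(X) - k)
  for (i in seq_len(k)) {
    mu <- colMeans(X[g == levels(g)[i], , drop = FALSE])
    coef_i <- solve(W, mu)
    const_i <- -0.5 * sum(mu * coef_i) + log(1 / k)
    expect_equal(unname(m$coef[i, ]), unname(coef_i), tolerance = 1e-8)
    expect_equal(unname(m$const[i]), unname(const_i), tolerance = 1e-8)
  }
})

test_that("classification agrees with an independent reference implementation", {
  d <- toy_3group()
  m <- fit_dfa(d, vars = c("v1", "v2", "v3"))
  cl <- classify(m, d)
  ref <- MASS::lda(individual_id ~ v1 + v2 + v3, d, prior = rep(1 / 3, 3))
  expect_identical(as.character(cl$assigned),
                   as.character(predict(ref, d)$class))
})

test_that("perfectly separated clusters classify at 100% and degenerate designs error", {
  set.seed(60)
  d <- data.frame(individual_id = rep(c("a", "b"), each = 10),
                  x = c(rnorm(10), rnorm(10) + 50),
                  y = rnorm(20))
  m <- fit_dfa(d, vars = c("x", "y"))
  cl <- classify(m, d)
  expect_equal(cl$average_pct, 100)
  expect_equal(sum(cl$confusion), 20)
  expect_error(fit_dfa(d[d$individual_id == "a", ], vars = c("x", "y")),
               "two groups")
  d1 <- d; d1$individual_id[1] <- "c"
  expect_error(fit_dfa(d1, vars = c("x", "y")), "at least 2 rows")
})

test_that("collinear variables produce a named singularity error", {
  d <- toy_3group()
  d$v4 <- d$v1
  expect_error(fit_dfa(d, vars = c("v1", "v2", "v4")), "collinear")
  expect_error(wilks_contributions(d, vars = c("v1", "v2", "v4")), "collinear")
})

test_that("classification results are invariant under invertible affine maps", {
  d <- toy_3group()
  set.seed(61)
  A <- matrix(rnorm(9), 3, 3) + diag(3) * 2
  b <- rnorm(3)
  d2 <- d
  d2[, c("v1", "v2", "v3")] <-
    as.matrix(d[, c("v1", "v2", "v3")]) %*% A +
    matrix(b, nrow(d), 3, byrow = TRUE)
  cl1 <- classify(fit_dfa(d, vars = c("v1", "v2", "v3")), d)
  cl2 <- classify(fit_dfa(d2, vars = c("v1", "v2", "v3")), d2)
  expect_identical(as.character(cl1$assigned), as.character(cl2$assigned))
  expect_equal(cl1$average_pct, cl2$average_pct, tolerance = 1e-8)
})

test_that("leave-one-out classification works and is below resubstitution on noise", {
  set.seed(62)
  d <- data.frame(individual_id = rep(letters[1:4], each = 8),
                  matrix(rnorm(32 * 5), 32, 5))
  names(d)[2:6] <- paste0("v", 1:5)
  resub <- classify(fit_dfa(d, vars = paste0("v", 1:5)), d)
  loo <- classify_loo(d, vars = paste0("v", 1:5))
  expect_equal(sum(loo$confusion), 32)
  expect_lt(loo$average_pct, resub$average_pct)  # overfitting gap on noise
})

test_that("partial Wilks' lambda isolates the informative variable", {
  set.seed(63)
  g <- rep(1:4, each = 10)
  d <- data.frame(individual_id = sprintf("id%d", g))
  for (j in 1:6) d[[paste0("v", j)]] <- rnorm(40)
  d$v3 <- d$v3 + g  # planted group effect
  wc <- wilks_contributions(d, vars = paste0("v", 1:6))
  expect_equal(wc$variable[which.min(wc$lambda)], "v3")
  expect_true(all(wc$lambda > 0 & wc$lambda <= 1))
  ## noise variables contribute almost nothing
  expect_gt(min(wc$lambda[wc$variable != "v3"]), 0.7)
  ## smaller lambda <-> larger F (monotone relationship)
  expect_equal(order(wc$lambda), order(wc$F, decreasing = TRUE))
})

test_that("partial Wilks' F for a single variable equals the one-way ANOVA F", {
  d <- toy_3group()
  wc <- wilks_contributions(d, vars = "v1")
  a <- one_way_anova(d$v1, d$individual_id)
  expect_equal(wc$F, a$F, tolerance = 1e-10)
})

test_that("permutation null is seeded, bounded, and shrinks with group size", {
  tab <- gaussian_null_table(rep(5, 6), 4, seed = 64)
  n1 <- permutation_null(tab, vars = sprintf("var%02d", 1:4), n_perm = 60, seed = 65)
  n2 <- permutation_null(tab, vars = sprintf("var%02d", 1:4), n_perm = 60, seed = 65)
  expect_identical(n1$samples, n2$samples)
  expect_length(n1$samples, 60)
  expect_true(all(n1$samples >= 0 & n1$samples <= 100))
  expect_equal(n1$mean, mean(n1$samples))
  expect_gte(n1$mean, 100 / 6)  # resubstitution overfitting floor
  ## larger per-group n -> less overfitting -> null mean closer to 100/k
  tab_big <- gaussian_null_table(rep(40, 6), 4, seed = 66)
  n_big <- permutation_null(tab_big, vars = sprintf("var%02d", 1:4), n_perm = 60, seed = 67)
  expect_lt(n_big$mean, n1$mean)
  expect_error(permutation_null(tab, vars = sprintf("var%02d", 1:4), n_perm = 0), "at least 1")
})

test_that("significance categories follow the one-sided percentile rule", {
  null <- structure(list(samples = as.numeric(1:1000)),
                    class = "permutation_null")
  expect_equal(significance(1001, null), "p < 0.001")
  expect_equal(significance(500.5, null), "n.s.")
  expect_equal(significance(960.5, null), "p < 0.05")   # above 96%, below 99%
  expect_equal(significance(995.5, null), "p < 0.01")
  expect_equal(significance(999.5, null), "p < 0.001")  # exceeds 99.9% of samples
})
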