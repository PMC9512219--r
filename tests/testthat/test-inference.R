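test_that("permutation plans are reproducible and valid", {
  p1 <- permutation_plan(3, B = 2, seed = 7)
  p2 <- permutation_plan(3, B = 2, seed = 7)
  expect_identical(p1$perms, p2$perms)
  ex <- permutation_plan(4, seed = 1, exhaustive = TRUE)
  expect_equal(ex$B, 24)
  expect_equal(nrow(unique(ex$perms)), 24)
  big <- permutation_plan(10, B = 50, seed = 2)
  expect_true(all(apply(big$perms, 1, function(v) identical(sort(v), 1:10))))
})

test_that("orthonormal bases span the covariates", {
  b <- orthonormal_basis(matrix(c(1, -1, 0), ncol = 1))
  expect_equal(abs(as.numeric(b)), abs(c(1, -1, 0) / sqrt(2)))
  X <- matrix(rnorm(40), 10, 4)
  B <- orthonormal_basis(X)
  expect_equal(crossprod(B), diag(4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(Bd <- orthonormal_basis(cbind(X[, 1], X[, 1])), "rank")
  expect_equal(ncol(Bd), 1)
  expect_equal(ncol(orthonormal_basis(NULL, n = 5)), 0)
})

test_that("covariate adjustment projects and normalizes", {
  X <- center_covariates(matrix(rnorm(20), 10, 2))
  b <- orthonormal_basis(X)
  v <- rnorm(10); v <- v - mean(v)
  v_perp <- v - b %*% crossprod(b, v)
  a <- adjust_vector(as.numeric(v_perp), b)
  expect_equal(as.numeric(a), as.numeric(v_perp / sqrt(sum(v_perp^2))),
               tolerance = 1e-12)
  # a vector in the covariate span is degenerate
  z <- adjust_vector(as.numeric(X %*% c(1, 2)), b)
  expect_true(attr(z, "degenerate"))
  expect_equal(as.numeric(z), rep(0, 10))
  # Martingale residuals are already orthogonal to their fit covariates
  d <- make_surv_data(n = 50, seed = 4, p = 2)
  fit <- fit_cox(d$time, d$event, d$X)
  M <- martingale_residuals(fit)
  bX <- orthonormal_basis(center_covariates(d$X))
  expect_equal(as.numeric(adjust_vector(M, bX, normalize = FALSE)), M,
               tolerance = 1e-6)
})

test_that("rank p-values follow the add-one convention", {
  expect_equal(rank_pvalue(100, 1:99), 1 / 100)
  expect_equal(rank_pvalue(0, 1:99), 1)
  expect_equal(rank_pvalue(5, 1:9), 0.6)  # ties count as >= observed
})

test_that("exhaustive rank p-values are uniform under relabeling", {
  set.seed(1)
  r <- rnorm(4)
  z <- rnorm(4)
  perms <- permutation_plan(4, exhaustive = TRUE)$perms
  stat <- function(v) sum(v * z)^2
  nulls <- apply(perms, 1, function(idx) stat(r[idx]))
  pvals <- vapply(nulls, function(o) rank_pvalue(o, nulls), numeric(1))
  expect_equal(sort(pvals), (2:25) / 25)
})

test_that("min-p combination matches brute-force enumeration", {
  obs <- c(5, 0)
  nulls <- cbind(c(1, 2, 3), c(9, 8, 7))
  res <- minp_combine(obs, nulls)
  expect_equal(res$component_p, c(0.25, 1))
  expect_equal(res$observed_min, 0.25)
  expect_equal(res$p, 0.25)
  expect_equal(res$p, oracle_minp(obs, nulls))
  set.seed(5)
  for (i in 1:20) {
    C <- sample(2:4, 1)
    nn <- matrix(rnorm(12 * C), 12, C)
    oo <- rnorm(C)
    expect_equal(minp_combine(oo, nn)$p, oracle_minp(oo, nn))
  }
})

test_that("min-p combination is label-invariant and monotone", {
  set.seed(2)
  nulls <- matrix(rnorm(300), 100, 3)
  obs <- rnorm(3)
  p1 <- minp_combine(obs, nulls)$p
  perm <- c(3, 1, 2)
  expect_equal(minp_combine(obs[perm], nulls[, perm])$p, p1)
  # improving one observed statistic never increases the combined p
  for (i in 1:20) {
    better <- obs
    idx <- sample(3, 1)
    better[idx] <- better[idx] + abs(rnorm(1))
    expect_lte(minp_combine(better, nulls)$p, p1 + 1e-12)
  }
  # duplicated identical components change nothing beyond one rank unit
  one <- minp_combine(obs[1], nulls[, 1, drop = FALSE])$p
  two <- minp_combine(obs[c(1, 1)], nulls[, c(1, 1)])$p
  expect_lt(abs(one - two), 1 / 101 + 1e-12)
})

test_that("combined p-values are uniform under the null", {
  set.seed(11)
  B <- 1000
  ps <- vapply(1:400, function(i) {
    nulls <- matrix(rnorm(B * 2), B, 2)
    minp_combine(rnorm(2), nulls)$p
  }, numeric(1))
  # p-values are discrete (multiples of 1/(B+1)); ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Benjamini-Hochberg adjustment and detection", {
  res <- bh_adjust(c(0.01, 0.02, 0.2), q = 0.10)
  expect_equal(res$adjusted, c(0.03, 0.03, 0.2))
  expect_equal(res$detected, c(TRUE, TRUE, FALSE))
  expect_false(any(bh_adjust(rep(1, 5), 0.10)$detected))
  expect_equal(bh_adjust(0.03, 0.1)$adjusted, 0.03)
})
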