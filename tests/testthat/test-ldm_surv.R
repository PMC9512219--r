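test_that("LDM statistics reduce to hand computations", {
  # orthogonal regressor and taxon: U = 0, F = 0
  r <- c(0.5, 0.5, -0.5, -0.5)
  z <- matrix(c(1, -1, 1, -1), ncol = 1)
  st <- ldm_statistics(center_columns(z), orthonormal_basis(NULL, n = 4), r)
  expect_equal(st$U, 0)
  expect_equal(st$F_taxon, 0)
  # all-zero taxa give zero statistics
  st0 <- ldm_statistics(matrix(0, 4, 3), orthonormal_basis(NULL, n = 4), r)
  expect_equal(st0$U, rep(0, 3))
  expect_equal(st0$F_global, 0)
})

test_that("global numerator equals the linear-kernel score statistic", {
  set.seed(21)
  n <- 30; J <- 12
  Z <- center_columns(matrix(rnorm(n * J), n, J))
  d <- make_surv_data(n, seed = 3, p = 0 + 1)
  fit <- fit_cox(d$time, d$event, NULL)
  M <- martingale_residuals(fit)
  st <- ldm_statistics(Z, orthonormal_basis(NULL, n = n), M)
  # sum U_j^2 with the normalized regressor, rescaled by |M|^2, is M'ZZ'M
  expect_equal(sum(st$U^2) * sum((M - mean(M))^2),
               mirkat_score(Z %*% t(Z), M - mean(M)),
               tolerance = 1e-8)
})

test_that("LDM F statistics match an lm() decomposition oracle", {
  set.seed(31)
  n <- 20; J <- 4
  X <- center_covariates(matrix(rnorm(2 * n), n, 2))
  Z <- center_columns(matrix(rnorm(n * J), n, J))
  r <- rnorm(n); r <- r - mean(r)
  st <- ldm_statistics(Z, orthonormal_basis(X), r)
  orc <- oracle_ldm_F(Z, X, r)
  expect_equal(st$F_taxon, orc$F_taxon, tolerance = 1e-8)
  expect_equal(st$F_global, orc$F_global, tolerance = 1e-8)
})

test_that("exhaustive permutation p-values match brute-force enumeration", {
  set.seed(41)
  n <- 4; J <- 2
  Z <- center_columns(matrix(rnorm(n * J), n, J))
  r <- rnorm(n); r <- r - mean(r)
  plan <- permutation_plan(n, exhaustive = TRUE)
  res <- ldm_test(Z, NULL, r, plan)
  # oracle: recompute every relabeling's F with lm()
  enum_global <- oracle_enum_pvalue(
    function(v) oracle_ldm_F(Z, NULL, v)$F_global, r, plan$perms)
  expect_equal(res$global$p, enum_global)
  for (j in 1:J) {
    enum_j <- oracle_enum_pvalue(
      function(v) oracle_ldm_F(Z[, j, drop = FALSE], NULL, v)$F_taxon, r,
      plan$perms)
    expect_equal(res$taxa$p[j], enum_j)
  }
  # with covariates (n = 5, 120 permutations)
  n <- 5
  X <- center_covariates(matrix(rnorm(n), n, 1))
  Z5 <- center_columns(matrix(rnorm(n * J), n, J))
  r5 <- rnorm(n); r5 <- r5 - mean(r5)
  plan5 <- permutation_plan(n, exhaustive = TRUE)
  res5 <- ldm_test(Z5, X, r5, plan5)
  enum5 <- oracle_enum_pvalue(
    function(v) {
      b <- orthonormal_basis(X)
      va <- as.numeric(adjust_vector(v - mean(v), b, normalize = FALSE))
      oracle_ldm_F(Z5, X, va)$F_global
    }, r5, plan5$perms)
  expect_equal(res5$global$p, enum5)
})

test_that("p-values are invariant to the scale of the regressor", {
  set.seed(51)
  n <- 30; J <- 6
  Z <- center_columns(matrix(rnorm(n * J), n, J))
  r <- rnorm(n)
  plan <- permutation_plan(n, B = 200, seed = 5)
  a <- ldm_test(Z, NULL, r, plan)
  b <- ldm_test(Z, NULL, 7.3 * r, plan)
  expect_equal(a$global$p, b$global$p)
  expect_equal(a$taxa$p, b$taxa$p)
})

test_that("a regressor inside the covariate span is rejected", {
  X <- center_covariates(matrix(rnorm(20), 20, 1))
  Z <- center_columns(matrix(rnorm(60), 20, 3))
  plan <- permutation_plan(20, B = 10, seed = 1)
  expect_error(ldm_test(Z, X, as.numeric(X[, 1]), plan), "span")
})

test_that("degenerate taxa receive p = 1 and no detection", {
  set.seed(61)
  counts <- count_table(matrix(rpois(40, 5) + 1L, 10, 4))  # all-present taxa
  Z <- taxon_matrix(counts, "presence", center = TRUE)     # constant columns
  r <- rnorm(10)
  plan <- permutation_plan(10, B = 50, seed = 2)
  res <- ldm_test(Z, NULL, r, plan)
  expect_true(all(res$taxa$degenerate))
  expect_true(all(res$taxa$p == 1))
  expect_false(any(res$taxa$detected))
})

test_that("combining a component with itself changes nothing beyond a rank unit", {
  set.seed(71)
  n <- 24; J <- 5
  Z <- center_columns(matrix(rnorm(n * J), n, J))
  r <- rnorm(n)
  plan <- permutation_plan(n, B = 100, seed = 3)
  t1 <- ldm_test(Z, NULL, r, plan, label = "martingale")
  t2 <- ldm_test(Z, NULL, r, plan, label = "deviance")
  cmb <- combine_ldm_tests(list(t1, t2))
  expect_lt(abs(cmb$global$p - t1$global$p), 1 / 101 + 1e-12)
  expect_true(all(abs(cmb$taxa$p - t1$taxa$p) < 1 / 101 + 1e-12))
  # mismatched plans are refused
  plan_b <- permutation_plan(n, B = 100, seed = 4)
  t3 <- ldm_test(Z, NULL, r, plan_b)
  expect_error(combine_ldm_tests(list(t1, t3)), "share")
})

test_that("combined test matches enumeration of the min-p rule", {
  set.seed(81)
  n <- 4; J <- 2
  Z <- center_columns(matrix(rnorm(n * J), n, J))
  rM <- rnorm(n); rM <- rM - mean(rM)
  rD <- sign(rM) * sqrt(abs(rM)); rD <- rD - mean(rD)
  plan <- permutation_plan(n, exhaustive = TRUE)
  tM <- ldm_test(Z, NULL, rM, plan, label = "martingale")
  tD <- ldm_test(Z, NULL, rD, plan, label = "deviance")
  cmb <- combine_ldm_tests(list(tM, tD))
  statM <- apply(plan$perms, 1, function(i) oracle_ldm_F(Z, NULL, rM[i])$F_global)
  statD <- apply(plan$perms, 1, function(i) oracle_ldm_F(Z, NULL, rD[i])$F_global)
  p_enum <- oracle_minp(c(oracle_ldm_F(Z, NULL, rM)$F_global,
                          oracle_ldm_F(Z, NULL, rD)$F_global),
                        cbind(statM, statD))
  expect_equal(cmb$global$p, p_enum)
})

test_that("omnibus over a single scale is that scale's test", {
  set.seed(91)
  n <- 20; J <- 4
  Z <- center_columns(matrix(rnorm(n * J), n, J))
  r <- rnorm(n)
  plan <- permutation_plan(n, B = 100, seed = 9)
  t1 <- ldm_test(Z, NULL, r, plan)
  solo <- combine_ldm_tests(list(t1))
  expect_lt(abs(solo$global$p - t1$global$p), 1 / 101 + 1e-12)
})

test_that("the data-frame-first interface runs end to end", {
  design <- sim_design(sim_config(n = 40, J = 50, beta = 2, n_causal = 3,
                                  n_confounded = 10, beta_xz = 0.5),
                       seed = 5)
  rp <- simulate_replicate(design, seed = 6)
  md <- data.frame(time = rp$time, event = rp$event, x = rp$x)
  fit <- ldm_surv(rp$counts, md, "time", "event", covariates = "x",
                  n_perm = 100, seed = 7)
  g <- glance(fit)
  expect_s3_class(g, "tbl_df")
  expect_true(all(g$p_combined >= 1 / 101 & g$p_combined <= 1))
  td <- tidy(fit)
  expect_true(all(c("component", "taxon", "p") %in% names(td)))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_residuals(fit), "ggplot")
})
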