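test_that("pseudo-F on a single-column Euclidean distance is the regression F", {
  set.seed(12)
  n <- 15
  z <- rnorm(n); z <- z - mean(z)
  D <- as.matrix(dist(z))
  r <- rnorm(n)
  plan <- permutation_plan(n, B = 50, seed = 1)
  res <- permanova_fl_test(D, NULL, r, plan)
  rt <- (r - mean(r)) / sqrt(sum((r - mean(r))^2))
  f_lm <- summary(lm(z ~ rt))$fstatistic[["value"]]
  expect_equal(res$global$statistic, f_lm, tolerance = 1e-8)
})

test_that("kernel score statistic follows its quadratic form", {
  K <- matrix(c(2, -1, -1, -1, 2, -1, -1, -1, 2), 3, 3)
  r <- c(1, 0, -1)
  expect_equal(mirkat_score(K, r), 2 + 2 + 2 * 1, tolerance = 1e-12)
  expect_equal(mirkat_score(K, rep(0, 3)), 0)
})

test_that("distance tests match exhaustive enumeration", {
  set.seed(22)
  n <- 4
  Z <- structure(matrix(runif(n * 3), n, 3), scale = NULL, centered = FALSE)
  D <- distance_matrix(Z, "euclidean")
  G <- gower_center(D)
  r <- rnorm(n); r <- r - mean(r)
  plan <- permutation_plan(n, exhaustive = TRUE)
  # permanovaFL: oracle recomputes the pseudo-F from scratch per relabeling
  res_p <- permanova_fl_test(D, NULL, r, plan)
  orc_stat <- function(v) {
    vc <- v - mean(v); vt <- vc / sqrt(sum(vc^2))
    q <- as.numeric(t(vt) %*% G %*% vt)
    q / ((sum(diag(G)) - q) / (n - 2))
  }
  expect_equal(res_p$global$p, oracle_enum_pvalue(orc_stat, r, plan$perms))
  # MiRKAT-S: quadratic form of the raw permuted residual
  res_m <- mirkat_s_test(G, r, plan)
  orc_q <- function(v) as.numeric(t(v) %*% G %*% v)
  expect_equal(res_m$global$p, oracle_enum_pvalue(orc_q, r, plan$perms))
  # adjusted variant with covariates
  X <- center_covariates(matrix(rnorm(n), n, 1))
  res_a <- mirkat_adjusted_test(G, X, r, plan)
  orc_adj <- function(v) {
    b <- orthonormal_basis(X)
    vt <- adjust_vector(v - mean(v), b)
    as.numeric(t(vt) %*% G %*% vt)
  }
  expect_equal(res_a$global$p, oracle_enum_pvalue(orc_adj, r, plan$perms))
})

test_that("adjusted kernel test reduces to MiRKAT-S when X is empty", {
  set.seed(32)
  n <- 18
  Z <- center_columns(matrix(rnorm(n * 5), n, 5))
  G <- Z %*% t(Z)
  M <- rnorm(n); M <- M - mean(M)
  plan <- permutation_plan(n, B = 200, seed = 2)
  expect_equal(mirkat_adjusted_test(G, NULL, M, plan)$global$p,
               mirkat_s_test(G, M, plan)$global$p)
})

test_that("Euclidean permanovaFL and the LDM global test agree on shared plans", {
  set.seed(42)
  for (i in 1:5) {
    n <- 16; J <- 4
    Z <- center_columns(matrix(rnorm(n * J), n, J))
    X <- center_covariates(matrix(rnorm(n), n, 1))
    r <- rnorm(n)
    plan <- permutation_plan(n, B = 300, seed = i)
    p_ldm <- ldm_test(Z, X, r, plan)$global$p
    p_prm <- permanova_fl_test(as.matrix(dist(Z)), X, r, plan)$global$p
    expect_equal(p_ldm, p_prm)
  }
})

test_that("combined distance tests behave like their components in degenerate cases", {
  set.seed(52)
  n <- 14
  Z <- center_columns(matrix(rnorm(n * 4), n, 4))
  G <- Z %*% t(Z)
  r <- rnorm(n)
  plan <- permutation_plan(n, B = 100, seed = 3)
  t1 <- mirkat_adjusted_test(G, NULL, r, plan, label = "martingale")
  expect_lt(abs(combine_dist_tests(list(t1))$p - t1$global$p), 1 / 101 + 1e-12)
  dup <- combine_dist_tests(list(t1, t1))
  expect_lt(abs(dup$p - t1$global$p), 1 / 101 + 1e-12)
  t2 <- mirkat_adjusted_test(G, NULL, r, permutation_plan(n, B = 100, seed = 9))
  expect_error(combine_dist_tests(list(t1, t2)), "share")
})

test_that("the distance-based interface runs end to end", {
  design <- sim_design(sim_config(n = 40, J = 50, beta = 2, n_causal = 3,
                                  n_confounded = 10, beta_xz = 0.5),
                       seed = 5)
  rp <- simulate_replicate(design, seed = 6)
  md <- data.frame(time = rp$time, event = rp$event, x = rp$x)
  fit <- dist_surv(rp$counts, md, covariates = "x", metric = "bray-curtis",
                   n_perm = 100, seed = 7)
  g <- glance(fit)
  expect_true(all(c("p_martingale", "p_deviance", "p_combined") %in% names(g)))
  expect_true(g$p_combined >= 1 / 101 && g$p_combined <= 1)
})
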