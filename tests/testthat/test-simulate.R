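test_that("baseline profiles are normalized and sorted", {
  expect_equal(make_baseline(4, gamma = 1),
               (1 / 1:4) / sum(1 / 1:4), tolerance = 1e-12)
  expect_equal(make_baseline(4, gamma = 1),
               c(0.48, 0.24, 0.16, 0.12), tolerance = 1e-12)
  p <- make_baseline(J = NULL, frequencies = c(0.2, 0.5, 0.1))
  expect_equal(p, c(0.5, 0.2, 0.1) / 0.8, tolerance = 1e-12)
  expect_equal(sum(make_baseline(200, 1.4)), 1, tolerance = 1e-12)
  expect_error(make_baseline(3, frequencies = c(0.5, 0, 0.5)), "positive")
})

test_that("confounded profiles permute frequencies within the selected set", {
  pi1 <- make_baseline(50, 1.4)
  expect_equal(as.numeric(make_confounded_pair(pi1, 0, seed = 1)), pi1)
  for (seed in 1:10) {
    pi2 <- make_confounded_pair(pi1, 20, seed = seed)
    sel <- attr(pi2, "confounded_set")
    expect_length(sel, 20)
    expect_equal(sort(pi2[sel]), sort(pi1[sel]))        # multiset conserved
    expect_equal(as.numeric(pi2[-sel]), pi1[-sel])      # untouched outside
    expect_equal(sum(pi2), 1, tolerance = 1e-12)
  }
})

test_that("subject frequencies interpolate between the two profiles", {
  pi1 <- c(0.6, 0.3, 0.1)
  pi2 <- c(0.3, 0.6, 0.1)
  f <- subject_frequencies(pi1, pi2, beta_xz = 0.8, x = c(0, 1))
  expect_equal(f[1, ], pi1)
  expect_equal(f[2, ], 0.2 * pi1 + 0.8 * pi2)
  expect_equal(subject_frequencies(pi1, pi2, 0, c(1, 1))[1, ], pi1)
  expect_equal(subject_frequencies(pi1, pi2, 1, c(0, 1))[2, ], pi2)
  expect_equal(rowSums(f), c(1, 1), tolerance = 1e-12)
})

test_that("count draws respect the DM mean and library-size law", {
  # degenerate composition puts every read on taxon 1
  f1 <- matrix(rep(c(1, 0, 0), each = 2), 2, 3)
  ct <- draw_counts(f1, theta = 0, seed = 1)
  expect_equal(unname(unclass(ct)[, 2:3]), matrix(0L, 2, 2))
  # DM mean identity over many subjects
  pi_t <- c(0.5, 0.3, 0.15, 0.05)
  fm <- matrix(rep(pi_t, each = 3000), 3000, 4)
  ct2 <- draw_counts(fm, theta = 0.02, lib_mean = 2000, lib_sd = 300,
                     lib_min = 500, seed = 2)
  freq <- sweep(unclass(ct2), 1, library_sizes(ct2), "/")
  se <- apply(freq, 2, sd) / sqrt(3000)
  expect_true(all(abs(colMeans(freq) - pi_t) < 3 * se + 1e-4))
  # library sizes: truncated-normal mean, hard floor
  lib <- library_sizes(draw_counts(fm[1:1000, ], theta = 0, seed = 3))
  expect_gt(min(lib), 999)
  expect_lt(abs(mean(lib) - 10000), 3 * 10000 / 3 / sqrt(1000) + 50)
})

test_that("causal scores follow their defining formulas", {
  ct <- count_table(rbind(s1 = c(2L, 2L, 6L), s2 = c(4L, 0L, 6L),
                          s3 = c(0L, 4L, 6L)))
  # M2: signed presence
  s2 <- causal_score(ct, "M2", causal_set = c(1, 2), delta = c(1, -1))
  expect_equal(as.numeric(s2), c(0, 1, -1))
  # subject with none of A present scores 0
  expect_equal(as.numeric(causal_score(ct, "M2", 2, delta = 1))[2], 0)
  # M1: frequency over mean frequency (all library sizes are 10)
  z <- unclass(ct) / 10
  zbar <- colMeans(z)
  s1 <- causal_score(ct, "M1", causal_set = c(1, 2), delta = c(1, -1))
  expect_equal(as.numeric(s1), as.numeric(z[, 1] / zbar[1] - z[, 2] / zbar[2]))
  # identical subjects make M1 scores constant
  ct_const <- count_table(rbind(a = c(3L, 7L), b = c(3L, 7L)))
  expect_equal(as.numeric(causal_score(ct_const, "M1", 1:2, c(1, 1))),
               rep(2, 2))
})

test_that("Cox-Weibull event times have the closed-form median", {
  set.seed(3)
  x <- rep(c(0, 1), each = 50000)
  s <- draw_survival(rnorm(1e5), x, beta = 0, beta_xs = 0,
                     censor_rate = 0, seed = 4)
  expect_equal(stats::median(s$time), 10 * sqrt(log(2)), tolerance = 0.01)
  expect_true(all(s$event == 1))  # no censoring at mu = 0
  expect_error(draw_survival(rnorm(4), c(0, 0, 1, 1), censor_rate = -1),
               ">= 0")
})

test_that("a constant causal score contributes nothing, with a warning", {
  expect_warning(
    s <- draw_survival(rep(1, 40), rep(c(0, 1), 20), beta = 2,
                       censor_rate = 0, seed = 5),
    "constant"
  )
  expect_equal(nrow(s), 40)
})

test_that("accelerated-hazards survival curves cross", {
  tgrid <- seq(0.05, 5, length.out = 200)
  gap <- ah_survival(tgrid, exp(1)) - ah_survival(tgrid, exp(-1))
  expect_true(any(gap > 0) && any(gap < 0))  # sign change = crossing curves
  # empirical law matches the closed form
  set.seed(6)
  x <- rep(c(0, 1), each = 2000)
  s <- draw_survival(rep(0, 4000), x, beta = 0, beta_xs = 0, censor_rate = 0,
                     hazard = "ah-lognormal", seed = 7)
  expect_equal(mean(s$time > 1), ah_survival(1, 1), tolerance = 0.03)
})

test_that("replicates are reproducible and the design is fixed across them", {
  cfg <- sim_config(n = 20, J = 30, n_confounded = 10, n_causal = 3, beta = 1)
  des <- sim_design(cfg, seed = 9)
  r1 <- simulate_replicate(des, seed = 11)
  r2 <- simulate_replicate(des, seed = 11)
  expect_identical(unclass(r1$counts)[, ], unclass(r2$counts)[, ])
  expect_identical(r1$time, r2$time)
  r3 <- simulate_replicate(des, seed = 12)
  expect_false(identical(r1$time, r3$time))
  expect_identical(r1$truth$causal_set, r3$truth$causal_set)
  expect_equal(sum(r1$x), 10)  # balanced groups
})

test_that("confounding shifts group means only for the confounded taxa", {
  cfg <- sim_config(n = 2000, J = 40, n_confounded = 15, beta_xz = 0.8,
                    model = "M1", n_causal = 2)
  des <- sim_design(cfg, seed = 13)
  rp <- simulate_replicate(des, seed = 14)
  Z <- taxon_matrix(rp$counts, "relabund")
  diff <- colMeans(Z[rp$x == 1, ]) - colMeans(Z[rp$x == 0, ])
  sel <- des$confounded_set
  moved <- abs(des$pi2 - des$pi1) > 1e-4  # taxa whose frequency truly changed
  expect_true(any(abs(diff[sel][moved[sel]]) > 0.8 * 0.5 *
                    abs(des$pi2 - des$pi1)[sel][moved[sel]]))
  se_null <- apply(Z[, -sel, drop = FALSE], 2, sd) / sqrt(1000)
  expect_true(all(abs(diff[-sel]) < 5 * se_null * sqrt(2)))
})

test_that("AH censoring at mu = 0.5 is near one half", {
  set.seed(15)
  cf <- replicate(200, {
    x <- rep(c(0, 1), each = 50)
    s <- draw_survival(rnorm(100), x, beta = 0.5, beta_xs = 0.5,
                       hazard = "ah-lognormal", censor_rate = 0.5)
    mean(s$event == 0)
  })
  expect_lt(abs(mean(cf) - 0.5), 0.08)
})
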