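# Independent oracles used to cross-check the package implementation.
# These deliberately use different computational routes (naive loops, lm()
# decompositions, explicit Newton iterations) from the package internals.

# Hand-coded Breslow partial-likelihood Newton fit + Martingale residuals.
# Assumes continuous (tie-free) event times; small n only.
oracle_cox_breslow <- function(time, event, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  for (iter in 1:100) {
    w <- exp(drop(X %*% beta))
    score <- rep(0, p)
    info <- matrix(0, p, p)
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      sw <- sum(w[risk])
      xbar <- colSums(X[risk, , drop = FALSE] * w[risk]) / sw
      score <- score + X[i, ] - xbar
      xx <- t(X[risk, , drop = FALSE] * w[risk]) %*% X[risk, , drop = FALSE] / sw
      info <- info + xx - outer(xbar, xbar)
    }
    step <- solve(info, score)
    beta <- beta + step
    if (sum(abs(step)) < 1e-12) break
  }
  w <- exp(drop(X %*% beta))
  cumhaz <- vapply(time, function(t) {
    ev <- which(event == 1 & time <= t)
    sum(vapply(ev, function(i) 1 / sum(w[time >= time[i]]), numeric(1)))
  }, numeric(1))
  list(beta = beta, martingale = event - cumhaz * w)
}

# F statistics of the LDM linear model via lm() sum-of-squares decomposition.
oracle_ldm_F <- function(Z, X, r) {
  Z <- as.matrix(Z)
  ssr <- sse <- numeric(ncol(Z))
  for (j in seq_len(ncol(Z))) {
    z <- Z[, j]
    if (is.null(X) || ncol(as.matrix(X)) == 0) {
      f0 <- stats::lm(z ~ 1)
      f1 <- stats::lm(z ~ r)
    } else {
      f0 <- stats::lm(z ~ X)
      f1 <- stats::lm(z ~ X + r)
    }
    ssr[j] <- sum(stats::residuals(f0)^2) - sum(stats::residuals(f1)^2)
    sse[j] <- sum(stats::residuals(f1)^2)
  }
  list(F_taxon = ssr / sse, F_global = sum(ssr) / sum(sse))
}

# Exhaustive-permutation p-value of a statistic function applied to every
# relabeling of r (including the identity among the nulls, add-one rule).
oracle_enum_pvalue <- function(stat_fn, r, perms) {
  obs <- stat_fn(r)
  nulls <- apply(perms, 1, function(idx) stat_fn(r[idx]))
  (1 + sum(nulls >= obs)) / (length(nulls) + 1)
}

# Literal implementation of the min-p combination rule with loops.
oracle_minp <- function(observed, nulls) {
  B <- nrow(nulls)
  C <- ncol(nulls)
  comp_p <- numeric(C)
  for (c in seq_len(C)) comp_p[c] <- (1 + sum(nulls[, c] >= observed[c])) / (B + 1)
  t_obs <- min(comp_p)
  t_null <- numeric(B)
  for (b in seq_len(B)) {
    pcs <- numeric(C)
    for (c in seq_len(C)) {
      pcs[c] <- (1 + sum(nulls[-b, c] >= nulls[b, c])) / B
    }
    t_null[b] <- min(pcs)
  }
  (1 + sum(t_null <= t_obs)) / (B + 1)
}

# Small simulated dataset for residual identity checks.
make_surv_data <- function(n, seed, p = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  time <- stats::rexp(n, rate = exp(0.5 * X[, 1]))
  cens <- stats::rexp(n, rate = 0.5)
  list(time = pmin(time, cens) + 1e-9, event = as.numeric(time <= cens), X = X)
}

tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
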