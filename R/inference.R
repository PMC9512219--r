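#' Permutation plan shared across component tests
#'
#' Draws `B` uniformly random permutations of `1..n` from a seed (or, with
#' `exhaustive = TRUE`, enumerates all `n!`).  Tests that will later be
#' combined with [minp_combine()] must be run on the *same* plan so that
#' their null statistic streams are comparable permutation by permutation.
#'
#' @param n Number of samples (>= 2).
#' @param B Number of permutations (ignored when `exhaustive`).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all `n!` permutations (requires `n <= 8`).
#' @return A `permutation_plan`: list with `n`, `B`, `seed`, `exhaustive`
#'   and the `B x n` integer matrix `perms`.
#' @export
permutation_plan <- function(n, B = 1000, seed = 1, exhaustive = FALSE) {
  stopifnot(n >= 2)
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
    perms <- .all_permutations(n)
    B <- nrow(perms)
  } else {
    stopifnot(B >= 1)
    set.seed(seed)
    perms <- matrix(0L, B, n)
    for (b in seq_len(B)) perms[b, ] <- sample.int(n)
  }
  structure(list(n = n, B = B, seed = seed, exhaustive = exhaustive,
                 perms = perms),
            class = "permutation_plan")
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' @export
print.permutation_plan <- function(x, ...) {
  cat(sprintf("<permutation_plan> n = %d, B = %d%s, seed = %d\n", x$n, x$B,
              if (x$exhaustive) " (exhaustive)" else "", x$seed))
  invisible(x)
}

.same_plan <- function(a, b) {
  identical(a$n, b$n) && identical(a$B, b$B) &&
    identical(a$seed, b$seed) && identical(a$exhaustive, b$exhaustive)
}

#' Orthonormal basis of the covariate column space
#'
#' @param X Centered covariate matrix (may have zero columns); rank-deficient
#'   input drops dependent columns with a warning.
#' @param n Number of samples, required when `X` is `NULL`.
#' @return An `n x p'` matrix with orthonormal columns spanning `col(X)`
#'   (zero columns when there are no covariates).
#' @export
orthonormal_basis <- function(X, n = NULL) {
  if (is.null(X) || ncol(as.matrix(X)) == 0) {
    if (is.null(n) && !is.null(X)) n <- nrow(as.matrix(X))
    if (is.null(n)) stop("`n` required when X is NULL", call. = FALSE)
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  X <- as.matrix(X)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    warning("rank-deficient covariates: dropping ", ncol(X) - qrx$rank,
            " dependent column(s)")
  }
  qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
}

#' Project out covariates (and optionally normalize)
#'
#' Returns `v - B B' v`, the component of `v` orthogonal to the covariate
#' space; with `normalize = TRUE` the result is scaled to unit Euclidean
#' norm.  A vector lying (numerically) in the covariate span is returned as
#' the zero vector with attribute `degenerate = TRUE`.
#'
#' @param v Centered numeric vector.
#' @param basis Output of [orthonormal_basis()].
#' @param normalize Scale the adjusted vector to unit norm?
#' @return The adjusted vector.
#' @export
adjust_vector <- function(v, basis, normalize = TRUE) {
  v <- as.numeric(v)
  if (ncol(basis) > 0) {
    v_adj <- v - basis %*% crossprod(basis, v)
    v_adj <- as.numeric(v_adj)
  } else {
    v_adj <- v
  }
  nrm <- sqrt(sum(v_adj^2))
  if (nrm < 1e-12 * max(1, sqrt(sum(v^2)))) {
    return(structure(rep(0, length(v)), degenerate = TRUE))
  }
  if (normalize) v_adj <- v_adj / nrm
  structure(v_adj, degenerate = FALSE)
}

# Permute r by each row of `perms`, re-project out the covariate basis, and
# normalize rows to unit norm.  Returns a B x n matrix (degenerate rows are
# all zero).  This is the Freedman-Lane-style scheme used by every
# covariate-adjusted permutation test in the package.
.permuted_regressors <- function(r, basis, perms, normalize = TRUE) {
  R <- matrix(r[perms], nrow(perms), ncol(perms))
  if (ncol(basis) > 0) {
    R <- R - (R %*% basis) %*% t(basis)
  }
  if (normalize) {
    nrm <- sqrt(rowSums(R^2))
    nrm[nrm < 1e-12] <- Inf
    R <- R / nrm
  }
  R
}

#' Permutation p-value by the rank rule
#'
#' `p = (1 + #[null >= observed]) / (B + 1)`: the add-one convention, so
#' p-values lie in `[1/(B+1), 1]` and are never zero.
#'
#' @param observed Observed statistic (larger = more extreme).
#' @param nulls Numeric vector of null statistics from permutations.
#' @return The permutation p-value.
#' @export
rank_pvalue <- function(observed, nulls) {
  (1 + sum(nulls >= observed - .tie_tol(observed))) / (length(nulls) + 1)
}

# Tie tolerance for observed-vs-null comparisons: permutations that
# reproduce the observed statistic exactly (e.g. the identity in an
# exhaustive plan) must count as ties even when the two values were reached
# by different floating-point routes.
.tie_tol <- function(observed) 1e-10 * (1 + abs(observed))

# Column-wise leave-self-in null p-value streams.
# For a column s of length B, p_b = #[b': s_b' >= s_b] / B, which equals the
# add-one leave-self-out count (1 + #[b' != b: s_b' >= s_b]) / B.
.null_pvalue_matrix <- function(nulls) {
  B <- nrow(nulls)
  apply(nulls, 2, function(s) (B - rank(s, ties.method = "min") + 1) / B)
}

#' Min-p combination of component permutation tests
#'
#' Combines component tests that were computed on one shared
#' [permutation_plan()].  The observed combination statistic is the minimum
#' of the component p-values; its null distribution is simulated by the
#' per-permutation minima of the components' null p-value streams (each null
#' statistic ranked within its own stream), and the combined p-value is the
#' rank of the observed minimum among those minima.
#'
#' @param observed Length-`C` vector of observed component statistics
#'   (larger = more extreme).
#' @param nulls `B x C` matrix of null statistics (column `c` from component
#'   `c`, row `b` from permutation `b` of the shared plan).
#' @return A list with `component_p` (length `C`), `observed_min`,
#'   `null_min` (length `B`) and the combined `p`.
#' @export
minp_combine <- function(observed, nulls) {
  nulls <- as.matrix(nulls)
  stopifnot(length(observed) == ncol(nulls))
  B <- nrow(nulls)
  component_p <- vapply(seq_along(observed),
                        function(c) rank_pvalue(observed[c], nulls[, c]),
                        numeric(1))
  t_obs <- min(component_p)
  null_p <- .null_pvalue_matrix(nulls)
  t_null <- do.call(pmin, as.data.frame(null_p))
  p <- (1 + sum(t_null <= t_obs + 1e-12)) / (B + 1)
  list(component_p = component_p, observed_min = t_obs,
       null_min = t_null, p = p)
}

# Vectorized min-p combination across J taxa.
# obs: C x J matrix of observed statistics; nulls: list of C matrices (B x J).
# Returns list(component_p = C x J, p = length-J combined p-values).
.minp_combine_columns <- function(obs, nulls) {
  C <- nrow(obs); J <- ncol(obs); B <- nrow(nulls[[1]])
  comp_p <- matrix(0, C, J)
  t_null <- NULL
  for (c in seq_len(C)) {
    ge <- colSums(nulls[[c]] >=
                    matrix(obs[c, ] - .tie_tol(obs[c, ]), B, J, byrow = TRUE))
    comp_p[c, ] <- (1 + ge) / (B + 1)
    pc <- .null_pvalue_matrix(nulls[[c]])
    t_null <- if (is.null(t_null)) pc else pmin(t_null, pc)
  }
  t_obs <- apply(comp_p, 2, min)
  p <- (1 + colSums(t_null <= matrix(t_obs + 1e-12, B, J, byrow = TRUE))) / (B + 1)
  list(component_p = comp_p, p = p)
}

#' Benjamini-Hochberg adjustment and detection
#'
#' @param p Vector of p-values.
#' @param q Nominal false discovery rate (default 0.10).
#' @return A list with `adjusted` (BH step-up adjusted p-values) and
#'   `detected` (logical, `adjusted <= q`).
#' @export
bh_adjust <- function(p, q = 0.10) {
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, detected = adjusted <= q)
}
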