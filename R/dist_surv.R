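#' PERMANOVA extension for survival outcomes (permanovaFL-surv)
#'
#' Global distance-based permutation test using a Cox-model residual as the
#' tested regressor alongside the covariates.  With `G` the Gower-centered
#' kernel of the distance matrix, `B_X` the orthonormal covariate basis and
#' `r~` the adjusted, normalized regressor, the pseudo-F statistic is
#' `(r~' G r~) / ((tr(G) - tr(H G H)) / (n - p - 2))` where `H` projects
#' onto `span(B_X, r~)`.  Permutations permute the regressor and
#' re-orthogonalize it against the covariates (the same scheme as
#' [ldm_test()]); this differs from classical PERMANOVA implementations and
#' is what preserves power under confounding.  Negative kernel eigenvalues
#' from semimetric distances (Bray-Curtis) are retained.
#'
#' @param D Distance matrix from [distance_matrix()] (or any square
#'   symmetric distance matrix).
#' @param X Centered covariate matrix or `NULL`.
#' @param r Residual regressor (centered internally).
#' @param plan A [permutation_plan()].
#' @param label Residual label for the result.
#' @return Object of class `dist_surv_test`: tibble `global`
#'   (`statistic`, `p`), null statistic stream, metric and residual labels.
#' @export
permanova_fl_test <- function(D, X = NULL, r, plan, label = "residual") {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(length(r) == n, plan$n == n)
  G <- gower_center(D)
  basis <- orthonormal_basis(X, n = n)
  p <- ncol(basis)
  if (n - p - 2 <= 0) stop("too few samples for the residual df (n - p - 2 <= 0)",
                           call. = FALSE)
  r <- r - mean(r)
  r_tilde <- adjust_vector(r, basis, normalize = TRUE)
  if (isTRUE(attr(r_tilde, "degenerate"))) {
    stop("regressor lies in the covariate span", call. = FALSE)
  }
  tr_G <- sum(diag(G))
  tr_BGB <- if (p > 0) sum(basis * (G %*% basis)) else 0
  df <- n - p - 2
  f_of_q <- function(q) q / ((tr_G - tr_BGB - q) / df)
  q_obs <- as.numeric(t(r_tilde) %*% G %*% r_tilde)
  Rt <- .permuted_regressors(r, basis, plan$perms)
  q_null <- rowSums((Rt %*% G) * Rt)
  stat_obs <- f_of_q(q_obs)
  stat_null <- f_of_q(q_null)
  structure(
    list(
      method = "permanovafl", label = label, metric = attr(D, "metric"),
      global = tibble::tibble(statistic = stat_obs,
                              p = rank_pvalue(stat_obs, stat_null)),
      null_global = stat_null,
      plan = plan[c("n", "B", "seed", "exhaustive")]
    ),
    class = "dist_surv_test"
  )
}

#' Kernel variance-component score statistic
#'
#' `Q = r' K r`.  With the linear kernel `K = Z Z'` of a centered taxon
#' matrix and `r` the Martingale residuals, `Q` equals the global LDM
#' numerator `sum_j (sum_i M_i Z_ij)^2`.
#'
#' @param K Kernel matrix (e.g. from [gower_center()]).
#' @param r Numeric vector.
#' @return The scalar score statistic.
#' @export
mirkat_score <- function(K, r) {
  as.numeric(t(r) %*% as.matrix(K) %*% r)
}

#' MiRKAT-S permutation test
#'
#' The kernel score test with the Martingale residual, permuting the
#' residual *directly* — without re-orthogonalizing against the covariates
#' inside permutations (covariates enter only through the Cox fit that
#' produced the residual).  This matches the published MiRKAT-S permutation
#' scheme and is what makes the test conservative when a covariate
#' confounds both the microbiome and survival.
#'
#' @param K Kernel matrix.
#' @param M Martingale residuals from the covariate-adjusted Cox fit.
#' @param plan A [permutation_plan()].
#' @return Object of class `dist_surv_test` with `Q` as the statistic.
#' @export
mirkat_s_test <- function(K, M, plan) {
  K <- as.matrix(K)
  n <- nrow(K)
  stopifnot(length(M) == n, plan$n == n)
  q_obs <- mirkat_score(K, M)
  Mp <- matrix(M[plan$perms], plan$B, n)
  q_null <- rowSums((Mp %*% K) * Mp)
  structure(
    list(
      method = "mirkat-s", label = "martingale", metric = attr(K, "metric"),
      global = tibble::tibble(statistic = q_obs,
                              p = rank_pvalue(q_obs, q_null)),
      null_global = q_null,
      plan = plan[c("n", "B", "seed", "exhaustive")]
    ),
    class = "dist_surv_test"
  )
}

#' Covariate-adjusted kernel score permutation test
#'
#' Variant of the kernel score test that regresses the covariates out of the
#' residual before computing `Q`, and re-adjusts inside every permutation
#' exactly like [permanova_fl_test()].  With no covariates it reduces to
#' [mirkat_s_test()] on the same plan.
#'
#' @param K Kernel matrix.
#' @param X Centered covariate matrix or `NULL`.
#' @param r Residual regressor (Martingale or deviance).
#' @param plan A [permutation_plan()].
#' @param label Residual label.
#' @return Object of class `dist_surv_test`.
#' @export
mirkat_adjusted_test <- function(K, X = NULL, r, plan, label = "residual") {
  K <- as.matrix(K)
  n <- nrow(K)
  stopifnot(length(r) == n, plan$n == n)
  basis <- orthonormal_basis(X, n = n)
  r <- r - mean(r)
  r_tilde <- adjust_vector(r, basis, normalize = TRUE)
  if (isTRUE(attr(r_tilde, "degenerate"))) {
    stop("regressor lies in the covariate span", call. = FALSE)
  }
  q_obs <- mirkat_score(K, as.numeric(r_tilde))
  Rt <- .permuted_regressors(r, basis, plan$perms)
  q_null <- rowSums((Rt %*% K) * Rt)
  structure(
    list(
      method = "mirkat-adjusted", label = label, metric = attr(K, "metric"),
      global = tibble::tibble(statistic = q_obs,
                              p = rank_pvalue(q_obs, q_null)),
      null_global = q_null,
      plan = plan[c("n", "B", "seed", "exhaustive")]
    ),
    class = "dist_surv_test"
  )
}

#' @export
print.dist_surv_test <- function(x, ...) {
  cat(sprintf("<dist_surv_test> %s (%s%s): statistic = %.4g, p = %.4g\n",
              x$method, x$label,
              if (!is.null(x$metric)) paste0(", ", x$metric) else "",
              x$global$statistic, x$global$p))
  invisible(x)
}

#' Min-p combination of distance-based global tests
#'
#' Combines [permanova_fl_test()] / [mirkat_adjusted_test()] /
#' [mirkat_s_test()] results across residual types and/or distances, all
#' computed on one shared plan.
#'
#' @param tests List of `dist_surv_test` objects.
#' @param label Label for the combined test.
#' @return A list with the combined `p`, the component p-values, and class
#'   `dist_surv_combined`.
#' @export
combine_dist_tests <- function(tests, label = "combined") {
  stopifnot(length(tests) >= 1)
  plan0 <- tests[[1]]$plan
  for (t in tests) {
    if (!identical(t$plan, plan0)) {
      stop("all combined tests must share one permutation plan", call. = FALSE)
    }
  }
  cmb <- minp_combine(
    observed = vapply(tests, function(t) t$global$statistic, numeric(1)),
    nulls = do.call(cbind, lapply(tests, function(t) t$null_global))
  )
  nm <- vapply(tests, function(t) {
    paste0(t$method, ".", t$label, if (!is.null(t$metric)) paste0(".", t$metric) else "")
  }, character(1))
  structure(
    list(label = label, components = stats::setNames(cmb$component_p, nm),
         p = cmb$p, plan = plan0),
    class = "dist_surv_combined"
  )
}

#' @export
print.dist_surv_combined <- function(x, ...) {
  cat(sprintf("<dist_surv_combined> %s: p = %.4g (components: %s)\n",
              x$label, x$p,
              paste(sprintf("%s = %.3g", names(x$components), x$components),
                    collapse = ", ")))
  invisible(x)
}

#' Distance-based microbiome-survival association test
#'
#' Data-frame-first wrapper running [permanova_fl_test()] (default),
#' [mirkat_s_test()] or [mirkat_adjusted_test()] on a chosen distance, with
#' Martingale and/or deviance residuals and their combination.
#'
#' @inheritParams ldm_surv
#' @param metric Distance: `"bray-curtis"`, `"jaccard"`, `"euclidean"`, or a
#'   precomputed square distance matrix.
#' @param method `"permanovafl"`, `"mirkat-s"` or `"mirkat-adjusted"`.
#' @return A `dist_surv_fit` object; `glance()` gives the global p-values.
#' @export
dist_surv <- function(counts, data, time = "time", event = "event",
                      covariates = NULL, metric = "bray-curtis",
                      method = c("permanovafl", "mirkat-s", "mirkat-adjusted"),
                      residual = c("both", "martingale", "deviance"),
                      n_perm = 5000, seed = 1, min_prevalence = 5,
                      ties = "breslow") {
  method <- match.arg(method)
  residual <- match.arg(residual)
  if (!inherits(counts, "count_table")) counts <- count_table(counts)
  if (nrow(data) != nrow(counts)) {
    stop("`data` must have one row per sample of `counts`", call. = FALSE)
  }
  meta <- read_metadata(path = NULL, time_col = time, event_col = event,
                        covariate_cols = covariates %||% character(),
                        data = cbind(sample_id = rownames(counts), data))
  if (min_prevalence > 0) counts <- filter_rare_taxa(counts, min_prevalence)
  fit <- fit_cox(meta$time, meta$event, meta$covariates, ties = ties)
  M <- martingale_residuals(fit)
  Dv <- deviance_residuals(M, fit$event)
  if (is.matrix(metric)) {
    D <- metric
  } else {
    sc <- switch(metric, "bray-curtis" = "relabund", "jaccard" = "presence",
                 "euclidean" = "relabund")
    D <- distance_matrix(taxon_matrix(counts, sc), metric)
  }
  plan <- permutation_plan(nrow(counts), B = n_perm, seed = seed)
  X <- meta$covariates
  if (method == "mirkat-s") residual <- "martingale"  # defined for M only
  res_list <- switch(residual,
    both = list(martingale = M, deviance = Dv),
    martingale = list(martingale = M),
    deviance = list(deviance = Dv)
  )
  tests <- purrr::imap(res_list, function(r, nm) {
    switch(method,
      "permanovafl" = permanova_fl_test(D, X, r, plan, label = nm),
      "mirkat-s" = mirkat_s_test(gower_center(D), M, plan),
      "mirkat-adjusted" = mirkat_adjusted_test(gower_center(D), X, r, plan,
                                               label = nm)
    )
  })
  combined <- if (length(tests) > 1) combine_dist_tests(tests) else NULL
  structure(
    list(tests = tests, combined = combined, cox_fit = fit,
         method = method, metric = if (is.matrix(metric)) "custom" else metric,
         n_perm = n_perm, seed = seed),
    class = "dist_surv_fit"
  )
}

#' @export
print.dist_surv_fit <- function(x, ...) {
  cat(sprintf("<dist_surv_fit> %s on %s, %d permutations\n",
              x$method, x$metric, x$n_perm))
  for (t in x$tests) print(t)
  if (!is.null(x$combined)) print(x$combined)
  invisible(x)
}

#' @rdname glance.ldm_surv_fit
#' @method glance dist_surv_fit
#' @export
glance.dist_surv_fit <- function(x, ...) {
  out <- tibble::tibble(method = x$method, metric = x$metric, n_perm = x$n_perm)
  for (nm in names(x$tests)) out[[paste0("p_", nm)]] <- x$tests[[nm]]$global$p
  if (!is.null(x$combined)) out$p_combined <- x$combined$p
  out
}
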