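#' LDM statistics for a residual regressor
#'
#' Computes the per-taxon and global test statistics of the linear
#' decomposition model for the model `Z_j = b_Xj' X + b_j r + e`: the
#' covariates are projected out of both the taxon matrix and the regressor,
#' the regressor is normalized, and
#' `U_j = r~' z*_j`, `F_j = U_j^2 / (|z*_j|^2 - U_j^2)`,
#' `F_global = sum(U_j^2) / sum(|z*_j|^2 - U_j^2)`.
#' With no covariates and an unnormalized regressor, `sum(U_j^2)` equals the
#' linear-kernel variance-component score statistic `r' Z Z' r`.
#'
#' @param Z Column-centered taxon matrix (`n x J`).
#' @param basis Orthonormal covariate basis from [orthonormal_basis()].
#' @param r Centered regressor (e.g. Martingale residuals).
#' @return List with `U`, `F_taxon`, `F_global`, `adjusted_sq_norms`
#'   (`|z*_j|^2`) and the normalized adjusted regressor `r_tilde`.
#' @export
ldm_statistics <- function(Z, basis, r) {
  Z <- as.matrix(Z)
  r_tilde <- adjust_vector(r, basis, normalize = TRUE)
  if (isTRUE(attr(r_tilde, "degenerate"))) {
    stop("regressor lies in the covariate span; remove collinear covariates",
         call. = FALSE)
  }
  Zstar <- if (ncol(basis) > 0) Z - basis %*% crossprod(basis, Z) else Z
  cj <- colSums(Zstar^2)
  U <- as.numeric(crossprod(Zstar, r_tilde))
  U2 <- U^2
  denom <- cj - U2
  F_taxon <- ifelse(cj <= 1e-12, 0, U2 / pmax(denom, .Machine$double.eps))
  F_global <- sum(U2) / max(sum(denom), .Machine$double.eps)
  list(U = U, F_taxon = F_taxon, F_global = F_global,
       adjusted_sq_norms = cj, r_tilde = as.numeric(r_tilde))
}

# Shared permutation engine for the LDM.  Z must be centered.  Returns the
# observed statistics plus per-taxon and global null U^2 streams.
.ldm_engine <- function(Z, basis, r, plan, taxon_pvalues = TRUE) {
  obs <- ldm_statistics(Z, basis, r)
  Zstar <- if (ncol(basis) > 0) Z - basis %*% crossprod(basis, Z) else Z
  Rt <- .permuted_regressors(r, basis, plan$perms)
  U2_null <- (Rt %*% Zstar)^2
  cj <- obs$adjusted_sq_norms
  sum_c <- sum(cj)
  g_null <- rowSums(U2_null)
  F_global_null <- g_null / pmax(sum_c - g_null, .Machine$double.eps)
  p_global <- rank_pvalue(obs$F_global, F_global_null)
  p_taxon <- NULL
  if (taxon_pvalues) {
    B <- plan$B
    U2_obs <- obs$U^2
    # per-taxon F is a monotone function of U^2 at fixed |z*_j|^2, so the
    # rank p-value can be computed on U^2 directly
    ge <- colSums(U2_null >= matrix(U2_obs - .tie_tol(U2_obs), B,
                                    length(U2_obs), byrow = TRUE))
    p_taxon <- (1 + ge) / (B + 1)
    degenerate <- cj <= 1e-12
    p_taxon[degenerate] <- 1
  }
  list(obs = obs, U2_null = U2_null, F_global_null = F_global_null,
       p_global = p_global, p_taxon = p_taxon)
}

#' LDM permutation test with a residual regressor
#'
#' Tests association between every taxon (and the community as a whole) and
#' a Cox-model residual, adjusting for covariates, by permutation F-tests.
#' The regressor is permuted and re-orthogonalized against the covariates in
#' every permutation (Freedman-Lane style), keeping the covariate effect
#' fixed; all statistics are recomputed per permutation.  Per-taxon
#' p-values use each taxon's own permutation null; taxa with zero adjusted
#' norm (e.g. constant presence columns) are flagged and given p = 1.
#'
#' @param Z Taxon matrix (centered internally if needed).
#' @param X Centered covariate matrix or `NULL`.
#' @param r Residual regressor (centered internally).
#' @param plan A [permutation_plan()].
#' @param q Nominal FDR for Benjamini-Hochberg detection (default 0.10).
#' @param label Residual label stored in the result (e.g. `"martingale"`).
#' @return An object of class `ldm_surv_test` with elements `global`
#'   (one-row tibble: `statistic`, `p`), `taxa` (tibble with per-taxon `U`,
#'   `F`, `p`, `p_adj`, `detected`), and the null streams needed for
#'   combination tests.
#' @export
ldm_test <- function(Z, X = NULL, r, plan, q = 0.10, label = "residual") {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  stopifnot(length(r) == n, plan$n == n)
  if (!isTRUE(attr(Z, "centered"))) Z <- center_columns(Z)
  r <- r - mean(r)
  basis <- orthonormal_basis(X, n = n)
  eng <- .ldm_engine(Z, basis, r, plan)
  taxa <- tibble::tibble(
    taxon = colnames(Z) %||% paste0("taxon", seq_len(ncol(Z))),
    U = eng$obs$U,
    F_stat = eng$obs$F_taxon,
    p = eng$p_taxon,
    degenerate = eng$obs$adjusted_sq_norms <= 1e-12
  )
  bh <- bh_adjust(taxa$p, q)
  taxa$p_adj <- bh$adjusted
  taxa$detected <- bh$detected
  structure(
    list(
      label = label,
      scale = attr(Z, "scale"),
      global = tibble::tibble(statistic = eng$obs$F_global, p = eng$p_global),
      taxa = taxa,
      q = q,
      plan = plan[c("n", "B", "seed", "exhaustive")],
      null_global = eng$F_global_null,
      null_taxa = eng$U2_null,
      obs_taxa = eng$obs$U^2
    ),
    class = "ldm_surv_test"
  )
}

#' @export
print.ldm_surv_test <- function(x, ...) {
  cat(sprintf("<ldm_surv_test> %s%s: global p = %.4g, %d/%d taxa detected (q = %g)\n",
              x$label, if (!is.null(x$scale)) paste0(" [", x$scale, "]") else "",
              x$global$p, sum(x$taxa$detected), nrow(x$taxa), x$q))
  invisible(x)
}

#' Min-p combination of LDM component tests
#'
#' Combines any number of [ldm_test()] results computed on the same
#' permutation plan (different residual types and/or data scales) into a
#' single test, at both the global and the per-taxon level.  This realizes
#' both the Martingale/deviance combination test and the multi-scale
#' omnibus test.
#'
#' @param tests List of `ldm_surv_test` objects sharing one plan.
#' @param q Nominal FDR for detection on the combined per-taxon p-values.
#' @param label Label for the combined test.
#' @return An object of class `ldm_surv_combined` with `global` (tibble:
#'   combined `p` plus component p-values) and `taxa` (tibble with combined
#'   `p`, `p_adj`, `detected`).
#' @export
combine_ldm_tests <- function(tests, q = 0.10, label = "combined") {
  stopifnot(length(tests) >= 1)
  plan0 <- tests[[1]]$plan
  for (t in tests) {
    if (!identical(t$plan, plan0)) {
      stop("all combined tests must share one permutation plan", call. = FALSE)
    }
  }
  comp_labels <- vapply(tests, function(t) {
    paste0(t$label, if (!is.null(t$scale)) paste0(".", t$scale) else "")
  }, character(1))
  # global combination on the F-statistic streams
  g <- minp_combine(
    observed = vapply(tests, function(t) t$global$statistic, numeric(1)),
    nulls = do.call(cbind, lapply(tests, function(t) t$null_global))
  )
  # per-taxon combination on the U^2 streams
  obs_mat <- do.call(rbind, lapply(tests, function(t) t$obs_taxa))
  tx <- .minp_combine_columns(obs_mat, lapply(tests, function(t) t$null_taxa))
  degenerate <- Reduce(`&`, lapply(tests, function(t) t$taxa$degenerate))
  p_taxon <- tx$p
  p_taxon[degenerate] <- 1
  bh <- bh_adjust(p_taxon, q)
  taxa <- tibble::tibble(
    taxon = tests[[1]]$taxa$taxon,
    p = p_taxon, p_adj = bh$adjusted, detected = bh$detected
  )
  global <- tibble::tibble(p = g$p)
  for (i in seq_along(comp_labels)) global[[paste0("p_", comp_labels[i])]] <- g$component_p[i]
  structure(
    list(label = label, components = comp_labels, global = global,
         taxa = taxa, q = q, plan = plan0),
    class = "ldm_surv_combined"
  )
}

#' @export
print.ldm_surv_combined <- function(x, ...) {
  cat(sprintf("<ldm_surv_combined> %s (%s): global p = %.4g, %d/%d taxa detected\n",
              x$label, paste(x$components, collapse = " + "),
              x$global$p, sum(x$taxa$detected), nrow(x$taxa)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Microbiome-survival association test (LDM framework)
#'
#' The package's main entry point.  Fits the covariate-only Cox model,
#' extracts Martingale and deviance residuals, and runs LDM permutation
#' tests of each taxon (and the community) against each residual on one or
#' more data scales, combining results across residuals (combination test)
#' and across scales (omnibus test) with permutation-calibrated min-p
#' statistics.
#'
#' @param counts A [count_table()] (or plain count matrix, samples in rows).
#' @param data Data frame of per-sample metadata, rows aligned with
#'   `counts` (or containing a column matching its rownames via
#'   `sample_col`).
#' @param time,event Column names in `data` of the follow-up time and the
#'   0/1 event indicator.
#' @param covariates Character vector of covariate column names in `data`
#'   (default none).
#' @param scales Data scales to analyze; any of `"relabund"`,
#'   `"arcsinroot"`, `"presence"`.  Default `c("relabund", "arcsinroot")`.
#' @param residual `"both"` (default; runs the Martingale/deviance
#'   combination test), `"martingale"`, or `"deviance"`.
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed for the permutation plan.
#' @param fdr Nominal FDR for taxon detection (default 0.10).
#' @param min_prevalence Taxa present in fewer samples are dropped before
#'   testing (default 5; set 0 to keep all).
#' @param sample_col Optional metadata column with sample IDs for alignment.
#' @param ties Cox tie handling (`"breslow"` or `"efron"`).
#' @return An object of class `ldm_surv_fit`; see [tidy.ldm_surv_fit()] and
#'   [glance.ldm_surv_fit()] for tidy accessors and [autoplot.ldm_surv_fit()]
#'   for plotting.
#' @examples
#' design <- sim_design(sim_config(n = 50, J = 40, beta = 1, n_causal = 3,
#'                                 n_confounded = 10), seed = 1)
#' rep1 <- simulate_replicate(design, seed = 2)
#' md <- data.frame(time = rep1$time, event = rep1$event, x = rep1$x)
#' fit <- ldm_surv(rep1$counts, md, "time", "event", covariates = "x",
#'                 n_perm = 200, seed = 3)
#' glance(fit)
#' @export
ldm_surv <- function(counts, data, time = "time", event = "event",
                     covariates = NULL,
                     scales = c("relabund", "arcsinroot"),
                     residual = c("both", "martingale", "deviance"),
                     n_perm = 5000, seed = 1, fdr = 0.10,
                     min_prevalence = 5, sample_col = NULL,
                     ties = "breslow") {
  residual <- match.arg(residual)
  scales <- match.arg(scales, c("relabund", "arcsinroot", "presence"),
                      several.ok = TRUE)
  if (!inherits(counts, "count_table")) counts <- count_table(counts)
  if (is.null(sample_col) && nrow(data) != nrow(counts)) {
    stop("`data` must have one row per sample of `counts` (or give `sample_col`)",
         call. = FALSE)
  }
  meta <- read_metadata(path = NULL, time_col = time, event_col = event,
                        covariate_cols = covariates %||% character(),
                        sample_ids = if (!is.null(sample_col)) rownames(counts),
                        data = if (!is.null(sample_col)) {
                          cbind(stats::setNames(data[sample_col], "sample_id"),
                                data[setdiff(names(data), sample_col)])
                        } else cbind(sample_id = rownames(counts), data))
  if (min_prevalence > 0) counts <- filter_rare_taxa(counts, min_prevalence)
  fit <- fit_cox(meta$time, meta$event, meta$covariates, ties = ties)
  M <- martingale_residuals(fit)
  D <- deviance_residuals(M, fit$event)
  res_list <- switch(residual,
    both = list(martingale = M, deviance = D),
    martingale = list(martingale = M),
    deviance = list(deviance = D)
  )
  plan <- permutation_plan(nrow(counts), B = n_perm, seed = seed)
  X <- meta$covariates
  tests <- list()
  for (sc in scales) {
    Z <- taxon_matrix(counts, sc, center = TRUE)
    for (rl in names(res_list)) {
      tests[[paste(rl, sc, sep = ".")]] <-
        ldm_test(Z, X, res_list[[rl]], plan, q = fdr, label = rl)
    }
  }
  combined <- if (length(tests) > 1) {
    combine_ldm_tests(tests, q = fdr, label = "omnibus")
  } else NULL
  structure(
    list(tests = tests, combined = combined, cox_fit = fit,
         residuals = tibble::tibble(martingale = M, deviance = D),
         scales = scales, residual = residual, fdr = fdr,
         n_perm = n_perm, seed = seed,
         n = fit$n, n_taxa = ncol(counts), taxon_ids = colnames(counts)),
    class = "ldm_surv_fit"
  )
}

#' @export
print.ldm_surv_fit <- function(x, ...) {
  cat(sprintf("<ldm_surv_fit> n = %d samples, %d taxa, %d permutations\n",
              x$n, x$n_taxa, x$n_perm))
  for (t in x$tests) print(t)
  if (!is.null(x$combined)) print(x$combined)
  invisible(x)
}

#' Tidy per-taxon results of an LDM survival fit
#'
#' @param x An [ldm_surv(x)] result (`ldm_surv_fit`) or a `survldm_coxfit`.
#' @param ... Unused.
#' @return A tibble with one row per taxon and component (plus the combined
#'   test when present): `taxon`, `component`, `U`, `F_stat`, `p`, `p_adj`,
#'   `detected`.
#' @rdname tidy.survldm
#' @method tidy ldm_surv_fit
#' @export
tidy.ldm_surv_fit <- function(x, ...) {
  out <- purrr::map_dfr(names(x$tests), function(nm) {
    dplyr::mutate(x$tests[[nm]]$taxa, component = nm, .before = 1)
  })
  if (!is.null(x$combined)) {
    out <- dplyr::bind_rows(out,
      dplyr::mutate(x$combined$taxa, component = "combined", .before = 1))
  }
  out
}

#' One-row summary of an LDM survival fit
#'
#' @param x An `ldm_surv_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the global p-value of each component test
#'   and of the combined (omnibus) test, plus detection counts.
#' @method glance ldm_surv_fit
#' @export
glance.ldm_surv_fit <- function(x, ...) {
  out <- tibble::tibble(n = x$n, n_taxa = x$n_taxa, n_perm = x$n_perm)
  for (nm in names(x$tests)) out[[paste0("p_", nm)]] <- x$tests[[nm]]$global$p
  if (!is.null(x$combined)) {
    out$p_combined <- x$combined$global$p
    out$n_detected <- sum(x$combined$taxa$detected)
  } else {
    out$n_detected <- sum(x$tests[[1]]$taxa$detected)
  }
  out
}
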