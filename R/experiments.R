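#' Taxon-by-taxon Cox regression comparator
#'
#' The ad hoc alternative to the permutation framework: for each taxon,
#' fits a Cox model with the covariates plus that taxon's value as
#' explanatory variables and reports the Wald p-value of the taxon
#' coefficient.  Taxa whose fit fails, does not converge, or is collinear
#' with the covariates are flagged and assigned p = 1 (counted as
#' non-detections).
#'
#' @param time,event Survival outcome.
#' @param X Covariate matrix or `NULL`.
#' @param Zm Uncentered taxon matrix on the analysis scale (relative
#'   abundance or presence-absence).
#' @param q Nominal FDR for Benjamini-Hochberg detection.
#' @return A tibble with `taxon`, `estimate`, `p`, `p_adj`, `detected`,
#'   `flagged`.
#' @export
taxonwise_cox <- function(time, event, X = NULL, Zm, q = 0.10) {
  Zm <- as.matrix(Zm)
  n <- nrow(Zm)
  y <- survival::Surv(as.numeric(time), as.numeric(event))
  if (!is.null(X)) X <- as.matrix(X)
  ctl <- survival::coxph.control()
  J <- ncol(Zm)
  p <- rep(1, J); est <- rep(NA_real_, J); flagged <- rep(FALSE, J)
  for (j in seq_len(J)) {
    z <- Zm[, j]
    xmat <- if (is.null(X) || ncol(X) == 0) matrix(z, ncol = 1) else cbind(X, z)
    if (stats::sd(z) < 1e-12 || qr(cbind(xmat))$rank < ncol(xmat)) {
      flagged[j] <- TRUE
      next
    }
    fit <- tryCatch(
      suppressWarnings(
        survival::coxph.fit(xmat, y, strata = NULL, offset = NULL,
                            init = NULL, control = ctl, weights = NULL,
                            method = "breslow", rownames = NULL)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) { flagged[j] <- TRUE; next }
    k <- ncol(xmat)
    b <- fit$coefficients[k]
    se <- sqrt(fit$var[k, k])
    if (!is.finite(b) || !is.finite(se) || se < 1e-12 || abs(b) / max(se, 1e-12) > 100) {
      flagged[j] <- TRUE
      next
    }
    est[j] <- b
    p[j] <- 2 * stats::pnorm(-abs(b / se))
  }
  bh <- bh_adjust(p, q)
  tibble::tibble(
    taxon = colnames(Zm) %||% paste0("taxon", seq_len(J)),
    estimate = est, p = p, p_adj = bh$adjusted,
    detected = bh$detected & !flagged, flagged = flagged
  )
}

# Fast per-replicate analysis used by the benchmark harness.  Returns
# global p-values per method and (optionally) per-method detected taxon
# name sets.  Shares one permutation plan, one Cox fit and the permuted
# regressor matrices across all methods, as the combination tests require.
.analyze_replicate <- function(rep, methods, n_perm, seed, q = 0.10,
                               adjust_x = TRUE, taxon_level = FALSE,
                               min_prevalence = 5) {
  cfg_model <- attr(rep, "model") %||% "M1"
  counts <- filter_rare_taxa(rep$counts, min_prevalence)
  n <- nrow(counts)
  X <- if (adjust_x) center_covariates(matrix(rep$x, ncol = 1,
                                              dimnames = list(NULL, "x"))) else NULL
  fit <- fit_cox(rep$time, rep$event, X)
  M <- martingale_residuals(fit)
  D <- deviance_residuals(M, fit$event)
  plan <- permutation_plan(n, B = n_perm, seed = seed)
  basis <- orthonormal_basis(X, n = n)
  scales <- if (cfg_model == "M1") c("relabund", "arcsinroot") else "presence"
  dist_metric <- if (cfg_model == "M1") "bray-curtis" else "jaccard"
  dist_scale <- if (cfg_model == "M1") "relabund" else "presence"

  need_ldm <- any(grepl("^ldm", methods))
  need_dist <- any(grepl("^permanovafl|^mirkat", methods))
  need_D <- any(methods %in% c("ldm-d", "ldm-c", "permanovafl-d",
                               "permanovafl-c", "mirkat-d"))

  # permuted, re-adjusted, normalized regressor matrices (B x n)
  Mc <- M - mean(M)
  Dc <- D - mean(D)
  Rt_M <- .permuted_regressors(Mc, basis, plan$perms)
  Rt_D <- if (need_D) .permuted_regressors(Dc, basis, plan$perms) else NULL
  rt_M <- as.numeric(adjust_vector(Mc, basis))
  rt_D <- if (need_D) as.numeric(adjust_vector(Dc, basis)) else NULL

  global_p <- c()
  detections <- list()
  B <- plan$B

  if (need_ldm) {
    # per scale/residual statistic streams
    streams <- list()  # each: list(Fg_obs, Fg_null, U2_obs, U2_null, cj)
    for (sc in scales) {
      Z <- taxon_matrix(counts, sc, center = TRUE)
      Zstar <- if (ncol(basis) > 0) Z - basis %*% crossprod(basis, Z) else Z
      cj <- colSums(Zstar^2)
      sum_c <- sum(cj)
      for (rl in c("m", if (need_D) "d")) {
        rt <- if (rl == "m") rt_M else rt_D
        Rt <- if (rl == "m") Rt_M else Rt_D
        U2_obs <- as.numeric(crossprod(Zstar, rt))^2
        U2_null <- (Rt %*% Zstar)^2
        g_obs <- sum(U2_obs) / max(sum_c - sum(U2_obs), .Machine$double.eps)
        g_null_num <- rowSums(U2_null)
        g_null <- g_null_num / pmax(sum_c - g_null_num, .Machine$double.eps)
        streams[[paste(rl, sc, sep = ".")]] <-
          list(Fg_obs = g_obs, Fg_null = g_null,
               U2_obs = U2_obs, U2_null = U2_null, cj = cj)
      }
    }
    .ldm_method <- function(keys) {
      sub <- streams[keys]
      if (length(sub) == 1) {
        s <- sub[[1]]
        gp <- rank_pvalue(s$Fg_obs, s$Fg_null)
        tp <- NULL
        if (taxon_level) {
          ge <- colSums(s$U2_null >= matrix(s$U2_obs - .tie_tol(s$U2_obs), B,
                                            length(s$U2_obs), byrow = TRUE))
          tp <- (1 + ge) / (B + 1)
          tp[s$cj <= 1e-12] <- 1
        }
      } else {
        gp <- minp_combine(vapply(sub, `[[`, numeric(1), "Fg_obs"),
                           do.call(cbind, lapply(sub, `[[`, "Fg_null")))$p
        tp <- NULL
        if (taxon_level) {
          cmb <- .minp_combine_columns(do.call(rbind, lapply(sub, `[[`, "U2_obs")),
                                       lapply(sub, `[[`, "U2_null"))
          tp <- cmb$p
          deg <- Reduce(`&`, lapply(sub, function(s) s$cj <= 1e-12))
          tp[deg] <- 1
        }
      }
      list(p = gp, taxon_p = tp)
    }
    keysets <- list(
      "ldm-m" = paste("m", scales, sep = "."),
      "ldm-d" = paste("d", scales, sep = "."),
      "ldm-c" = c(paste("m", scales, sep = "."), paste("d", scales, sep = "."))
    )
    for (mth in intersect(names(keysets), methods)) {
      res <- .ldm_method(keysets[[mth]])
      global_p[mth] <- res$p
      if (taxon_level) {
        det <- bh_adjust(res$taxon_p, q)$detected
        detections[[mth]] <- colnames(counts)[det]
      }
    }
  }

  if (need_dist) {
    Zd <- taxon_matrix(counts, dist_scale)
    G <- gower_center(distance_matrix(Zd, dist_metric))
    tr_G <- sum(diag(G))
    tr_BGB <- if (ncol(basis) > 0) sum(basis * (G %*% basis)) else 0
    df <- n - ncol(basis) - 2
    f_of_q <- function(qq) qq / ((tr_G - tr_BGB - qq) / df)
    qstreams <- list()
    qstreams$m <- list(obs = as.numeric(t(rt_M) %*% G %*% rt_M),
                       null = rowSums((Rt_M %*% G) * Rt_M))
    if (need_D) {
      qstreams$d <- list(obs = as.numeric(t(rt_D) %*% G %*% rt_D),
                         null = rowSums((Rt_D %*% G) * Rt_D))
    }
    if ("permanovafl-m" %in% methods) {
      global_p["permanovafl-m"] <- rank_pvalue(f_of_q(qstreams$m$obs),
                                               f_of_q(qstreams$m$null))
    }
    if ("permanovafl-d" %in% methods) {
      global_p["permanovafl-d"] <- rank_pvalue(f_of_q(qstreams$d$obs),
                                               f_of_q(qstreams$d$null))
    }
    if ("permanovafl-c" %in% methods) {
      global_p["permanovafl-c"] <- minp_combine(
        c(f_of_q(qstreams$m$obs), f_of_q(qstreams$d$obs)),
        cbind(f_of_q(qstreams$m$null), f_of_q(qstreams$d$null))
      )$p
    }
    if ("mirkat-m" %in% methods) {
      global_p["mirkat-m"] <- rank_pvalue(qstreams$m$obs, qstreams$m$null)
    }
    if ("mirkat-d" %in% methods) {
      global_p["mirkat-d"] <- rank_pvalue(qstreams$d$obs, qstreams$d$null)
    }
    if ("mirkat-s" %in% methods) {
      q_obs <- mirkat_score(G, M)
      Mp <- matrix(M[plan$perms], B, n)
      q_null <- rowSums((Mp %*% G) * Mp)
      global_p["mirkat-s"] <- rank_pvalue(q_obs, q_null)
    }
  }

  if ("cox" %in% methods) {
    Zm <- taxon_matrix(counts, dist_scale)
    cx <- taxonwise_cox(rep$time, rep$event, X, Zm, q = q)
    global_p["cox"] <- NA_real_  # no global test for the comparator
    if (taxon_level) detections[["cox"]] <- cx$taxon[cx$detected]
  }

  list(global_p = global_p, detections = detections,
       censor_frac = rep$censor_frac)
}

.replicate_seed <- function(seed, r) {
  as.integer((as.numeric(seed) + 7919 * r) %% 2147483647)
}

#' Type-I-error / power experiment for the global tests
#'
#' Simulates `n_rep` replicates from `config`, analyzes each with the
#' requested methods, and reports the fraction of global p-values at or
#' below `alpha` with its Monte-Carlo standard error.  With `beta = 0` in
#' the configuration this estimates type I error; with `beta > 0`, power.
#'
#' @param config A [sim_config()].
#' @param methods Character vector from `"ldm-m"`, `"ldm-d"`, `"ldm-c"`,
#'   `"permanovafl-m"`, `"permanovafl-d"`, `"permanovafl-c"`, `"mirkat-s"`,
#'   `"mirkat-m"`, `"mirkat-d"`.
#' @param alpha Nominal level (default 0.05).
#' @param n_rep Number of replicates.
#' @param n_perm Permutations per replicate.
#' @param seed Experiment seed (fixes the design and the replicate stream).
#' @param adjust_x Adjust for X in the Cox fit and in the tests?  Setting
#'   `FALSE` omits the confounder from the entire analysis.
#' @param min_prevalence Prevalence filter applied before analysis.
#' @return An `experiment_report` tibble: `method`, `rejection`, `se`,
#'   `n_rep`, `alpha`, plus the mean realized censoring fraction as
#'   attribute `censoring`.
#' @export
run_type1 <- function(config, methods = c("ldm-m", "ldm-d", "ldm-c"),
                      alpha = 0.05, n_rep = 1000, n_perm = 1000, seed = 1,
                      adjust_x = TRUE, min_prevalence = 5) {
  design <- sim_design(config, seed = seed)
  pmat <- matrix(NA_real_, n_rep, length(methods),
                 dimnames = list(NULL, methods))
  cens <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    rs <- .replicate_seed(seed, r)
    rep_ <- simulate_replicate(design, seed = rs)
    attr(rep_, "model") <- config$model
    res <- .analyze_replicate(rep_, methods, n_perm, seed = rs + 1L,
                              adjust_x = adjust_x,
                              min_prevalence = min_prevalence)
    pmat[r, names(res$global_p)] <- res$global_p
    cens[r] <- res$censor_frac
  }
  rejection <- colMeans(pmat <= alpha)
  out <- tibble::tibble(
    method = methods,
    rejection = as.numeric(rejection),
    se = sqrt(rejection * (1 - rejection) / n_rep),
    n_rep = n_rep, alpha = alpha
  )
  attr(out, "censoring") <- mean(cens)
  attr(out, "config") <- config
  class(out) <- c("experiment_report", class(out))
  out
}

#' Power curve over a grid of effect sizes
#'
#' Runs [run_type1()] at each value of `beta_grid` (reusing the same design
#' seed, so the causal set and directions are fixed across the grid) and
#' stacks the reports.
#'
#' @inheritParams run_type1
#' @param beta_grid Numeric vector of causal effect sizes.
#' @return A tibble with columns of [run_type1()] plus `beta`.
#' @export
run_power <- function(config, beta_grid, methods = c("ldm-m", "ldm-d", "ldm-c"),
                      alpha = 0.05, n_rep = 1000, n_perm = 1000, seed = 1,
                      adjust_x = TRUE, min_prevalence = 5) {
  purrr::map_dfr(beta_grid, function(b) {
    cfg <- config
    cfg$beta <- b
    rep_out <- run_type1(cfg, methods = methods, alpha = alpha, n_rep = n_rep,
                         n_perm = n_perm, seed = seed, adjust_x = adjust_x,
                         min_prevalence = min_prevalence)
    dplyr::mutate(tibble::as_tibble(rep_out), beta = b, .before = 1)
  })
}

#' Sensitivity and empirical FDR of the taxon-level tests
#'
#' For each replicate, runs the requested taxon-level methods (LDM variants
#' and/or the taxon-by-taxon Cox comparator), records the detected taxa at
#' nominal FDR `q`, and averages per-replicate sensitivity
#' (`|detected & causal| / |causal|`) and empirical false discovery
#' proportion (`|detected \ causal| / max(|detected|, 1)`).
#'
#' @inheritParams run_type1
#' @param q Nominal FDR (default 0.10).
#' @return An `experiment_report` tibble: `method`, `sensitivity`,
#'   `sensitivity_se`, `fdr`, `fdr_se`, `n_rep`, `q`.
#' @export
run_fdr_sensitivity <- function(config,
                                methods = c("ldm-m", "ldm-d", "ldm-c", "cox"),
                                q = 0.10, n_rep = 1000, n_perm = 1000,
                                seed = 1, adjust_x = TRUE,
                                min_prevalence = 5) {
  design <- sim_design(config, seed = seed)
  truth <- paste0("taxon", design$causal_set)
  sens <- matrix(NA_real_, n_rep, length(methods),
                 dimnames = list(NULL, methods))
  fdp <- matrix(NA_real_, n_rep, length(methods),
                dimnames = list(NULL, methods))
  for (r in seq_len(n_rep)) {
    rs <- .replicate_seed(seed, r)
    rep_ <- simulate_replicate(design, seed = rs)
    attr(rep_, "model") <- config$model
    res <- .analyze_replicate(rep_, methods, n_perm, seed = rs + 1L,
                              q = q, adjust_x = adjust_x, taxon_level = TRUE,
                              min_prevalence = min_prevalence)
    for (mth in methods) {
      det <- res$detections[[mth]] %||% character(0)
      sens[r, mth] <- length(intersect(det, truth)) / length(truth)
      fdp[r, mth] <- length(setdiff(det, truth)) / max(length(det), 1)
    }
  }
  out <- tibble::tibble(
    method = methods,
    sensitivity = colMeans(sens),
    sensitivity_se = apply(sens, 2, stats::sd) / sqrt(n_rep),
    fdr = colMeans(fdp),
    fdr_se = apply(fdp, 2, stats::sd) / sqrt(n_rep),
    n_rep = n_rep, q = q
  )
  attr(out, "config") <- config
  class(out) <- c("experiment_report", class(out))
  out
}
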