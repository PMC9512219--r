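#' Fit the covariate-only Cox proportional hazards model
#'
#' Fits the Cox model for `(time, event)` on the covariates `X` alone — no
#' microbiome terms — as the first stage of the survival extension of the
#' LDM.  With no covariates (`X = NULL` or zero columns) the "fit" is the
#' null model, whose baseline cumulative hazard is the Nelson-Aalen
#' estimator.  The model is fitted exactly once per dataset; all downstream
#' permutation inference reuses its residuals.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (1 = event observed, 0 = censored).
#' @param X Covariate matrix (samples in rows), or `NULL`.
#' @param ties Tie-handling method, `"breslow"` (default; keeps the score
#'   equations, and hence the residual orthogonality identities, exact) or
#'   `"efron"`.
#' @return An object of class `survldm_coxfit` with elements
#'   `coefficients`, `baseline` (tibble of `time`, `cumhaz`),
#'   `linear_predictors`, `converged`, `separation` (flag for monotone
#'   likelihood), and the underlying [survival::coxph()] fit.
#' @examples
#' fit <- fit_cox(c(1, 2, 3, 4), c(1, 1, 0, 1), X = NULL)
#' martingale_residuals(fit)
#' @export
fit_cox <- function(time, event, X = NULL, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  time <- as.numeric(time)
  event <- as.numeric(event)
  stopifnot(length(time) == length(event))
  if (any(time <= 0)) stop("all follow-up times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0/1", call. = FALSE)
  if (sum(event) == 0) stop("no events observed; Cox fit is degenerate", call. = FALSE)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (ncol(X) == 0) X <- NULL
  }
  y <- survival::Surv(time, event)
  separation <- FALSE
  if (is.null(X)) {
    fit <- survival::coxph(y ~ 1, ties = ties)
    converged <- TRUE
  } else {
    if (nrow(X) != length(time)) stop("X rows must match samples", call. = FALSE)
    fit <- withCallingHandlers(
      survival::coxph(y ~ X, ties = ties),
      warning = function(w) {
        if (grepl("infinite|converge", conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    converged <- is.null(fit$info) || !separation
  }
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(
    list(
      coefficients = if (is.null(X)) numeric(0) else unname(stats::coef(fit)),
      baseline = tibble::tibble(time = bh$time, cumhaz = bh$hazard),
      linear_predictors = if (is.null(X)) rep(0, length(time)) else unname(fit$linear.predictors),
      converged = converged,
      separation = separation,
      ties = ties,
      n = length(time),
      n_events = sum(event),
      time = time,
      event = as.integer(event),
      X = X,
      fit = fit
    ),
    class = "survldm_coxfit"
  )
}

#' @export
print.survldm_coxfit <- function(x, ...) {
  cat(sprintf("<survldm_coxfit> n = %d, events = %d, covariates = %d (%s ties)\n",
              x$n, x$n_events, length(x$coefficients), x$ties))
  if (x$separation) cat("  warning: possible monotone likelihood (separation)\n")
  invisible(x)
}

#' Martingale residuals of a fitted Cox model
#'
#' The Martingale residual of sample i is the observed event count minus
#' its estimated cumulative hazard, M_i = Delta_i - Lambda0(U_i) exp(b'X_i).
#' At the partial-likelihood maximizer with Breslow ties they satisfy
#' sum(M) = 0 and sum(M * X_k) = 0 for every covariate column k, so they
#' are already centered and orthogonal to the covariates.
#'
#' @param fit A [fit_cox()] object.
#' @return Numeric vector of Martingale residuals.
#' @export
martingale_residuals <- function(fit) {
  stopifnot(inherits(fit, "survldm_coxfit"))
  unname(stats::residuals(fit$fit, type = "martingale"))
}

#' Deviance residuals from Martingale residuals
#'
#' The deviance residual is the signed square-root transformation
#' D_i = sign(M_i) * sqrt(-2 * (M_i + Delta_i * log(Delta_i - M_i)))
#' which symmetrizes the skewed Martingale residual (bounded above by 1,
#' unbounded below).  `M_i = 0` with `Delta_i = 0` maps to `D_i = 0`.
#'
#' @param martingale Martingale residuals.
#' @param event 0/1 event indicators.
#' @return Numeric vector of deviance residuals, with `sign(D) = sign(M)`.
#' @examples
#' deviance_residuals(c(1 - exp(-1), -1), c(1, 0))
#' @export
deviance_residuals <- function(martingale, event) {
  m <- as.numeric(martingale)
  d <- as.numeric(event)
  stopifnot(length(m) == length(d), all(d %in% c(0, 1)))
  if (any(m > 1 + 1e-12)) stop("Martingale residuals cannot exceed 1", call. = FALSE)
  arg <- d - m  # log argument where Delta = 1; equals -M where Delta = 0
  bad <- (d == 1 & arg <= 0) | (d == 0 & m > 1e-12)
  if (any(bad)) {
    stop("invalid deviance-residual domain for sample(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  inner <- -2 * (m + ifelse(d == 1, d * log(arg), 0))
  inner[abs(m) < 1e-15 & d == 0] <- 0
  inner <- pmax(inner, 0)  # guard tiny negative round-off at M ~ 0
  sign(m) * sqrt(inner)
}

#' Martingale and deviance residuals in one call
#'
#' Convenience wrapper: fits the covariate-only Cox model and returns both
#' residual types as a tibble.
#'
#' @inheritParams fit_cox
#' @return A tibble with columns `martingale` and `deviance`; the
#'   `survldm_coxfit` is attached as attribute `"fit"`.
#' @export
cox_residuals <- function(time, event, X = NULL, ties = c("breslow", "efron")) {
  fit <- fit_cox(time, event, X, ties = match.arg(ties))
  m <- martingale_residuals(fit)
  out <- tibble::tibble(
    martingale = m,
    deviance = deviance_residuals(m, fit$event)
  )
  attr(out, "fit") <- fit
  out
}

#' @rdname tidy.survldm
#' @method tidy survldm_coxfit
#' @export
tidy.survldm_coxfit <- function(x, ...) {
  if (!length(x$coefficients)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "coef"],
    std.error = s[, "se(coef)"],
    statistic = s[, "z"],
    p.value = s[, "Pr(>|z|)"]
  )
}
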