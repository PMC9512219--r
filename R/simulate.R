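#' Simulation configuration
#'
#' Collects every parameter of the synthetic data generator: a baseline
#' taxon frequency profile; a binary group variable X confounding a random
#' subset of taxa via a frequency permutation; Dirichlet-Multinomial counts;
#' a causal taxon score feeding a Cox-Weibull or accelerated-hazards event
#' time; and exponential censoring.
#'
#' Defaults follow the study design the package's benchmark experiments
#' emulate: `n = 100` subjects (half per group), overdispersion
#' `theta = 0.02`, library sizes `N(10000, (10000/3)^2)` left-truncated at
#' 1000, 100 confounded taxa with effect `beta_xz = 0.8`, 10 causal taxa
#' (the 10 most abundant under M1; 10 drawn from abundance ranks 11-100
#' under M2), group effect on the hazard `beta_xs = 0.5`, and censoring
#' rate `mu = 0.08` (about 50% censoring under the Cox-Weibull model).
#' The baseline profile is a power-law `pi_j proportional to j^-gamma` with
#' `gamma = 1.4`, chosen so that taxa in ranks 11-100 have variable
#' presence-absence patterns and overall zero-fractions in the 50-90% range
#' typical of 16S count tables; a measured frequency vector can be supplied
#' through `baseline` instead.
#'
#' @param n Number of subjects (even; half per group).
#' @param J Number of taxa.
#' @param gamma Power-law exponent of the synthetic baseline frequencies.
#' @param baseline Optional vector of baseline taxon frequencies (overrides
#'   `gamma`); normalized and sorted decreasing.
#' @param n_confounded Number of taxa associated with X (default 100).
#' @param beta_xz Effect of X on the confounded taxa, in `[0, 1]`.
#' @param theta Dirichlet-Multinomial overdispersion (0 = multinomial).
#' @param lib_mean,lib_sd,lib_min Library-size distribution parameters.
#' @param model Causal model: `"M1"` (relative abundances of the most
#'   abundant taxa) or `"M2"` (presence of taxa from ranks 11-100).
#' @param causal_set Optional explicit causal taxon indices (overrides
#'   `model`'s default choice; e.g. `11`, `21`, or `91:100`).
#' @param n_causal Number of causal taxa (default 10).
#' @param beta Effect of the causal score on the hazard (0 = null).
#' @param beta_xs Effect of X on the hazard (fixed default 0.5).
#' @param hazard `"cox-weibull"` (baseline Weibull W(2, 0.01)) or
#'   `"ah-lognormal"` (accelerated hazards; violates proportionality).
#' @param censor_rate Exponential censoring rate `mu` (0 = no censoring).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 100, J = 856, gamma = 1.4, baseline = NULL,
                       n_confounded = 100, beta_xz = 0.8, theta = 0.02,
                       lib_mean = 10000, lib_sd = 10000 / 3, lib_min = 1000,
                       model = c("M1", "M2"), causal_set = NULL,
                       n_causal = 10, beta = 0, beta_xs = 0.5,
                       hazard = c("cox-weibull", "ah-lognormal"),
                       censor_rate = 0.08) {
  model <- match.arg(model)
  hazard <- match.arg(hazard)
  if (n %% 2 != 0) stop("`n` must be even (half per X group)", call. = FALSE)
  if (beta_xz < 0 || beta_xz > 1) stop("`beta_xz` must be in [0, 1]", call. = FALSE)
  if (theta < 0 || theta >= 1) stop("`theta` must be in [0, 1)", call. = FALSE)
  if (censor_rate < 0) stop("`censor_rate` must be >= 0", call. = FALSE)
  if (n_confounded > J) stop("`n_confounded` cannot exceed J", call. = FALSE)
  structure(
    list(n = n, J = J, gamma = gamma, baseline = baseline,
         n_confounded = n_confounded, beta_xz = beta_xz, theta = theta,
         lib_mean = lib_mean, lib_sd = lib_sd, lib_min = lib_min,
         model = model, causal_set = causal_set, n_causal = n_causal,
         beta = beta, beta_xs = beta_xs, hazard = hazard,
         censor_rate = censor_rate),
    class = "sim_config"
  )
}

#' Baseline taxon frequency profile
#'
#' Either normalizes and sorts (decreasing) a supplied frequency vector, or
#' builds the synthetic power-law profile `pi_j proportional to j^-gamma`.
#' Taxon 1 is always the most abundant.
#'
#' @param J Number of taxa (ignored when `frequencies` given).
#' @param gamma Power-law exponent (> 0).
#' @param frequencies Optional positive frequency vector.
#' @return A length-`J` simplex vector sorted decreasing.
#' @examples
#' make_baseline(4, gamma = 1)  # harmonic weights
#' @export
make_baseline <- function(J, gamma = 1.4, frequencies = NULL) {
  if (!is.null(frequencies)) {
    if (any(frequencies <= 0)) stop("frequencies must be positive", call. = FALSE)
    p <- sort(frequencies, decreasing = TRUE)
    return(p / sum(p))
  }
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  w <- seq_len(J)^(-gamma)
  w / sum(w)
}

#' Confounded companion frequency profile
#'
#' Builds `pi2` from `pi1` by permuting the frequencies *within* a randomly
#' selected set of `n_confounded` taxa, leaving all other taxa untouched, so
#' the two profiles share the same frequency multiset and differ only on
#' the selected taxa.
#'
#' @param pi1 Baseline simplex vector.
#' @param n_confounded Number of taxa to associate with the group variable.
#' @param seed Integer seed (fixes the selected set and permutation).
#' @return `pi2`, with the selected indices as attribute `confounded_set`.
#' @export
make_confounded_pair <- function(pi1, n_confounded, seed) {
  J <- length(pi1)
  stopifnot(n_confounded <= J)
  pi2 <- pi1
  set.seed(seed)
  sel <- if (n_confounded > 0) sort(sample.int(J, n_confounded)) else integer(0)
  if (length(sel) > 1) pi2[sel] <- pi1[sample(sel)]
  structure(pi2, confounded_set = sel)
}

#' Subject-specific taxon frequencies
#'
#' `pi~(X_i) = (1 - beta_xz * X_i) * pi1 + beta_xz * X_i * pi2`: subjects
#' with `X_i = 0` keep the baseline profile; subjects with `X_i = 1` move a
#' fraction `beta_xz` of the way toward the confounded profile.
#'
#' @param pi1,pi2 Simplex vectors.
#' @param beta_xz Mixing weight in `[0, 1]`.
#' @param x Vector of 0/1 group indicators (one per subject).
#' @return An `n x J` matrix of subject frequency vectors.
#' @export
subject_frequencies <- function(pi1, pi2, beta_xz, x) {
  stopifnot(all(x %in% c(0, 1)))
  w <- beta_xz * x
  out <- outer(1 - w, pi1) + outer(w, pi2)
  out
}

#' Draw Dirichlet-Multinomial count data
#'
#' Library sizes are drawn from `N(lib_mean, lib_sd^2)`, redrawn while below
#' `lib_min` (left truncation) and then rounded.  Each subject's composition
#' is Dirichlet with mean equal to its frequency vector and concentration
#' `(1 - theta) / theta` (so the pairwise overdispersion parameter equals
#' `theta`); `theta = 0` draws multinomial counts directly.
#'
#' @param freqs `n x J` matrix of subject frequency vectors (rows sum to 1).
#' @param theta Overdispersion in `[0, 1)`.
#' @param lib_mean,lib_sd,lib_min Library-size parameters.
#' @param seed Optional integer seed.
#' @return A [count_table()].
#' @export
draw_counts <- function(freqs, theta = 0.02, lib_mean = 10000,
                        lib_sd = 10000 / 3, lib_min = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(freqs); J <- ncol(freqs)
  lib <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      l <- stats::rnorm(1, lib_mean, lib_sd)
      if (l >= lib_min) break
    }
    lib[i] <- round(l)
  }
  counts <- matrix(0L, n, J)
  conc <- if (theta > 0) (1 - theta) / theta else Inf
  for (i in seq_len(n)) {
    p <- freqs[i, ]
    if (theta > 0) {
      g <- stats::rgamma(J, shape = p * conc)
      s <- sum(g)
      p <- if (s > 0) g / s else p
    }
    counts[i, ] <- stats::rmultinom(1, size = lib[i], prob = p)
  }
  rownames(counts) <- paste0("subject", seq_len(n))
  colnames(counts) <- paste0("taxon", seq_len(J))
  count_table(counts)
}

#' Causal score of each subject
#'
#' `S_i = sum_{j in A} delta_j * Z_ij / Zbar_j` under M1 (observed
#' frequency relative to its cross-subject mean) or
#' `S_i = sum_{j in A} delta_j * I(Z_ij > 0)` under M2 (signed presence
#' count), where `Z_ij` is count divided by library size.  Under M1, causal
#' taxa never observed in the replicate (mean frequency 0) are skipped and
#' recorded in attribute `skipped`.
#'
#' @param counts A [count_table()].
#' @param model `"M1"` or `"M2"`.
#' @param causal_set Integer indices of the causal taxa A.
#' @param delta Directions (+1/-1), one per causal taxon.
#' @return Length-`n` numeric score vector.
#' @export
causal_score <- function(counts, model = c("M1", "M2"), causal_set, delta) {
  model <- match.arg(model)
  stopifnot(length(causal_set) == length(delta))
  Z <- sweep(unclass(counts), 1, library_sizes(counts), "/")
  Zc <- Z[, causal_set, drop = FALSE]
  skipped <- integer(0)
  if (model == "M1") {
    zbar <- colMeans(Zc)
    ok <- zbar > 0
    skipped <- causal_set[!ok]
    S <- as.numeric(sweep(Zc[, ok, drop = FALSE], 2, zbar[ok], "/") %*% delta[ok])
  } else {
    S <- as.numeric((Zc > 0) %*% delta)
  }
  structure(S, skipped = skipped)
}

#' Draw censored survival outcomes
#'
#' Event times follow either the Cox model with Weibull W(2, 0.01) baseline
#' hazard, `T_i = 10 * B_i^(-1/2) * sqrt(-log V_i)`, or the accelerated
#' hazards model with lognormal baseline,
#' `T_i = B_i^(-1) * exp(qnorm(1 - V_i^B_i))`, where `V_i ~ U(0, 1)` and
#' `B_i = exp(beta_xs * scale(x) + beta * scale(S))` (`scale` standardizes
#' to mean 0, sd 1 with the n-1 denominator; a constant input contributes 0
#' with a warning).  Censoring times are `Exp(mu)`, drawn independently;
#' the observed data are `U_i = min(T_i, C_i)` and
#' `Delta_i = I(T_i <= C_i)`.
#'
#' @param S Causal score vector.
#' @param x 0/1 group indicator vector.
#' @param beta,beta_xs Hazard effect sizes.
#' @param hazard `"cox-weibull"` or `"ah-lognormal"`.
#' @param censor_rate Exponential rate `mu` (0 = no censoring).
#' @param seed Optional integer seed.
#' @return A tibble with `time` and `event`; latent `T` and `C` are
#'   attached as attributes `latent_T`, `latent_C`.
#' @export
draw_survival <- function(S, x, beta = 0, beta_xs = 0.5,
                          hazard = c("cox-weibull", "ah-lognormal"),
                          censor_rate = 0.08, seed = NULL) {
  hazard <- match.arg(hazard)
  if (censor_rate < 0) stop("`censor_rate` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  stopifnot(length(S) == n)
  # zero coefficients contribute exactly 0 (and skip the constant-input check)
  lp <- (if (beta_xs != 0) beta_xs * .safe_scale(x) else 0) +
    (if (beta != 0) beta * .safe_scale(S) else 0)
  if (length(lp) == 1) lp <- rep(lp, n)
  B <- exp(lp)
  V <- stats::runif(n)
  T_lat <- switch(hazard,
    "cox-weibull" = 10 * B^(-1 / 2) * sqrt(-log(V)),
    "ah-lognormal" = B^(-1) * exp(stats::qnorm(1 - exp(B * log(V))))
  )
  C_lat <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  out <- tibble::tibble(time = pmin(T_lat, C_lat),
                        event = as.integer(T_lat <= C_lat))
  attr(out, "latent_T") <- T_lat
  attr(out, "latent_C") <- C_lat
  out
}

.safe_scale <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-12) {
    warning("constant input to scale(); contributing 0 to the hazard")
    return(rep(0, length(v)))
  }
  (v - mean(v)) / s
}

#' Freeze the experiment-level design of a simulation
#'
#' Draws, from a single seed, everything that the study design holds fixed
#' across replicates: the baseline profile `pi1`, the confounded taxon set
#' and its permuted companion `pi2`, the causal set A, and the directions
#' `delta`.  Under M1 the causal set defaults to the `n_causal` most
#' abundant taxa; under M2 it is drawn from abundance ranks 11-100.
#'
#' @param config A [sim_config()].
#' @param seed Integer experiment seed.
#' @return A `sim_design` list (`config`, `pi1`, `pi2`, `confounded_set`,
#'   `causal_set`, `delta`).
#' @export
sim_design <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  pi1 <- make_baseline(config$J, config$gamma, config$baseline)
  pi2 <- make_confounded_pair(pi1, config$n_confounded, seed = seed)
  set.seed(seed + 1L)
  causal_set <- config$causal_set
  if (is.null(causal_set)) {
    causal_set <- if (config$model == "M1") {
      seq_len(config$n_causal)
    } else {
      if (config$J < 100) stop("M2 requires J >= 100 (causal ranks 11-100)",
                               call. = FALSE)
      sort(sample(11:100, config$n_causal))
    }
  }
  delta <- sample(c(-1, 1), length(causal_set), replace = TRUE)
  structure(
    list(config = config, pi1 = pi1, pi2 = as.numeric(pi2),
         confounded_set = attr(pi2, "confounded_set"),
         causal_set = causal_set, delta = delta, seed = seed),
    class = "sim_design"
  )
}

#' Generate one simulated replicate
#'
#' Applies the full generative pipeline for one dataset: group assignment
#' (first half `X = 0`, second half `X = 1`), subject frequencies, DM
#' counts, causal score, and censored survival outcome.  The design
#' (causal set, directions, confounded set) comes from [sim_design()] and
#' is fixed across replicates; only the counts and outcomes vary with
#' `seed`.
#'
#' @param design A [sim_design()].
#' @param seed Integer replicate seed.
#' @return A `sim_replicate` list: `counts` ([count_table()]), `x`, `time`,
#'   `event`, `S`, `censor_frac`, and `truth` (causal set, directions,
#'   confounded set, latent times).
#' @export
simulate_replicate <- function(design, seed = 1) {
  stopifnot(inherits(design, "sim_design"))
  cfg <- design$config
  x <- rep(c(0, 1), each = cfg$n / 2)
  freqs <- subject_frequencies(design$pi1, design$pi2, cfg$beta_xz, x)
  set.seed(seed)
  counts <- draw_counts(freqs, cfg$theta, cfg$lib_mean, cfg$lib_sd, cfg$lib_min)
  S <- causal_score(counts, cfg$model, design$causal_set, design$delta)
  surv <- draw_survival(S, x, cfg$beta, cfg$beta_xs, cfg$hazard,
                        cfg$censor_rate)
  structure(
    list(counts = counts, x = x, time = surv$time, event = surv$event,
         S = as.numeric(S), censor_frac = mean(surv$event == 0),
         truth = list(causal_set = design$causal_set, delta = design$delta,
                      confounded_set = design$confounded_set,
                      latent_T = attr(surv, "latent_T"),
                      latent_C = attr(surv, "latent_C"))),
    class = "sim_replicate"
  )
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat(sprintf("<sim_replicate> n = %d, J = %d, %.0f%% censored\n",
              nrow(x$counts), ncol(x$counts), 100 * x$censor_frac))
  invisible(x)
}

#' Survival function of the accelerated-hazards generator
#'
#' Closed form `S(t | B) = (1 - pnorm(log(B t)))^(1 / B)` of the event-time
#' law used by the `"ah-lognormal"` hazard model, useful for checking that
#' groups with reciprocal `B` have crossing survival curves (a strong
#' violation of proportional hazards).
#'
#' @param t Time grid.
#' @param B Relative hazard factor.
#' @return Survival probabilities.
#' @export
ah_survival <- function(t, B) {
  (1 - stats::pnorm(log(B * t)))^(1 / B)
}
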