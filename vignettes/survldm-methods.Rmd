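---
title: "Testing microbiome-survival associations with Cox residuals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing microbiome-survival associations with Cox residuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survldm)
```

## The model

For subject $i = 1,\dots,n$ we observe the censored follow-up time
$U_i = \min(T_i, C_i)$, the event indicator $\Delta_i = I(T_i \le C_i)$,
confounding covariates $X_i$ (no intercept), and counts for taxa
$j = 1,\dots,J$.  Censoring prevents putting $U_i$ directly into a linear
model, so survival information enters through residuals of a Cox
proportional hazards model fitted once to $(U_i, \Delta_i, X_i)$ —
microbiome data never enter this fit.  The Martingale residual
$M_i = \Delta_i - \hat\Lambda_0(U_i)e^{\hat\beta^\top X_i}$ measures the
excess of observed over expected events; at the partial-likelihood
maximizer with Breslow tie handling it satisfies $\sum_i M_i = 0$ and
$\sum_i M_i X_i = 0$ exactly (these identities are asserted in the test
suite).  Because $M_i \le 1$ but is unbounded below, we also use the
deviance residual
$D_i = \mathrm{sign}(M_i)\sqrt{-2\{M_i + \Delta_i\log(\Delta_i - M_i)\}}$,
which symmetrizes the distribution.

Each taxon is then modelled as
$$Z_{ij} = \beta_{X,j}^\top X_i + \beta_j M_i + e_{ij},$$
with $Z_{ij}$ the (centered) relative abundance, arcsin-root abundance, or
presence-absence indicator.  The per-taxon score is
$U_j = \sum_i M_i Z_{ij}$ and the community statistic is
$U^2_{\text{global}} = \sum_j U_j^2$; the implementation uses the
equivalent F-form $F_j = U_j^2 / (\|z^*_j\|^2 - U_j^2)$ (with $z^*_j$ the
covariate-adjusted taxon vector and the regressor normalized), whose
permutation ranks coincide with those of $U_j^2$ taxon by taxon.  With the
linear kernel and no covariates, $U^2_{\text{global}}$ equals the kernel
variance-component score statistic $M^\top Z Z^\top M$ — the package
asserts this identity to $10^{-8}$ — which connects the approach to
kernel-machine survival tests.

## Permutation inference

All inference is by permutation, avoiding distributional assumptions on
the taxon data.  The scheme is Freedman-Lane-style: the *residual
regressor* is permuted, re-orthogonalized against the covariates, and
renormalized in every permutation, while the covariate effect on $Z$ stays
fixed.  Keeping $X$ in the model even though $M \perp X$ is what preserves
power and calibration under confounding; the kernel test that permutes the
residual *without* re-adjustment (`mirkat_s_test()`) is deliberately
implemented that way to reproduce its documented conservativeness when $X$
confounds both the microbiome and survival (empirically ~0.00-0.01
rejection at nominal 0.05 in the confounded presence-absence design).

P-values use the add-one rank rule $p = (1 + \#\{b : s_b \ge
s_{\text{obs}}\})/(B+1)$, so $p \in [1/(B+1), 1]$ and is never zero.
Observed-versus-null comparisons use a relative tie tolerance of
$10^{-10}$ so that permutations reproducing the observed statistic (the
identity permutation in exhaustive plans) count as ties regardless of
floating-point route.

**Combination tests.**  The Martingale and deviance residuals each win in
different scenarios, and no a priori rule predicts which; likewise for
data scales.  Components computed on one shared permutation plan are
combined by the minimum of their p-values, calibrated against the
per-permutation minima of the components' null p-value streams: for
component $c$ and permutation $b$,
$p_{c,b} = \#\{b' : s_{c,b'} \ge s_{c,b}\}/B$ (equivalently, the add-one
leave-self-out count), $t_b = \min_c p_{c,b}$, and the combined p-value is
the rank of $\min_c p_c$ among the $t_b$.  A brute-force loop
implementation of this rule serves as the test-suite oracle.  The same
machinery yields the residual-combination test, the multi-scale omnibus
test, and the distance omnibus; when several scales and both residuals are
requested, all component streams enter one flat min-p combination.

**Taxon-level inference.**  Each taxon is ranked against its own
permutation null (taxon variances are heterogeneous, so pooling nulls
across taxa would misrank sparse taxa); detection applies
Benjamini-Hochberg to the per-taxon permutation p-values at nominal FDR
$q = 0.10$.  The original LDM's sequential-stopping and permutation-based
FDR procedures are not implemented; BH on fixed-$B$ p-values is a
simpler, slightly more conservative choice.  Note the resolution
constraint this implies: with $J$ taxa the smallest attainable adjusted
p-value is $J/(B+1)$ at the top rank, so taxon-level analyses need
$B \gtrsim 10\,J$ for detection at $q = 0.10$ to be possible at all.
Degenerate taxa (zero adjusted norm — e.g. a presence column constant
across samples) get $p = 1$ and a flag.

**Distance-based tests.**  `permanova_fl_test()` explains a Gower-centered
distance kernel $G = -\tfrac12 C (D \circ D) C$ with the covariates plus
the adjusted residual $\tilde r$; its pseudo-F is
$\tilde r^\top G \tilde r \,/\, \{(\mathrm{tr}\,G - \mathrm{tr}\,B_X^\top
G B_X - \tilde r^\top G \tilde r)/(n-p-2)\}$, permuted with the same
re-adjusting scheme.  Squared distances are used for every metric,
following the PERMANOVA/kernel convention; Bray-Curtis is a semimetric,
so $G$ may have negative eigenvalues, which are retained (standard
PERMANOVA behaviour).  Jaccard distance between two all-empty samples is
defined as 0 (identical samples).  On Euclidean distances of the centered
taxon matrix the pseudo-F is a monotone transform of the LDM global
statistic, so the two tests return identical permutation p-values on
shared plans — a cross-check in the test suite.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_perm` (B) | 5000 (analysis), 1000–2000 (experiments) | permutation count; p-value floor is 1/(B+1); use ≥ 10·J for taxon detection |
| `seed` | required | permutation plan and simulator reproducibility |
| `fdr` (q) | 0.10 | nominal BH false discovery rate for taxon detection |
| `min_prevalence` | 5 | taxa present in fewer subjects are dropped before testing (the sample-count threshold does not scale with n; it is exposed as a parameter) |
| `scales` | relabund + arcsinroot | analysis scales; presence-absence is the natural scale for occupancy-driven hypotheses |
| `ties` | breslow | Cox tie handling; Breslow keeps the residual orthogonality identities exact, Efron is available; simulated times are continuous so the choice is immaterial there |

## The synthetic-data generator

The simulator emulates a confounded 16S-style cohort:

* **Baseline profile.**  Taxon frequencies $\pi_1$ follow a power law
  $\pi_j \propto j^{-\gamma}$ with $\gamma = 1.4$, or any measured
  frequency vector supplied by the user.  $\gamma = 1.4$ was chosen once so
  that (i) taxa of abundance ranks 11–100 have presence probabilities well
  inside (0, 1) under the count model below — so occupancy-driven signals
  and Jaccard distances are informative — and (ii) the realized zero
  fraction of the count table (~70%) sits in the 50–90% range typical of
  real amplicon tables.
* **Confounding.**  A binary group $X$ (half the subjects each) shifts a
  random set of taxa (default 100) by permuting their frequencies within
  the set: $\pi_2$ equals $\pi_1$ elsewhere, and subject frequencies are
  the mixture $\tilde\pi(X_i) = (1-\beta_{XZ}X_i)\pi_1 + \beta_{XZ}X_i\pi_2$
  with $\beta_{XZ} = 0.8$ for a strong confounder and 0 for a plain
  covariate.
* **Counts.**  Dirichlet-Multinomial with mean $\tilde\pi(X_i)$,
  overdispersion $\theta = 0.02$ (concentration $(1-\theta)/\theta$, so
  $\theta$ is the pairwise correlation parameter; 0.002 and 0.0002 give
  successively denser tables), and library sizes
  $N(10^4, (10^4/3)^2)$ redrawn while below $10^3$ and then rounded
  (truncation applied to the real draw, before rounding).
* **Causal signal.**  Model M1: the 10 most abundant taxa act through
  their relative abundances, $S_i = \sum_{j\in A}\delta_j Z_{ij}/\bar Z_j$;
  model M2: 10 taxa drawn from ranks 11–100 act through presence,
  $S_i = \sum_{j\in A}\delta_j I(Z_{ij}>0)$.  Directions
  $\delta_j \in \{\pm1\}$ and the sets are drawn once per experiment and
  held fixed across replicates.  Custom causal sets (a single taxon, the
  rare taxa 91–100, …) are supported.
* **Event times.**  Cox model with Weibull $W(2, 0.01)$ baseline:
  $T_i = 10\,B_i^{-1/2}\sqrt{-\log V_i}$ with
  $B_i = \exp\{\beta_{XS}\,\mathrm{scale}(X_i) + \beta\,\mathrm{scale}(S_i)\}$,
  $\beta_{XS} = 0.5$, $V_i \sim U(0,1)$; or the accelerated-hazards model
  with lognormal baseline, $T_i = B_i^{-1}\exp\{\Phi^{-1}(1 - V_i^{B_i})\}$,
  whose groups with reciprocal $B$ have *crossing* survival curves
  ($S(t\mid B) = (1-\Phi(\log Bt))^{1/B}$, a closed form checked
  deterministically in the tests) — a strong violation of proportional
  hazards used to probe robustness.  `scale()` standardizes with the
  $n-1$ denominator; the binary $X$ is standardized as its 0/1 coding; a
  constant input contributes 0 with a warning.  Censoring is
  $\mathrm{Exp}(\mu)$, independent; $\mu = 0.08$ gives ≈50% censoring
  under the Weibull design ($\mu = 0.03$ and $0.2$ give ≈25% and ≈75%,
  $\mu = 0.5$ ≈50% under AH).

What the generator does **not** emulate: phylogenetic structure among
taxa, zero inflation beyond the DM's own zeros, library-size/biology
confounding, batch effects, or time-varying microbiome effects.  Passing
calibration tests on these synthetic tables therefore demonstrates
correctness of the inferential machinery under realistic sparsity and
confounding — not robustness to every failure mode of real amplicon data.

## Experiment harness and problem sizes

`run_type1()` / `run_power()` report global rejection fractions with exact
binomial Monte-Carlo standard errors; `run_fdr_sensitivity()` reports
taxon-level sensitivity $|A \cap \hat A|/|A|$ and empirical FDR
$\mathbb{E}[|\hat A \setminus A|/\max(|\hat A|, 1)]$ (the standard
convention; non-converged comparator fits count as non-detections).  The
taxon-by-taxon Cox comparator (`taxonwise_cox()`) fits each taxon with the
covariates and reports Wald p-values, BH-adjusted.

The packaged experiments use scaled-down sizes chosen once: type-I runs
with $R = 1000$ replicates, $J = 200$ taxa, $B = 1000$ permutations;
taxon-level runs with $R = 500$, $J = 100$ (50 confounded), $B = 2000$
(so BH detection is attainable, see above), and $\beta = 8$, which puts
the LDM tests in a moderate-sensitivity regime (~40–50%).  Full-scale
settings (e.g. $R = 10^4$, $J = 856$) remain configurable.  Replicate
seeds are derived deterministically from the experiment seed, and reports
are bit-reproducible from `(config, seed, R, B)`.

## Known limitations

* Global tests only for the distance-based methods; taxon-level results
  come from the LDM framework.
* No Firth-corrected Cox comparator, no phylogeny-aware (UniFrac)
  distances, no rarefaction-averaged ("all rarefactions") analyses —
  a single reproducible rarefaction (`rarefy()`) is provided.
* No clustered/longitudinal designs; subjects are assumed unrelated.
* Analytic (Davies-type) kernel p-values are not implemented; permutation
  p-values make small-sample corrections unnecessary but set a resolution
  floor of $1/(B+1)$.
* With very low sensitivity the combined taxon-level test can show minor
  FDR inflation, consistent with the behaviour reported for
  permutation-based FDR procedures in this regime.
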