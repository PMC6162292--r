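---
title: "Temporal eQTL mapping and causality testing: models, assumptions and design choices"
author: "teqtl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal eQTL mapping and causality testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teqtl)
set.seed(1)
```

## The problem

In a genotyped population whose expression traits are profiled at a handful
of timepoints (here, a time course of `m = 6` points per strain), a locus may
shape a trait's whole trajectory even when no single timepoint shows a
significant difference. `teqtl` provides association tests that treat the
time course as the unit of analysis (temporal eQTLs, "teQTLs"), and a
causality test that uses a shared locus plus temporal precedence to orient
the relationship between two linked traits.

## The temporal association model

The core test models the `m`-vector of one strain's trait as multivariate
normal. For genotype group $j$ the mean trajectory is a cubic polynomial in
the timepoint index,

$$ g_j(t) = \beta_{0j} + \beta_{1j} t + \beta_{2j} t^2 + \beta_{3j} t^3,
   \qquad t = 1, \dots, m, $$

and residuals are equicorrelated in the AR(1) sense,
$\Sigma = \sigma_e^2\, [\rho^{|s-t|}]_{st}$. A cubic is the lowest degree
that can express the non-monotone, twice-fluctuating shapes seen in short
expression time courses, and `m = 6` supports no more. The presence of a
teQTL is a likelihood-ratio test of one shared curve against per-genotype
curves; with $G$ genotype groups the statistic is referred to
$\chi^2_{4(G-1)}$ (one constraint per curve coefficient).

Three facts about the implementation are worth knowing:

* **Profiling.** For fixed $\rho$ the coefficients solve a per-group
  $4 \times 4$ linear system built from the tridiagonal quadratic form of
  the AR(1) inverse (`q_form()`), and $\sigma_e^2$ has a closed form, so
  only $\rho$ is searched: a grid over $[-0.99, 0.99]$ in steps of $0.01$
  followed by Brent refinement of the best bracket. The closed form used
  for $\sigma_e^2$ is the one obtained by differentiating the stated
  log-likelihood — the residual quadratic form averaged over all $mN$
  observations — and the stored log-likelihood is tested against a dense
  multivariate-normal log-density computed independently.
* **Degenerate fits.** $\sigma_e^2$ is floored at $10^{-12}$ so that exact
  (noiseless) interpolation keeps a defined log-likelihood; a rank-deficient
  time basis (fewer than 4 distinct timepoints) is an error, not a silent
  fallback.
* **Calibration.** The $\chi^2$ reference is advisory. On no-eQTL data the
  p-values show a mild liberal drift (QQ inflation factor around 1.1 at
  `N = 95`), which is why genome-wide error control goes through
  `permutation_fdr()`: strain labels of the genotype matrix are permuted, so
  the temporal correlation of every trait survives while genetic
  associations are destroyed. With $\rho$ forced to zero the test ranks
  datasets exactly as the stacked cubic regression F-test, its
  uncorrelated-residual counterpart.

The comparator methods (per-timepoint Wilcoxon at one timepoint; union and
product combinations over timepoints; MANOVA; stacked cubic regression;
lag-one AR F-test) are intentionally standard; the product combination is
kept as the raw product — a ranking score calibrated by permutation, not a
calibrated p-value, because the per-timepoint tests are strongly dependent.
Pillai's trace is the MANOVA default; for two genotype groups all four
classical statistics are monotone transformations of the single nonzero
eigenvalue and give identical p-values. The static Wilcoxon default (rather
than a t-test) matches how the comparison baseline is normally run on
non-normal expression data; both group sizes must be at least 2.

Time is encoded as the index $t = 1..m$. For the regression F-test any
affine re-encoding of time leaves the p-value unchanged (same column span);
for the AR(1) model the grid and profile behave identically, so the index
convention is a notational choice, not a modelling one.

## The causality test

For traits X and Y that share a locus, five lag-one structures are
considered: causal (M1, the locus acts on Y only through X), reactive (M2),
independent (M3), and partial causal/reactive (M4/M5). Each is a pair of
lag-one regressions stacked over `t = 2..m` and strains; genotype enters as
group-specific intercepts and lag coefficients, causality as the other
trait's lagged value. Log-likelihoods use the Gaussian profile form
$\ln \hat L = -\tfrac{n}{2}\ln(2\pi) - \tfrac{n}{2}\ln(\mathrm{RSS}) +
\tfrac{n}{2}\ln n - \tfrac{n}{2}$.

* **The sample size in the likelihood and BIC** is taken as the number of
  stacked regression observations, $n = N_\mathrm{strains} \times (m-1)$,
  isolated in one helper. The alternative reading (number of strains) only
  rescales all BICs jointly for M1/M3/M4 — the selected model is
  insensitive for equal-$n$ comparisons, but the observation count is the
  quantity the residual sum actually runs over.
* **Parameter counts** include regression coefficients only (M1: 3, M3: 4,
  M4: 5 for the Y-equation). The residual variance is profiled identically
  in every model, so counting it would shift all BICs equally.
* **Direction calls (M1 vs M2)** compare the joint likelihood
  $\ln\hat L(X) + \ln\hat L(Y)$; the two models have equal parameter
  counts, so likelihood and BIC comparisons coincide. The call is exactly
  antisymmetric under swapping the traits.
* **Cis–trans model selection (M1/M3/M4)** uses the Y-equation BIC only —
  the three structures share the X-equation, which therefore cancels. Ties
  break toward fewer parameters.
* **The association filter** (both traits at MPTGA p below $10^{-6}$ at the
  locus) is part of the procedure, not an optimisation: the causality
  models assume the locus acts on both traits, and the published operating
  characteristics are conditional on that filter.

Regulator ranking counts, per candidate cis gene, the trans-linked genes
whose best-supported structure is causal (M1 by default;
`count_partial = TRUE` adds M4, which the source analyses leave ambiguous).
Two caveats are structural rather than implementation choices. First,
duplicate or strongly correlated cis drivers receive tied counts and are all
reported — with one locus and six timepoints they are not statistically
distinguishable. Second, the lag models contain no explicit time term, so
the lagged value of *any* cis trait with a pronounced mean trajectory acts
partly as a time covariate and can absorb a trajectory-shaped genotype
effect; candidate sets should therefore be restricted to genuinely
cis-linked genes, and ranking interpreted as ordering candidates, not as a
certificate of uniqueness.

## What the synthetic-data module emulates

`pattern_library()` ships eight named cubic mean trajectories (flat,
increase, decrease, peak, dip, two S-shapes, saturating rise) spanning the
qualitative shapes of short expression time courses; the original study's
exact pattern set is not recoverable from its text, so this library defines
the package's study conditions. All simulation designs draw from it.

* **Association datasets** (`simulate_assoc_dataset()`): N strains, a fair
  Bernoulli genotype, and a trait drawn from the pattern model with a
  dataset-level $\rho \sim N(\mu_\rho, 0.02)$ truncated to $[0, 0.99]$;
  effect datasets use two distinct patterns, null datasets one. The
  method-comparison studies use `N = 50`, residual sd 4 against pattern
  amplitudes of order 1–2: per-timepoint standardised differences around
  0.3–0.5, which keeps every method's ROC in the mid-range where ranking
  differences are visible rather than saturated — the regime in which the
  published comparison operates.
* **Causal pairs** (`simulate_pair()`): X is a pattern-model trait with
  genotype-specific patterns and $\rho \sim N(0.8, 0.1)$; Y follows the
  chosen lag recursion with unit innovation sd. Y at `t = 1` is drawn from
  the stationary law of Y's own AR recursion (the recursion needs an
  anchor; the stationary choice adds no transient). The coefficient grid
  mixed over per replicate is $\beta_1 \in \{0.2, 0.4, 0.6, 0.8\}$,
  $\beta_2 \in \{0.3, 0.5, 0.8, 1.0\}$, genotype intercept offsets
  $\{0.5, 1.0\}$ — the exact grids behind the published accuracy figures
  are not recoverable, so this grid is the package's fixed stand-in.
  In the independent and partial-causal designs the genotype acts on Y's own
  dynamics: the two genotype groups draw their lag coefficients
  independently from the $\beta_1$ grid (the model's display has
  per-genotype lag coefficients; forcing them equal would simulate a
  degenerate special case).
* **Missing data** (`drop_missing()`): independent per-cell masking at
  rates 0.02–0.1, with the mask and the complete values retained so tests
  can check imputation against truth. Curve-based methods refit per-genotype
  cubics on complete strains and impute masked cells from the fitted curve;
  the per-timepoint methods drop incomplete strains, which is exactly why
  their power decays with the missing rate while the curve-based methods
  barely move. One honest caveat: filling masked cells from per-genotype
  curves injects group-specific values into null datasets, so in the
  mid-range operating regime the AR(1) polynomial test's discrimination
  degrades slightly more with missingness than the uncorrelated regression
  does; with strong effects (saturated ROC) the difference disappears.
* **Genotypes** (`simulate_genotypes()`): i.i.d. Bernoulli(0.5), or a
  linkage mode chaining neighbours with a per-strain flip probability so
  adjacent-marker concordance is $1 - p$ — enough LD structure for the
  confidence-interval and neighbour-transfer diagnostics, with no attempt
  to model recombination maps or real LD decay.

What passing these simulations does *not* show: real traits are not
multivariate normal with exactly AR(1) residuals, real LD is not a
flip-chain, and real effect sizes are not drawn from a grid. In particular,
the published real-data observation that the AR(1) association model
transfers better than the plain regression to LD neighbours (correlations
0.89 vs 0.69) is not reproduced by this generator: when the data really are
pattern-model draws, the regression method's extra significance is
strain-level and transfers across tightly linked markers just as well. The
neighbour-transfer diagnostic is therefore tested on its own guarantees
(perfect LD gives correlation 1, pure noise none, transfer decays as LD
weakens) and left to real data for the method contrast. Similarly, MANOVA —
which is close to the correct model class under this generator — does not
reproduce the published mid-correlation dip, and the lag-recursion
association method is the uniformly worst performer only in the
low-correlation regime here.

## Genome-scan utilities

* **Permutation FDR**: the estimate at cutoff $p$ is (mean permuted hits
  below $p$) / (real hits below $p$); the raw curve is reported alongside a
  monotone smoothing (running minimum from the large-$p$ end, q-value
  style) used for cutoff lookup. Ten permutations follow the source
  protocol; the expression matrix is never touched.
* **Hotspots**: fixed 20 kb bins, one peak marker per gene and chromosome
  (configurable to all significant markers), and the smallest count $N_0$
  whose binomial tail under uniform scattering falls below
  $\alpha / B$ for $B$ bins; adjacent significant bins merge. Bin
  coordinates are half-open `[start, end)` with 0-based starts.
* **Confidence intervals**: the marker-wise likelihood-ratio profile
  $R(d)$, the drop statistic $T(d_0) = \max_d R(d) - R(d_0)$, and the
  interval of positions with $T$ below the upper-$\alpha$ $\chi^2_{df}$
  critical value. The degrees of freedom are exposed (`df = 1` default)
  because the reference derivation leaves them design-dependent. On
  discrete maps with strong LD and strong effects the interval is
  conservative (coverage near 1); simulated coverage sits near the nominal
  95% in the moderate-effect regime the acceptance suite uses (`N = 95`,
  15 markers, neighbour concordance 0.9, residual sd 4).
* **Enrichment**: one-sided hypergeometric test plus fold enrichment, with
  the user supplying hit set, signature and universe as plain id vectors.

## Problem sizes used by the evaluation suites

The published accuracy surfaces are recomputed at a scale that a single CPU
handles comfortably: 2,000 filter-passing pairs per sample size (the source
used 10,000 simulated pairs), 2,000 datasets per autocorrelation regime for
the ROC comparisons, 500 replicates for degenerate-limit, coverage and
calibration checks, and 100 replicates for parameter recovery. At these
sizes the binomial/Monte-Carlo error of each reported fraction is well
inside the tolerances asserted.

## Known limitations

Six timepoints cap the mean model at a cubic and the causal models at lag
one; covariates, interactions beyond genotype-by-curve, mixed models and
count likelihoods are out of scope. The causality test addresses one pair
and one locus at a time — it is a screen for candidate regulators, not a
network reconstruction — and its documented blind spots (correlated cis
candidates; trajectory-shaped confounding of the lag term) are inherent to
the model class, not to this implementation.
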