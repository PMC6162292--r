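## Simulation studies: dataset-level generators and the study drivers that
## the evaluation suites and the acceptance script share. Study conditions
## (sample sizes, noise scales, coefficient grids) are fixed here once; see
## the methods vignette for the rationale behind each value.

#' Simulate one association-study dataset
#'
#' One dataset of the method-comparison design: `N` strains, a 0/1 genotype
#' split, and a trait drawn from the multivariate-normal pattern model. With
#' probability one half the dataset carries an eQTL effect (two distinct
#' patterns from the library), otherwise both groups share one pattern.
#'
#' @param N Number of strains.
#' @param rho_mean,rho_sd AR(1) correlation prior of the regime.
#' @param noise_sd Residual scale; the default 4 places detection in the
#'   mid-range (non-saturated) operating regime used for ROC comparisons.
#' @param effect `TRUE`/`FALSE` to force an effect or null dataset, or `NA`
#'   (default) to flip a fair coin.
#' @param m Number of timepoints.
#' @return List: `trait` (`N x m`), `genotype`, `effect` (logical).
#' @export
simulate_assoc_dataset <- function(N, rho_mean = 0.9, rho_sd = 0.02,
                                   noise_sd = 4, effect = NA, m = 6) {
  lib <- pattern_library()
  if (is.na(effect)) effect <- stats::runif(1) < 0.5
  g <- stats::rbinom(N, 1, 0.5)
  while (min(sum(g == 0), sum(g == 1)) < 2) g <- stats::rbinom(N, 1, 0.5)
  pats <- lib[sample(names(lib), if (effect) 2 else 1)]
  trait <- simulate_trait(sim_design(N, m, rho_mean, rho_sd, pats, noise_sd),
                          g)
  list(trait = trait, genotype = g, effect = effect)
}

## Area under the ROC curve of score -log10(p) for separating effect from
## null datasets, via the rank-sum statistic.
auc_from_pvalues <- function(p, truth) {
  score <- -log10(pmax(p, 1e-300))
  w <- suppressWarnings(stats::wilcox.test(score[truth], score[!truth],
                                           exact = FALSE))
  unname(w$statistic) / (sum(truth) * sum(!truth))
}

#' AUC comparison of association methods on simulated data
#'
#' Simulates `n_data` datasets (half with an eQTL effect, half null) in one
#' autocorrelation regime, runs each requested association method on every
#' dataset, and scores each method by the area under its ROC curve for
#' recovering the effect label. Optionally masks cells at a missing-data
#' rate first, in which case each method goes through its
#' [handle_missing()] path (curve-based methods impute, the others drop
#' incomplete strains).
#'
#' @param n_data Number of datasets (effect and null alternate).
#' @param N Strains per dataset.
#' @param rho_mean,rho_sd Autocorrelation regime.
#' @param noise_sd Residual scale (see [simulate_assoc_dataset()]).
#' @param methods Methods to score.
#' @param missing_rate Per-cell masking probability applied before testing.
#' @return Named numeric vector of AUCs.
#' @export
association_auc_study <- function(n_data = 2000, N = 50, rho_mean = 0.9,
                                  rho_sd = 0.02, noise_sd = 4,
                                  methods = c("mptga", "regression", "ar",
                                              "union", "fisher", "manova",
                                              "static"),
                                  missing_rate = 0) {
  p <- matrix(NA_real_, n_data, length(methods),
              dimnames = list(NULL, methods))
  truth <- logical(n_data)
  for (i in seq_len(n_data)) {
    d <- simulate_assoc_dataset(N, rho_mean, rho_sd, noise_sd,
                                effect = i %% 2 == 0)
    truth[i] <- d$effect
    trait <- if (missing_rate > 0) drop_missing(d$trait, missing_rate) else
      d$trait
    for (meth in methods) {
      p[i, meth] <- tryCatch(
        association_test(trait, d$genotype, method = meth)$p.value,
        error = function(e) NA_real_)
    }
  }
  apply(p, 2, function(col) {
    ok <- !is.na(col)
    auc_from_pvalues(col[ok], truth[ok])
  })
}

#' Direction accuracy of the causality test on simulated causal pairs
#'
#' Simulates trait pairs under the causal structure M1 (parameters drawn
#' uniformly from [tgct_sim_grid()], X carrying the genetic effect with
#' `rho ~ N(0.8, 0.1)`), keeps pairs where both traits pass the temporal
#' association filter at the locus, and calls direction by the joint
#' likelihood comparison of M1 vs M2.
#'
#' @param N Strains per pair.
#' @param n_retained Target number of filtered pairs.
#' @param max_pairs Simulation cap.
#' @param filter_p Association filter (MPTGA p-value) threshold.
#' @return List: `accuracy` (percent correct M1 calls among retained),
#'   `n_retained`, `n_simulated`.
#' @export
tgct_direction_study <- function(N, n_retained = 2000, max_pairs = 40 * n_retained,
                                 filter_p = 1e-6) {
  kept <- 0L
  correct <- 0L
  tried <- 0L
  while (kept < n_retained && tried < max_pairs) {
    tried <- tried + 1L
    g <- stats::rbinom(N, 1, 0.5)
    if (min(sum(g == 0), sum(g == 1)) < 2) next
    pr <- simulate_pair(random_causal_design("M1", N), g)
    if (mptga_test(pr$Y, g)$p.value >= filter_p) next
    if (mptga_test(pr$X, g)$p.value >= filter_p) next
    kept <- kept + 1L
    correct <- correct + (compare_m1_m2(pr$X, pr$Y, g)$call == "M1")
  }
  if (kept == 0) stop("no pairs passed the association filter")
  list(accuracy = 100 * correct / kept, n_retained = kept,
       n_simulated = tried)
}

#' Model-selection accuracy of the causality test on cis-trans pairs
#'
#' Simulates trait pairs under one generating structure (`M1`, `M3` or
#' `M4`), keeps pairs where both traits pass the association filter, selects
#' among M1/M3/M4 by the Y-equation BIC, and reports how often the
#' generating structure is recovered.
#'
#' @param model Generating structure.
#' @inheritParams tgct_direction_study
#' @return List: `accuracy` (percent recovering `model`), `n_retained`,
#'   `n_simulated`, `selected` (table of selected models).
#' @export
tgct_selection_study <- function(model = "M3", N, n_retained = 2000,
                                 max_pairs = 40 * n_retained,
                                 filter_p = 1e-6) {
  kept <- 0L
  tried <- 0L
  selected <- c(M1 = 0L, M3 = 0L, M4 = 0L)
  while (kept < n_retained && tried < max_pairs) {
    tried <- tried + 1L
    g <- stats::rbinom(N, 1, 0.5)
    if (min(sum(g == 0), sum(g == 1)) < 2) next
    pr <- simulate_pair(random_causal_design(model, N), g)
    if (mptga_test(pr$Y, g)$p.value >= filter_p) next
    if (mptga_test(pr$X, g)$p.value >= filter_p) next
    kept <- kept + 1L
    best <- select_cis_trans_model(pr$X, pr$Y, g)$best_model
    selected[best] <- selected[best] + 1L
  }
  if (kept == 0) stop("no pairs passed the association filter")
  list(accuracy = 100 * selected[[model]] / kept, n_retained = kept,
       n_simulated = tried, selected = selected)
}
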