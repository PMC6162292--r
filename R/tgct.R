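## Number of stacked lag-regression observations entering the TGCT
## likelihood and BIC: strains x (m - 1). Isolated here because the
## likelihood display reuses one symbol for sample size.
tgct_n_obs <- function(n_strains, m) n_strains * (m - 1L)

## Gaussian profile log-likelihood of a lag regression with residual sum of
## squares `rss` over `n` stacked observations:
## ln L = -n/2 ln(2*pi) - n/2 ln(rss) + n/2 ln(n) - n/2.
tgct_loglik <- function(rss, n) {
  rss <- max(rss, 1e-12)
  -n / 2 * log(2 * pi) - n / 2 * log(rss) + n / 2 * log(n) - n / 2
}

## Stacked lag frame for one trait: response t = 2..m, predictors at t-1.
lag_frame <- function(Z, other = NULL, genotype) {
  m <- ncol(Z)
  list(y = as.vector(Z[, -1]),
       zlag = as.vector(Z[, -m]),
       xlag = if (is.null(other)) NULL else as.vector(other[, -m]),
       d1 = rep(as.numeric(genotype), m - 1L))
}

## OLS on an explicit design matrix; returns coefficients and rss.
ols_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) stop("rank-deficient lag design (constant trait?)")
  list(coef = fit$coefficients, rss = sum(fit$residuals^2))
}

## Design matrices for the two equation shapes used by the causal models.
## split AR(1): per-genotype intercept and lag coefficient (4 parameters),
## optionally augmented with the other trait's lag (5).
design_split <- function(fr, with_xlag = FALSE) {
  d0 <- 1 - fr$d1
  X <- cbind(i0 = d0, l0 = d0 * fr$zlag, i1 = fr$d1, l1 = fr$d1 * fr$zlag)
  if (with_xlag) X <- cbind(X, xlag = fr$xlag)
  X
}

## pooled AR(1) plus the other trait's lag (3 parameters).
design_pooled_xlag <- function(fr) {
  cbind(i = 1, lag = fr$zlag, xlag = fr$xlag)
}

#' Fit the lag-one causal structures M1-M5 for a trait pair
#'
#' Fits any subset of the five genotype-anchored causal structures relating
#' traits X and Y at a shared locus, each by ordinary least squares on its
#' lag-one equations stacked over `t = 2..m` and strains:
#' * `M1` (X causes Y): genotype-split AR(1) for X; `Y_t ~ Y_{t-1} + X_{t-1}`.
#' * `M2` (Y causes X): the mirror image of M1.
#' * `M3` (independent): genotype-split AR(1) for both traits.
#' * `M4` (partial causal): genotype-split AR(1) for Y plus `X_{t-1}`.
#' * `M5` (partial reactive): the mirror image of M4.
#'
#' Each fit carries per-equation Gaussian profile log-likelihoods over the
#' `N * (m - 1)` stacked observations and a BIC computed from the Y-equation
#' (X-equation for M2/M5), `BIC = ln(n_obs) * k - 2 * loglik`, where `k`
#' counts that equation's regression coefficients.
#'
#' @param X,Y Numeric `N x m` trait matrices aligned on strains; X is the
#'   cis (locus-anchored) trait.
#' @param genotype Two-group 0/1 genotype vector.
#' @param models Character subset of `c("M1","M2","M3","M4","M5")`.
#' @return Named list of `tgct_fit` objects with fields `model`, `coef_x`,
#'   `coef_y`, `rss_x`, `rss_y`, `loglik_x`, `loglik_y`, `k`, `bic`, `n_obs`.
#' @export
fit_tgct_models <- function(X, Y, genotype,
                            models = c("M1", "M3", "M4")) {
  stopifnot(is.matrix(X), is.matrix(Y), all(dim(X) == dim(Y)),
            ncol(X) >= 2, length(genotype) == nrow(X))
  if (anyNA(X) || anyNA(Y)) stop("masked cells; impute first")
  models <- match.arg(models, c("M1", "M2", "M3", "M4", "M5"),
                      several.ok = TRUE)
  labels <- two_group_labels(genotype)
  g01 <- as.integer(genotype == labels[2])
  if (min(sum(g01 == 0), sum(g01 == 1)) < 2)
    stop("every genotype group must contain at least 2 strains")
  frx <- lag_frame(X, Y, g01)
  fry <- lag_frame(Y, X, g01)
  n_obs <- tgct_n_obs(nrow(X), ncol(X))

  one <- function(model) {
    spec <- switch(model,
      M1 = list(x = design_split(frx), y = design_pooled_xlag(fry), eq = "y"),
      M2 = list(x = design_pooled_xlag(frx), y = design_split(fry), eq = "x"),
      M3 = list(x = design_split(frx), y = design_split(fry), eq = "y"),
      M4 = list(x = design_split(frx), y = design_split(fry, TRUE), eq = "y"),
      M5 = list(x = design_split(frx, TRUE), y = design_split(fry), eq = "x"))
    fx <- ols_fit(spec$x, frx$y)
    fy <- ols_fit(spec$y, fry$y)
    llx <- tgct_loglik(fx$rss, n_obs)
    lly <- tgct_loglik(fy$rss, n_obs)
    k <- if (spec$eq == "y") ncol(spec$y) else ncol(spec$x)
    ll <- if (spec$eq == "y") lly else llx
    structure(list(model = model, coef_x = fx$coef, coef_y = fy$coef,
                   rss_x = fx$rss, rss_y = fy$rss,
                   loglik_x = llx, loglik_y = lly,
                   k = k, bic = log(n_obs) * k - 2 * ll, n_obs = n_obs),
              class = "tgct_fit")
  }
  stats::setNames(lapply(models, one), models)
}

#' Direction call between causal (M1) and reactive (M2) structures
#'
#' Compares the joint log-likelihood `ln L(X) + ln L(Y)` under M1 (X causes
#' Y) and M2 (Y causes X). The two models have the same parameter count, so
#' the likelihood comparison and a BIC comparison are equivalent. Both traits
#' are expected to pass the temporal association filter at the shared locus
#' first (the pair-level analysis enforces MPTGA p below `filter_p`).
#'
#' @inheritParams fit_tgct_models
#' @param x_p,y_p Optional MPTGA association p-values of X and Y at the
#'   locus; when supplied, a pair failing `filter_p` is an error.
#' @param filter_p Association filter threshold (default `1e-6`).
#' @return A one-row data.frame: `call` (`"M1"` or `"M2"`), `loglr`
#'   (`ln L(M1) - ln L(M2)`), joint log-likelihoods of both models.
#' @export
compare_m1_m2 <- function(X, Y, genotype, x_p = NULL, y_p = NULL,
                          filter_p = 1e-6) {
  if (!is.null(x_p) && !is.null(y_p) && (x_p >= filter_p || y_p >= filter_p))
    stop("pair fails the association filter (MPTGA p >= ", filter_p, ")")
  fits <- fit_tgct_models(X, Y, genotype, models = c("M1", "M2"))
  ll1 <- fits$M1$loglik_x + fits$M1$loglik_y
  ll2 <- fits$M2$loglik_x + fits$M2$loglik_y
  data.frame(call = if (ll1 >= ll2) "M1" else "M2",
             loglr = ll1 - ll2, loglik_m1 = ll1, loglik_m2 = ll2,
             stringsAsFactors = FALSE)
}

#' BIC model selection for a cis-trans trait pair
#'
#' For X with a cis association and Y with a trans association at the same
#' locus, the candidate structures reduce to M1 (causal), M3 (independent)
#' and M4 (partial causal), which share the X-equation; selection therefore
#' uses the Y-equation BIC only. Ties are broken toward the model with fewer
#' parameters (M1 with 3, then M3 with 4, then M4 with 5).
#'
#' @inheritParams fit_tgct_models
#' @return A one-row data.frame: `best_model`, `bic_margin` (second best
#'   minus best), `bic_m1`, `bic_m3`, `bic_m4`.
#' @export
select_cis_trans_model <- function(X, Y, genotype) {
  fits <- fit_tgct_models(X, Y, genotype, models = c("M1", "M3", "M4"))
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  ord <- order(bic, c(M1 = 1, M3 = 2, M4 = 3)[names(bic)])
  data.frame(best_model = names(bic)[ord[1]],
             bic_margin = bic[ord[2]] - bic[ord[1]],
             bic_m1 = bic[["M1"]], bic_m3 = bic[["M3"]],
             bic_m4 = bic[["M4"]], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Run the causality test over all cis-trans pairs at a hotspot
#'
#' @param expression Named list of trait matrices.
#' @param genotype Genotype vector at the hotspot's peak marker.
#' @param cis_genes,trans_genes Gene-id vectors: candidate causal (cis)
#'   genes and trans-linked genes at the hotspot.
#' @param marker Marker id recorded in the output.
#' @return Data.frame with one row per cis x trans pair: `x_gene`, `y_gene`,
#'   `marker`, `best_model`, BICs and `bic_margin`.
#' @export
tgct_pairs <- function(expression, genotype, cis_genes, trans_genes,
                       marker = "marker") {
  if (length(cis_genes) == 0) stop("no cis genes at hotspot")
  rows <- list()
  for (xg in cis_genes) {
    for (yg in setdiff(trans_genes, xg)) {
      sel <- select_cis_trans_model(expression[[xg]], expression[[yg]],
                                    genotype)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(x_gene = xg, y_gene = yg, marker = marker,
                         stringsAsFactors = FALSE), sel)
    }
  }
  if (length(rows) == 0)
    return(data.frame(x_gene = character(), y_gene = character(),
                      marker = character(), best_model = character(),
                      bic_margin = numeric(), bic_m1 = numeric(),
                      bic_m3 = numeric(), bic_m4 = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Rank candidate causal regulators of a hotspot
#'
#' Counts, per cis gene, the trans genes whose best-supported structure is
#' causal (`M1`; optionally also partial causal `M4`), ranks cis genes by
#' that count, and flags those meeting the hotspot cutoff as putative key
#' regulators. Cis genes with tied counts are all reported: the test cannot
#' distinguish between duplicate cis drivers of the same targets.
#'
#' @param calls Data.frame from [tgct_pairs()].
#' @param hotspot_cutoff Minimum number of causal edges to flag a regulator
#'   (the hotspot-defining count is the natural choice).
#' @param count_partial Also count `M4` calls as causal edges.
#' @return Data.frame: `x_gene`, `n_causal`, `is_regulator`, ranked by
#'   descending count.
#' @export
rank_regulators <- function(calls, hotspot_cutoff = 1L,
                            count_partial = FALSE) {
  if (nrow(calls) == 0)
    return(data.frame(x_gene = character(), n_causal = integer(),
                      is_regulator = logical(), stringsAsFactors = FALSE))
  causal_models <- if (count_partial) c("M1", "M4") else "M1"
  cis <- unique(calls$x_gene)
  n_causal <- vapply(cis, function(g)
    sum(calls$x_gene == g & calls$best_model %in% causal_models), integer(1))
  out <- data.frame(x_gene = cis, n_causal = n_causal,
                    is_regulator = n_causal >= hotspot_cutoff,
                    stringsAsFactors = FALSE)
  out[order(-out$n_causal, out$x_gene), , drop = FALSE]
}
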