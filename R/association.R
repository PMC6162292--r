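## Per-timepoint Wilcoxon rank-sum p-value between genotype groups, NA cells
## dropped. Exact enumeration for small tie-free groups, normal approximation
## with tie correction otherwise (wilcox.test's own switching rule).
timepoint_wilcoxon <- function(y, genotype, labels) {
  a <- y[genotype == labels[1]]
  b <- y[genotype == labels[2]]
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (all(c(a, b) == c(a, b)[1])) return(1)
  suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
}

two_group_labels <- function(genotype) {
  labels <- sort(unique(genotype))
  if (length(labels) != 2)
    stop("this test requires exactly 2 genotype groups; recode diploid ",
         "genotypes (dominant/recessive) upstream")
  labels
}

#' Single-timepoint (static) association test
#'
#' Wilcoxon rank-sum test of the trait at one timepoint between the two
#' genotype groups, the baseline any time-aware method is compared against.
#'
#' @param trait Numeric `N x m` matrix; `NA` cells are dropped.
#' @param genotype Two-group genotype vector.
#' @param timepoint Column index tested (default 1, the pre-treatment
#'   baseline).
#' @param gene,marker Identifiers for the returned record.
#' @return One-row association record (see [mptga_test()]).
#' @export
static_test <- function(trait, genotype, timepoint = 1L,
                        gene = "trait", marker = "marker") {
  stopifnot(is.matrix(trait), timepoint >= 1, timepoint <= ncol(trait))
  labels <- two_group_labels(genotype)
  p <- timepoint_wilcoxon(trait[, timepoint], genotype, labels)
  if (is.na(p)) stop("fewer than 2 unmasked strains per group at timepoint ",
                     timepoint)
  assoc_record(gene, marker, "static", p, p)
}

#' Union association test over timepoints
#'
#' Runs the per-timepoint Wilcoxon test at every timepoint and takes the
#' minimum p-value; a trait is linked if it is linked at any timepoint.
#' Masked timepoints (fewer than 2 unmasked strains in a group) are excluded
#' from the minimum. All per-timepoint p-values are kept in attribute
#' `"p_time"`.
#'
#' @inheritParams static_test
#' @export
union_test <- function(trait, genotype, gene = "trait", marker = "marker") {
  labels <- two_group_labels(genotype)
  p_t <- vapply(seq_len(ncol(trait)), function(t)
    timepoint_wilcoxon(trait[, t], genotype, labels), numeric(1))
  if (all(is.na(p_t))) stop("all timepoints degenerate")
  p <- min(p_t, na.rm = TRUE)
  rec <- assoc_record(gene, marker, "union", p, p)
  attr(rec, "p_time") <- p_t
  rec
}

#' Fisher product score over timepoints
#'
#' Multiplies the per-timepoint Wilcoxon p-values. The product is a ranking
#' score, not a calibrated p-value (the per-timepoint tests are correlated);
#' significance is assessed by [permutation_fdr()]. The record stores the
#' product in both the statistic and p-value columns and keeps the
#' per-timepoint p-values in attribute `"p_time"`.
#'
#' @inheritParams static_test
#' @export
fisher_test <- function(trait, genotype, gene = "trait", marker = "marker") {
  labels <- two_group_labels(genotype)
  p_t <- vapply(seq_len(ncol(trait)), function(t)
    timepoint_wilcoxon(trait[, t], genotype, labels), numeric(1))
  if (all(is.na(p_t))) stop("all timepoints degenerate")
  score <- prod(p_t, na.rm = TRUE)
  rec <- assoc_record(gene, marker, "fisher", score, score)
  attr(rec, "p_time") <- p_t
  rec
}

#' MANOVA association test
#'
#' One-way multivariate analysis of variance of the `m`-dimensional trait on
#' genotype, testing equality of the group mean vectors at all timepoints
#' jointly. Pillai's trace is the default statistic; with two groups all four
#' classical MANOVA statistics are monotone-equivalent. Strains with any
#' masked cell are dropped.
#'
#' @inheritParams static_test
#' @param statistic MANOVA statistic passed to `summary.manova`.
#' @export
manova_test <- function(trait, genotype, statistic = "Pillai",
                        gene = "trait", marker = "marker") {
  stopifnot(is.matrix(trait))
  keep <- stats::complete.cases(trait)
  y <- trait[keep, , drop = FALSE]
  g <- factor(genotype[keep])
  if (nlevels(g) < 2) stop("fewer than 2 genotype groups after masking")
  if (nrow(y) <= ncol(y) + nlevels(g))
    stop("too few complete strains for MANOVA (N <= m + groups)")
  if (ncol(y) == 1) {
    fit <- stats::aov(y[, 1] ~ g)
    tab <- summary(fit)[[1]]
    return(assoc_record(gene, marker, "manova",
                        tab[["F value"]][1], tab[["Pr(>F)"]][1]))
  }
  fit <- stats::manova(y ~ g)
  tab <- summary(fit, test = statistic)$stats
  assoc_record(gene, marker, "manova", tab[1, "approx F"], tab[1, "Pr(>F)"])
}

## Stacked long-format design for the curve-based tests.
stack_trait <- function(trait, genotype, times) {
  n <- nrow(trait)
  m <- ncol(trait)
  data.frame(y = as.vector(t(trait)),
             t = rep(times, n),
             g = factor(rep(genotype, each = m)))
}

#' Cubic regression association test
#'
#' Stacks all observations (`m` per strain) and compares the reduced model,
#' one shared cubic polynomial in time (4 parameters), against the full
#' model with a separate cubic per genotype group (`4G` parameters) by F-test.
#' Residuals are treated as independent; this is the uncorrelated-residual
#' counterpart of [mptga_test()].
#'
#' @inheritParams static_test
#' @param times Timepoint grid; defaults to `1:m`.
#' @export
regression_test <- function(trait, genotype, times = NULL,
                            gene = "trait", marker = "marker") {
  stopifnot(is.matrix(trait))
  if (anyNA(trait))
    stop("`trait` contains masked cells; impute first (see handle_missing)")
  m <- ncol(trait)
  if (m < 4) stop("need at least 4 timepoints for a cubic fit")
  if (is.null(times)) times <- seq_len(m)
  d <- stack_trait(trait, genotype, times)
  if (nlevels(d$g) < 2) stop("need at least 2 genotype groups")
  reduced <- stats::lm(y ~ poly(t, 3, raw = TRUE), data = d)
  full <- stats::lm(y ~ 0 + g + g:poly(t, 3, raw = TRUE), data = d)
  an <- stats::anova(reduced, full)
  assoc_record(gene, marker, "regression", an$F[2], an$`Pr(>F)`[2])
}

#' Lag-one autoregressive association test
#'
#' Regresses `Y_t` on `Y_{t-1}` over `t = 2..m`, stacked across strains, and
#' compares the pooled recursion (2 parameters) against genotype-specific
#' intercepts and lag coefficients (`2G` parameters) by F-test.
#'
#' @inheritParams static_test
#' @export
ar_test <- function(trait, genotype, gene = "trait", marker = "marker") {
  stopifnot(is.matrix(trait), ncol(trait) >= 2)
  if (anyNA(trait))
    stop("`trait` contains masked cells; impute first (see handle_missing)")
  m <- ncol(trait)
  d <- data.frame(y = as.vector(trait[, -1]),
                  ylag = as.vector(trait[, -m]),
                  g = factor(rep(genotype, m - 1L)))
  if (nlevels(d$g) < 2) stop("need at least 2 genotype groups")
  reduced <- stats::lm(y ~ ylag, data = d)
  full <- stats::lm(y ~ 0 + g + g:ylag, data = d)
  an <- stats::anova(reduced, full)
  assoc_record(gene, marker, "ar", an$F[2], an$`Pr(>F)`[2])
}

#' Handle missing cells for a given association method
#'
#' For the curve-fitting methods (`mptga`, `regression`, `ar`) strains with
#' masked cells are set aside, the method's curve is fitted per genotype group
#' on the complete strains, masked cells are imputed from the fitted curves,
#' and the completed matrix is returned. For the remaining methods (`static`,
#' `union`, `fisher`, `manova`) strains with masked cells are dropped
#' entirely (those tests are then run on the reduced matrix).
#'
#' @param trait Numeric `N x m` matrix with `NA` for masked cells (e.g. from
#'   [drop_missing()]).
#' @param genotype Genotype vector (needed for the per-group curve fits; may
#'   be `NULL` for a pooled curve).
#' @param method Association method name.
#' @param times Timepoint grid; defaults to `1:m`.
#' @return A completed (impute path) or row-reduced (mask path) matrix.
#' @export
handle_missing <- function(trait, genotype = NULL,
                           method = c("mptga", "regression", "ar", "static",
                                      "union", "fisher", "manova"),
                           times = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(trait))
  if (!anyNA(trait)) return(trait)
  m <- ncol(trait)
  if (is.null(times)) times <- seq_len(m)
  if (method %in% c("static", "union", "fisher", "manova")) {
    out <- trait[stats::complete.cases(trait), , drop = FALSE]
    attr(out, "kept") <- which(stats::complete.cases(trait))
    return(out)
  }
  complete <- stats::complete.cases(trait)
  groups <- if (is.null(genotype)) rep(0L, nrow(trait)) else genotype
  out <- trait
  for (g in unique(groups)) {
    rows <- groups == g
    fit_rows <- rows & complete
    if (sum(fit_rows) < 2)
      stop("no usable complete strains in group ", g, " to fit a curve")
    if (method == "ar") {
      ## lag-one recursion fitted on complete strains, masked cells filled
      ## forward from the previous observed value
      d <- data.frame(y = as.vector(trait[fit_rows, -1, drop = FALSE]),
                      ylag = as.vector(trait[fit_rows, -m, drop = FALSE]))
      cf <- stats::coef(stats::lm(y ~ ylag, data = d))
      for (i in which(rows & !complete)) {
        for (t in seq_len(m)) {
          if (is.na(out[i, t])) {
            out[i, t] <- if (t == 1) mean(trait[fit_rows, 1]) else
              cf[1] + cf[2] * out[i, t - 1]
          }
        }
      }
    } else {
      ## cubic mean trajectory fitted on complete strains of the group
      d <- data.frame(y = as.vector(t(trait[fit_rows, , drop = FALSE])),
                      t = rep(times, sum(fit_rows)))
      cf <- stats::coef(stats::lm(y ~ poly(t, 3, raw = TRUE), data = d))
      fitted_curve <- eval_pattern(unname(cf), times)
      for (i in which(rows & !complete)) {
        nai <- is.na(out[i, ])
        out[i, nai] <- fitted_curve[nai]
      }
    }
  }
  out
}

#' Run one association method on one trait/marker pair
#'
#' Dispatcher used by [teqtl_scan()]; applies [handle_missing()] first when
#' the trait has masked cells.
#'
#' @inheritParams static_test
#' @param method Association method name.
#' @param ... Passed to the individual test.
#' @export
association_test <- function(trait, genotype,
                             method = c("mptga", "regression", "ar", "static",
                                        "union", "fisher", "manova"),
                             gene = "trait", marker = "marker", ...) {
  method <- match.arg(method)
  if (anyNA(trait)) {
    trait2 <- handle_missing(trait, genotype, method)
    kept <- attr(trait2, "kept")
    if (!is.null(kept)) genotype <- genotype[kept]
    trait <- trait2
  }
  fun <- switch(method, mptga = mptga_test, regression = regression_test,
                ar = ar_test, static = static_test, union = union_test,
                fisher = fisher_test, manova = manova_test)
  fun(trait, genotype, gene = gene, marker = marker, ...)
}

#' Scan all gene x marker pairs with one association method
#'
#' @param expression Named list of `N x m` trait matrices (one per gene) with
#'   identical strain order, e.g. from [read_expression()].
#' @param genotypes `N x M` genotype matrix (strains x markers).
#' @param method Association method name.
#' @param ... Passed to [association_test()].
#' @return Data.frame of association records, gene-major, marker-minor.
#' @export
teqtl_scan <- function(expression, genotypes,
                       method = c("mptga", "regression", "ar", "static",
                                  "union", "fisher", "manova"), ...) {
  method <- match.arg(method)
  stopifnot(is.list(expression), is.matrix(genotypes))
  genes <- names(expression)
  if (is.null(genes)) genes <- paste0("g", seq_along(expression))
  markers <- colnames(genotypes)
  if (is.null(markers)) markers <- paste0("m", seq_len(ncol(genotypes)))
  out <- vector("list", length(genes) * length(markers))
  k <- 0L
  for (i in seq_along(genes)) {
    for (j in seq_along(markers)) {
      k <- k + 1L
      out[[k]] <- association_test(expression[[i]], genotypes[, j],
                                   method = method, gene = genes[i],
                                   marker = markers[j], ...)
    }
  }
  do.call(rbind, out)
}
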