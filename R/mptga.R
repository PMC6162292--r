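#' AR(1) quadratic form
#'
#' Computes `Q(rho, U, V) = U %*% solve(ar1_cor(rho, m)) %*% V` through the
#' closed tridiagonal form of the AR(1) inverse, without building the matrix.
#'
#' @param rho AR(1) correlation, `|rho| < 1`.
#' @param U,V Numeric vectors of equal length `m >= 2`.
#' @return A scalar.
#' @export
q_form <- function(rho, U, V) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  m <- length(U)
  stopifnot(m == length(V), m >= 2)
  inner <- if (m > 2) sum(U[2:(m - 1)] * V[2:(m - 1)]) else 0
  (U[1] * V[1] + U[m] * V[m] -
     rho * sum(U[-m] * V[-1] + U[-1] * V[-m]) +
     (1 + rho^2) * inner) / (1 - rho^2)
}

## Polynomial basis 1, t, t^2, t^3 on the time grid.
cubic_basis <- function(times) {
  outer(times, 0:3, "^")
}

## Validate a trait matrix + genotype vector; returns 0-based group index and
## group labels. genotype = NULL encodes the pooled single-group (null) fit.
split_groups <- function(trait, genotype) {
  if (!is.matrix(trait) || !is.numeric(trait))
    stop("`trait` must be a numeric strains x timepoints matrix")
  if (anyNA(trait))
    stop("`trait` contains masked cells; impute first (see handle_missing)")
  n <- nrow(trait)
  if (is.null(genotype))
    return(list(index = integer(n), labels = "pooled", G = 1L))
  if (length(genotype) != n)
    stop("`genotype` length must match nrow(trait)")
  labels <- sort(unique(genotype))
  if (length(labels) < 2)
    stop("genotype is constant; use genotype = NULL for a pooled fit")
  idx <- match(genotype, labels) - 1L
  sizes <- tabulate(idx + 1L, length(labels))
  if (any(sizes < 2))
    stop("every genotype group must contain at least 2 strains")
  list(index = idx, labels = labels, G = length(labels))
}

#' Fit the polynomial AR(1) multivariate-normal association model
#'
#' Fits per-genotype cubic mean trajectories with AR(1)-correlated residuals
#' by profiling the likelihood over the AR(1) correlation `rho`: for each
#' candidate `rho` the polynomial coefficients solve a per-group 4x4 linear
#' system and the residual scale has a closed form, so only `rho` is searched
#' numerically (a grid pass followed by Brent refinement of the best bracket).
#'
#' @param trait Numeric `N x m` matrix (`m >= 4`), no missing cells.
#' @param genotype Genotype vector splitting strains into groups (haploid 0/1
#'   or diploid 0/1/2), or `NULL` for the pooled single-curve (null) fit.
#' @param rho Optional fixed value of the AR(1) correlation; `NULL` (default)
#'   profiles it. `rho = 0` reproduces the independence-of-residuals model.
#' @param rho_grid Grid searched before refinement.
#' @param times Timepoint grid; defaults to `1:m`.
#' @return An object of class `mptga_fit`: list with `beta` (4 x G coefficient
#'   matrix), `rho`, `sigma2`, `loglik`, `n_groups`, `groups`, `n`, `m`,
#'   `times`.
#' @export
fit_mptga <- function(trait, genotype = NULL, rho = NULL,
                      rho_grid = seq(-0.99, 0.99, by = 0.01), times = NULL) {
  sp <- split_groups(trait, genotype)
  m <- ncol(trait)
  if (m < 4) stop("need at least 4 timepoints for a cubic mean trajectory")
  if (is.null(times)) times <- seq_len(m)
  stopifnot(length(times) == m)
  basis <- cubic_basis(times)
  if (qr(basis)$rank < 4L) stop("degenerate time grid: cubic basis is singular")
  storage.mode(trait) <- "double"
  if (is.null(rho)) {
    ll <- mptga_profile_cpp(trait, sp$index, sp$G, basis, rho_grid)
    best <- which.max(ll)
    lo <- rho_grid[max(1L, best - 1L)]
    hi <- rho_grid[min(length(rho_grid), best + 1L)]
    opt <- stats::optimize(function(r)
      mptga_profile_cpp(trait, sp$index, sp$G, basis, r),
      lower = lo, upper = hi, maximum = TRUE, tol = 1e-6)
    rho_hat <- if (opt$objective >= ll[best]) opt$maximum else rho_grid[best]
  } else {
    if (abs(rho) >= 1) stop("|rho| must be < 1")
    rho_hat <- rho
  }
  fit <- mptga_fit_cpp(trait, sp$index, sp$G, basis, rho_hat)
  beta <- matrix(fit$beta, 4L, sp$G,
                 dimnames = list(c("b0", "b1", "b2", "b3"),
                                 as.character(sp$labels)))
  structure(list(beta = beta, rho = rho_hat, sigma2 = fit$sigma2,
                 loglik = fit$loglik, n_groups = sp$G, groups = sp$labels,
                 n = nrow(trait), m = m, times = times),
            class = "mptga_fit")
}

#' @export
print.mptga_fit <- function(x, ...) {
  cat(sprintf("MPTGA fit: %d strains x %d timepoints, %d group(s)\n",
              x$n, x$m, x$n_groups))
  cat(sprintf("  rho = %.4f  sigma2 = %.4g  loglik = %.3f\n",
              x$rho, x$sigma2, x$loglik))
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
logLik.mptga_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- 4L * object$n_groups + 2L
  class(val) <- "logLik"
  val
}

## One-row association record shared by all tests.
assoc_record <- function(gene, marker, method, statistic, p_value) {
  data.frame(gene = gene, marker = marker, method = method,
             statistic = statistic, p.value = p_value,
             stringsAsFactors = FALSE)
}

#' Temporal genetic association test by likelihood ratio (MPTGA)
#'
#' Compares the per-genotype-curve full model against the pooled single-curve
#' null model, both fit with [fit_mptga()], and refers twice the
#' log-likelihood ratio to a chi-square with `4 * (G - 1)` degrees of freedom
#' (the number of constrained mean-curve coefficients). The nominal p-value is
#' advisory: genome-wide error control should use [permutation_fdr()].
#'
#' @inheritParams fit_mptga
#' @param gene,marker Identifiers copied into the returned record.
#' @return One-row data.frame: `gene`, `marker`, `method`, `statistic`,
#'   `p.value`, with the two fits attached as attributes `fit_full` and
#'   `fit_null`.
#' @export
mptga_test <- function(trait, genotype, rho = NULL,
                       gene = "trait", marker = "marker", times = NULL) {
  full <- fit_mptga(trait, genotype, rho = rho, times = times)
  null <- fit_mptga(trait, NULL, rho = rho, times = times)
  stat <- max(0, 2 * (full$loglik - null$loglik))
  df <- 4L * (full$n_groups - 1L)
  rec <- assoc_record(gene, marker, "mptga", stat,
                      stats::pchisq(stat, df = df, lower.tail = FALSE))
  attr(rec, "fit_full") <- full
  attr(rec, "fit_null") <- null
  rec
}
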