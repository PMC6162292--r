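#' Simulation design for a single temporal trait
#'
#' Bundles the parameters of the multivariate-normal generating model used in
#' the association power studies: per-genotype cubic mean patterns, an AR(1)
#' residual correlation whose value is drawn once per dataset from a truncated
#' normal, and an i.i.d.-scale residual standard deviation.
#'
#' @param n_strains Number of strains (N, at least 2).
#' @param n_timepoints Number of timepoints (m, at least 4; default 6).
#' @param rho_mean,rho_sd Mean and sd of the normal from which the dataset's
#'   AR(1) correlation is drawn; draws are truncated to `[0, 0.99]`.
#' @param patterns List of one or two coefficient 4-vectors: the mean
#'   trajectory for genotype group 0 and (optionally) group 1. A single
#'   pattern (or two identical ones) encodes the no-eQTL null.
#' @param noise_sd Residual standard deviation `sigma_e` (> 0).
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_strains = 95, n_timepoints = 6,
                       rho_mean = 0.9, rho_sd = 0.02,
                       patterns = pattern_library()[c("increase", "peak")],
                       noise_sd = 1) {
  stopifnot(n_strains >= 2, n_timepoints >= 4, noise_sd > 0,
            is.list(patterns), length(patterns) %in% c(1, 2))
  structure(list(n_strains = as.integer(n_strains),
                 n_timepoints = as.integer(n_timepoints),
                 rho_mean = rho_mean, rho_sd = rho_sd,
                 patterns = patterns, noise_sd = noise_sd),
            class = "sim_design")
}

#' AR(1) correlation matrix
#'
#' @param rho AR(1) correlation, `|rho| < 1`.
#' @param m Dimension.
#' @return An `m x m` matrix with entries `rho^|i-j|`.
#' @export
ar1_cor <- function(rho, m) {
  stopifnot(abs(rho) < 1, m >= 1)
  rho^abs(outer(seq_len(m), seq_len(m), "-"))
}

## One truncated-normal rho draw per dataset; negative draws clipped to 0,
## draws above 0.99 clipped to 0.99 (the generating designs use positive rho).
draw_rho <- function(mean, sd) {
  min(max(stats::rnorm(1, mean, sd), 0), 0.99)
}

#' Simulate a time-course trait matrix
#'
#' Each strain's `m`-vector is drawn from a multivariate normal whose mean is
#' its genotype group's pattern evaluated at `t = 1..m` and whose covariance
#' is `noise_sd^2 * ar1_cor(rho, m)`, with a single `rho` drawn per dataset
#' from `N(rho_mean, rho_sd)` truncated to `[0, 0.99]`.
#'
#' @param design A [sim_design()].
#' @param genotypes Integer 0/1 vector of length `n_strains`. Group 1 uses the
#'   second pattern when present, otherwise the first.
#' @return Numeric `N x m` matrix with attribute `"rho"` (the drawn value) and
#'   `"times"` (`1:m`).
#' @export
simulate_trait <- function(design, genotypes) {
  stopifnot(inherits(design, "sim_design"))
  n <- design$n_strains
  m <- design$n_timepoints
  if (length(genotypes) != n)
    stop("`genotypes` must have length n_strains (", n, ")")
  if (!all(genotypes %in% c(0, 1)))
    stop("`genotypes` must be coded 0/1")
  rho <- draw_rho(design$rho_mean, design$rho_sd)
  times <- seq_len(m)
  pat <- design$patterns
  mu0 <- eval_pattern(pat[[1]], times)
  mu1 <- if (length(pat) == 2) eval_pattern(pat[[2]], times) else mu0
  cl <- chol(ar1_cor(rho, m))
  z <- matrix(stats::rnorm(n * m), n, m) %*% cl * design$noise_sd
  mu <- matrix(mu0, n, m, byrow = TRUE)
  g1 <- genotypes == 1
  if (any(g1)) mu[g1, ] <- matrix(mu1, sum(g1), m, byrow = TRUE)
  y <- mu + z
  dimnames(y) <- list(paste0("s", seq_len(n)), paste0("t", times))
  attr(y, "rho") <- rho
  attr(y, "times") <- times
  y
}

#' Simulate a genotype table
#'
#' Marker codes are i.i.d. Bernoulli(0.5) per cell. In linkage mode
#' (`flip_prob` not `NULL`) the first marker is Bernoulli(0.5) and each
#' subsequent marker copies its left neighbour, flipping independently per
#' strain with probability `flip_prob`, giving adjacent-marker concordance
#' `1 - flip_prob`.
#'
#' @param n_strains,n_markers Positive counts.
#' @param flip_prob Optional per-strain flip probability chaining neighbouring
#'   markers (linkage mode); `NULL` for independent markers.
#' @param chrom Chromosome label for the marker map.
#' @param spacing Marker spacing in bp for the marker map positions.
#' @return A list with `genotypes` (strains x markers 0/1 matrix) and
#'   `map` (data.frame: marker, chrom, pos).
#' @export
simulate_genotypes <- function(n_strains, n_markers, flip_prob = NULL,
                               chrom = "chr1", spacing = 20000L) {
  stopifnot(n_strains >= 1, n_markers >= 1)
  g <- matrix(0L, n_strains, n_markers)
  g[, 1] <- stats::rbinom(n_strains, 1, 0.5)
  if (n_markers > 1) {
    if (is.null(flip_prob)) {
      g[, -1] <- stats::rbinom(n_strains * (n_markers - 1), 1, 0.5)
    } else {
      stopifnot(flip_prob >= 0, flip_prob <= 1)
      for (j in 2:n_markers) {
        flip <- stats::rbinom(n_strains, 1, flip_prob)
        g[, j] <- ifelse(flip == 1, 1L - g[, j - 1], g[, j - 1])
      }
    }
  }
  dimnames(g) <- list(paste0("s", seq_len(n_strains)),
                      paste0("m", seq_len(n_markers)))
  map <- data.frame(marker = colnames(g), chrom = chrom,
                    pos = as.integer(seq_len(n_markers)) * spacing,
                    stringsAsFactors = FALSE)
  list(genotypes = g, map = map)
}

#' Design for a simulated causal trait pair
#'
#' Describes how a pair of traits (X, Y) sharing a locus is generated. X
#' always carries the genetic effect: it is drawn from the multivariate-normal
#' pattern model with per-genotype patterns and `rho ~ N(0.8, 0.1)`. Y is then
#' built recursively from the lag-one equation of the chosen causal structure:
#' `"M1"` (X causes Y: `Y_t = b0 + b1*Y_{t-1} + b2*X_{t-1} + noise`),
#' `"M3"` (independent: genotype-split AR(1) for Y), or `"M4"` (partial
#' causal: genotype-split AR(1) plus `b2*X_{t-1}`).
#'
#' @param model One of `"M1"`, `"M3"`, `"M4"`.
#' @param n_strains,n_timepoints Dimensions of both traits.
#' @param x_patterns Two coefficient 4-vectors for X's genotype groups.
#' @param x_rho_mean,x_rho_sd AR(1) correlation prior for X's residuals.
#' @param x_noise_sd Residual sd for X.
#' @param b0 Intercept(s) of Y's equation: scalar for M1, length-2
#'   `(b00, b01)` per genotype for M3/M4.
#' @param b1 Lag coefficient(s) of Y: scalar for M1, length-2 per genotype for
#'   M3/M4; all must be strictly inside (-1, 1).
#' @param b2 Coefficient on `X_{t-1}` (ignored for M3).
#' @param y_noise_sd Standard deviation of Y's innovation noise.
#' @param y_init How Y at `t = 1` is drawn: `"stationary"` uses the
#'   stationary mean and variance of Y's own AR recursion (ignoring the X
#'   term), `"noise"` uses `b0 + noise`.
#' @return An object of class `causal_design`.
#' @export
causal_design <- function(model = c("M1", "M3", "M4"),
                          n_strains = 100, n_timepoints = 6,
                          x_patterns = pattern_library()[c("increase", "peak")],
                          x_rho_mean = 0.8, x_rho_sd = 0.1, x_noise_sd = 1,
                          b0 = 0.5, b1 = 0.5, b2 = 0.5,
                          y_noise_sd = 1,
                          y_init = c("stationary", "noise")) {
  model <- match.arg(model)
  y_init <- match.arg(y_init)
  if (model == "M1") {
    stopifnot(length(b0) == 1, length(b1) == 1)
  } else {
    if (length(b0) == 1) b0 <- rep(b0, 2)
    if (length(b1) == 1) b1 <- rep(b1, 2)
    stopifnot(length(b0) == 2, length(b1) == 2)
  }
  if (any(abs(b1) >= 1))
    stop("lag coefficients `b1` must satisfy |b1| < 1 (stationarity)")
  stopifnot(n_strains >= 2, n_timepoints >= 2, x_noise_sd > 0, y_noise_sd >= 0,
            is.list(x_patterns), length(x_patterns) == 2)
  structure(list(model = model, n_strains = as.integer(n_strains),
                 n_timepoints = as.integer(n_timepoints),
                 x_patterns = x_patterns, x_rho_mean = x_rho_mean,
                 x_rho_sd = x_rho_sd, x_noise_sd = x_noise_sd,
                 b0 = b0, b1 = b1, b2 = b2, y_noise_sd = y_noise_sd,
                 y_init = y_init),
            class = "causal_design")
}

#' Default parameter grid for causal-pair simulation studies
#'
#' The coefficient grid the pair-simulation studies mix over, one uniform draw
#' per replicate: lag coefficients `b1` in `{0.2, 0.4, 0.6, 0.8}`, causal
#' coefficients `b2` in `{0.3, 0.5, 0.8, 1.0}`, and genotype-effect intercept
#' offsets in `{0.5, 1.0}`.
#'
#' @return A list with components `b1`, `b2`, `offset`.
#' @export
tgct_sim_grid <- function() {
  list(b1 = c(0.2, 0.4, 0.6, 0.8),
       b2 = c(0.3, 0.5, 0.8, 1.0),
       offset = c(0.5, 1.0))
}

#' Draw a random causal design from the default grid
#'
#' Samples one parameter combination from [tgct_sim_grid()] and two distinct
#' X patterns from [pattern_library()]. For M3/M4 the two genotype groups of Y
#' get intercepts `0` and `offset` and share one lag coefficient.
#'
#' @param model `"M1"`, `"M3"` or `"M4"`.
#' @param n_strains Sample size.
#' @return A [causal_design()].
#' @export
random_causal_design <- function(model, n_strains) {
  grid <- tgct_sim_grid()
  lib <- pattern_library()
  pats <- lib[sample(names(lib), 2)]
  b2 <- sample(grid$b2, 1)
  off <- sample(grid$offset, 1)
  if (model == "M1") {
    causal_design("M1", n_strains = n_strains, x_patterns = pats,
                  b0 = off, b1 = sample(grid$b1, 1), b2 = b2)
  } else {
    # genotype acts on Y's own dynamics: per-genotype lag coefficients drawn
    # independently, intercepts separated by the grid offset
    causal_design(model, n_strains = n_strains, x_patterns = pats,
                  b0 = c(0, off), b1 = sample(grid$b1, 2, replace = TRUE),
                  b2 = b2)
  }
}

#' Simulate a causal, independent, or partial-causal trait pair
#'
#' @param design A [causal_design()].
#' @param genotypes 0/1 vector of length `n_strains`.
#' @return List with matrices `X` and `Y` (both `N x m`) and the `design`.
#' @export
simulate_pair <- function(design, genotypes) {
  stopifnot(inherits(design, "causal_design"))
  n <- design$n_strains
  m <- design$n_timepoints
  if (length(genotypes) != n)
    stop("`genotypes` must have length n_strains (", n, ")")
  xdes <- sim_design(n_strains = n, n_timepoints = m,
                     rho_mean = design$x_rho_mean, rho_sd = design$x_rho_sd,
                     patterns = design$x_patterns,
                     noise_sd = design$x_noise_sd)
  X <- simulate_trait(xdes, genotypes)
  g <- as.integer(genotypes)
  b0 <- if (design$model == "M1") rep(design$b0, 2) else design$b0
  b1 <- if (design$model == "M1") rep(design$b1, 2) else design$b1
  b2 <- if (design$model == "M3") 0 else design$b2
  sd_y <- design$y_noise_sd
  b0i <- b0[g + 1]
  b1i <- b1[g + 1]
  Y <- matrix(0, n, m, dimnames = dimnames(X))
  Y[, 1] <- if (design$y_init == "stationary") {
    b0i / (1 - b1i) + stats::rnorm(n, 0, sd_y / sqrt(1 - b1i^2))
  } else {
    b0i + stats::rnorm(n, 0, sd_y)
  }
  for (t in 2:m) {
    Y[, t] <- b0i + b1i * Y[, t - 1] + b2 * X[, t - 1] +
      stats::rnorm(n, 0, sd_y)
  }
  attr(Y, "times") <- seq_len(m)
  list(X = X, Y = Y, design = design)
}

#' Mask cells of a trait matrix at random
#'
#' Independently masks each cell with probability `rate`, setting it to `NA`
#' while preserving the complete values for later checks.
#'
#' @param trait Numeric `N x m` matrix.
#' @param rate Missingness probability per cell; rates above 0.1 are allowed
#'   with a warning (the robustness studies use 0.02-0.1).
#' @return The matrix with `NA`s, plus attributes `"mask"` (logical matrix of
#'   masked cells) and `"complete"` (the original values).
#' @export
drop_missing <- function(trait, rate) {
  stopifnot(is.matrix(trait), rate >= 0, rate <= 1)
  if (rate > 0.1)
    warning("missing rate ", rate, " is above the 0.02-0.1 range the ",
            "robustness studies were designed for")
  mask <- matrix(stats::runif(length(trait)) < rate,
                 nrow(trait), ncol(trait), dimnames = dimnames(trait))
  out <- trait
  out[mask] <- NA_real_
  attr(out, "mask") <- mask
  attr(out, "complete") <- trait
  attr(out, "times") <- attr(trait, "times")
  out
}
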