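#' Permutation-based FDR for a genome scan
#'
#' Reruns the scan on datasets in which the strain labels of the genotype
#' matrix are permuted, so expression values (and their temporal correlation)
#' are untouched while genetic associations are destroyed. At a p-value
#' cutoff `p` the FDR is estimated as the average number of permuted
#' associations below `p` divided by the number of real associations below
#' `p`. The raw ratio is reported together with a monotone (isotonic)
#' smoothing, `FDR(p_i) = min over p_j >= p_i of raw(p_j)`, which is the
#' curve used for cutoff lookup.
#'
#' @param expression Named list of trait matrices.
#' @param genotypes Strains x markers genotype matrix.
#' @param method Association method name.
#' @param n_perm Number of permutations (default 10).
#' @param fdr_target Target FDR for the cutoff lookup (default 0.05).
#' @param scan Optional precomputed real scan (from [teqtl_scan()] with the
#'   same method) to avoid recomputation.
#' @param ... Passed to [teqtl_scan()].
#' @return List: `table` (data.frame `p_cutoff`, `n_real`, `mean_perm`,
#'   `fdr_raw`, `fdr`), `cutoff` (largest p with smoothed FDR <= target, or
#'   `NA`), `fdr_target`, `n_perm`, `scan` (the real scan).
#' @export
permutation_fdr <- function(expression, genotypes, method = "mptga",
                            n_perm = 10, fdr_target = 0.05, scan = NULL, ...) {
  stopifnot(n_perm >= 1)
  if (is.null(scan)) scan <- teqtl_scan(expression, genotypes, method, ...)
  real_p <- scan$p.value
  if (length(real_p) == 0 || all(is.na(real_p))) stop("empty scan")
  perm_p <- numeric(0)
  for (b in seq_len(n_perm)) {
    gp <- genotypes[sample(nrow(genotypes)), , drop = FALSE]
    rownames(gp) <- rownames(genotypes)
    perm_p <- c(perm_p, teqtl_scan(expression, gp, method, ...)$p.value)
  }
  cuts <- sort(unique(real_p))
  n_real <- vapply(cuts, function(p) sum(real_p <= p), numeric(1))
  mean_perm <- vapply(cuts, function(p) sum(perm_p <= p) / n_perm, numeric(1))
  raw <- mean_perm / n_real
  smooth <- rev(cummin(rev(pmin(raw, 1))))
  tab <- data.frame(p_cutoff = cuts, n_real = n_real, mean_perm = mean_perm,
                    fdr_raw = raw, fdr = smooth)
  ok <- which(smooth <= fdr_target)
  cutoff <- if (length(ok)) cuts[max(ok)] else NA_real_
  list(table = tab, cutoff = cutoff, fdr_target = fdr_target,
       n_perm = n_perm, scan = scan)
}

## Peak (minimum-p) marker per gene and chromosome; one eQTL per gene per
## chromosome enters hotspot counting by default.
peak_records <- function(scan, map) {
  d <- merge(scan, map, by = "marker", sort = FALSE)
  key <- paste(d$gene, d$chrom, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(d)), key), function(ix)
    ix[which.min(d$p.value[ix])]), use.names = FALSE)
  d[sort(keep), , drop = FALSE]
}

#' Detect eQTL hotspots by binomial thresholding
#'
#' Partitions the genome into fixed-size bins, counts significant eQTLs whose
#' peak marker falls in each bin (one per gene and chromosome by default) and
#' declares a hotspot when a bin's count reaches the smallest `N0` such that
#' `P(Binomial(n_total, 1/B) >= N0) < alpha / B`, where `n_total` is the
#' total number of linkages and `B` the number of bins, i.e. a uniform
#' binomial null with a Bonferroni-corrected tail. Adjacent significant bins
#' are merged.
#'
#' @param scan Data.frame of significant association records (already
#'   filtered at the FDR cutoff), with `gene`, `marker`, `p.value`.
#' @param map Marker map data.frame (`marker`, `chrom`, `pos`), positions
#'   0-based within chromosome.
#' @param bin_size Bin width in bp (default 20000).
#' @param alpha Family-wise tail level before the `1/B` correction.
#' @param n_bins Override for the total bin count `B`; defaults to the
#'   number of bins tiling the mapped chromosomes.
#' @param per_gene_peak Count one peak marker per gene and chromosome
#'   (default) instead of all significant records.
#' @return List: `hotspots` (data.frame `chrom`, `start`, `end`, `count`,
#'   `n0`), `n0` (threshold), `n_bins`, `bins` (per-bin counts).
#' @export
detect_hotspots <- function(scan, map, bin_size = 20000, alpha = 0.05,
                            n_bins = NULL, per_gene_peak = TRUE) {
  if (nrow(scan) == 0) stop("empty scan")
  d <- if (per_gene_peak) peak_records(scan, map) else
    merge(scan, map, by = "marker", sort = FALSE)
  chroms <- unique(map$chrom)
  bins <- do.call(rbind, lapply(chroms, function(ch) {
    maxpos <- max(map$pos[map$chrom == ch])
    nb <- max(1L, ceiling((maxpos + 1) / bin_size))
    data.frame(chrom = ch, start = (seq_len(nb) - 1) * bin_size,
               stringsAsFactors = FALSE)
  }))
  bins$end <- bins$start + bin_size
  if (is.null(n_bins)) n_bins <- nrow(bins)
  bins$count <- mapply(function(ch, s)
    sum(d$chrom == ch & d$pos >= s & d$pos < s + bin_size),
    bins$chrom, bins$start)
  n_total <- nrow(d)
  n0 <- hotspot_threshold(n_total, n_bins, alpha)
  sig <- bins[bins$count >= n0, , drop = FALSE]
  hot <- merge_adjacent_bins(sig, bin_size)
  hot$n0 <- if (nrow(hot)) n0 else integer(0)
  list(hotspots = hot, n0 = n0, n_bins = n_bins, bins = bins)
}

#' Binomial hotspot count threshold
#'
#' Smallest `k` such that `P(Binomial(n_total, 1/n_bins) >= k)` is below
#' `alpha / n_bins`.
#'
#' @param n_total Total number of eQTL linkages genome-wide.
#' @param n_bins Number of genome bins.
#' @param alpha Tail level before the per-bin correction.
#' @return Integer threshold `N0`.
#' @export
hotspot_threshold <- function(n_total, n_bins, alpha = 0.05) {
  target <- alpha / n_bins
  ## smallest k with upper tail P(X >= k) < target
  k <- stats::qbinom(target, n_total, 1 / n_bins, lower.tail = FALSE) + 1L
  while (k > 1 &&
         stats::pbinom(k - 2, n_total, 1 / n_bins, lower.tail = FALSE) < target)
    k <- k - 1L
  as.integer(k)
}

merge_adjacent_bins <- function(sig, bin_size) {
  if (nrow(sig) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), count = integer(),
                      stringsAsFactors = FALSE))
  sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
  out <- list()
  cur <- sig[1, ]
  for (i in seq_len(nrow(sig))[-1]) {
    row <- sig[i, ]
    if (row$chrom == cur$chrom && row$start == cur$end) {
      cur$end <- row$end
      cur$count <- cur$count + row$count
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- row
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("chrom", "start", "end", "count")]
}

#' Confidence interval for a QTL location by the chi-square quantile method
#'
#' Along one chromosome, computes the likelihood-ratio profile
#' `R(d) = -2 log [ L(no eQTL) / L(eQTL at d) ]` at every marker with the
#' chosen association model, forms `T(d0) = max_d R(d) - R(d0)`, and returns
#' the interval spanned by positions where `T(d0)` stays below the upper
#' `alpha` critical value of a chi-square with `df` degrees of freedom.
#'
#' @param trait Numeric `N x m` trait matrix.
#' @param genotypes `N x K` genotype matrix for the chromosome's markers.
#' @param positions Marker positions (bp), same order as columns.
#' @param alpha Miscoverage level (default 0.05 for a 95 percent interval).
#' @param df Degrees of freedom of the chi-square reference (default 1).
#' @param method Association method for the profile (default `"mptga"`).
#' @return List: `peak_pos`, `ci` (`c(lower, upper)`), `profile` (data.frame
#'   `pos`, `R`, `T`), `threshold`, `alpha`, `df`.
#' @export
estimate_ci <- function(trait, genotypes, positions, alpha = 0.05, df = 1,
                        method = c("mptga", "regression")) {
  method <- match.arg(method)
  stopifnot(is.matrix(genotypes), length(positions) == ncol(genotypes),
            ncol(genotypes) >= 3)
  K <- ncol(genotypes)
  R <- numeric(K)
  if (method == "mptga") {
    ll0 <- fit_mptga(trait, NULL)$loglik
    for (j in seq_len(K))
      R[j] <- 2 * (fit_mptga(trait, genotypes[, j])$loglik - ll0)
  } else {
    for (j in seq_len(K)) {
      rec <- regression_test(trait, genotypes[, j])
      R[j] <- stats::qchisq(rec$p.value, df = 4, lower.tail = FALSE)
    }
  }
  if (diff(range(R)) < 1e-10) stop("flat likelihood-ratio profile (no peak)")
  Td <- max(R) - R
  thr <- stats::qchisq(1 - alpha, df = df)
  inside <- which(Td < thr)
  peak <- positions[which.max(R)]
  list(peak_pos = peak,
       ci = c(lower = min(positions[inside]), upper = max(positions[inside])),
       profile = data.frame(pos = positions, R = R, T = Td),
       threshold = thr, alpha = alpha, df = df)
}

#' QQ calibration summary for a set of p-values
#'
#' Sorted observed `-log10` p-values against uniform expectations, plus a
#' genomic-inflation-style factor: the median observed chi-square equivalent
#' (`qchisq(1 - p, 1)`) divided by the median of the chi-square(1)
#' distribution.
#'
#' @param p Numeric vector of p-values.
#' @return List: `qq` (data.frame `expected`, `observed`, both `-log10`
#'   scale), `lambda` (inflation factor).
#' @export
qq_validate <- function(p) {
  p <- p[!is.na(p)]
  stopifnot(length(p) > 0, all(p >= 0 & p <= 1))
  obs <- sort(p)
  n <- length(obs)
  expd <- (seq_len(n) - 0.5) / n
  lambda <- stats::median(stats::qchisq(1 - obs, df = 1)) /
    stats::qchisq(0.5, df = 1)
  list(qq = data.frame(expected = -log10(expd),
                       observed = -log10(pmax(obs, 1e-300))),
       lambda = lambda)
}

#' Overfitting diagnostic from LD-neighbour concordance of p-values
#'
#' For each gene's significant peak marker, finds flanking markers within
#' `window` positions whose genotype concordance with the peak marker is at
#' least `ld_threshold`, and correlates `-log10 p` at the peak with
#' `-log10 p` at those neighbours across all such pairs. A method that fits
#' signal rather than noise transfers to correlated markers, giving a high
#' correlation.
#'
#' @param scan Full scan data.frame (`gene`, `marker`, `p.value`) for one
#'   method.
#' @param genotypes Strains x markers genotype matrix (column order defines
#'   neighbourhood).
#' @param p_cutoff Significance cutoff selecting peak associations.
#' @param window Number of flanking markers considered on each side.
#' @param ld_threshold Minimum genotype concordance for a neighbour.
#' @return List: `correlation`, `pairs` (data.frame `peak_logp`,
#'   `neighbor_logp`).
#' @export
overfit_check <- function(scan, genotypes, p_cutoff = 0.001, window = 2,
                          ld_threshold = 0.9) {
  markers <- colnames(genotypes)
  peak_lp <- neigh_lp <- numeric(0)
  for (g in unique(scan$gene)) {
    sg <- scan[scan$gene == g, , drop = FALSE]
    j <- which.min(sg$p.value)
    if (sg$p.value[j] > p_cutoff) next
    pj <- match(sg$marker[j], markers)
    for (off in setdiff(seq(-window, window), 0)) {
      q <- pj + off
      if (q < 1 || q > length(markers)) next
      conc <- mean(genotypes[, pj] == genotypes[, q])
      if (conc < ld_threshold) next
      pn <- sg$p.value[match(markers[q], sg$marker)]
      if (is.na(pn)) next
      peak_lp <- c(peak_lp, -log10(pmax(sg$p.value[j], 1e-300)))
      neigh_lp <- c(neigh_lp, -log10(pmax(pn, 1e-300)))
    }
  }
  corr <- if (length(peak_lp) >= 3 && stats::sd(peak_lp) > 0 &&
              stats::sd(neigh_lp) > 0)
    stats::cor(peak_lp, neigh_lp) else NA_real_
  list(correlation = corr,
       pairs = data.frame(peak_logp = peak_lp, neighbor_logp = neigh_lp))
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric (Fisher's exact) test of the overlap between a
#' hit set and a signature within a finite gene universe, with the fold
#' enrichment observed/expected.
#'
#' @param hits Character vector of hit gene ids.
#' @param signature Character vector of signature gene ids (non-empty).
#' @param universe Character vector of all testable gene ids.
#' @return List: `overlap`, `expected`, `fold`, `p.value`.
#' @export
enrichment_test <- function(hits, signature, universe) {
  if (length(signature) == 0) stop("empty signature")
  stopifnot(length(universe) > 0)
  hits <- unique(hits)
  signature <- unique(signature)
  universe <- unique(universe)
  if (!all(hits %in% universe) || !all(signature %in% universe))
    stop("hits and signature must be subsets of the universe")
  q <- length(intersect(hits, signature))
  mN <- length(signature)
  nN <- length(universe) - mN
  kN <- length(hits)
  expected <- kN * mN / length(universe)
  p <- stats::phyper(q - 1, mN, nN, kN, lower.tail = FALSE)
  list(overlap = q, expected = expected,
       fold = if (expected > 0) q / expected else NA_real_, p.value = p)
}
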