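make_scan_fixture <- function(N = 40, n_genes = 6, n_markers = 5,
                              flip = NULL, noise = 2) {
  gt <- simulate_genotypes(N, n_markers, flip_prob = flip)
  lib <- pattern_library()
  expr <- list()
  truth <- character(n_genes)
  for (i in seq_len(n_genes)) {
    eff <- i <= n_genes / 2
    mk <- ((i - 1) %% n_markers) + 1
    truth[i] <- if (eff) colnames(gt$genotypes)[mk] else NA_character_
    pats <- if (eff) lib[c("increase", "dip")] else lib["peak"]
    expr[[sprintf("g%02d", i)]] <-
      simulate_trait(sim_design(N, 6, 0.85, 0.02, pats, noise),
                     gt$genotypes[, mk])
  }
  list(expr = expr, gt = gt, truth = truth)
}

test_that("permutation FDR preserves expression and matches its formula", {
  set.seed(30)
  fx <- make_scan_fixture()
  before <- fx$expr
  res <- permutation_fdr(fx$expr, fx$gt$genotypes, method = "regression",
                         n_perm = 3, fdr_target = 0.2)
  expect_identical(fx$expr, before)  # only genotype strain labels move
  tab <- res$table
  expect_equal(tab$fdr_raw, tab$mean_perm / tab$n_real)
  # smoothed curve is monotone non-decreasing in the p cutoff
  expect_true(all(diff(tab$fdr) >= -1e-12))
  expect_true(is.na(res$cutoff) || res$cutoff %in% tab$p_cutoff)
})

test_that("a fully null scan yields FDR estimates near one", {
  set.seed(31)
  gt <- simulate_genotypes(30, 4)
  expr <- lapply(1:6, function(i)
    matrix(rnorm(180), 30, 6))
  names(expr) <- paste0("n", 1:6)
  res <- permutation_fdr(expr, gt$genotypes, method = "regression",
                         n_perm = 4)
  expect_gt(res$table$fdr[nrow(res$table)], 0.6)
})

test_that("hotspot threshold matches the binomial survival oracle", {
  for (cfg in list(c(602, 602), c(150, 30), c(3000, 602))) {
    n_total <- cfg[1]; B <- cfg[2]
    n0 <- hotspot_threshold(n_total, B, alpha = 0.05)
    oracle <- min(which(vapply(1:60, function(k)
      pbinom(k - 1, n_total, 1 / B, lower.tail = FALSE) < 0.05 / B,
      logical(1))))
    expect_equal(n0, oracle)
  }
})

test_that("hotspot calls concentrate, merge and respect marker order", {
  map <- data.frame(marker = paste0("m", 1:10), chrom = "chr1",
                    pos = (0:9) * 20000 + 1000)
  # 30 genes all peaking at marker 3: one hotspot
  scan <- data.frame(gene = paste0("g", 1:30), marker = "m3",
                     p.value = 1e-8)
  res <- detect_hotspots(scan, map)
  expect_equal(nrow(res$hotspots), 1)
  expect_equal(res$hotspots$count, 30)
  expect_gte(res$hotspots$count, res$n0)
  # adjacent significant bins merge into one span
  scan2 <- rbind(scan,
                 data.frame(gene = paste0("h", 1:30), marker = "m4",
                            p.value = 1e-8))
  res2 <- detect_hotspots(scan2, map)
  expect_equal(nrow(res2$hotspots), 1)
  expect_equal(res2$hotspots$end - res2$hotspots$start, 40000)
  expect_equal(res2$hotspots$count, 60)
  # invariant to row order of the scan
  res3 <- detect_hotspots(scan2[sample(nrow(scan2)), ], map)
  expect_equal(res3$hotspots, res2$hotspots)
  expect_error(detect_hotspots(scan[0, ], map), "empty scan")
})

test_that("one peak per gene and chromosome enters hotspot counting", {
  map <- data.frame(marker = paste0("m", 1:4), chrom = "chr1",
                    pos = (0:3) * 20000)
  scan <- data.frame(gene = "g1", marker = paste0("m", 1:4),
                     p.value = c(1e-10, 1e-4, 1e-4, 1e-4))
  res <- detect_hotspots(scan, map)
  expect_equal(sum(res$bins$count), 1)
  expect_equal(res$bins$count[1], 1)  # the peak marker's bin
  res_all <- detect_hotspots(scan, map, per_gene_peak = FALSE)
  expect_equal(sum(res_all$bins$count), 4)
})

test_that("the QTL interval always contains the peak and shrinks with effect size", {
  set.seed(33)
  lib <- pattern_library()
  widths <- vapply(c(2, 8), function(noise) {
    mean(replicate(25, {
      gt <- simulate_genotypes(95, 15, flip_prob = 0.1)
      y <- simulate_trait(sim_design(95, 6, 0.85, 0.02,
                                     lib[c("increase", "peak")], noise),
                          gt$genotypes[, 8])
      ci <- estimate_ci(y, gt$genotypes, gt$map$pos)
      expect_gte(ci$peak_pos, ci$ci[["lower"]])
      expect_lte(ci$peak_pos, ci$ci[["upper"]])
      expect_equal(min(ci$profile$T), 0)
      diff(ci$ci)
    }))
  }, numeric(1))
  expect_lt(widths[1], widths[2])
  flat <- matrix(1, 95, 6)
  gt <- simulate_genotypes(95, 5)
  expect_error(estimate_ci(flat, gt$genotypes, gt$map$pos), "flat")
})

test_that("QQ summary sits on the diagonal for exact-uniform p-values", {
  p <- (1:2000 - 0.5) / 2000
  qv <- qq_validate(p)
  expect_equal(qv$qq$observed, qv$qq$expected, tolerance = 1e-10)
  expect_equal(qv$lambda, 1, tolerance = 0.01)
})

test_that("null association scans show the documented mild liberal drift", {
  set.seed(34)
  ps <- replicate(300, {
    d <- simulate_assoc_dataset(95, 0.9, 0.02, 4, effect = FALSE)
    mptga_test(d$trait, d$genotype)$p.value
  })
  lam <- qq_validate(ps)$lambda
  expect_gt(lam, 1)
  expect_lt(lam, 1.5)
})

test_that("overfitting diagnostic: perfect LD gives correlation one, noise none", {
  set.seed(35)
  fx <- make_scan_fixture(N = 60, n_genes = 8, n_markers = 6, flip = 0,
                          noise = 3)
  scan <- teqtl_scan(fx$expr, fx$gt$genotypes, method = "regression")
  res <- overfit_check(scan, fx$gt$genotypes, p_cutoff = 0.01)
  expect_equal(res$correlation, 1, tolerance = 1e-8)
  # pure-noise p-values at unlinked markers: no transfer
  gt <- simulate_genotypes(60, 30)
  expr <- stats::setNames(lapply(1:25, function(i) matrix(rnorm(360), 60, 6)),
                          paste0("n", 1:25))
  scan0 <- teqtl_scan(expr, gt$genotypes, method = "regression")
  res0 <- overfit_check(scan0, gt$genotypes, p_cutoff = 1, ld_threshold = 0)
  expect_lt(abs(res0$correlation), 0.35)
})

test_that("p-value transfer to neighbours weakens as LD weakens", {
  set.seed(36)
  corr_at <- function(flip) {
    mean(replicate(3, {
      fx <- make_scan_fixture(N = 60, n_genes = 20, n_markers = 8,
                              flip = flip, noise = 4)
      sc <- teqtl_scan(fx$expr, fx$gt$genotypes, method = "regression")
      overfit_check(sc, fx$gt$genotypes, p_cutoff = 0.01,
                    ld_threshold = 0.5)$correlation
    }))
  }
  strong <- corr_at(0.02)
  weak <- corr_at(0.3)
  expect_gt(strong, weak + 0.1)
})

test_that("enrichment test matches exhaustive hypergeometric enumeration", {
  universe <- paste0("u", 1:12)
  signature <- universe[1:4]
  hits <- universe[1:3]
  res <- enrichment_test(hits, signature, universe)
  # enumerate all C(12,3) hit sets, count those with overlap >= 3
  combos <- combn(12, 3)
  tail_mass <- mean(apply(combos, 2, function(ix)
    sum(ix <= 4) >= res$overlap))
  expect_equal(res$p.value, tail_mass, tolerance = 1e-10)
  expect_equal(res$overlap, 3)
  expect_equal(res$fold, 3 / (3 * 4 / 12))
  # overlap equal to expectation: fold = 1
  r1 <- enrichment_test(universe[c(1, 5, 6)], signature, universe)
  expect_equal(r1$fold, 1)
  expect_error(enrichment_test(hits, character(0), universe),
               "empty signature")
})
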