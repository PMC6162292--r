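test_that("a perfect lag-copy of X is called causal with near-zero residual", {
  set.seed(20)
  g <- balanced_geno(30)
  pr <- simulate_pair(causal_design("M1", n_strains = 30, b0 = 0, b1 = 0,
                                    b2 = 1, y_noise_sd = 0), g)
  fits <- fit_tgct_models(pr$X, pr$Y, g, models = c("M1", "M3", "M4"))
  expect_lt(fits$M1$rss_y, 1e-12)
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  expect_equal(names(which.min(bic)), "M1")
  expect_equal(select_cis_trans_model(pr$X, pr$Y, g)$best_model, "M1")
})

test_that("coefficients, likelihoods and BIC match explicit normal equations", {
  # tiny fixture: 4 strains (2 per genotype), 3 timepoints
  X <- matrix(c(1, 2, 3,
                0, 1, 1,
                2, 1, 0,
                1, 0, 2), 4, 3, byrow = TRUE)
  Y <- matrix(c(0, 2, 1,
                1, 1, 2,
                0, 1, 1,
                2, 2, 0), 4, 3, byrow = TRUE)
  g <- c(0, 0, 1, 1)
  fits <- fit_tgct_models(X, Y, g, models = c("M1", "M3", "M4"))
  n_obs <- 4 * 2
  d1 <- rep(g, 2)
  yv <- as.vector(Y[, -1]); ylag <- as.vector(Y[, -3])
  xlag <- as.vector(X[, -3])
  oracle <- function(D, y) {
    cf <- unname(drop(solve(t(D) %*% D, t(D) %*% y)))
    rss <- sum((y - D %*% cf)^2)
    ll <- -n_obs / 2 * log(2 * pi) - n_obs / 2 * log(rss) +
      n_obs / 2 * log(n_obs) - n_obs / 2
    list(cf = drop(cf), rss = rss, ll = ll)
  }
  o1 <- oracle(unname(cbind(1, ylag, xlag)), yv)
  o3 <- oracle(cbind(1 - d1, (1 - d1) * ylag, d1, d1 * ylag), yv)
  o4 <- oracle(cbind(1 - d1, (1 - d1) * ylag, d1, d1 * ylag, xlag), yv)
  expect_equal(unname(fits$M1$coef_y), o1$cf, tolerance = 1e-10)
  expect_equal(fits$M1$rss_y, o1$rss, tolerance = 1e-10)
  expect_equal(fits$M1$bic, log(n_obs) * 3 - 2 * o1$ll, tolerance = 1e-10)
  expect_equal(fits$M3$rss_y, o3$rss, tolerance = 1e-10)
  expect_equal(fits$M3$bic, log(n_obs) * 4 - 2 * o3$ll, tolerance = 1e-10)
  expect_equal(unname(fits$M4$coef_y), o4$cf, tolerance = 1e-10)
  expect_equal(fits$M4$bic, log(n_obs) * 5 - 2 * o4$ll, tolerance = 1e-10)
  # BIC recomputed from stored pieces
  for (f in fits)
    expect_equal(f$bic, log(f$n_obs) * f$k - 2 * f$loglik_y)
})

test_that("the independent model's Y-equation is the AR association full model", {
  set.seed(22)
  g <- balanced_geno(40)
  pr <- simulate_pair(causal_design("M3", n_strains = 40, b0 = c(0, 1)), g)
  f3 <- fit_tgct_models(pr$X, pr$Y, g, models = "M3")$M3
  d <- data.frame(y = as.vector(pr$Y[, -1]),
                  ylag = as.vector(pr$Y[, -6]),
                  gf = factor(rep(g, 5)))
  full <- lm(y ~ 0 + gf + gf:ylag, data = d)
  expect_equal(f3$rss_y, sum(residuals(full)^2), tolerance = 1e-8)
})

test_that("nested models never increase the residual sum of squares", {
  set.seed(23)
  for (model in c("M1", "M3", "M4")) {
    g <- balanced_geno(25)
    pr <- simulate_pair(random_causal_design(model, 25), g)
    fits <- fit_tgct_models(pr$X, pr$Y, g, models = c("M1", "M3", "M4"))
    expect_lte(fits$M4$rss_y, fits$M3$rss_y + 1e-10)
    pooled_ar <- sum(residuals(lm(as.vector(pr$Y[, -1]) ~
                                    as.vector(pr$Y[, -6])))^2)
    expect_lte(fits$M1$rss_y, pooled_ar + 1e-10)
  }
})

test_that("the direction call is antisymmetric under trait swap", {
  set.seed(24)
  for (i in 1:5) {
    g <- balanced_geno(30)
    pr <- simulate_pair(random_causal_design("M1", 30), g)
    fwd <- compare_m1_m2(pr$X, pr$Y, g)
    rev <- compare_m1_m2(pr$Y, pr$X, g)
    expect_equal(fwd$loglr, -rev$loglr, tolerance = 1e-8)
    expect_true(fwd$call != rev$call)
  }
})

test_that("the direction call is a coin flip on exchangeable noise pairs", {
  set.seed(25)
  calls <- replicate(400, {
    X <- matrix(rnorm(20 * 6), 20, 6)
    Y <- matrix(rnorm(20 * 6), 20, 6)
    compare_m1_m2(X, Y, balanced_geno(20))$call
  })
  expect_lt(abs(mean(calls == "M1") - 0.5), 0.09)
})

test_that("the association filter is enforced when p-values are supplied", {
  set.seed(26)
  g <- balanced_geno(20)
  pr <- simulate_pair(random_causal_design("M1", 20), g)
  expect_error(compare_m1_m2(pr$X, pr$Y, g, x_p = 1e-8, y_p = 1e-3),
               "filter")
  expect_s3_class(compare_m1_m2(pr$X, pr$Y, g, x_p = 1e-8, y_p = 1e-8),
                  "data.frame")
})

test_that("BIC ties and margins are reported coherently", {
  set.seed(27)
  g <- balanced_geno(30)
  pr <- simulate_pair(random_causal_design("M3", 30), g)
  sel <- select_cis_trans_model(pr$X, pr$Y, g)
  expect_gte(sel$bic_margin, 0)
  bics <- c(M1 = sel$bic_m1, M3 = sel$bic_m3, M4 = sel$bic_m4)
  expect_equal(min(bics), bics[[sel$best_model]])
})

test_that("a planted regulator is ranked first at a synthetic hotspot", {
  set.seed(28)
  N <- 100
  g <- balanced_geno(N)
  lib <- pattern_library()
  # driver: cis trait with a consistent-sign genotype effect on its trajectory
  driver_des <- causal_design("M1", n_strains = N, b0 = 0.5, b1 = 0.5,
                              b2 = 0.8,
                              x_patterns = lib[c("increase", "flat")])
  expr <- list()
  driver_pair <- simulate_pair(driver_des, g)
  expr$driver <- driver_pair$X
  for (k in 1:10) {
    # each target generated directly from the driver trait (true M1 edge)
    Y <- matrix(0, N, 6)
    Y[, 1] <- rnorm(N)
    for (t in 2:6) Y[, t] <- 0.5 + 0.5 * Y[, t - 1] +
        0.8 * expr$driver[, t - 1] + rnorm(N)
    expr[[paste0("target", k)]] <- Y
  }
  # decoys: independent flat traits with no genetic effect (candidate genes
  # that drive nothing; trending or genetically-driven decoys are genuinely
  # indistinguishable from the driver - see the methods vignette)
  for (k in 1:2) {
    expr[[paste0("decoy", k)]] <-
      simulate_trait(sim_design(N, 6, 0.8, 0.05, lib["flat"], 1), g)
  }
  calls <- tgct_pairs(expr, g, cis_genes = c("driver", "decoy1", "decoy2"),
                      trans_genes = paste0("target", 1:10))
  ranking <- rank_regulators(calls, hotspot_cutoff = 8)
  expect_equal(ranking$x_gene[1], "driver")
  expect_gte(ranking$n_causal[1], 8)
  expect_true(ranking$is_regulator[1])
  # duplicated cis driver: tied counts, both reported
  expr$driver2 <- expr$driver
  calls2 <- tgct_pairs(expr, g, cis_genes = c("driver", "driver2"),
                       trans_genes = paste0("target", 1:10))
  r2 <- rank_regulators(calls2, hotspot_cutoff = 8)
  expect_equal(r2$n_causal[1], r2$n_causal[2])
  # no trans genes: empty ranking
  empty <- rank_regulators(tgct_pairs(expr, g, "driver", character(0)))
  expect_equal(nrow(empty), 0)
  expect_error(tgct_pairs(expr, g, character(0), "target1"), "no cis genes")
})
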