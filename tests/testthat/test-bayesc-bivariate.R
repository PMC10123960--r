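biv_quick <- function(..., n_iter = 5000, burn_in = 1000, thin = 4, seed = 60)
  bivariate_config(n_iter = n_iter, burn_in = burn_in, thin = thin,
                   seed = seed, ...)

test_that("a duplicated trait yields genomic correlation near one", {
  set.seed(61)
  G <- random_geno(150, 60, seed = 61)
  eff <- numeric(60); eff[c(10, 30, 50)] <- c(0.7, -0.6, 0.5)
  y1 <- as.numeric(G$dosages %*% eff + rnorm(150, 0, 0.7))
  fit <- fit_bayesc_bivariate(cbind(t1 = y1, t2 = y1), NULL, G,
                              biv_quick(pi_t = c(0.9, 0.9)))
  expect_gt(fit$genomic_correlation, 0.9)
  expect_true(all(is.finite(fit$chains$rg) | is.na(fit$chains$rg)))
})

test_that("an independent noise trait yields genomic correlation near zero", {
  set.seed(62)
  G <- random_geno(200, 60, seed = 62)
  eff <- numeric(60); eff[c(10, 30, 50)] <- c(0.7, -0.6, 0.5)
  y1 <- as.numeric(G$dosages %*% eff + rnorm(200, 0, 0.7))
  y2 <- rnorm(200)
  fit <- fit_bayesc_bivariate(cbind(t1 = y1, t2 = y2), NULL, G,
                              biv_quick(pi_t = c(0.9, 0.9), seed = 63))
  expect_lt(abs(fit$genomic_correlation), 0.25)
})

test_that("trait labelling is symmetric", {
  set.seed(64)
  G <- random_geno(150, 40, seed = 64)
  eff1 <- numeric(40); eff1[c(5, 25)] <- c(0.8, -0.5)
  eff2 <- 0.6 * eff1; eff2[35] <- 0.7
  y1 <- as.numeric(G$dosages %*% eff1 + rnorm(150, 0, 0.8))
  y2 <- as.numeric(G$dosages %*% eff2 + rnorm(150, 0, 0.8))
  fa <- fit_bayesc_bivariate(cbind(a = y1, b = y2), NULL, G,
                             biv_quick(seed = 65, pi_t = c(0.9, 0.9)))
  fb <- fit_bayesc_bivariate(cbind(b = y2, a = y1), NULL, G,
                             biv_quick(seed = 66, pi_t = c(0.9, 0.9)))
  expect_equal(fb$genomic_correlation, fa$genomic_correlation,
               tolerance = 0.12)
  expect_equal(fb$post_mean_Sigma_alpha[1, 1], fa$post_mean_Sigma_alpha[2, 2],
               tolerance = 0.5 * fa$post_mean_Sigma_alpha[2, 2] + 0.01)
  expect_equal(unname(fb$h2), unname(rev(fa$h2)), tolerance = 0.1)
})

test_that("retained covariance draws are symmetric positive definite", {
  set.seed(67)
  G <- random_geno(80, 30, seed = 67)
  y1 <- rnorm(80); y2 <- rnorm(80)
  fit <- fit_bayesc_bivariate(cbind(y1, y2), NULL, G, biv_quick(seed = 68))
  for (ch in list(fit$chains$Sigma_alpha, fit$chains$Sigma_eps)) {
    expect_equal(ch[, 2], ch[, 3], tolerance = 1e-12)   # symmetric
    dets <- ch[, 1] * ch[, 4] - ch[, 2] * ch[, 3]
    expect_true(all(ch[, 1] > 0 & ch[, 4] > 0 & dets > 0))  # PD
  }
  expect_true(all(abs(fit$chains$rg[is.finite(fit$chains$rg)]) <= 1))
})

test_that("forcing joint inclusion with diagonal prior matches univariate pi=0 fits", {
  set.seed(69)
  n <- 50; m <- 8
  G <- random_geno(n, m, seed = 69)
  y1 <- as.numeric(G$dosages %*% rnorm(m, 0, 0.3) + rnorm(n))
  y2 <- as.numeric(G$dosages %*% rnorm(m, 0, 0.3) + rnorm(n))
  eps <- 1e-6
  # pi_t near 0 so the slab-variance prior scale matches the univariate
  # pi = 0 fits; the category prior then forces (1,1) essentially always
  # wishart_df = 5 makes the inverse-Wishart's diagonal marginal exactly the
  # univariate scaled inverse-chi-squared prior (df 4, same sum of squares)
  bc <- bivariate_config(pi_t = c(eps, eps), wishart_df = 5,
                         delta_prior = c(eps, eps, eps, 1 - 3 * eps),
                         n_iter = 20000, burn_in = 2000, thin = 2, seed = 70)
  bf <- fit_bayesc_bivariate(cbind(y1, y2), NULL, G, bc)
  for (t in 1:2) {
    y <- list(y1, y2)[[t]]
    uf <- fit_bayesc(y, NULL, G,
                     bayesc_config(pi = 0, n_iter = 20000, burn_in = 2000,
                                   thin = 2, seed = 70 + t))
    expect_lt(max(abs(bf$post_mean_alpha[, t] - uf$markers$post_mean_alpha)),
              0.12)
  }
  expect_true(all(bf$pip > 0.999))
})

test_that("genomic_correlation_from_draws summarizes and skips degenerate draws", {
  set.seed(71)
  g1 <- matrix(rnorm(20 * 50), 20, 50)
  # trait2 = 2 * trait1 -> correlation exactly 1 in every draw
  arr <- array(0, dim = c(20, 50, 2))
  arr[, , 1] <- g1; arr[, , 2] <- 2 * g1
  s <- genomic_correlation_from_draws(arr)
  expect_equal(s$mean, 1)
  expect_equal(s$n_skipped, 0)
  # anti-correlated
  arr[, , 2] <- -g1
  expect_equal(genomic_correlation_from_draws(arr)$mean, -1)
  # independent vectors at n = 100 lines: small mean |correlation|
  arr2 <- array(rnorm(40 * 100 * 2), dim = c(40, 100, 2))
  expect_lt(abs(genomic_correlation_from_draws(arr2)$mean), 0.25)
  # zero-variance draws are skipped and counted
  arr[3, , 1] <- 0
  s3 <- genomic_correlation_from_draws(arr)
  expect_equal(s3$n_skipped, 1)
  expect_equal(s3$n_used, 19)
  expect_error(genomic_correlation_from_draws(arr[1:5, , ]), "at least 10")
})

test_that("the pair runner emits one long-format row per pair and management", {
  cfg <- sim_config(n_lines = 120, n_markers = 60, n_chrom = 2,
                    n_causal = 8, h2_target = c(PH = 0.5, SDM = 0.4),
                    seed = 72, management_resample_frac = 0)
  G <- simulate_genotypes(cfg)
  st <- simulate_traits(G, cfg)
  sp <- simulate_spectra(G, st$truth, st$phenotypes,
                         sim_config(n_lines = 120, n_markers = 60, n_chrom = 2,
                                    n_causal = 8,
                                    h2_target = c(PH = 0.5, SDM = 0.4),
                                    seed = 72, management_resample_frac = 0,
                                    n_bands = 10))
  dat <- cbind(st$phenotypes, sp[match(st$phenotypes$plot_id, sp$plot_id), -1])
  pairs <- data.frame(trait = "PH", phenotype = c("R386", "R1021"))
  out <- fit_rg_pairs(dat, pairs, G,
                      biv_quick(n_iter = 2000, burn_in = 400, thin = 4,
                                seed = 73))
  expect_equal(nrow(out), 4)  # 2 pairs x 2 managements
  expect_setequal(names(out), c("management", "trait", "phenotype", "rg_mean",
                                "rg_low", "rg_high", "h2_trait",
                                "h2_phenotype"))
  expect_true(all(abs(out$rg_mean) <= 1))
  expect_true(all(out$rg_low <= out$rg_high))
})
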