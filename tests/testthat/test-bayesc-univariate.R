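test_that("single-marker PIP matches the quadrature oracle (fixed variances)", {
  set.seed(40)
  n <- 40
  w <- rbinom(n, 2, 0.3)
  y <- 0.3 * w + rnorm(n)
  G <- toy_geno(cbind(m = w))
  cfg <- bayesc_config(pi = 0.9, update_variances = FALSE,
                       sigma2_alpha = 0.2, sigma2_eps = 1,
                       n_iter = 30000, burn_in = 3000, thin = 1,
                       center_markers = FALSE, seed = 41)
  fit <- fit_bayesc(y, design = "none", G, cfg)
  expect_equal(fit$markers$pip, pip_quadrature(y, w, 0.9, 0.2, 1),
               tolerance = 0.02)
})

test_that("pi = 0 with fixed variances recovers the ridge solution", {
  set.seed(42)
  n <- 50; m <- 20
  W <- matrix(rbinom(n * m, 2, 0.4), n, m)
  y <- as.numeric(W %*% rnorm(m, 0, 0.2) + rnorm(n))
  yc <- y - mean(y)
  G <- toy_geno(W)
  s2a <- 0.04; s2e <- 1
  cfg <- bayesc_config(pi = 0, update_variances = FALSE, sigma2_alpha = s2a,
                       sigma2_eps = s2e, n_iter = 20000, burn_in = 2000,
                       thin = 1, center_markers = FALSE, seed = 43)
  fit <- fit_bayesc(yc, design = "none", G, cfg)
  ridge <- ridge_oracle(W, yc, s2a, s2e)
  expect_lt(max(abs(fit$markers$post_mean_alpha - ridge)), 0.05)
})

test_that("zero-marker residual variance follows the analytic posterior", {
  set.seed(44)
  n <- 60
  y <- rnorm(n, 5, 2)
  G <- genotype_matrix(matrix(numeric(0), n, 0), chrom = character(0),
                       pos_bp = integer(0))
  cfg <- bayesc_config(n_iter = 12000, burn_in = 2000, thin = 5, seed = 45)
  fit <- fit_bayesc(y, design = NULL, G, cfg)
  # flat prior on mu + scaled inv-chi2(nu, S) prior: marginal posterior of
  # sigma2 is scaled inv-chi2 with df nu + n - 1 and sum of squares
  # nu*S + sum((y - ybar)^2)
  nu <- cfg$prior_df
  S <- cfg$variance_partition * var(y) * (nu - 2) / nu
  ss <- nu * S + sum((y - mean(y))^2)
  df <- nu + n - 1
  ks <- suppressWarnings(
    ks.test(fit$chains$sigma2_eps, function(x) 1 - pchisq(ss / x, df)))
  expect_gt(ks$p.value, 0.01)
  expect_equal(fit$h2, 0)                 # no markers, no genomic variance
})

test_that("marker order does not change posterior summaries", {
  set.seed(46)
  G <- random_geno(120, 30, seed = 46)
  eff <- numeric(30); eff[c(5, 20)] <- c(0.8, -0.8)
  y <- as.numeric(G$dosages %*% eff + rnorm(120))
  cfg <- quick_chain(n_iter = 20000, burn_in = 2000, thin = 2, seed = 47,
                     pi = 0.9)
  f1 <- fit_bayesc(y, NULL, G, cfg)
  # same marker columns visited in reverse order (positions relabelled so the
  # map stays valid)
  Gr <- toy_geno(G$dosages[, 30:1])
  f2 <- fit_bayesc(y, NULL, Gr, cfg)
  expect_equal(rev(f2$markers$pip), f1$markers$pip, tolerance = 0.05)
  expect_equal(rev(f2$markers$post_mean_alpha), f1$markers$post_mean_alpha,
               tolerance = 0.05)
  expect_equal(f2$h2, f1$h2, tolerance = 0.05)
})

test_that("per-draw heritability averages to the reported h2", {
  set.seed(48)
  G <- random_geno(100, 20, seed = 48)
  y <- as.numeric(G$dosages %*% c(rep(0, 18), 0.5, -0.5) + rnorm(100))
  fit <- fit_bayesc(y, NULL, G, quick_chain(seed = 49))
  h2_draws <- genomic_heritability(fit$chains$sigma2_g,
                                   fit$chains$sigma2_eps,
                                   fit$config$n_rep_for_h2)
  expect_equal(mean(h2_draws), fit$h2, tolerance = 1e-12)
  expect_equal(h2_draws, fit$chains$h2, tolerance = 1e-12)
  expect_equal(fit$n_retained, length(fit$chains$h2))
  expect_equal(fit$n_retained,
               (fit$config$n_iter - fit$config$burn_in) %/% fit$config$thin)
  expect_true(all(fit$markers$pip >= 0 & fit$markers$pip <= 1))
  expect_true(all(fit$chains$h2 >= 0 & fit$chains$h2 <= 1))
})

test_that("heritability formula handles its boundary cases", {
  expect_equal(genomic_heritability(1, 1, 2), 2 / 3)
  expect_equal(genomic_heritability(0, 5, 2), 0)
  expect_equal(genomic_heritability(3, 0, 1), 1)
  expect_error(genomic_heritability(0, 0, 2), "undefined")
  expect_error(genomic_heritability(-1, 1, 2))
})

test_that("design construction enforces full rank and names confounded columns", {
  des <- data.frame(rep = c(1, 1, 2, 2), block = c(1, 2, 1, 2))
  X <- build_design_matrix(des, 4)
  expect_equal(qr(X)$rank, ncol(X))
  expect_true("(Intercept)" %in% colnames(X))
  # nested reference coding stays full rank across awkward layouts
  set.seed(90)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    des_i <- data.frame(rep = sample(1:2, n, TRUE),
                        block = sample(1:3, n, TRUE))
    Xi <- build_design_matrix(des_i, n)
    expect_equal(qr(Xi)$rank, ncol(Xi))
  }
  expect_equal(ncol(build_design_matrix("none", 4)), 0)
  expect_equal(ncol(build_design_matrix(NULL, 4)), 1)
})

test_that("input validation rejects broken phenotypes and mappings", {
  G <- random_geno(20, 5, seed = 50)
  expect_error(fit_bayesc(c(rnorm(19), NA), NULL, G, quick_chain()),
               "non-finite")
  expect_error(fit_bayesc(rnorm(10), NULL, G, quick_chain()), "per genotyped")
  Gna <- G; Gna$dosages[1, 1] <- NA
  expect_error(fit_bayesc(rnorm(20), NULL, Gna, quick_chain()), "impute")
  des <- data.frame(line_id = rep("nope", 20))
  expect_error(fit_bayesc(rnorm(20), des, G, quick_chain()), "unknown line_id")
})

test_that("diagnostics report sensible ESS for iid, AR(1) and degenerate chains", {
  set.seed(51)
  # single-chain spectral ESS estimates are noisy; average over replicates
  ess_reps <- vapply(1:8, function(i)
    diagnostics(list(iid = rnorm(1000)))$ess, 0)
  expect_lt(abs(mean(ess_reps) - 1000), 200)
  d1 <- diagnostics(list(iid = rnorm(1000)))
  expect_false(d1$degenerate)
  # AR(1) with phi = 0.9: ESS ~ n (1 - phi) / (1 + phi)
  phi <- 0.9
  ar <- as.numeric(arima.sim(list(ar = phi), 20000))
  d2 <- diagnostics(list(ar = ar))
  expect_equal(d2$ess, 20000 * (1 - phi) / (1 + phi), tolerance = 0.35)
  # constant chain flagged as degenerate, no numeric ESS
  d3 <- diagnostics(list(const = rep(3, 100)))
  expect_true(d3$degenerate)
  expect_true(is.na(d3$ess))
  # trace plots get written when asked
  dir <- file.path(tempdir(), "traces")
  diagnostics(list(iid = rnorm(1000)), plot_dir = dir)
  expect_true(file.exists(file.path(dir, "trace_iid.png")))
})
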