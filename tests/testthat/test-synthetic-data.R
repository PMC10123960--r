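test_that("simulated genotypes respect dimensions, dosage domain and determinism", {
  cfg <- sim_config(n_lines = 100, n_markers = 200, n_chrom = 3, seed = 1)
  G <- simulate_genotypes(cfg)
  expect_equal(dim(G$dosages), c(100, 200))
  expect_true(all(G$dosages %in% c(0, 1, 2)))
  expect_equal(nrow(G$map), 200)
  # remainder markers distributed, never dropped
  expect_equal(as.vector(table(G$map$chrom)[c("1", "2", "3")]), c(67, 67, 66))
  for (ch in unique(G$map$chrom))
    expect_true(all(diff(G$map$pos_bp[G$map$chrom == ch]) > 0))
  # bit-identical rerun under the same config
  G2 <- simulate_genotypes(cfg)
  expect_identical(G$dosages, G2$dosages)
  expect_identical(G$map, G2$map)
  # different seed differs
  G3 <- simulate_genotypes(sim_config(n_lines = 100, n_markers = 200,
                                      n_chrom = 3, seed = 2))
  expect_false(identical(G$dosages, G3$dosages))
})

test_that("realized allele frequencies track the configured MAF", {
  cfg <- sim_config(n_lines = 2000, n_markers = 60, n_chrom = 2,
                    maf_range = c(0.5, 0.5), ld_block_size = 1, seed = 3)
  G <- simulate_genotypes(cfg)
  frq <- colMeans(G$dosages) / 2
  se <- sqrt(0.25 / (2 * 2000))
  # individual markers within 4 SE (3 SE would fail ~15% of 60-marker panels)
  expect_true(all(abs(frq - 0.5) < 4 * se))
  expect_lt(abs(mean(frq) - 0.5), 3 * se / sqrt(60))
})

test_that("LD structure follows the block size", {
  # independent markers: mean |off-diagonal r| near zero
  cfg1 <- sim_config(n_lines = 2000, n_markers = 40, n_chrom = 1,
                     ld_block_size = 1, seed = 4)
  r1 <- cor(simulate_genotypes(cfg1)$dosages)
  expect_lt(mean(abs(r1[upper.tri(r1)])), 0.05)
  # blocked markers: within-block correlation clearly positive
  cfg2 <- sim_config(n_lines = 1000, n_markers = 40, n_chrom = 1,
                     ld_block_size = 5, ld_flip_prob = 0.05, seed = 5)
  G2 <- simulate_genotypes(cfg2)
  r2 <- cor(G2$dosages)
  adjacent_same_block <- which(seq_len(39) %% 5 != 0)
  within <- mapply(function(i) r2[i, i + 1], adjacent_same_block)
  expect_gt(mean(within), 0.5)
  # across-block adjacent pairs uncorrelated
  across <- mapply(function(i) r2[i, i + 1], which(seq_len(39) %% 5 == 0))
  expect_lt(mean(abs(across)), 0.15)
})

test_that("simulated traits hit the target heritability and sparsity", {
  cfg <- sim_config(n_lines = 2000, n_markers = 1000, n_chrom = 5,
                    pi_sparsity = 0.99, h2_target = c(y = 0.5),
                    rg_target = matrix(1, 1, 1), seed = 6)
  G <- simulate_genotypes(cfg)
  st <- simulate_traits(G, cfg)
  # ~10 causal markers expected from binomial(1000, 0.01)
  expect_gt(length(st$truth$causal_marker_ids), 1)
  expect_lt(length(st$truth$causal_marker_ids), 30)
  # realized plot-level h2 from the true variance components
  g <- st$truth$true_genetic_values[["B-"]][, 1]
  h2_real <- var(g) / (var(g) + 1 / cfg$n_rep)
  expect_lt(abs(h2_real - 0.5), 0.05)
  # markers outside the causal set have effect exactly zero
  out <- setdiff(G$map$marker_id, st$truth$causal_marker_ids)
  expect_true(all(st$truth$true_effects[["B-"]][match(out, G$map$marker_id), ] == 0))
  # phenotype table covers both managements with all plots
  expect_equal(nrow(st$phenotypes), 2000 * cfg$n_rep * 2)
  expect_setequal(unique(st$phenotypes$management), c("B-", "B+"))
})

test_that("zero heritability and h2 = 1 behave as contracted", {
  cfg0 <- sim_config(n_lines = 150, n_markers = 100, n_chrom = 1,
                     h2_target = c(y = 0), rg_target = matrix(1, 1, 1),
                     seed = 7)
  st0 <- simulate_traits(simulate_genotypes(cfg0), cfg0)
  expect_true(all(st0$truth$true_genetic_values[["B-"]] == 0))
  expect_error(sim_config(h2_target = c(y = 1)), "residual")
})

test_that("management architectures differ via effect resampling", {
  cfg <- sim_config(n_lines = 200, n_markers = 200, n_chrom = 2,
                    n_causal = 20, management_resample_frac = 0.8, seed = 8,
                    h2_target = c(y = 0.5), rg_target = matrix(1, 1, 1))
  st <- simulate_traits(simulate_genotypes(cfg), cfg)
  e1 <- st$truth$true_effects[["B-"]]
  e2 <- st$truth$true_effects[["B+"]]
  nz <- rowSums(e1 != 0) > 0
  changed <- sum(e1[nz, 1] != e2[nz, 1])
  expect_gt(changed, 10)   # ~80% of 20 redrawn (scaling also shifts values)
  # with no resampling and same scaling target the architectures coincide
  cfg0 <- sim_config(n_lines = 200, n_markers = 200, n_chrom = 2,
                     n_causal = 20, management_resample_frac = 0, seed = 8,
                     h2_target = c(y = 0.5), rg_target = matrix(1, 1, 1))
  st0 <- simulate_traits(simulate_genotypes(cfg0), cfg0)
  expect_equal(st0$truth$true_effects[["B-"]], st0$truth$true_effects[["B+"]])
})

test_that("simulated spectra stay in [0,1] and carry the injected sign pattern", {
  cfg <- sim_config(n_lines = 400, n_markers = 200, n_chrom = 2,
                    n_causal = 20, h2_target = c(y = 0.6),
                    rg_target = matrix(1, 1, 1), n_bands = 30, seed = 9,
                    management_resample_frac = 0)
  G <- simulate_genotypes(cfg)
  st <- simulate_traits(G, cfg)
  sp <- simulate_spectra(G, st$truth, st$phenotypes, cfg)
  R <- as.matrix(sp[, -1])
  expect_true(all(R >= 0 & R <= 1))
  expect_equal(nrow(sp), nrow(st$phenotypes))
  # band-vs-trait genetic correlation reproduces the loading sign pattern
  L <- attr(sp, "loadings")
  rows <- st$phenotypes$management == "B-"
  gv <- st$truth$true_genetic_values[["B-"]][
    match(st$phenotypes$line_id[rows], rownames(G$dosages)), 1]
  band_gen <- outer(gv, L[, 1])          # genetic component per band
  rs <- vapply(seq_len(ncol(R)), function(b) {
    if (sd(band_gen[, b]) == 0) return(0)
    cor(band_gen[, b], gv)
  }, 0)
  big <- abs(L[, 1]) > 0.5 * max(abs(L[, 1]))
  expect_true(all(sign(rs[big]) == sign(L[big, 1])))
  # zero loadings remove the genetic signal entirely
  sp0 <- simulate_spectra(G, st$truth, st$phenotypes, cfg,
                          loadings = matrix(0, cfg$n_bands, 1))
  base <- baseline_reflectance(spectra_wavelengths(sp0))
  resid <- sweep(as.matrix(sp0[, -1]), 2, base)
  expect_lt(max(abs(colMeans(resid))), 0.02)
})

test_that("simulated cubes expose a recoverable leaf region", {
  # noiseless leaf covering the full cube reproduces the input exactly
  refl <- seq(0.2, 0.6, length.out = 10)
  cube <- simulate_cube(refl, shape = c(8, 8), background_value = 0,
                        leaf_rows = 1:8, leaf_cols = 1:8, noise_sd = 0)
  for (b in 1:10) expect_true(all(cube$values[, , b] == refl[b]))
  # constant leaf on zero background: leaf mean equals the leaf value
  cube2 <- simulate_cube(rep(0.4, 5), shape = c(20, 20))
  expect_equal(mean(cube2$values[, , 3][cube2$mask]), 0.4)
  expect_true(all(cube2$values[, , 3][!cube2$mask] == 0))
  # noisy leaf: recovered band mean within 3 standard errors
  set.seed(10)
  cube3 <- simulate_cube(rep(0.4, 4), shape = c(200, 200),
                         leaf_rows = 1:100, leaf_cols = 1:100,
                         noise_sd = 0.01)
  mns <- vapply(1:4, function(b) mean(cube3$values[, , b][cube3$mask]), 0)
  expect_true(all(abs(mns - 0.4) < 3 * 0.01 / sqrt(10000)))
  # leaf larger than the cube is rejected
  expect_error(simulate_cube(rep(0.4, 3), shape = c(5, 5), leaf_rows = 1:9,
                             leaf_cols = 1:2), "exceeds")
})

test_that("genotype and truth round-trip through their file formats", {
  cfg <- sim_config(n_lines = 30, n_markers = 40, n_chrom = 2, seed = 11)
  G <- simulate_genotypes(cfg)
  tsv <- tempfile(fileext = ".tsv")
  write_dosage_tsv(G, tsv)
  G2 <- read_dosage_tsv(tsv)
  expect_equal(G2$dosages, G$dosages)
  expect_equal(G2$map, G$map)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(G, vcf)
  G3 <- read_vcf(vcf)
  expect_equal(unname(G3$dosages), unname(G$dosages))
  expect_equal(G3$map$pos_bp, G$map$pos_bp)
  st <- simulate_traits(G, cfg)
  js <- tempfile(fileext = ".json")
  write_sim_truth(st$truth, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_setequal(back$causal_marker_ids, st$truth$causal_marker_ids)
})
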