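test_that("call-rate and MAF filters apply in order with strict boundaries", {
  d <- cbind(
    m1 = c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0),            # clean, common
    m2 = c(NA, NA, 2, 0, 1, 2, 0, 1, 2, 0),          # call rate 0.8 -> removed
    m3 = c(rep(0, 9), 1),                            # MAF exactly 0.05 -> kept
    m4 = c(rep(0, 10)),                              # MAF 0 -> removed
    m5 = c(NA, 0, 1, 2, 0, 1, 2, 0, 1, 2))           # call rate 0.9 -> kept
  G <- toy_geno(d)
  res <- filter_markers(G)
  ids <- res$genotypes$map$marker_id
  expect_length(ids, 3)
  expect_equal(res$report$n_removed_callrate, 1)
  expect_equal(res$report$n_removed_maf, 1)
  expect_equal(res$report$removed_ids$callrate, "Chr1_200")
  expect_equal(res$report$removed_ids$maf, "Chr1_400")
  # a marker appears in at most one removal list and counts reconcile
  expect_length(intersect(res$report$removed_ids$callrate,
                          res$report$removed_ids$maf), 0)
  expect_equal(res$report$n_input,
               res$report$n_retained + res$report$n_removed_callrate +
                 res$report$n_removed_maf + res$report$n_removed_ld)
  # MAF 0.03 removed under strict < 0.05
  d2 <- cbind(m1 = c(rep(0, 97), rep(1, 3), rep(0, 0)),
              m2 = rbinom(100, 2, 0.5))
  res2 <- filter_markers(toy_geno(d2))
  expect_equal(res2$genotypes$map$marker_id, "Chr1_200")
  # everything removed is an explicit error
  expect_error(filter_markers(toy_geno(cbind(m = rep(0, 10)))), "empty")
})

test_that("filtering is idempotent", {
  G <- random_geno(50, 30, seed = 20)
  G$dosages[sample(length(G$dosages), 60)] <- NA
  once <- filter_markers(G)
  twice <- filter_markers(once$genotypes)
  expect_equal(twice$genotypes$map, once$genotypes$map)
  expect_equal(twice$report$n_removed_callrate +
                 twice$report$n_removed_maf, 0)
})

test_that("mean imputation fills missing dosages and nothing else", {
  G <- toy_geno(cbind(m1 = c(0, 2, NA), m2 = c(1, 1, 1)))
  out <- impute_missing(G)
  expect_equal(out$dosages[3, 1], 1.0)
  expect_equal(out$dosages[, 2], c(1, 1, 1), ignore_attr = TRUE)
  # identity when complete
  G2 <- toy_geno(cbind(m1 = c(0, 1, 2)))
  expect_identical(impute_missing(G2)$dosages, G2$dosages)
  # constant observed values propagate
  G3 <- toy_geno(cbind(m1 = c(2, 2, NA, NA), m2 = c(0, 1, 2, 0)))
  expect_equal(impute_missing(G3)$dosages[3:4, 1], c(2, 2),
               ignore_attr = TRUE)
  # fully missing marker is an error
  G4 <- toy_geno(cbind(m1 = c(NA, NA, NA), m2 = c(0, 1, 2)))
  expect_error(impute_missing(G4), "fully missing")
})

test_that("LD pruning removes later duplicates and keeps independent markers", {
  x <- rbinom(1000, 2, 0.4)
  y <- rbinom(1000, 2, 0.4)
  G <- toy_geno(cbind(a = x, b = x, c = y))
  res <- ld_prune(G)
  expect_equal(res$genotypes$map$marker_id, c("Chr1_100", "Chr1_300"))
  expect_equal(res$report$removed_ids$ld, "Chr1_200")
  # three mutually identical columns: first survives
  G3 <- toy_geno(cbind(a = x, b = x, c = x))
  expect_equal(ld_prune(G3)$genotypes$map$marker_id, "Chr1_100")
  # independent random columns both retained
  expect_equal(ld_prune(toy_geno(cbind(a = x, b = y)))$report$n_removed_ld, 0)
  # cross-chromosome duplicates are not pruned (within-chromosome rule)
  Gx <- genotype_matrix(cbind(a = x, b = x), chrom = c(1, 2),
                        pos_bp = c(100, 100))
  expect_equal(ld_prune(Gx)$report$n_removed_ld, 0)
  # missing dosages rejected
  Gna <- toy_geno(cbind(a = c(x[1:999], NA)))
  expect_error(ld_prune(Gna), "complete")
})

test_that("pruned panels have no surviving pair above the threshold and pruning is idempotent", {
  set.seed(21)
  base <- matrix(rbinom(200 * 10, 2, 0.4), 200, 10)
  # make several highly correlated copies
  noisy <- base[, rep(1:10, each = 3)]
  flip <- matrix(runif(length(noisy)) < 0.02, nrow(noisy))
  noisy[flip] <- rbinom(sum(flip), 2, 0.4)
  G <- toy_geno(noisy)
  res <- ld_prune(G, max_r2 = 0.9)
  r2 <- cor(res$genotypes$dosages)^2
  expect_true(all(r2[upper.tri(r2)] <= 0.9 + 1e-12))
  again <- ld_prune(res$genotypes, max_r2 = 0.9)
  expect_equal(again$report$n_removed_ld, 0)
  expect_equal(again$genotypes$map, res$genotypes$map)
})

test_that("zero-variance markers are flagged, never pruned by correlation", {
  x <- rbinom(300, 2, 0.4)
  G <- toy_geno(cbind(a = x, b = rep(2, 300), c = x))
  res <- ld_prune(G)
  expect_equal(res$report$zero_variance_flagged, "Chr1_200")
  expect_true("Chr1_200" %in% res$genotypes$map$marker_id)
  expect_false("Chr1_300" %in% res$genotypes$map$marker_id)  # duplicate of a
})

test_that("multi-allelic VCF records are skipped with a warning", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
               "1\t100\tChr1_100\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
               "1\t200\tChr1_200\tA\tT,G\t.\tPASS\t.\tGT\t0/1\t0/2",
               "1\t300\tChr1_300\tA\tT\t.\tPASS\t.\tGT\t./.\t0/0"), vcf)
  expect_warning(G <- read_vcf(vcf), "multi-allelic")
  expect_equal(ncol(G$dosages), 2)
  expect_equal(unname(G$dosages[, 1]), c(1, 2))
  expect_true(is.na(G$dosages[1, 2]))
})
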