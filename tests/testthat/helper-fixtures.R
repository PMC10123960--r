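# Shared fixtures and independent oracles used across test files.

# small genotype matrix with explicit dosages
toy_geno <- function(dosages, chrom = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(chrom)) chrom <- rep(1, m)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = m)
  genotype_matrix(dosages, chrom = chrom, pos_bp = pos)
}

random_geno <- function(n, m, p = 0.3, seed = 1, n_chrom = 1) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, p), n, m)
  chrom <- rep(seq_len(n_chrom), length.out = m)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(m), chrom), function(i)
    seq(100, by = 100, length.out = length(i))), use.names = FALSE)
  genotype_matrix(d, chrom = chrom, pos_bp = pos)
}

# Quadrature oracle for the single-marker fixed-variance posterior inclusion
# probability: one-dimensional numerical integration of the slab component
# relative to the spike, with a log shift for numerical stability.
pip_quadrature <- function(y, w, pi_excl, s2a, s2e) {
  ll <- function(a) vapply(a, function(ai)
    sum(dnorm(y, w * ai, sqrt(s2e), log = TRUE)), 0)
  l0 <- ll(0)
  f <- function(a) exp(ll(a) - l0) * dnorm(a, 0, sqrt(s2a))
  m1_rel <- integrate(f, -Inf, Inf)$value   # m1 / m0
  (1 - pi_excl) * m1_rel / ((1 - pi_excl) * m1_rel + pi_excl)
}

# Closed-form ridge solution on residualized data (the pi = 0,
# fixed-variance limit of the sampler's posterior mean).
ridge_oracle <- function(W, y, s2a, s2e) {
  m <- ncol(W)
  solve(crossprod(W) + diag(s2e / s2a, m), crossprod(W, y))
}

# Brute-force gene-window scan, independent of the GenomicRanges route.
gene_window_bruteforce <- function(chrom, pos, annotation, flank) {
  ws <- max(1, pos - flank); we <- pos + flank
  hit <- annotation$chrom == as.character(chrom) &
    annotation$start <= we & annotation$end >= ws
  annotation$gene_id[hit]
}

quick_chain <- function(n_iter = 4000, burn_in = 500, thin = 4, seed = 1, ...)
  bayesc_config(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
                ...)
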