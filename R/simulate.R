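#' Simulation configuration
#'
#' Defines the statistical structure of the synthetic experiment: a diversity
#' panel of inbred lines genotyped at SNPs organised in LD blocks, evaluated
#' in a randomised design (replications with blocks nested within
#' replication) under two managements (B+ with, B- without growth-promoting
#' bacteria inoculation), with sparse marker architectures and hyperspectral
#' reflectance phenotypes genetically correlated with the growth traits.
#'
#' Defaults emulate the greenhouse study the package targets: 360 lines,
#' 13,826 SNPs on 10 chromosomes after QC, 2 replications, a 0.99 exclusion
#' prior (so roughly 1% of markers carry effects), per-trait heritabilities
#' of 0.61/0.60/0.30 (plant height, stalk diameter, shoot dry mass under
#' inoculation), moderate positive genetic correlations among growth traits,
#' and 150 bands spanning 386-1021 nm.
#'
#' @param n_lines number of inbred lines.
#' @param n_markers total SNP count (distributed over chromosomes; any
#'   remainder goes to the first chromosomes).
#' @param maf_range minor-allele-frequency range `(lo, hi]` within `(0, 0.5]`
#'   for the per-marker founder frequency.
#' @param n_chrom number of chromosomes.
#' @param ld_block_size markers per correlated LD block (1 = independent
#'   markers).
#' @param ld_flip_prob per-allele probability that a copied allele is
#'   resampled from the founder frequency when generating an LD block
#'   (controls within-block r2).
#' @param n_rep replications per management.
#' @param n_block blocks nested within each replication.
#' @param rep_block_sd standard deviation of the fixed replication and block
#'   effects (drawn once per simulation, treated as fixed unknowns by the
#'   samplers).
#' @param pi_sparsity probability a marker has zero effect.
#' @param n_causal optional exact number of causal markers; overrides the
#'   binomial draw implied by `pi_sparsity` (useful for controlled recovery
#'   experiments).
#' @param h2_target named numeric vector of per-trait plot-level
#'   heritabilities in `[0, 1)`; its length sets the number of traits.
#' @param rg_target genetic correlation matrix among traits (symmetric PSD,
#'   unit diagonal).
#' @param management_shift additive mean offset of B+ relative to B-.
#' @param management_resample_frac fraction of causal markers whose effects
#'   are redrawn independently under B+, so the two managements' genetic
#'   architectures overlap only partially.
#' @param n_bands number of hyperspectral bands.
#' @param band_range_nm wavelength range of the (uniform) band grid.
#' @param spectra_loading_scale reflectance change per genetic standard
#'   deviation injected into the bands.
#' @param spectra_noise_sd standard deviation of the smooth non-genetic
#'   reflectance noise.
#' @param residual_sd residual standard deviation of the growth traits.
#' @param seed integer master seed; each stage uses a documented offset of
#'   it (`+101` genotypes, `+202` traits, `+303` spectra) so stages are
#'   reproducible independently.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 360, n_markers = 13826, maf_range = c(0.05, 0.5),
                       n_chrom = 10, ld_block_size = 5, ld_flip_prob = 0.1,
                       n_rep = 2, n_block = 10, rep_block_sd = 0.5,
                       pi_sparsity = 0.99, n_causal = NULL,
                       h2_target = c(PH = 0.61, SD = 0.60, SDM = 0.30),
                       rg_target = NULL, management_shift = 0.5,
                       management_resample_frac = 0.8,
                       n_bands = 150, band_range_nm = c(386, 1021),
                       spectra_loading_scale = 0.02, spectra_noise_sd = 0.01,
                       residual_sd = 1, seed = 1) {
  k <- length(h2_target)
  if (is.null(rg_target)) {
    rg_target <- matrix(0.3, k, k)
    diag(rg_target) <- 1
  }
  cfg <- list(n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
              maf_range = maf_range, n_chrom = as.integer(n_chrom),
              ld_block_size = as.integer(ld_block_size),
              ld_flip_prob = ld_flip_prob, n_rep = as.integer(n_rep),
              n_block = as.integer(n_block), rep_block_sd = rep_block_sd,
              pi_sparsity = pi_sparsity, n_causal = n_causal,
              h2_target = h2_target, rg_target = rg_target,
              management_shift = management_shift,
              management_resample_frac = management_resample_frac,
              n_bands = as.integer(n_bands), band_range_nm = band_range_nm,
              spectra_loading_scale = spectra_loading_scale,
              spectra_noise_sd = spectra_noise_sd,
              residual_sd = residual_sd, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_lines >= 1, n_markers >= 1, n_chrom >= 1, ld_block_size >= 1,
              n_rep >= 1, n_block >= 1, n_bands >= 1)
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
      stop("maf_range must lie within (0, 0.5]")
    if (pi_sparsity < 0 || pi_sparsity > 1)
      stop("pi_sparsity must be a probability")
    if (any(h2_target < 0) || any(h2_target >= 1))
      stop("h2_target entries must be in [0, 1); h2 = 1 leaves no residual variance")
    k <- length(h2_target)
    if (!isTRUE(all.equal(rg_target, t(rg_target))) ||
        nrow(rg_target) != k)
      stop("rg_target must be a symmetric ", k, "x", k, " matrix")
    if (any(diag(rg_target) != 1)) stop("rg_target diagonal must be 1")
    ev <- eigen(rg_target, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("rg_target must be positive semidefinite")
    if (band_range_nm[1] >= band_range_nm[2]) stop("band_range_nm must increase")
  })
  invisible(cfg)
}

#' Simulate genotypes with block LD structure
#'
#' Dosages are sampled per marker from a binomial with founder allele
#' frequency drawn uniformly in `maf_range`. Within each LD block the first
#' marker is drawn fresh and subsequent markers copy the previous marker's
#' alleles, each allele being resampled from the founder frequency with
#' probability `ld_flip_prob`; blocks are independent, so pairwise r2 decays
#' geometrically within a block and is zero across blocks. Positions are
#' strictly increasing within chromosome with random inter-marker spacing.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()]; deterministic given `config` (including
#'   seed).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 101L)
  n <- config$n_lines
  per_chrom <- rep(config$n_markers %/% config$n_chrom, config$n_chrom)
  rem <- config$n_markers %% config$n_chrom
  if (rem > 0) per_chrom[seq_len(rem)] <- per_chrom[seq_len(rem)] + 1L

  cols <- vector("list", config$n_chrom)
  chrom <- integer(0); pos <- integer(0)
  for (ch in seq_len(config$n_chrom)) {
    m_c <- per_chrom[ch]
    if (m_c == 0) next
    d <- matrix(0L, n, m_c)
    a1 <- a2 <- NULL; p <- NA_real_
    for (j in seq_len(m_c)) {
      new_block <- ((j - 1) %% config$ld_block_size) == 0
      if (new_block) {
        p <- stats::runif(1, config$maf_range[1], config$maf_range[2])
        a1 <- stats::rbinom(n, 1, p)
        a2 <- stats::rbinom(n, 1, p)
      } else {
        flip1 <- stats::runif(n) < config$ld_flip_prob
        flip2 <- stats::runif(n) < config$ld_flip_prob
        a1[flip1] <- stats::rbinom(sum(flip1), 1, p)
        a2[flip2] <- stats::rbinom(sum(flip2), 1, p)
      }
      d[, j] <- a1 + a2
    }
    cols[[ch]] <- d
    gaps <- as.integer(round(stats::runif(m_c, 5e3, 3e5)))
    pos <- c(pos, cumsum(gaps))
    chrom <- c(chrom, rep(ch, m_c))
  }
  genotype_matrix(do.call(cbind, cols), chrom = chrom, pos_bp = pos)
}

#' Simulate growth traits with known genetic architecture
#'
#' For each management a sparse set of causal markers carries effects drawn
#' jointly across traits from a multivariate normal with correlation
#' `rg_target`; per-trait effects are rescaled so the plot-level heritability
#' `Var(g) / (Var(g) + sigma2_e / n_rep)` equals `h2_target` exactly in the
#' realized genetic values. Under B+ a configurable fraction of causal
#' markers has its effects redrawn independently, so the two managements
#' share genotypes but only part of the architecture. Phenotypes add fixed
#' replication and block-within-replication effects (drawn once) and i.i.d.
#' Gaussian residuals.
#'
#' @param G a [genotype_matrix()] (typically from [simulate_genotypes()]).
#' @param config a [sim_config()].
#' @return a list with `phenotypes` (plot-level data frame: `plot_id`,
#'   `line_id`, `management`, `rep`, `block`, one column per trait) and
#'   `truth` (a `sim_truth` object recording causal markers, per-management
#'   effects, realized heritabilities and genetic correlations, and
#'   line-level genetic values).
#' @export
simulate_traits <- function(G, config) {
  validate_sim_config(config)
  stopifnot(inherits(G, "genotype_matrix"))
  set.seed(config$seed + 202L)
  n <- nrow(G$dosages); m <- ncol(G$dosages)
  k <- length(config$h2_target)
  traits <- names(config$h2_target)
  if (is.null(traits)) traits <- paste0("trait", seq_len(k))

  if (is.null(config$n_causal)) {
    causal <- which(stats::runif(m) > config$pi_sparsity)
  } else {
    causal <- sort(sample.int(m, min(config$n_causal, m)))
  }
  Lr <- chol_psd(config$rg_target)
  draw_effects <- function(idx) {
    # rows = markers, columns = traits; joint across traits
    matrix(stats::rnorm(length(idx) * k), length(idx), k) %*% Lr
  }
  eff <- list(`B-` = matrix(0, m, k), `B+` = matrix(0, m, k))
  if (length(causal) > 0) {
    base <- draw_effects(causal)
    eff[["B-"]][causal, ] <- base
    eff_bp <- base
    n_res <- round(config$management_resample_frac * length(causal))
    if (n_res > 0) {
      res_idx <- sample(seq_along(causal), n_res)
      eff_bp[res_idx, ] <- draw_effects(causal[res_idx])
    }
    eff[["B+"]][causal, ] <- eff_bp
  }

  sigma_e2 <- config$residual_sd^2
  gvals <- list()
  for (mg in names(eff)) {
    g <- G$dosages %*% eff[[mg]]
    for (t in seq_len(k)) {
      h2 <- config$h2_target[t]
      v_target <- if (h2 > 0) h2 / (1 - h2) * sigma_e2 / config$n_rep else 0
      vg <- stats::var(g[, t])
      if (v_target == 0 || vg == 0) {
        eff[[mg]][, t] <- 0
        g[, t] <- 0
      } else {
        s <- sqrt(v_target / vg)
        eff[[mg]][, t] <- eff[[mg]][, t] * s
        g[, t] <- g[, t] * s
      }
    }
    colnames(g) <- traits
    gvals[[mg]] <- g
  }

  # design, shared across managements: lines randomised to blocks per rep
  rep_eff <- stats::rnorm(config$n_rep, 0, config$rep_block_sd)
  block_eff <- matrix(stats::rnorm(config$n_rep * config$n_block, 0,
                                   config$rep_block_sd),
                      config$n_rep, config$n_block)
  design <- do.call(rbind, lapply(seq_len(config$n_rep), function(r) {
    data.frame(line = seq_len(n), rep = r,
               block = sample(rep(seq_len(config$n_block), length.out = n)))
  }))

  rows <- list()
  for (mg in names(eff)) {
    shift <- if (mg == "B+") config$management_shift else 0
    y <- matrix(shift + rep_eff[design$rep] + block_eff[cbind(design$rep, design$block)],
                nrow(design), k) +
      gvals[[mg]][design$line, , drop = FALSE] +
      matrix(stats::rnorm(nrow(design) * k, 0, config$residual_sd),
             nrow(design), k)
    colnames(y) <- traits
    rows[[mg]] <- data.frame(
      line_id = rownames(G$dosages)[design$line], management = mg,
      rep = design$rep, block = design$block, y, check.names = FALSE,
      stringsAsFactors = FALSE)
  }
  pheno <- do.call(rbind, rows)
  pheno <- data.frame(plot_id = sprintf("P%05d", seq_len(nrow(pheno))), pheno,
                      stringsAsFactors = FALSE)
  rownames(pheno) <- NULL

  realized_h2 <- vapply(names(gvals), function(mg)
    apply(gvals[[mg]], 2, function(g)
      stats::var(g) / (stats::var(g) + sigma_e2 / config$n_rep)),
    numeric(k))
  if (k == 1) realized_h2 <- matrix(realized_h2, 1,
                                    dimnames = list(traits, names(gvals)))
  realized_rg <- lapply(gvals, function(g) {
    r <- suppressWarnings(stats::cor(g))
    r[!is.finite(r)] <- 0
    diag(r) <- 1
    r
  })
  truth <- structure(
    list(causal_marker_ids = G$map$marker_id[causal],
         true_effects = eff, true_h2 = realized_h2, true_rg = realized_rg,
         true_genetic_values = gvals, traits = traits,
         rep_effects = rep_eff, block_effects = block_eff),
    class = "sim_truth")
  list(phenotypes = pheno, truth = truth)
}

chol_psd <- function(S) {
  # upper Cholesky factor, tolerant of a semidefinite correlation matrix
  ev <- eigen(S, symmetric = TRUE)
  v <- pmax(ev$values, 0)
  t(ev$vectors %*% diag(sqrt(v), length(v)))
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$causal_marker_ids), "causal markers,",
      length(x$traits), "trait(s)\n")
  cat("  realized h2 (B+):",
      paste(sprintf("%s=%.3f", x$traits, x$true_h2[, "B+"]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Baseline vegetation reflectance template
#'
#' Smooth leaf-like reflectance: low visible reflectance with a green bump
#' near 550 nm, chlorophyll absorption near 670 nm, and a red-edge rise to a
#' NIR plateau.
#'
#' @param wavelengths_nm numeric vector of wavelengths.
#' @return reflectance values in `[0, 1]`.
#' @export
baseline_reflectance <- function(wavelengths_nm) {
  w <- wavelengths_nm
  r <- 0.05 + 0.05 * exp(-((w - 550) / 35)^2) -
    0.02 * exp(-((w - 670) / 25)^2) + 0.40 / (1 + exp(-(w - 715) / 12))
  pmin(pmax(r, 0), 1)
}

#' Simulate per-plot hyperspectral reflectance
#'
#' Each plot's spectrum is the baseline template plus band-specific loadings
#' times the plot's genetic values plus smooth correlated noise (a low-order
#' random Fourier series), clipped to `[0, 1]`. The loading curve of trait
#' `t` is a phase-shifted sinusoid across the spectral range, so band-trait
#' genetic correlations change sign along the spectrum.
#'
#' @param G a [genotype_matrix()] (provides line identifiers and, through
#'   `truth`, genetic values).
#' @param truth a `sim_truth` from [simulate_traits()].
#' @param phenotypes the plot table from [simulate_traits()] (defines the
#'   plots the spectra belong to).
#' @param config a [sim_config()].
#' @param loadings optional `n_bands x n_traits` matrix overriding the
#'   default sinusoid loadings (e.g. all zero for a no-signal spectrum).
#' @return a `spectra_table` data frame: `plot_id` then one `R<nm>` column
#'   per band; wavelengths retrievable with [spectra_wavelengths()]. The
#'   loading matrix used is attached as attribute `loadings`.
#' @export
simulate_spectra <- function(G, truth, phenotypes, config, loadings = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 303L)
  wl <- seq(config$band_range_nm[1], config$band_range_nm[2],
            length.out = config$n_bands)
  k <- length(truth$traits)
  if (is.null(loadings)) {
    x <- (wl - wl[1]) / (wl[length(wl)] - wl[1])
    loadings <- sapply(seq_len(k), function(t)
      sin(2 * pi * (1 + 0.5 * (t - 1)) * x + (t - 1) * pi / 3))
    loadings <- loadings * config$spectra_loading_scale
  }
  stopifnot(nrow(loadings) == config$n_bands, ncol(loadings) == k)

  base <- baseline_reflectance(wl)
  n_plot <- nrow(phenotypes)
  # genetic signal per plot
  gsig <- matrix(0, n_plot, config$n_bands)
  for (mg in names(truth$true_genetic_values)) {
    rows <- which(phenotypes$management == mg)
    li <- match(phenotypes$line_id[rows], rownames(G$dosages))
    gv <- truth$true_genetic_values[[mg]][li, , drop = FALSE]
    gsig[rows, ] <- gv %*% t(loadings)
  }
  # smooth correlated noise: low-order Fourier series with random coefficients
  xs <- (wl - wl[1]) / (wl[length(wl)] - wl[1])
  basis <- cbind(1, sin(2 * pi * xs), cos(2 * pi * xs),
                 sin(4 * pi * xs), cos(4 * pi * xs))
  coefs <- matrix(stats::rnorm(n_plot * ncol(basis), 0, config$spectra_noise_sd),
                  n_plot, ncol(basis))
  refl <- matrix(base, n_plot, config$n_bands, byrow = TRUE) + gsig +
    coefs %*% t(basis)
  refl <- pmin(pmax(refl, 0), 1)
  colnames(refl) <- paste0("R", round(wl))
  out <- data.frame(plot_id = phenotypes$plot_id, refl, check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "wavelengths_nm") <- wl
  attr(out, "loadings") <- loadings
  class(out) <- c("spectra_table", "data.frame")
  out
}

#' Wavelength grid of a spectra table
#' @param spectra a `spectra_table` (or any data frame with `R<nm>` columns).
#' @return numeric vector of wavelengths in nm.
#' @export
spectra_wavelengths <- function(spectra) {
  wl <- attr(spectra, "wavelengths_nm")
  if (!is.null(wl)) return(wl)
  nm <- grep("^R[0-9.]+$", names(spectra), value = TRUE)
  as.numeric(sub("^R", "", nm))
}

#' Simulate a hyperspectral cube with a rectangular leaf region
#'
#' Pixels inside the leaf rectangle carry the supplied reflectance vector
#' plus i.i.d. Gaussian noise per pixel and band; background pixels carry a
#' constant `background_value`. The leaf mask is recoverable by thresholding
#' any band on which leaf and background reflectances differ.
#'
#' @param reflectance per-band leaf reflectance vector.
#' @param shape `c(rows, cols)` pixel dimensions.
#' @param background_value background reflectance (default 0).
#' @param leaf_rows,leaf_cols integer ranges of the leaf rectangle; default
#'   is the centered half-size rectangle.
#' @param noise_sd per-pixel reflectance noise standard deviation.
#' @param wavelengths_nm band wavelengths; default uniform over 386-1021 nm.
#' @return a `hyperspectral_cube`: list with `values`
#'   (`rows x cols x bands` array, clipped to `[0, 1]`), `wavelengths_nm`,
#'   and the leaf `mask`.
#' @export
simulate_cube <- function(reflectance, shape = c(40, 40), background_value = 0,
                          leaf_rows = NULL, leaf_cols = NULL, noise_sd = 0,
                          wavelengths_nm = NULL) {
  nb <- length(reflectance)
  if (is.null(wavelengths_nm))
    wavelengths_nm <- seq(386, 1021, length.out = nb)
  stopifnot(length(wavelengths_nm) == nb, length(shape) == 2)
  if (is.null(leaf_rows))
    leaf_rows <- seq(floor(shape[1] / 4) + 1, floor(3 * shape[1] / 4))
  if (is.null(leaf_cols))
    leaf_cols <- seq(floor(shape[2] / 4) + 1, floor(3 * shape[2] / 4))
  if (max(leaf_rows) > shape[1] || max(leaf_cols) > shape[2] ||
      min(leaf_rows) < 1 || min(leaf_cols) < 1)
    stop("leaf region exceeds cube dimensions ", shape[1], "x", shape[2])
  vals <- array(background_value, dim = c(shape[1], shape[2], nb))
  mask <- matrix(FALSE, shape[1], shape[2])
  mask[leaf_rows, leaf_cols] <- TRUE
  n_leaf <- sum(mask)
  for (b in seq_len(nb)) {
    plane <- vals[, , b]
    px <- rep(reflectance[b], n_leaf)
    if (noise_sd > 0) px <- px + stats::rnorm(n_leaf, 0, noise_sd)
    plane[mask] <- px
    vals[, , b] <- pmin(pmax(plane, 0), 1)
  }
  structure(list(values = vals, wavelengths_nm = wavelengths_nm, mask = mask),
            class = "hyperspectral_cube")
}

#' Write simulation ground truth as JSON
#' @param truth a `sim_truth`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  out <- list(causal_marker_ids = truth$causal_marker_ids,
              traits = truth$traits,
              true_h2 = as.data.frame(truth$true_h2),
              true_rg = lapply(truth$true_rg, function(m) unclass(m)),
              true_effects = lapply(truth$true_effects, function(m) {
                nz <- which(rowSums(m != 0) > 0)
                list(marker_index = nz, effects = unclass(m[nz, , drop = FALSE]))
              }))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
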