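#' Configuration for the bivariate BayesC sampler
#'
#' Two-trait spike-and-slab regression with per-marker inclusion indicators
#' `delta_j = (delta_j1, delta_j2)` over the four categories (0,0), (0,1),
#' (1,0), (1,1), marker-effect covariance `Sigma_alpha` and residual
#' covariance `Sigma_eps`, both with inverse-Wishart priors. The default
#' category prior is the product of independent per-trait inclusion
#' probabilities (`pi_t = 0.99` each, so (0,0) has prior mass 0.9801); all
#' four categories keep nonzero probability. Inverse-Wishart scale matrices
#' are set so each prior mean (`S / (nu - dim - 1)`) equals the configured
#' partition of the phenotypic (co)variance, with zero prior covariance.
#'
#' @param pi_t length-2 prior exclusion probability per trait.
#' @param delta_prior optional length-4 probability vector over categories
#'   in order (0,0), (0,1), (1,0), (1,1); must sum to 1.
#' @param wishart_df inverse-Wishart degrees of freedom for both covariance
#'   priors (must exceed `dim + 1 = 3`).
#' @param variance_partition fraction of each trait's phenotypic variance
#'   assigned a priori to each component.
#' @param n_iter,burn_in,thin,seed,n_rep_for_h2 as in [bayesc_config()].
#' @param center_markers center marker covariates before sampling.
#' @param keep_g store line-level genetic-value draws
#'   (`lines x 2 x retained` array).
#' @return a list of class `bayesc_biv_config`.
#' @export
bivariate_config <- function(pi_t = c(0.99, 0.99), delta_prior = NULL,
                             wishart_df = 4, variance_partition = 0.5,
                             n_iter = 60000, burn_in = 6000, thin = 60,
                             seed = NULL, n_rep_for_h2 = 2,
                             center_markers = TRUE, keep_g = FALSE) {
  stopifnot(length(pi_t) == 2, all(pi_t >= 0), all(pi_t <= 1),
            wishart_df > 3, burn_in < n_iter, thin >= 1)
  if (is.null(delta_prior)) {
    p1 <- 1 - pi_t[1]; p2 <- 1 - pi_t[2]
    delta_prior <- c((1 - p1) * (1 - p2), (1 - p1) * p2, p1 * (1 - p2),
                     p1 * p2)
  }
  stopifnot(length(delta_prior) == 4, all(delta_prior > 0),
            abs(sum(delta_prior) - 1) < 1e-8)
  structure(list(pi_t = pi_t, delta_prior = delta_prior,
                 wishart_df = wishart_df,
                 variance_partition = variance_partition,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed,
                 n_rep_for_h2 = n_rep_for_h2, center_markers = center_markers,
                 keep_g = keep_g),
            class = "bayesc_biv_config")
}

#' Fit bivariate BayesC by Gibbs sampling
#'
#' Per iteration: fixed effects per trait from their Gaussian full
#' conditionals (flat prior, accounting for residual correlation); for each
#' marker the four-category inclusion indicator is sampled with the effect
#' vector integrated out under the active sub-block of `Sigma_alpha`,
#' followed by the active effects; `Sigma_alpha` from its inverse-Wishart
#' full conditional over markers with at least one active trait (inactive
#' components filled in from the conditional prior); `Sigma_eps` from its
#' inverse-Wishart full conditional of the residuals. Per retained draw the
#' genomic correlation is the Pearson correlation of the two traits'
#' line-level genetic values (draws with a zero-variance genetic value are
#' skipped and counted); the correlation implied by `Sigma_alpha` is also
#' recorded. Non-positive-definite covariance draws are retried with a
#' logged diagonal jitter.
#'
#' @param Y numeric matrix/data frame with exactly 2 complete phenotype
#'   columns (one row per plot).
#' @param design as in [fit_bayesc()] (shared by both traits).
#' @param geno a [genotype_matrix()] with no missing dosages.
#' @param config a [bivariate_config()].
#' @return an object of class `bayesc_biv_fit` with posterior means of
#'   `Sigma_alpha` and `Sigma_eps`, `genomic_correlation` (mean + 95% CI of
#'   per-draw genetic-value correlations), `rg_from_Sigma_alpha`, per-trait
#'   `pip` and `h2`, per-marker category frequencies, chains, and jitter /
#'   skipped-draw counters.
#' @export
fit_bayesc_bivariate <- function(Y, design = NULL, geno,
                                 config = bivariate_config()) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(config, "bayesc_biv_config"))
  Y <- as.matrix(Y)
  if (ncol(Y) != 2) stop("Y must have exactly two phenotype columns")
  if (!all(is.finite(Y))) stop("both phenotype columns must be complete")
  if (any(apply(Y, 2, stats::var) == 0))
    stop("phenotype column has zero variance")
  trait_names <- colnames(Y) %||% c("trait1", "trait2")

  if (is.data.frame(design) && !is.null(design$line_id)) {
    li <- match(design$line_id, rownames(geno$dosages))
    if (anyNA(li)) stop("design rows reference unknown line_id(s)")
    W <- geno$dosages[li, , drop = FALSE]
    line_rows <- vapply(seq_len(nrow(geno$dosages)),
                        function(l) which(li == l)[1], 1L)
    line_rows <- line_rows[!is.na(line_rows)]
  } else {
    if (nrow(Y) != nrow(geno$dosages))
      stop("without line_id mapping, Y must have one row per genotyped line")
    W <- geno$dosages
    line_rows <- seq_len(nrow(W))
  }
  X <- build_design_matrix(design, nrow(Y))

  p_frq <- colMeans(geno$dosages) / 2
  if (config$center_markers && ncol(W) > 0)
    W <- sweep(W, 2, colMeans(W))

  nu <- config$wishart_df
  sum2pq <- max(sum(2 * p_frq * (1 - p_frq)), 1e-8)
  vy <- apply(Y, 2, stats::var)
  e_s2a <- config$variance_partition * vy /
    (pmax(1 - config$pi_t, 1e-8) * sum2pq)
  # prior mean of IW(S, nu) is S/(nu - dim - 1); diagonal target, zero covariance
  S_alpha <- diag(e_s2a * (nu - 3), 2)
  S_eps <- diag(config$variance_partition * vy * (nu - 3), 2)

  if (!is.null(config$seed)) set.seed(config$seed)
  res <- bayesc_biv_gibbs_cpp(Y, X, W, log(config$delta_prior), nu,
                              S_alpha, S_eps, config$n_iter, config$burn_in,
                              config$thin, config$n_rep_for_h2,
                              as.matrix(line_rows - 1L), config$keep_g)

  Sa <- matrix(colMeans(res$chain_Sigma_alpha), 2, 2)
  Se <- matrix(colMeans(res$chain_Sigma_eps), 2, 2)
  dimnames(Sa) <- dimnames(Se) <- list(trait_names, trait_names)
  rg <- res$chain_rg
  rg_ok <- rg[is.finite(rg)]
  chains <- list(rg = as.numeric(rg),
                 rg_from_Sigma_alpha = as.numeric(res$chain_rg_Sigma_alpha),
                 h2_trait1 = as.numeric(res$chain_h2_trait1),
                 h2_trait2 = as.numeric(res$chain_h2_trait2),
                 Sigma_alpha = res$chain_Sigma_alpha,
                 Sigma_eps = res$chain_Sigma_eps)
  pip <- res$pip
  dimnames(pip) <- list(geno$map$marker_id, trait_names)
  cat_freq <- res$category_freq
  dimnames(cat_freq) <- list(geno$map$marker_id,
                             c("00", "01", "10", "11"))

  structure(list(
    traits = trait_names,
    post_mean_Sigma_alpha = Sa, post_mean_Sigma_eps = Se,
    genomic_correlation = mean(rg_ok),
    genomic_correlation_ci = unname(stats::quantile(rg_ok, c(0.025, 0.975))),
    rg_from_Sigma_alpha = mean(chains$rg_from_Sigma_alpha),
    h2 = c(mean(chains$h2_trait1), mean(chains$h2_trait2)),
    pip = pip, category_freq = cat_freq,
    post_mean_alpha = res$post_mean_alpha,
    chains = chains,
    g_draws = if (config$keep_g) res$chain_g else NULL,
    n_retained = res$n_retained,
    jitter_count = res$jitter_count,
    rg_draws_skipped = res$rg_draws_skipped,
    config = config), class = "bayesc_biv_fit")
}

#' @export
print.bayesc_biv_fit <- function(x, ...) {
  cat("bayesc_biv_fit:", paste(x$traits, collapse = " x "), "|",
      x$n_retained, "retained draws\n")
  cat(sprintf("  genomic correlation = %.3f [%.3f, %.3f] (Sigma_alpha: %.3f)\n",
              x$genomic_correlation, x$genomic_correlation_ci[1],
              x$genomic_correlation_ci[2], x$rg_from_Sigma_alpha))
  cat(sprintf("  h2: %s = %.3f, %s = %.3f\n", x$traits[1], x$h2[1],
              x$traits[2], x$h2[2]))
  invisible(x)
}

#' Genomic correlation from genetic-value draws
#'
#' Computes the per-draw Pearson correlation of the two traits' genetic
#' values and summarizes across draws. Draws in which either trait has zero
#' genetic variance are skipped and counted.
#'
#' @param g_draws numeric array `draws x lines x 2` (or `lines x 2 x draws`
#'   as stored by [fit_bayesc_bivariate()] with `keep_g = TRUE`).
#' @return list with `mean`, `lower`, `upper` (central 95% interval),
#'   `n_used`, `n_skipped`.
#' @export
genomic_correlation_from_draws <- function(g_draws) {
  d <- dim(g_draws)
  stopifnot(length(d) == 3)
  if (d[3] == 2) {                         # draws x lines x 2
    nd <- d[1]
    get <- function(i) g_draws[i, , ]
  } else if (d[2] == 2) {                  # lines x 2 x draws
    nd <- d[3]
    get <- function(i) g_draws[, , i]
  } else stop("cannot identify the trait dimension (no axis of length 2)")
  if (nd < 10) stop("need at least 10 draws")
  rs <- vapply(seq_len(nd), function(i) {
    g <- get(i)
    if (stats::var(g[, 1]) == 0 || stats::var(g[, 2]) == 0) return(NA_real_)
    stats::cor(g[, 1], g[, 2])
  }, 0)
  ok <- rs[!is.na(rs)]
  if (length(ok) == 0) stop("all draws had zero-variance genetic values")
  list(mean = mean(ok),
       lower = unname(stats::quantile(ok, 0.025)),
       upper = unname(stats::quantile(ok, 0.975)),
       n_used = length(ok), n_skipped = sum(is.na(rs)))
}

#' Run bivariate fits over a list of trait-phenotype pairs
#'
#' Fits one bivariate model per (manual trait, hyperspectral phenotype)
#' pair and management, and returns the long-format table behind a genomic-
#' correlation spectrum plot.
#'
#' @param data plot-level data frame containing `line_id`, `rep`, `block`,
#'   a `management` column, and all phenotype columns referenced by `pairs`.
#' @param pairs data frame with columns `trait` and `phenotype` (column
#'   names in `data`).
#' @param geno a [genotype_matrix()].
#' @param config a [bivariate_config()]; its seed is advanced
#'   deterministically per fit.
#' @param managements managements to fit (default: all present).
#' @return data frame: `management`, `trait`, `phenotype`, `rg_mean`,
#'   `rg_low`, `rg_high`, `h2_trait`, `h2_phenotype`.
#' @export
fit_rg_pairs <- function(data, pairs, geno, config = bivariate_config(),
                         managements = NULL) {
  stopifnot(all(c("trait", "phenotype") %in% names(pairs)))
  if (is.null(managements)) managements <- unique(data$management)
  rows <- list()
  fit_id <- 0L
  for (mg in managements) {
    sub <- data[data$management == mg, , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      fit_id <- fit_id + 1L
      tr <- pairs$trait[i]; ph <- pairs$phenotype[i]
      cfg <- config
      if (!is.null(config$seed)) cfg$seed <- config$seed + fit_id
      fit <- fit_bayesc_bivariate(
        as.matrix(sub[, c(tr, ph)]),
        design = sub[, intersect(c("line_id", "rep", "block"), names(sub))],
        geno = geno, config = cfg)
      rows[[fit_id]] <- data.frame(
        management = mg, trait = tr, phenotype = ph,
        rg_mean = fit$genomic_correlation,
        rg_low = fit$genomic_correlation_ci[1],
        rg_high = fit$genomic_correlation_ci[2],
        h2_trait = fit$h2[1], h2_phenotype = fit$h2[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
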