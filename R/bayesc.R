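#' Configuration for the univariate BayesC sampler
#'
#' Defaults follow common practice for spike-and-slab whole-genome
#' regression of moderately sized diversity panels: exclusion prior
#' `pi = 0.99` (about 1% of markers in the model at a time), scaled
#' inverse-chi-squared priors with 4 degrees of freedom on both variances
#' with scales chosen so each prior variance mean equals half of the
#' phenotypic variance, and a 60,000-iteration chain with 6,000 burn-in
#' and thinning of 60 (900 retained samples).
#'
#' The slab-variance prior scale is derived from the phenotypic variance
#' through the standard marker-variance partition: the implied prior genetic
#' variance `(1 - pi) * sum_j 2 p_j (1 - p_j) * E[sigma2_alpha]` is set
#' equal to `variance_partition * Var(y)`.
#'
#' @param pi prior exclusion probability of a marker (fixed, never
#'   estimated).
#' @param prior_df degrees of freedom of both scaled inverse-chi-squared
#'   priors (must exceed 2 so the prior mean exists).
#' @param variance_partition fraction of phenotypic variance assigned a
#'   priori to each variance component.
#' @param n_iter,burn_in,thin MCMC schedule; `burn_in < n_iter`,
#'   `thin >= 1`; retained draws = `floor((n_iter - burn_in)/thin)`.
#' @param seed integer RNG seed (`set.seed()` is called before sampling when
#'   non-`NULL`).
#' @param n_rep_for_h2 replication count `nr` in the heritability formula
#'   `h2 = sigma2_g / (sigma2_g + sigma2_e / nr)`.
#' @param update_variances sample the two variances (`TRUE`) or hold them
#'   fixed at `sigma2_alpha`/`sigma2_eps` (used for validation against
#'   closed-form oracles).
#' @param sigma2_alpha,sigma2_eps fixed variance values, required when
#'   `update_variances = FALSE`.
#' @param center_markers center marker covariates before sampling (improves
#'   mixing with an intercept in the model; disable to match raw-scale
#'   oracles).
#' @param keep_alpha store the full marker-effect chain (`retained x m`
#'   matrix; memory-heavy for large panels).
#' @return a validated list of class `bayesc_config`.
#' @export
bayesc_config <- function(pi = 0.99, prior_df = 4, variance_partition = 0.5,
                          n_iter = 60000, burn_in = 6000, thin = 60,
                          seed = NULL, n_rep_for_h2 = 2,
                          update_variances = TRUE, sigma2_alpha = NULL,
                          sigma2_eps = NULL, center_markers = TRUE,
                          keep_alpha = FALSE) {
  stopifnot(pi >= 0, pi <= 1, prior_df > 2, burn_in < n_iter, thin >= 1,
            variance_partition > 0, variance_partition <= 1,
            n_rep_for_h2 >= 1)
  if (!update_variances && (is.null(sigma2_alpha) || is.null(sigma2_eps)))
    stop("fixed-variance runs need sigma2_alpha and sigma2_eps")
  structure(list(pi = pi, prior_df = prior_df,
                 variance_partition = variance_partition,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed,
                 n_rep_for_h2 = n_rep_for_h2,
                 update_variances = update_variances,
                 sigma2_alpha = sigma2_alpha, sigma2_eps = sigma2_eps,
                 center_markers = center_markers, keep_alpha = keep_alpha),
            class = "bayesc_config")
}

#' Fixed-effect design matrix with reference-level coding
#'
#' Builds the design for the model mean: intercept, replication dummies and
#' block-within-replication dummies, all with the first level as reference
#' and flat priors. `design = NULL` yields an intercept-only model and
#' `design = "none"` a zero-column matrix (known zero mean, used in
#' validation).
#'
#' @param design `NULL`, `"none"`, or a data frame with columns `rep` and
#'   `block` (block labels are interpreted within replication) and
#'   optionally `line_id`.
#' @param n number of plots (rows).
#' @return numeric design matrix with named columns.
#' @export
build_design_matrix <- function(design, n) {
  if (identical(design, "none"))
    return(matrix(numeric(0), n, 0))
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(design)) return(X)
  stopifnot(nrow(design) == n)
  if (!is.null(design$rep)) {
    r <- factor(design$rep)
    if (nlevels(r) > 1) {
      Xr <- stats::model.matrix(~r)[, -1, drop = FALSE]
      colnames(Xr) <- paste0("rep", levels(r)[-1])
      X <- cbind(X, Xr)
    }
    if (!is.null(design$block)) {
      # blocks nested within replication: drop one block per replication
      for (lev in levels(r)) {
        rows <- design$rep == lev
        b <- factor(design$block[rows])
        if (nlevels(b) < 2) next
        for (bl in levels(b)[-1]) {
          col <- as.numeric(rows & design$block == bl)
          X <- cbind(X, col)
          colnames(X)[ncol(X)] <- paste0("rep", lev, ":block", bl)
        }
      }
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; confounded columns: ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Fit univariate BayesC by Gibbs sampling
#'
#' Model: `y = mu + rep + block(rep) + sum_j w_ij alpha_j + eps`, with flat
#' priors on the fixed effects, a spike-and-slab prior on each marker effect
#' (`alpha_j = 0` with probability `pi`, else `N(0, sigma2_alpha)`), and
#' scaled inverse-chi-squared priors on `sigma2_alpha` and `sigma2_eps`.
#' Each Gibbs sweep samples fixed effects, every marker's inclusion
#' indicator (effect integrated out) and effect, and the two variances, with
#' the residual vector updated incrementally after every move. Per retained
#' draw the genomic variance `sigma2_g` is the empirical variance of the
#' genetic values `W alpha` across plots, and heritability is
#' `sigma2_g / (sigma2_g + sigma2_eps / nr)`; the marker's posterior
#' inclusion probability (PIP) is the fraction of retained draws with a
#' nonzero effect.
#'
#' @param y numeric phenotype vector (one value per plot).
#' @param design `NULL` (intercept only), `"none"`, or a data frame with one
#'   row per plot: `line_id` mapping plots to genotyped lines, plus optional
#'   `rep` and `block` factors (see [build_design_matrix()]). When `NULL` or
#'   `"none"`, `y` must be line-level (one value per genotype row).
#' @param geno a [genotype_matrix()] with no missing dosages.
#' @param config a [bayesc_config()].
#' @return an object of class `bayesc_fit`: `markers` (data frame
#'   `marker_id`, `chrom`, `pos_bp`, `maf`, `post_mean_alpha`, `pip`),
#'   `chains` (retained draws of `sigma2_alpha`, `sigma2_eps`, `sigma2_g`,
#'   `h2`, `n_included`, fixed effects; plus `alpha` when requested),
#'   `h2` (posterior mean of the per-draw ratio), `h2_ci` (central 95%),
#'   `h2_from_post_means` (ratio of posterior-mean variances),
#'   `fixed_effects`, `n_retained`, `config`.
#' @export
fit_bayesc <- function(y, design = NULL, geno, config = bayesc_config()) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "bayesc_config"))
  if (!all(is.finite(y))) stop("non-finite phenotype values")
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  if (anyNA(geno$dosages)) stop("missing dosages; run impute_missing() first")

  if (is.data.frame(design) && !is.null(design$line_id)) {
    li <- match(design$line_id, rownames(geno$dosages))
    if (anyNA(li)) stop("design rows reference unknown line_id(s)")
    W <- geno$dosages[li, , drop = FALSE]
  } else {
    if (length(y) != nrow(geno$dosages))
      stop("without line_id mapping, y must have one value per genotyped line")
    W <- geno$dosages
  }
  if (length(y) != nrow(W)) stop("y length does not match design rows")
  X <- build_design_matrix(design, length(y))

  p_frq <- colMeans(geno$dosages) / 2
  maf <- pmin(p_frq, 1 - p_frq)
  if (config$center_markers && ncol(W) > 0)
    W <- sweep(W, 2, colMeans(W))

  vy <- stats::var(y)
  nu <- config$prior_df
  s_eps <- config$variance_partition * vy * (nu - 2) / nu
  sum2pq <- sum(2 * p_frq * (1 - p_frq))
  e_s2a <- config$variance_partition * vy /
    (max(1 - config$pi, 1e-8) * max(sum2pq, 1e-8))
  s_alpha <- e_s2a * (nu - 2) / nu

  if (config$update_variances) {
    s2a0 <- e_s2a
    s2e0 <- config$variance_partition * vy
  } else {
    s2a0 <- config$sigma2_alpha
    s2e0 <- config$sigma2_eps
  }

  if (!is.null(config$seed)) set.seed(config$seed)
  res <- bayesc_gibbs_cpp(y, X, W, config$pi, nu, s_alpha, s_eps,
                          config$update_variances, s2a0, s2e0,
                          config$n_iter, config$burn_in, config$thin,
                          config$n_rep_for_h2, config$keep_alpha)

  chains <- list(sigma2_alpha = as.numeric(res$chain_sigma2_alpha),
                 sigma2_eps = as.numeric(res$chain_sigma2_eps),
                 sigma2_g = as.numeric(res$chain_sigma2_g),
                 h2 = as.numeric(res$chain_h2),
                 n_included = as.numeric(res$chain_n_included))
  if (ncol(X) > 0) {
    fx <- res$chain_fixed
    colnames(fx) <- colnames(X)
    chains$fixed <- fx
  }
  if (config$keep_alpha) chains$alpha <- res$chain_alpha

  structure(list(
    markers = data.frame(geno$map, maf = unname(maf),
                         post_mean_alpha = as.numeric(res$post_mean_alpha),
                         pip = as.numeric(res$pip), stringsAsFactors = FALSE),
    chains = chains,
    h2 = mean(chains$h2),
    h2_ci = unname(stats::quantile(chains$h2, c(0.025, 0.975))),
    h2_from_post_means = genomic_heritability(mean(chains$sigma2_g),
                                              mean(chains$sigma2_eps),
                                              config$n_rep_for_h2),
    fixed_effects = if (ncol(X) > 0) colMeans(chains$fixed) else numeric(0),
    n_retained = res$n_retained, config = config),
    class = "bayesc_fit")
}

#' @export
print.bayesc_fit <- function(x, ...) {
  cat("bayesc_fit:", nrow(x$markers), "markers,", x$n_retained,
      "retained draws\n")
  cat(sprintf("  h2 = %.3f [%.3f, %.3f]\n", x$h2, x$h2_ci[1], x$h2_ci[2]))
  top <- utils::head(x$markers[order(-x$markers$pip), ], 3)
  cat("  top PIP:", paste(sprintf("%s=%.2f", top$marker_id, top$pip),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Genomic heritability from variance components
#'
#' `h2 = sigma2_g / (sigma2_g + sigma2_e / nr)`: the proportion of
#' line-mean phenotypic variance captured by markers, with the residual
#' variance divided by the replication count.
#'
#' @param sigma2_g additive genomic variance (>= 0).
#' @param sigma2_e residual variance (>= 0).
#' @param nr replication count (>= 1).
#' @return heritability in `[0, 1]`; vectorized over the variances.
#' @export
genomic_heritability <- function(sigma2_g, sigma2_e, nr) {
  stopifnot(all(sigma2_g >= 0), all(sigma2_e >= 0), nr >= 1)
  if (any(sigma2_g == 0 & sigma2_e == 0))
    stop("heritability undefined: both variance components are zero")
  sigma2_g / (sigma2_g + sigma2_e / nr)
}

#' MCMC convergence diagnostics
#'
#' Per-parameter effective sample size and Geweke z-score on the retained
#' draws; parameters with `|z| > 2` are flagged. Constant (degenerate)
#' chains are flagged rather than given a numeric ESS. Optionally writes a
#' trace plot per parameter.
#'
#' @param x a `bayesc_fit`, `bayesc_biv_fit`, a named list of numeric
#'   chains, or a numeric matrix with one column per parameter.
#' @param plot_dir if non-`NULL`, a directory to which one `trace_<param>.png`
#'   per parameter is written.
#' @return data frame: `parameter`, `n`, `ess`, `geweke_z`, `degenerate`,
#'   `flagged`.
#' @export
diagnostics <- function(x, plot_dir = NULL) {
  chains <- if (inherits(x, c("bayesc_fit", "bayesc_biv_fit"))) {
    ch <- x$chains
    ch[vapply(ch, is.numeric, TRUE) & !vapply(ch, is.matrix, TRUE)]
  } else if (is.matrix(x)) {
    stats::setNames(lapply(seq_len(ncol(x)), function(j) x[, j]),
                    colnames(x) %||% paste0("param", seq_len(ncol(x))))
  } else if (is.numeric(x)) list(chain = x) else x
  stopifnot(all(lengths(chains) >= 10))

  rows <- lapply(names(chains), function(nm) {
    v <- chains[[nm]]
    v <- v[is.finite(v)]
    if (length(v) < 10 || stats::var(v) == 0)
      return(data.frame(parameter = nm, n = length(v), ess = NA_real_,
                        geweke_z = NA_real_, degenerate = TRUE,
                        flagged = TRUE))
    mc <- coda::mcmc(v)
    ess <- unname(coda::effectiveSize(mc))
    z <- tryCatch(unname(coda::geweke.diag(mc)$z), error = function(e) NA_real_)
    data.frame(parameter = nm, n = length(v), ess = ess, geweke_z = z,
               degenerate = FALSE,
               flagged = is.na(z) || abs(z) > 2)
  })
  out <- do.call(rbind, rows)
  if (!is.null(plot_dir)) {
    dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(chains)) {
      f <- file.path(plot_dir, paste0("trace_", gsub("[^A-Za-z0-9_]", "_", nm),
                                      ".png"))
      grDevices::png(f, width = 700, height = 300)
      plot(chains[[nm]], type = "l", xlab = "retained draw", ylab = nm,
           main = paste("Trace:", nm))
      grDevices::dev.off()
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
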