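#' Marker quality-control filters
#'
#' Applies the panel's QC rules in order: markers with call rate below
#' `min_call_rate` are removed first; minor allele frequency is then computed
#' on the non-missing dosages of the survivors and markers with MAF strictly
#' below `min_maf` are removed. Both comparisons are strict (`<`), so a
#' marker at exactly the boundary is retained.
#'
#' @param G a [genotype_matrix()].
#' @param min_call_rate minimum fraction of non-missing calls (default 0.90).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @return list with `genotypes` (filtered [genotype_matrix()]) and `report`
#'   (a `qc_report`).
#' @export
filter_markers <- function(G, min_call_rate = 0.90, min_maf = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (ncol(G$dosages) == 0) stop("empty marker panel")
  call_rate <- colMeans(!is.na(G$dosages))
  rm_cr <- which(call_rate < min_call_rate)
  keep1 <- setdiff(seq_len(ncol(G$dosages)), rm_cr)
  p <- colMeans(G$dosages[, keep1, drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  rm_maf <- keep1[maf < min_maf]
  keep <- setdiff(keep1, rm_maf)
  if (length(keep) == 0)
    stop("all markers removed by QC (call rate < ", min_call_rate,
         " or MAF < ", min_maf, "): empty panel")
  report <- qc_report(
    n_input = ncol(G$dosages),
    removed = list(callrate = G$map$marker_id[rm_cr],
                   maf = G$map$marker_id[rm_maf], ld = character(0)),
    n_retained = length(keep))
  list(genotypes = subset_markers(G, keep), report = report)
}

qc_report <- function(n_input, removed, n_retained, zero_variance = character(0)) {
  rep <- list(n_input = n_input,
              n_removed_callrate = length(removed$callrate),
              n_removed_maf = length(removed$maf),
              n_removed_ld = length(removed$ld),
              n_retained = n_retained, removed_ids = removed,
              zero_variance_flagged = zero_variance)
  stopifnot(rep$n_input == rep$n_retained + rep$n_removed_callrate +
              rep$n_removed_maf + rep$n_removed_ld)
  structure(rep, class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", x$n_input, "markers in ->", x$n_retained, "retained\n")
  cat("  removed: call rate", x$n_removed_callrate, "| MAF", x$n_removed_maf,
      "| LD", x$n_removed_ld, "\n")
  if (length(x$zero_variance_flagged))
    cat("  zero-variance markers flagged:",
        length(x$zero_variance_flagged), "\n")
  invisible(x)
}

#' Mean imputation of missing dosages
#'
#' Replaces each missing dosage with the marker's mean dosage over observed
#' lines (a simple stand-in for haplotype-based imputation; adequate after
#' call-rate filtering). Imputed values are fractional by design.
#'
#' @param G a [genotype_matrix()].
#' @return a `genotype_matrix` with no missing values (dosage values may be
#'   non-integer where imputed).
#' @export
impute_missing <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages
  nmiss <- colSums(is.na(d))
  if (any(nmiss == nrow(d)))
    stop("marker(s) fully missing (should have been removed by call-rate filter): ",
         paste(utils::head(G$map$marker_id[nmiss == nrow(d)], 3), collapse = ", "))
  if (any(nmiss > 0)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  out <- G
  out$dosages <- d
  out
}

#' Greedy LD pruning within chromosome
#'
#' Left-to-right greedy pruning in map order: for each retained marker, any
#' later marker on the same chromosome whose squared Pearson correlation of
#' dosages with it exceeds `max_r2` is removed, so the earlier-position
#' marker of a high-LD pair always wins. Zero-variance markers have
#' undefined r2; they are never pruned by correlation and are flagged in the
#' report.
#'
#' @param G a [genotype_matrix()] with no missing dosages (run
#'   [impute_missing()] first).
#' @param max_r2 maximum allowed squared correlation (default 0.99, strict
#'   `>` removal).
#' @return list with `genotypes` (pruned panel) and `report` (a
#'   `qc_report`).
#' @export
ld_prune <- function(G, max_r2 = 0.99) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (anyNA(G$dosages)) stop("ld_prune requires complete dosages; impute first")
  removed <- logical(ncol(G$dosages))
  zero_var <- character(0)
  for (ch in unique(G$map$chrom)) {
    idx <- which(G$map$chrom == ch)          # map order = increasing position
    d <- G$dosages[, idx, drop = FALSE]
    v <- apply(d, 2, stats::var)
    zero_var <- c(zero_var, G$map$marker_id[idx[v == 0]])
    mc <- length(idx)
    if (mc < 2) next
    r2 <- suppressWarnings(stats::cor(d))^2  # NA rows/cols for zero variance
    for (a in seq_len(mc - 1)) {
      if (removed[idx[a]]) next
      later <- (a + 1):mc
      hit <- later[!removed[idx[later]] & !is.na(r2[a, later]) &
                     r2[a, later] > max_r2]
      removed[idx[hit]] <- TRUE
    }
  }
  keep <- which(!removed)
  report <- qc_report(
    n_input = ncol(G$dosages),
    removed = list(callrate = character(0), maf = character(0),
                   ld = G$map$marker_id[removed]),
    n_retained = length(keep), zero_variance = zero_var)
  list(genotypes = subset_markers(G, keep), report = report)
}

#' Write a QC report as JSON
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
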