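#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Accepts
#' either a YAML file path or a named list; missing blocks get defaults. A
#' fully synthetic run needs no input files; to analyse existing data,
#' supply `genotype_file` (dosage TSV or VCF), `phenotype_file` (CSV) and
#' optionally `spectra_file` (CSV) and `annotation_file` (GFF3) instead of
#' a `sim` block.
#'
#' @param config YAML path or named list with (all optional) elements
#'   `out_dir`, `seed`, `sim` (arguments to [sim_config()]), `chain`
#'   (`n_iter`, `burn_in`, `thin`), `pi`, `thresholds` (`manual`,
#'   `hyperspectral`), `flank_bp`, `n_rg_pairs`, `stages`, input file paths.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    out_dir = file.path(tempdir(), "specgwas_run"), seed = 1,
    sim = list(), chain = list(n_iter = 6000, burn_in = 600, thin = 6),
    pi = 0.99, thresholds = list(manual = 0.10, hyperspectral = 0.50),
    flank_bp = 50000, n_rg_pairs = 3, n_index = 5,
    genotype_file = NULL, phenotype_file = NULL, spectra_file = NULL,
    annotation_file = NULL,
    stages = c("simulate", "qc", "indices", "gwas_uni", "gwas_bi", "select",
               "annotate", "report"))
  cfg <- utils::modifyList(defaults, config)
  for (f in c("genotype_file", "phenotype_file", "spectra_file",
              "annotation_file")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input file does not exist: ", f, " = ", cfg[[f]])
  }
  if (!"simulate" %in% cfg$stages && is.null(cfg$genotype_file))
    stop("no simulate stage and no genotype_file: nothing to analyse")
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: simulate (synthetic genotypes, design,
#' traits, spectra, and a synthetic gene annotation), qc (call-rate/MAF
#' filters, mean imputation, LD pruning), indices (spectral indices from
#' band means), gwas_uni (univariate BayesC per phenotype and management),
#' gwas_bi (bivariate fits for trait-band pairs), select (PIP thresholds per
#' phenotype class), annotate (gene windows around hyperspectral hits),
#' report (heritability/correlation spectra, Manhattan and PheWAS figures,
#' HTML PheWAS). Every stage is deterministic given the configuration seed;
#' all outputs land under `out_dir` and are listed, with content hashes, in
#' `manifest.json`.
#'
#' @param config a [run_config()], a list, or a YAML path.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `manifest` (data frame `file`, `md5`),
#'   `out_dir`, and the main result tables (`h2_table`, `hits`, `rg_table`).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[specgwas] ", ...)
  outputs <- character(0)
  keep <- function(path) { outputs <<- c(outputs, path); path }

  sim_args <- utils::modifyList(list(seed = config$seed), config$sim)
  scfg <- do.call(sim_config, sim_args)

  geno <- pheno <- spectra <- truth <- annotation <- NULL

  if ("simulate" %in% config$stages) {
    say("simulate: ", scfg$n_lines, " lines x ", scfg$n_markers, " markers")
    geno <- simulate_genotypes(scfg)
    st <- simulate_traits(geno, scfg)
    pheno <- st$phenotypes; truth <- st$truth
    spectra <- simulate_spectra(geno, truth, pheno, scfg)
    annotation <- synthetic_gene_annotation(geno, seed = config$seed)
    write_dosage_tsv(geno, keep(file.path(config$out_dir, "genotypes.tsv")))
    write_vcf(geno, keep(file.path(config$out_dir, "genotypes.vcf")))
    utils::write.table(pheno, keep(file.path(config$out_dir, "phenotypes.csv")),
                       sep = ",", quote = FALSE, row.names = FALSE)
    write_spectra_csv(spectra, keep(file.path(config$out_dir, "spectra.csv")))
    write_sim_truth(truth, keep(file.path(config$out_dir, "sim_truth.json")))
    write_gene_annotation_gff3(
      annotation, keep(file.path(config$out_dir, "genes_synthetic.gff3")))
  } else {
    geno <- if (grepl("\\.vcf", config$genotype_file))
      read_vcf(config$genotype_file) else read_dosage_tsv(config$genotype_file)
    pheno <- utils::read.table(config$phenotype_file, sep = ",", header = TRUE,
                               stringsAsFactors = FALSE)
    if (!is.null(config$spectra_file))
      spectra <- read_spectra_csv(config$spectra_file)
    if (!is.null(config$annotation_file))
      annotation <- read_gene_annotation(config$annotation_file)
  }

  if ("qc" %in% config$stages) {
    f1 <- filter_markers(geno)
    g1 <- impute_missing(f1$genotypes)
    f2 <- ld_prune(g1)
    geno <- f2$genotypes
    say("qc: ", f1$report$n_input, " -> ", f2$report$n_retained, " markers")
    rep_all <- f1$report
    rep_all$n_removed_ld <- f2$report$n_removed_ld
    rep_all$n_retained <- f2$report$n_retained
    rep_all$removed_ids$ld <- f2$report$removed_ids$ld
    rep_all$zero_variance_flagged <- f2$report$zero_variance_flagged
    write_qc_report(rep_all, keep(file.path(config$out_dir, "qc_report.json")))
    write_dosage_tsv(geno, keep(file.path(config$out_dir, "genotypes_qc.tsv")))
  } else {
    geno <- impute_missing(geno)
  }

  index_tab <- NULL
  if ("indices" %in% config$stages && !is.null(spectra)) {
    registry <- default_index_registry()
    if (!is.null(config$n_index)) registry <- registry[seq_len(config$n_index)]
    index_tab <- compute_indices(spectra, registry)
    say("indices: ", ncol(index_tab) - 1, " computed")
    utils::write.table(index_tab, keep(file.path(config$out_dir, "indices.csv")),
                       sep = ",", quote = FALSE, row.names = FALSE)
  }

  # assemble the phenotype panel: manual traits + bands + indices
  traits <- if (!is.null(truth)) truth$traits else
    setdiff(names(pheno), c("plot_id", "line_id", "management", "rep", "block"))
  panel <- pheno[, c("plot_id", "line_id", "management", "rep", "block",
                     traits)]
  phen_class <- stats::setNames(rep("manual", length(traits)), traits)
  band_wl <- numeric(0)
  if (!is.null(spectra)) {
    wl <- spectra_wavelengths(spectra)
    bands <- setdiff(names(spectra), "plot_id")
    panel <- cbind(panel, spectra[match(panel$plot_id, spectra$plot_id),
                                  bands, drop = FALSE])
    phen_class <- c(phen_class, stats::setNames(rep("band", length(bands)),
                                                bands))
    band_wl <- stats::setNames(wl, bands)
  }
  if (!is.null(index_tab)) {
    idx <- setdiff(names(index_tab), "plot_id")
    ok <- idx[colSums(is.na(index_tab[idx])) < nrow(index_tab)]
    panel <- cbind(panel, index_tab[match(panel$plot_id, index_tab$plot_id),
                                    ok, drop = FALSE])
    phen_class <- c(phen_class, stats::setNames(rep("index", length(ok)), ok))
  }

  all_pips <- h2_table <- NULL
  if ("gwas_uni" %in% config$stages) {
    say("gwas_uni: ", length(phen_class), " phenotypes x ",
        length(unique(panel$management)), " managements")
    pips_rows <- list(); h2_rows <- list(); fit_id <- 0L
    dir.create(file.path(config$out_dir, "gwas"), showWarnings = FALSE)
    for (mg in unique(panel$management)) {
      sub <- panel[panel$management == mg, ]
      for (ph in names(phen_class)) {
        fit_id <- fit_id + 1L
        y <- sub[[ph]]
        okr <- is.finite(y)
        if (sum(okr) < 10 || var(y[okr]) < 1e-12) {
          say("gwas_uni: skipping degenerate phenotype ", ph, " (", mg, ")")
          next
        }
        cfg <- bayesc_config(pi = config$pi,
                             n_iter = config$chain$n_iter,
                             burn_in = config$chain$burn_in,
                             thin = config$chain$thin,
                             seed = config$seed + 1000L + fit_id)
        fit <- fit_bayesc(y[okr], sub[okr, c("line_id", "rep", "block")],
                          geno, cfg)
        pips_rows[[fit_id]] <- data.frame(
          fit$markers, phenotype = ph, class = phen_class[[ph]],
          management = mg, stringsAsFactors = FALSE)
        h2_rows[[fit_id]] <- data.frame(
          phenotype = ph, class = phen_class[[ph]], management = mg,
          h2 = fit$h2, h2_low = fit$h2_ci[1], h2_high = fit$h2_ci[2],
          wavelength_nm = if (ph %in% names(band_wl)) band_wl[[ph]] else NA,
          stringsAsFactors = FALSE)
      }
    }
    all_pips <- do.call(rbind, pips_rows)
    h2_table <- do.call(rbind, h2_rows)
    utils::write.table(all_pips, keep(file.path(config$out_dir, "gwas",
                                                "marker_pips.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(h2_table, keep(file.path(config$out_dir, "gwas",
                                                "heritability.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  rg_table <- NULL
  if ("gwas_bi" %in% config$stages && !is.null(spectra) &&
      config$n_rg_pairs > 0) {
    bands <- names(band_wl)
    sel_bands <- bands[round(seq(1, length(bands),
                                 length.out = min(config$n_rg_pairs,
                                                  length(bands))))]
    pairs <- expand.grid(trait = traits[1], phenotype = sel_bands,
                         stringsAsFactors = FALSE)
    say("gwas_bi: ", nrow(pairs), " pairs per management")
    bcfg <- bivariate_config(n_iter = config$chain$n_iter,
                             burn_in = config$chain$burn_in,
                             thin = config$chain$thin,
                             seed = config$seed + 5000L)
    rg_table <- fit_rg_pairs(panel, pairs, geno, bcfg)
    rg_table$wavelength_nm <- band_wl[rg_table$phenotype]
    utils::write.table(rg_table, keep(file.path(config$out_dir,
                                                "genomic_correlations.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  hits <- NULL
  if ("select" %in% config$stages && !is.null(all_pips)) {
    thr <- config$thresholds
    manual_hits <- select_markers(all_pips[all_pips$class == "manual", ],
                                  thr$manual)
    hyper_hits <- select_markers(all_pips[all_pips$class != "manual", ],
                                 thr$hyperspectral)
    hits <- rbind(manual_hits, hyper_hits)
    say("select: ", nrow(manual_hits), " manual hits, ", nrow(hyper_hits),
        " hyperspectral hits")
    utils::write.table(hits, keep(file.path(config$out_dir, "hits.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("annotate" %in% config$stages && !is.null(hits) && nrow(hits) > 0 &&
      !is.null(annotation)) {
    ann_hits <- annotate_hits(hits, annotation, config$flank_bp)
    # Table-1 shaped summary: one row per hyperspectral marker x management
    hyp <- ann_hits[ann_hits$class != "manual", , drop = FALSE]
    tab1 <- NULL
    if (nrow(hyp) > 0) {
      key <- interaction(hyp$marker_id, hyp$management, drop = TRUE)
      tab1 <- do.call(rbind, lapply(split(hyp, key), function(h) data.frame(
        management = h$management[1], chrom = h$chrom[1],
        marker_id = h$marker_id[1], n_phenotypes = nrow(h),
        maf = round(h$maf[1], 2), mean_pip = round(mean(h$pip), 3),
        n_genes = h$n_genes[1], candidate_genes = h$candidate_genes[1],
        stringsAsFactors = FALSE)))
    }
    utils::write.table(ann_hits, keep(file.path(config$out_dir,
                                                "hits_annotated.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(tab1))
      utils::write.table(tab1, keep(file.path(config$out_dir,
                                              "hyperspectral_hit_table.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("report" %in% config$stages && !is.null(all_pips)) {
    figdir <- file.path(config$out_dir, "figures")
    dir.create(figdir, showWarnings = FALSE)
    if (!is.null(h2_table) && any(h2_table$class == "band"))
      save_figure(plot_h2_spectrum(h2_table),
                  keep(file.path(figdir, "heritability_spectrum.png")))
    if (!is.null(rg_table))
      save_figure(plot_rg_spectrum(rg_table),
                  keep(file.path(figdir, "genomic_correlation_spectrum.png")))
    manual <- all_pips[all_pips$class == "manual", ]
    for (ph in unique(manual$phenotype))
      save_figure(plot_manhattan(manual[manual$phenotype == ph, ],
                                 config$thresholds$manual),
                  keep(file.path(figdir, paste0("manhattan_", ph, ".png"))))
    if (!is.null(hits) && nrow(hits) > 0) {
      agg <- aggregate_phewas(hits, all_pips)
      save_figure(plot_phewas(agg$profile),
                  keep(file.path(figdir, "phewas.png")))
      write_phewas_html(agg$profile, keep(file.path(figdir, "phewas.html")))
    }
  }

  manifest <- data.frame(
    file = sub(paste0("^", config$out_dir, "/?"), "", outputs),
    md5 = unname(tools::md5sum(outputs)), stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: ", nrow(manifest), " artifacts in ", config$out_dir)
  invisible(list(manifest = manifest, out_dir = config$out_dir,
                 h2_table = h2_table, hits = hits, rg_table = rg_table))
}

save_figure <- function(p, path, width = 8, height = 5) {
  grDevices::png(path, width = width * 100, height = height * 100, res = 110)
  print(p)
  grDevices::dev.off()
  invisible(path)
}

#' Synthetic gene annotation along a marker map
#'
#' Tiles pseudo-genes (2-10 kbp spans every ~20-60 kbp) along each
#' chromosome of a genotype panel so gene-window lookups can be exercised
#' without a reference annotation. Clearly synthetic: gene IDs are
#' `SYNGENE<k>`.
#'
#' @param G a [genotype_matrix()].
#' @param seed RNG seed.
#' @return data frame `gene_id`, `chrom`, `start`, `end`.
#' @export
synthetic_gene_annotation <- function(G, seed = 1) {
  set.seed(seed + 404L)
  rows <- list()
  gid <- 0L
  for (ch in unique(G$map$chrom)) {
    chr_end <- max(G$map$pos_bp[G$map$chrom == ch]) + 5e4
    pos <- 1
    starts <- integer(0); ends <- integer(0)
    while (pos < chr_end) {
      pos <- pos + round(stats::runif(1, 2e4, 6e4))
      len <- round(stats::runif(1, 2e3, 1e4))
      starts <- c(starts, pos); ends <- c(ends, pos + len)
      pos <- pos + len
    }
    rows[[ch]] <- data.frame(
      gene_id = sprintf("SYNGENE%05d", gid + seq_along(starts)),
      chrom = ch, start = starts, end = ends, stringsAsFactors = FALSE)
    gid <- gid + length(starts)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a gene table as GFF3
#' @param annotation data frame `gene_id`, `chrom`, `start`, `end`.
#' @param path output `.gff3` file.
#' @return `path`, invisibly.
#' @export
write_gene_annotation_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tspecgwas\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     annotation$chrom, annotation$start, annotation$end,
                     annotation$gene_id), con)
  invisible(path)
}
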