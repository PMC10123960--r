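#' Select markers by posterior inclusion probability
#'
#' Markers with `pip >= threshold` (inclusive comparison), sorted by
#' descending PIP and then by genome position. An empty result is valid: a
#' trait may have no marker reaching the threshold under a management.
#'
#' @param pips data frame with at least `marker_id` and `pip` (in `[0, 1]`);
#'   `chrom`, `pos_bp`, `phenotype`, `management`, `class` are carried
#'   through when present. Typically `fit$markers` from [fit_bayesc()].
#' @param threshold PIP threshold; 0.10 is the conventional choice for
#'   manually measured traits and 0.50 the conservative one for
#'   hyperspectral phenotypes.
#' @return data frame of hits with a `threshold_used` column.
#' @export
select_markers <- function(pips, threshold) {
  stopifnot(all(c("marker_id", "pip") %in% names(pips)),
            all(pips$pip >= 0 & pips$pip <= 1))
  hits <- pips[pips$pip >= threshold, , drop = FALSE]
  if (nrow(hits) > 0) {
    ord <- if (all(c("chrom", "pos_bp") %in% names(hits)))
      order(-hits$pip, hits$chrom, hits$pos_bp) else order(-hits$pip)
    hits <- hits[ord, , drop = FALSE]
  }
  hits$threshold_used <- rep(threshold, nrow(hits))
  rownames(hits) <- NULL
  hits
}

#' Read gene features from a GFF3 annotation
#'
#' @param path GFF3 file; only `gene` features are kept.
#' @return data frame `gene_id`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  id <- gr$ID %||% gr$gene_id %||% gr$Name
  if (is.null(id)) id <- paste0("gene", seq_along(gr))
  data.frame(gene_id = as.character(id),
             chrom = sub("^[Cc]hr", "", as.character(GenomicRanges::seqnames(gr))),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Genes within a flanking window of a marker
#'
#' The window is `[pos - flank_bp, pos + flank_bp]` (1-based inclusive,
#' clipped at 1); genes whose span intersects the window on the same
#' chromosome (closed-interval overlap, so a gene ending exactly at the
#' window start counts) are returned.
#'
#' @param chrom,pos_bp marker position, or pass a one-row hit data frame as
#'   `chrom` (with `chrom`/`pos_bp` columns, e.g. from [select_markers()]).
#' @param annotation gene table from [read_gene_annotation()].
#' @param flank_bp flank on each side (default 50,000).
#' @return list of class `gene_window`: `marker_id`, `chrom`, `pos_bp`,
#'   `window_start_bp`, `window_end_bp`, `gene_ids`, `n_genes`.
#' @export
gene_window_lookup <- function(chrom, pos_bp = NULL, annotation,
                               flank_bp = 50000) {
  if (is.data.frame(chrom)) {
    stopifnot(nrow(chrom) == 1)
    hit <- chrom
    marker_id <- hit$marker_id %||% paste0("Chr", hit$chrom, "_", hit$pos_bp)
    chrom <- as.character(hit$chrom)
    pos_bp <- hit$pos_bp
  } else {
    chrom <- as.character(chrom)
    marker_id <- paste0("Chr", chrom, "_", pos_bp)
  }
  ws <- max(1, pos_bp - flank_bp)
  we <- pos_bp + flank_bp
  ann <- annotation[annotation$chrom == chrom, , drop = FALSE]
  if (nrow(ann) == 0 && !(chrom %in% unique(annotation$chrom)))
    warning("chromosome ", chrom, " absent from annotation; empty gene list")
  genes <- character(0)
  if (nrow(ann) > 0) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ann$start, ann$end))
    win <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ws, we))
    ov <- GenomicRanges::findOverlaps(gr, win)
    genes <- ann$gene_id[S4Vectors::queryHits(ov)]
  }
  structure(list(marker_id = marker_id, chrom = chrom, pos_bp = pos_bp,
                 window_start_bp = ws, window_end_bp = we,
                 gene_ids = genes, n_genes = length(genes)),
            class = "gene_window")
}

#' @export
print.gene_window <- function(x, ...) {
  cat(sprintf("gene_window %s: [%s, %s] -> %d gene(s)\n", x$marker_id,
              format(x$window_start_bp, big.mark = ","),
              format(x$window_end_bp, big.mark = ","), x$n_genes))
  invisible(x)
}

#' Annotate a hit table with gene windows
#'
#' @param hits data frame of hits (needs `marker_id`, `chrom`, `pos_bp`).
#' @param annotation gene table from [read_gene_annotation()].
#' @param flank_bp flank on each side of each marker.
#' @return `hits` with `n_genes` and comma-separated `candidate_genes`
#'   columns appended.
#' @export
annotate_hits <- function(hits, annotation, flank_bp = 50000) {
  if (nrow(hits) == 0) {
    hits$n_genes <- integer(0)
    hits$candidate_genes <- character(0)
    return(hits)
  }
  wins <- lapply(seq_len(nrow(hits)), function(i)
    gene_window_lookup(hits$chrom[i], hits$pos_bp[i], annotation, flank_bp))
  hits$n_genes <- vapply(wins, function(w) w$n_genes, 0L)
  hits$candidate_genes <- vapply(wins, function(w)
    paste(w$gene_ids, collapse = ","), "")
  hits
}

#' Phenome-wide aggregation of selected markers
#'
#' For every marker appearing in the hit list, assembles its PIP profile
#' across all phenotypes and managements, counts the phenotypes on which it
#' passes the class-specific threshold, and flags markers selected in both
#' the manually measured and hyperspectral (band or index) classes.
#'
#' @param hits nonempty data frame of selected markers (needs `marker_id`).
#' @param all_pips long data frame with one row per marker x phenotype x
#'   management: columns `marker_id`, `phenotype`, `class` (one of
#'   `"manual"`, `"band"`, `"index"`), `management`, `pip`.
#' @param class_thresholds named PIP thresholds per phenotype class.
#' @return list with `profile` (rows of `all_pips` for the hit markers with
#'   a logical `selected` column) and `summary` (per marker x management:
#'   `n_phenotypes_selected`, `shared` flag across classes).
#' @export
aggregate_phewas <- function(hits, all_pips,
                             class_thresholds = c(manual = 0.10, band = 0.50,
                                                  index = 0.50)) {
  stopifnot(nrow(hits) > 0,
            all(c("marker_id", "phenotype", "class", "management", "pip")
                %in% names(all_pips)),
            all(all_pips$class %in% names(class_thresholds)))
  markers <- unique(hits$marker_id)
  profile <- all_pips[all_pips$marker_id %in% markers, , drop = FALSE]
  profile$selected <- profile$pip >= class_thresholds[profile$class]
  key <- interaction(profile$marker_id, profile$management, drop = TRUE)
  summ <- do.call(rbind, lapply(split(profile, key), function(p) {
    sel <- p[p$selected, , drop = FALSE]
    data.frame(marker_id = p$marker_id[1], management = p$management[1],
               n_phenotypes_selected = nrow(sel),
               shared = any(sel$class == "manual") &&
                 any(sel$class %in% c("band", "index")),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(profile = profile, summary = summ)
}
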