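#' Construct a genotype matrix object
#'
#' Container for a line-by-marker dosage matrix (counts of the alternate
#' allele, 0/1/2, `NA` for missing) together with its marker map. Marker IDs
#' follow the `Chr<k>_<pos>` convention (chromosome and 1-based bp position
#' joined by an underscore).
#'
#' @param dosages numeric matrix, lines in rows, markers in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param chrom integer/character vector of chromosome per marker. If `NULL`,
#'   parsed from column names of `dosages`.
#' @param pos_bp integer vector of 1-based positions per marker, strictly
#'   increasing within chromosome. If `NULL`, parsed from column names.
#' @param line_ids character vector of line identifiers; defaults to row
#'   names or `L001`-style labels.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (matrix with marker IDs as column names) and `map`
#'   (data frame `marker_id`, `chrom`, `pos_bp`).
#' @export
genotype_matrix <- function(dosages, chrom = NULL, pos_bp = NULL,
                            line_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(chrom) || is.null(pos_bp)) {
    if (is.null(colnames(dosages)))
      stop("chrom/pos_bp not given and dosage columns are unnamed")
    parsed <- parse_marker_ids(colnames(dosages))
    chrom <- parsed$chrom
    pos_bp <- parsed$pos_bp
  }
  if (length(chrom) != ncol(dosages) || length(pos_bp) != ncol(dosages))
    stop("chrom and pos_bp must have one entry per marker")
  marker_id <- if (ncol(dosages) == 0) character(0) else
    paste0("Chr", chrom, "_", format(pos_bp, scientific = FALSE, trim = TRUE))
  if (anyDuplicated(marker_id))
    stop("duplicated marker IDs: ", paste(
      utils::head(marker_id[duplicated(marker_id)], 3), collapse = ", "))
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  for (ch in unique(chrom)) {
    p <- pos_bp[chrom == ch]
    if (any(diff(p) <= 0))
      stop("pos_bp not strictly increasing within chromosome ", ch)
  }
  if (is.null(line_ids)) {
    line_ids <- rownames(dosages)
    if (is.null(line_ids))
      line_ids <- sprintf("L%04d", seq_len(nrow(dosages)))
  }
  if (ncol(dosages) > 0) {
    dimnames(dosages) <- list(line_ids, marker_id)
  } else {
    rownames(dosages) <- line_ids
  }
  structure(
    list(dosages = dosages,
         map = data.frame(marker_id = marker_id, chrom = as.character(chrom),
                          pos_bp = as.integer(pos_bp),
                          stringsAsFactors = FALSE)),
    class = "genotype_matrix")
}

parse_marker_ids <- function(ids) {
  m <- regmatches(ids, regexec("^Chr([^_]+)_([0-9]+)$", ids))
  ok <- lengths(m) == 3L
  if (!all(ok))
    stop("marker IDs not in Chr<k>_<pos> form: ",
         paste(utils::head(ids[!ok], 3), collapse = ", "))
  list(chrom = vapply(m, `[`, "", 2L),
       pos_bp = as.integer(vapply(m, `[`, "", 3L)))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "lines x", ncol(x$dosages),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  nmiss <- sum(is.na(x$dosages))
  if (nmiss > 0) cat("  missing calls:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by marker
#' @param G a [genotype_matrix()].
#' @param keep logical/integer/character index over markers.
#' @return a `genotype_matrix` restricted to the selected markers.
#' @export
subset_markers <- function(G, keep) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.character(keep)) keep <- match(keep, G$map$marker_id)
  d <- G$dosages[, keep, drop = FALSE]
  map <- G$map[keep, , drop = FALSE]
  structure(list(dosages = d, map = map), class = "genotype_matrix")
}

#' Write and read dosage tables
#'
#' Plain TSV with lines in rows: first column `line_id`, then one column per
#' marker named `Chr<k>_<pos>`. Missing dosages are empty fields.
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @return `write_dosage_tsv()` returns `path` invisibly; `read_dosage_tsv()`
#'   returns a `genotype_matrix`.
#' @export
write_dosage_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  df <- data.frame(line_id = rownames(G$dosages), G$dosages,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          na.strings = c("", "NA"))
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- df[[1]]
  genotype_matrix(d)
}

#' Write a genotype matrix as plain-text VCF
#'
#' One VCF sample per line; biallelic pseudo-SNPs (REF `A`, ALT `T`) with GT
#' fields `0/0`, `0/1`, `1/1` for dosages 0, 1, 2 and `./.` for missing.
#'
#' @param G a [genotype_matrix()].
#' @param path output `.vcf` file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=specgwas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G$dosages)),
                     collapse = "\t")), con)
  m <- ncol(G$dosages)
  for (j in seq_len(m)) {
    d <- G$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    writeLines(paste(c(G$map$chrom[j], G$map$pos_bp[j], G$map$marker_id[j],
                       "A", "T", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a biallelic-SNP VCF into a genotype matrix
#'
#' Dosages count the alternate allele per genotype call. Multi-allelic
#' records are skipped with a warning; dosage tables produced by this package
#' are biallelic by construction.
#'
#' @param path a VCF file (plain or gzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    alleles <- strsplit(gsub("\\|", "/", x[ok]), "/", fixed = FALSE)
    out[ok] <- vapply(alleles, function(a) sum(a != "0"), 0)
    out
  }
  d <- apply(gt, 2, count_alt)            # markers x samples -> per sample
  d <- t(matrix(d, nrow = nrow(gt), dimnames = dimnames(gt)))
  chrom <- sub("^[Cc]hr", "", fix[, "CHROM"])
  genotype_matrix(d, chrom = chrom, pos_bp = as.integer(fix[, "POS"]),
                  line_ids = rownames(d))
}
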