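#' Manhattan plot of posterior inclusion probabilities
#'
#' PIP against genome position with alternating chromosome shading, a
#' horizontal threshold line, and labels on markers at or above the
#' threshold; faceted by management when a `management` column is present.
#'
#' @param pips data frame with `marker_id`, `chrom`, `pos_bp`, `pip` and
#'   optionally `management`.
#' @param threshold PIP threshold drawn and used for labelling.
#' @return a ggplot object.
#' @export
plot_manhattan <- function(pips, threshold = 0.10) {
  stopifnot(all(c("chrom", "pos_bp", "pip") %in% names(pips)))
  d <- pips
  d$chrom <- factor(d$chrom, levels = unique(d$chrom[order(
    suppressWarnings(as.numeric(d$chrom)), d$chrom)]))
  offs <- tapply(d$pos_bp, d$chrom, max)
  offs <- c(0, cumsum(as.numeric(offs)))[seq_len(nlevels(d$chrom))]
  names(offs) <- levels(d$chrom)
  d$x <- d$pos_bp + offs[as.character(d$chrom)]
  d$shade <- as.integer(d$chrom) %% 2 == 0
  lab <- d[d$pip >= threshold, , drop = FALSE]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$pip,
                                       colour = .data$shade)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "red3") +
    ggplot2::scale_colour_manual(values = c("grey25", "steelblue4")) +
    ggplot2::scale_x_continuous(
      breaks = offs + as.numeric(tapply(d$pos_bp, d$chrom, max)) / 2,
      labels = levels(d$chrom)) +
    ggplot2::labs(x = "Chromosome", y = "Posterior inclusion probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
  if (nrow(lab) > 0 && "marker_id" %in% names(lab))
    p <- p + ggplot2::geom_text(data = lab,
                                ggplot2::aes(label = .data$marker_id),
                                size = 2.4, vjust = -0.6, colour = "black")
  if ("management" %in% names(d))
    p <- p + ggplot2::facet_wrap(~management, ncol = 1)
  p
}

#' Phenome-wide association plot
#'
#' PIP of each selected marker across every phenotype, grouped on the x axis
#' by class in the order Bands, Index, MM (manually measured), faceted by
#' management, one colour per marker.
#'
#' @param profile long data frame from [aggregate_phewas()]`$profile`
#'   (columns `marker_id`, `phenotype`, `class`, `management`, `pip`).
#' @return a ggplot object.
#' @export
plot_phewas <- function(profile) {
  d <- profile
  class_lab <- c(band = "Bands", index = "Index", manual = "MM")
  d$class_lab <- factor(class_lab[d$class], levels = class_lab)
  d <- d[order(d$class_lab, d$phenotype), ]
  d$xpos <- as.integer(factor(paste(d$class_lab, d$phenotype),
                              levels = unique(paste(d$class_lab, d$phenotype))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$xpos, y = .data$pip,
                                  colour = .data$marker_id)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(management ~ class_lab, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Phenotype (grouped by class)",
                  y = "Posterior inclusion probability", colour = "Marker") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Self-contained HTML PheWAS report with hover identification
#'
#' Writes a single HTML file containing an inline SVG scatter of PIP across
#' phenotypes (grouped Bands, Index, MM; one panel per management); hovering
#' a point reveals marker, phenotype and PIP via a tooltip. A static
#' stand-in for an interactive multiphenotype GWAS browser.
#'
#' @param profile long data frame as in [plot_phewas()].
#' @param path output `.html` file.
#' @return `path`, invisibly.
#' @export
write_phewas_html <- function(profile, path) {
  class_lab <- c(band = "Bands", index = "Index", manual = "MM")
  d <- profile
  d$class_lab <- factor(class_lab[d$class], levels = class_lab)
  d <- d[order(d$class_lab, d$phenotype), ]
  d$xkey <- paste(d$class_lab, d$phenotype)
  d$xpos <- as.integer(factor(d$xkey, levels = unique(d$xkey)))
  mgmts <- unique(d$management)
  markers <- unique(d$marker_id)
  pal <- grDevices::hcl.colors(max(3, length(markers)), "Dark 3")
  cols <- stats::setNames(pal[seq_along(markers)], markers)

  w <- 900; h_panel <- 260; pad <- 50
  nx <- max(d$xpos)
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   w, (h_panel + 30) * length(mgmts) + 30))
  for (i in seq_along(mgmts)) {
    top <- (i - 1) * (h_panel + 30) + 20
    sub <- d[d$management == mgmts[i], ]
    svg <- c(svg,
             sprintf('<text x="%d" y="%d" font-size="14">%s</text>',
                     pad, top, mgmts[i]),
             sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="black"/>',
                     pad, top + h_panel, w - 20, top + h_panel),
             sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="black"/>',
                     pad, top, pad, top + h_panel))
    for (r in seq_len(nrow(sub))) {
      cx <- pad + (w - pad - 30) * sub$xpos[r] / (nx + 1)
      cy <- top + h_panel * (1 - sub$pip[r])
      svg <- c(svg, sprintf(
        '<circle cx="%.1f" cy="%.1f" r="3" fill="%s" fill-opacity="0.8"><title>%s | %s | PIP=%.3f</title></circle>',
        cx, cy, cols[sub$marker_id[r]], sub$marker_id[r], sub$phenotype[r],
        sub$pip[r]))
    }
  }
  svg <- c(svg, "</svg>")
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>Phenome-wide association</title></head><body>",
            "<h2>Phenome-wide association (hover points to identify)</h2>",
            svg,
            "<p>Classes left to right: Bands, Index, MM. One colour per marker.</p>",
            "</body></html>")
  writeLines(html, path)
  invisible(path)
}

#' Heritability spectrum plot
#'
#' Genomic heritability against wavelength for band phenotypes, per
#' management.
#'
#' @param h2_table data frame with `phenotype`, `class`, `management`, `h2`
#'   and, for bands, `wavelength_nm`.
#' @return a ggplot object.
#' @export
plot_h2_spectrum <- function(h2_table) {
  bands <- h2_table[h2_table$class == "band", , drop = FALSE]
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$wavelength_nm, y = .data$h2,
                                      colour = .data$management)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = "Genomic heritability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' Genomic-correlation spectrum plot
#'
#' Genomic correlation between a manual trait and each band phenotype
#' against wavelength, per management.
#'
#' @param rg_table long table from [fit_rg_pairs()] with an added
#'   `wavelength_nm` column for band phenotypes.
#' @return a ggplot object.
#' @export
plot_rg_spectrum <- function(rg_table) {
  ggplot2::ggplot(rg_table,
                  ggplot2::aes(x = .data$wavelength_nm, y = .data$rg_mean,
                               colour = .data$management)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rg_low,
                                      ymax = .data$rg_high,
                                      fill = .data$management),
                         alpha = 0.15, colour = NA) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Genomic correlation") +
    ggplot2::theme_bw()
}
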