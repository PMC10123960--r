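#' Spectral index registry
#'
#' Index formulas vary between sources, so the registry is data-driven:
#' every definition carries its formula as text and a literature source
#' string, and users can load an edited JSON registry without code changes.
#' Formulas are arithmetic expressions over `R<nm>` (reflectance at the
#' nominal wavelength, resolved to the nearest band), `D<nm>` (centred
#' first-derivative of reflectance with respect to wavelength), and
#' `dsum(from, to)` (sum of the first derivative over all bands in the
#' range).
#'
#' @param path JSON registry file; default is the registry shipped with the
#'   package (NDVI, EVI, NPQI, CRI1-4, Chlg, Datt6, GMI1/2, PARS, SR1/SR3,
#'   D1/D2, RDVI, RARSa/b/c, the red-edge derivative sum "SD", PRI, SAVI,
#'   OSAVI, NDNI, GNDVI).
#' @return list of `index_definition` objects (fields `name`,
#'   `display_name`, `formula`, `required_wavelengths_nm`, `source`).
#' @export
load_index_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "spectral_indices.json",
                        package = "specgwas")
  defs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  lapply(defs, function(d) {
    d$required_wavelengths_nm <- as.numeric(unlist(d$required_wavelengths_nm))
    validate_index_definition(d)
    structure(d, class = "index_definition")
  })
}

#' @rdname load_index_registry
#' @export
default_index_registry <- function() load_index_registry()

validate_index_definition <- function(d) {
  stopifnot(is.character(d$name), is.character(d$formula),
            length(d$required_wavelengths_nm) >= 1)
  vars <- all.vars(str2lang(d$formula))
  wls <- as.numeric(sub("^[RD]", "", grep("^[RD][0-9]+$", vars, value = TRUE)))
  extra <- setdiff(wls, d$required_wavelengths_nm)
  if (length(extra))
    stop("index ", d$name, " formula references wavelengths not declared: ",
         paste(extra, collapse = ", "))
  invisible(d)
}

#' Compute spectral indices from per-plot band means
#'
#' Evaluates each registry formula once per plot on the band-mean spectra.
#' An index whose nominal wavelengths cannot be resolved on the spectra's
#' band grid (e.g. SWIR indices on a VNIR camera) yields `NA` for every plot
#' and is listed in the `unresolved` attribute. Division by zero or other
#' non-finite results yield `NA` for the affected plot and index, counted in
#' the `failures` attribute.
#'
#' @param spectra a `spectra_table` (see [spectra_table()]).
#' @param registry list of index definitions from [load_index_registry()].
#' @return data frame `plot_id` + one column per index (internal names;
#'   display names in attribute `display_names`).
#' @export
compute_indices <- function(spectra, registry = default_index_registry()) {
  wl <- spectra_wavelengths(spectra)
  R <- as.matrix(spectra[, paste0("R", round(wl)), drop = FALSE])
  n <- nrow(R); nb <- length(wl)
  # centred first derivative wrt wavelength, one-sided at the grid edges
  D <- matrix(NA_real_, n, nb)
  if (nb >= 2) {
    for (b in seq_len(nb)) {
      lo <- max(1, b - 1); hi <- min(nb, b + 1)
      D[, b] <- (R[, hi] - R[, lo]) / (wl[hi] - wl[lo])
    }
  }
  band_at <- function(target) nearest_band(wl, target)

  out <- list(plot_id = spectra$plot_id)
  display <- character(0)
  unresolved <- character(0)
  failures <- integer(0)
  for (d in registry) {
    vars <- all.vars(str2lang(d$formula))
    rd_vars <- grep("^[RD][0-9]+$", vars, value = TRUE)
    env <- new.env(parent = baseenv())
    resolved <- TRUE
    for (v in rd_vars) {
      target <- as.numeric(substring(v, 2))
      b <- tryCatch(band_at(target), error = function(e) NA_integer_)
      if (is.na(b)) { resolved <- FALSE; break }
      assign(v, if (startsWith(v, "R")) R[, b] else D[, b], envir = env)
    }
    if ("dsum" %in% vars || grepl("dsum(", d$formula, fixed = TRUE)) {
      assign("dsum", function(from, to) {
        ok <- tryCatch({ band_at(from); band_at(to); TRUE },
                       error = function(e) FALSE)
        if (!ok) stop("dsum range unresolvable")
        sel <- which(wl >= from & wl <= to)
        rowSums(D[, sel, drop = FALSE])
      }, envir = env)
    }
    val <- if (!resolved) rep(NA_real_, n) else
      tryCatch(eval(str2lang(d$formula), envir = env),
               error = function(e) { resolved <<- FALSE; rep(NA_real_, n) })
    if (!resolved) unresolved <- c(unresolved, d$name)
    val <- as.numeric(val)
    if (length(val) == 1) val <- rep(val, n)
    bad <- !is.finite(val) & resolved
    if (any(bad)) {
      failures[d$name] <- sum(bad)
      val[bad] <- NA_real_
    }
    out[[d$name]] <- val
    display[d$name] <- if (!is.null(d$display_name)) d$display_name else d$name
  }
  res <- as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  attr(res, "display_names") <- display
  attr(res, "unresolved") <- unresolved
  attr(res, "failures") <- failures
  res
}
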