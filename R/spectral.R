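#' Nearest band to a nominal wavelength
#'
#' Index definitions cite nominal wavelengths; the camera grid is discrete.
#' Returns the index of the band minimizing `|lambda - target|`; on a tie
#' the lower wavelength wins. Targets farther than one grid spacing outside
#' the grid are rejected.
#'
#' @param wavelengths_nm strictly increasing wavelength grid.
#' @param target_nm nominal wavelength.
#' @return integer band index.
#' @export
nearest_band <- function(wavelengths_nm, target_nm) {
  stopifnot(length(wavelengths_nm) >= 1)
  delta <- if (length(wavelengths_nm) > 1) stats::median(diff(wavelengths_nm)) else Inf
  lo <- min(wavelengths_nm) - delta
  hi <- max(wavelengths_nm) + delta
  if (target_nm < lo || target_nm > hi)
    stop("target wavelength ", target_nm, " nm outside grid range [",
         round(lo, 1), ", ", round(hi, 1), "]")
  which.min(abs(wavelengths_nm - target_nm))  # first minimum = lower wavelength
}

#' Mask a hyperspectral cube and average foreground pixels
#'
#' Foreground ("leaf") pixels are those whose reflectance at the band
#' nearest `threshold_band_nm` exceeds `threshold`; the per-band mean over
#' foreground pixels is returned. The result is by construction invariant
#' to the value of background pixels that fall below the threshold.
#'
#' @param cube a `hyperspectral_cube` (see [simulate_cube()]) or a list with
#'   `values` (rows x cols x bands array) and `wavelengths_nm`.
#' @param threshold reflectance threshold defining the foreground.
#' @param threshold_band_nm wavelength of the thresholding band (commonly in
#'   the NIR where vegetation is bright).
#' @return named numeric vector of per-band mean reflectance.
#' @export
mask_and_mean <- function(cube, threshold, threshold_band_nm = 800) {
  stopifnot(!is.null(cube$values), !is.null(cube$wavelengths_nm))
  b <- nearest_band(cube$wavelengths_nm, threshold_band_nm)
  fg <- cube$values[, , b] > threshold
  if (!any(fg))
    stop("empty foreground: no pixel exceeds threshold ", threshold,
         " at ", round(cube$wavelengths_nm[b], 1), " nm")
  nb <- dim(cube$values)[3]
  out <- vapply(seq_len(nb), function(k) mean(cube$values[, , k][fg]), 0)
  names(out) <- paste0("R", round(cube$wavelengths_nm))
  out
}

#' Build a spectra table from per-plot band means
#'
#' @param plot_id character vector of plot identifiers.
#' @param reflectance matrix of band means, one row per plot.
#' @param wavelengths_nm band wavelengths.
#' @return a `spectra_table` data frame (`plot_id` + `R<nm>` columns).
#' @export
spectra_table <- function(plot_id, reflectance, wavelengths_nm) {
  reflectance <- as.matrix(reflectance)
  stopifnot(length(plot_id) == nrow(reflectance),
            length(wavelengths_nm) == ncol(reflectance),
            all(diff(wavelengths_nm) > 0))
  if (any(reflectance < 0 | reflectance > 1, na.rm = TRUE))
    stop("reflectance values must lie in [0, 1]")
  colnames(reflectance) <- paste0("R", round(wavelengths_nm))
  out <- data.frame(plot_id = plot_id, reflectance, check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "wavelengths_nm") <- wavelengths_nm
  class(out) <- c("spectra_table", "data.frame")
  out
}

#' Read/write spectra tables as CSV
#' @param spectra a `spectra_table`.
#' @param path CSV path (columns: `plot_id`, then `R<nm>` per band).
#' @return the path / the table.
#' @export
write_spectra_csv <- function(spectra, path) {
  utils::write.table(spectra, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE, check.names = FALSE)
  wl <- as.numeric(sub("^R", "", setdiff(names(df), "plot_id")))
  spectra_table(df$plot_id, as.matrix(df[, -1, drop = FALSE]), wl)
}
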