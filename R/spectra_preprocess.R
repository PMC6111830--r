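#' Construct a spectrum set
#'
#' A `spectrum_set` holds a matrix of per-sample spectra on a common,
#' strictly increasing, uniformly spaced 1-nm-class wavelength grid. It is
#' the container every pipeline stage consumes and produces. `kind` tags the
#' physical quantity: `"RL"` water-leaving reflectance, `"RRS"` remote
#' sensing reflectance, `"FDR"` first derivative reflectance (the only kind
#' allowed to be negative).
#'
#' @param wavelengths integer-valued vector of wavelengths in nm, strictly
#'   increasing with constant step.
#' @param values numeric matrix, samples in rows, one column per wavelength.
#' @param sample_ids character vector of unique sample identifiers.
#' @param station_ids optional station labels, recycled checks apply.
#' @param kind one of `"RL"`, `"RRS"`, `"FDR"`.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavelengths, values, sample_ids = NULL,
                         station_ids = NULL, kind = c("RL", "RRS", "FDR")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != ncol(values))
    stop("number of wavelengths (", length(wavelengths),
         ") does not match value columns (", ncol(values), ")")
  d <- diff(wavelengths)
  if (length(wavelengths) > 1) {
    if (any(d <= 0)) stop("wavelengths must be strictly increasing")
    if (max(d) - min(d) > 1e-8 * max(abs(d)))
      stop("wavelength grid must have a constant step")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values)) stop("sample_ids length mismatch")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (!is.null(station_ids)) {
    station_ids <- as.character(station_ids)
    if (length(station_ids) != nrow(values)) stop("station_ids length mismatch")
  }
  if (kind != "FDR" && any(values < 0, na.rm = TRUE))
    stop(kind, " reflectance values must be non-negative")
  dimnames(values) <- list(sample_ids, as.character(wavelengths))
  structure(
    list(wavelengths = wavelengths, values = values, sample_ids = sample_ids,
         station_ids = station_ids, kind = kind),
    class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set kind=%s: %d samples x %d bands, %g-%g nm (step %g)>\n",
              x$kind, nrow(x$values), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              if (length(x$wavelengths) > 1) diff(x$wavelengths)[1] else NA))
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$values)

grid_step <- function(s) {
  if (length(s$wavelengths) < 2) return(NA_real_)
  diff(s$wavelengths)[1]
}

band_index <- function(s, nm) {
  i <- which.min(abs(s$wavelengths - nm))
  if (abs(s$wavelengths[i] - nm) > grid_step(s) / 2 + 1e-9)
    stop("wavelength ", nm, " nm is outside the grid (",
         min(s$wavelengths), "-", max(s$wavelengths), " nm)")
  i
}

#' Construct a chlorophyll-a table
#'
#' Per-sample chlorophyll-a concentrations (ug/L) with sample and station
#' identifiers, alignable to a [spectrum_set()] by `sample_id`.
#'
#' @param sample_ids unique identifiers.
#' @param chl positive concentrations, ug/L.
#' @param station_ids optional station labels.
#' @param dates optional ISO dates.
#' @return A `chl_table` (also a data.frame).
#' @export
chl_table <- function(sample_ids, chl, station_ids = NULL, dates = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  chl <- as.numeric(chl)
  if (length(chl) != length(sample_ids)) stop("chl length mismatch")
  if (any(!is.finite(chl)) || any(chl <= 0))
    stop("chl values must be finite and positive")
  df <- data.frame(sample_id = sample_ids, chl = chl,
                   stringsAsFactors = FALSE)
  df$station_id <- if (is.null(station_ids)) NA_character_ else as.character(station_ids)
  df$date <- if (is.null(dates)) NA_character_ else as.character(dates)
  class(df) <- c("chl_table", "data.frame")
  df
}

#' Read paired spectra and chlorophyll CSV files
#'
#' The spectra CSV has a `sample_id` column followed by one column per
#' integer wavelength (nm); the chlorophyll CSV has columns `sample_id`,
#' `station_id`, `date` (optional) and `chl_ugL`. Samples present in the
#' spectra file but lacking a chlorophyll value are dropped with a message;
#' chlorophyll rows with no spectrum are an error (they indicate a
#' misaligned pair of files).
#'
#' @param path spectra CSV path.
#' @param chl_path chlorophyll CSV path.
#' @param kind kind tag for the spectra, default `"RL"`.
#' @return `list(spectra = spectrum_set, chl = chl_table)`, aligned row-wise.
#' @export
load_spectra <- function(path, chl_path, kind = "RL") {
  sp <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(sp) == 0 || ncol(sp) < 2) stop("spectra file is empty or malformed: ", path)
  if (names(sp)[1] != "sample_id") stop("first spectra column must be 'sample_id'")
  wl <- suppressWarnings(as.numeric(names(sp)[-1]))
  if (any(is.na(wl))) stop("non-numeric wavelength headers in ", path)
  ch <- read.csv(chl_path, stringsAsFactors = FALSE)
  if (nrow(ch) == 0) stop("chl file is empty: ", chl_path)
  if (!all(c("sample_id", "chl_ugL") %in% names(ch)))
    stop("chl file must have columns sample_id and chl_ugL")
  ch$sample_id <- as.character(ch$sample_id)
  sp$sample_id <- as.character(sp$sample_id)
  if (anyDuplicated(sp$sample_id))
    stop("duplicate sample ids in spectra: ",
         paste(unique(sp$sample_id[duplicated(sp$sample_id)]), collapse = ", "))
  orphan_chl <- setdiff(ch$sample_id, sp$sample_id)
  if (length(orphan_chl) > 0)
    stop("chl rows with no matching spectrum: ", paste(orphan_chl, collapse = ", "))
  missing_chl <- setdiff(sp$sample_id, ch$sample_id)
  if (length(missing_chl) > 0) {
    message("dropping ", length(missing_chl), " sample(s) lacking a chl value: ",
            paste(missing_chl, collapse = ", "))
    sp <- sp[!(sp$sample_id %in% missing_chl), , drop = FALSE]
  }
  ch <- ch[match(sp$sample_id, ch$sample_id), , drop = FALSE]
  st <- if ("station_id" %in% names(ch)) as.character(ch$station_id) else NULL
  spectra <- spectrum_set(wl, as.matrix(sp[, -1, drop = FALSE]),
                          sample_ids = sp$sample_id, station_ids = st,
                          kind = kind)
  chl <- chl_table(ch$sample_id, ch$chl_ugL, station_ids = st,
                   dates = if ("date" %in% names(ch)) ch$date else NULL)
  list(spectra = spectra, chl = chl)
}

#' Write a spectrum set / chlorophyll table to CSV
#'
#' Inverse of [load_spectra()]; full double precision is preserved.
#'
#' @param s a `spectrum_set`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_spectra <- function(s, path) {
  df <- data.frame(sample_id = s$sample_ids, stringsAsFactors = FALSE)
  vals <- as.data.frame(format(s$values, digits = 17, trim = TRUE, scientific = FALSE),
                        stringsAsFactors = FALSE)
  names(vals) <- as.character(s$wavelengths)
  write.csv(cbind(df, vals), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @param chl a `chl_table`.
#' @export
write_chl_table <- function(chl, path) {
  df <- data.frame(sample_id = chl$sample_id, station_id = chl$station_id,
                   date = chl$date,
                   chl_ugL = format(chl$chl, digits = 17, trim = TRUE),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trim a spectrum set to the analysis wavelength range
#'
#' The measured 350-1050 nm range carries instrument noise at both ends;
#' analysis is restricted to 400-900 nm (501 bands at 1 nm), inclusive.
#'
#' @param s a `spectrum_set`.
#' @param lo,hi range bounds in nm, inclusive.
#' @return A `spectrum_set` on the restricted grid.
#' @export
trim_to_analysis_range <- function(s, lo = 400, hi = 900) {
  if (lo > hi) stop("lo must be <= hi")
  if (lo < min(s$wavelengths) || hi > max(s$wavelengths))
    stop("requested range [", lo, ", ", hi, "] outside grid [",
         min(s$wavelengths), ", ", max(s$wavelengths), "]")
  keep <- s$wavelengths >= lo & s$wavelengths <= hi
  spectrum_set(s$wavelengths[keep], s$values[, keep, drop = FALSE],
               sample_ids = s$sample_ids, station_ids = s$station_ids,
               kind = s$kind)
}

#' Savitzky-Golay smoothing
#'
#' Smooths each sample's spectrum independently with a Savitzky-Golay
#' filter (local least-squares polynomial). The default 15-point window with
#' a quadratic polynomial is the common chemometrics setting; polynomials of
#' degree up to `polyorder` pass through unchanged.
#'
#' @param s a `spectrum_set`.
#' @param window odd number of points in the filter window.
#' @param polyorder polynomial order, less than `window`.
#' @return A smoothed `spectrum_set` on the same grid.
#' @export
savgol_smooth <- function(s, window = 15, polyorder = 2) {
  if (window %% 2 == 0) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (window > length(s$wavelengths)) stop("window exceeds band count")
  sm <- t(apply(s$values, 1, function(r)
    signal::sgolayfilt(r, p = polyorder, n = window)))
  # local polynomial fits can slightly undershoot zero on noisy data
  if (s$kind != "FDR") sm[sm < 0] <- 0
  spectrum_set(s$wavelengths, sm, sample_ids = s$sample_ids,
               station_ids = s$station_ids, kind = s$kind)
}

#' First derivative reflectance (FDR)
#'
#' Wavelength derivative of water-leaving reflectance: central differences
#' at interior bands, one-sided differences at the two edges, so an
#' n-band input yields an n-band FDR spectrum (the 501-band analysis grid
#' is preserved). Units are reflectance per nm.
#'
#' @param s a `spectrum_set` of kind `"RL"` (or `"RRS"`).
#' @return A `spectrum_set` of kind `"FDR"` on the same grid.
#' @export
first_derivative <- function(s) {
  if (s$kind == "FDR") stop("input is already a derivative spectrum")
  p <- length(s$wavelengths)
  if (p < 2) stop("need at least 2 bands to differentiate")
  h <- grid_step(s)
  v <- s$values
  d <- matrix(NA_real_, nrow(v), p)
  d[, 1] <- (v[, 2] - v[, 1]) / h
  d[, p] <- (v[, p] - v[, p - 1]) / h
  if (p > 2) {
    i <- 2:(p - 1)
    d[, i] <- (v[, i + 1, drop = FALSE] - v[, i - 1, drop = FALSE]) / (2 * h)
  }
  spectrum_set(s$wavelengths, d, sample_ids = s$sample_ids,
               station_ids = s$station_ids, kind = "FDR")
}

#' Convert water-leaving reflectance to remote sensing reflectance
#'
#' Rrs and RL differ by the constant pi. The convention used here is
#' Rrs = RL / pi; because every implemented retrieval model is built on
#' band ratios, predictions are provably identical under the multiplied
#' convention, which is available via `convention = "multiply"`.
#'
#' @param s a `spectrum_set` of kind `"RL"`.
#' @param convention `"divide"` (Rrs = RL/pi, default) or `"multiply"`.
#' @return A `spectrum_set` of kind `"RRS"`.
#' @export
to_rrs <- function(s, convention = c("divide", "multiply")) {
  convention <- match.arg(convention)
  if (s$kind != "RL") stop("to_rrs expects kind RL, got ", s$kind)
  f <- if (convention == "divide") 1 / pi else pi
  spectrum_set(s$wavelengths, s$values * f, sample_ids = s$sample_ids,
               station_ids = s$station_ids, kind = "RRS")
}
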