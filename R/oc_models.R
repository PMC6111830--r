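#' Ocean chlorophyll algorithm variants
#'
#' Band definitions of the empirical ocean chlorophyll (OC) algorithms:
#' OC2 uses the 490/555 nm blue/green ratio; OC3 and OC4 take the maximum
#' of two (443, 490) and three (443, 490, 510) blue/green ratios. Bands are
#' the nominal SeaWiFS centers; on a hyperspectral grid the nearest 1-nm
#' band is used.
#'
#' @param name `"OC2"`, `"OC3"` or `"OC4"`.
#' @return An `oc_variant` list with `name`, `blue_bands`, `green_band`.
#' @export
oc_variant <- function(name = c("OC2", "OC3", "OC4")) {
  name <- match.arg(name)
  blue <- switch(name, OC2 = 490, OC3 = c(443, 490), OC4 = c(443, 490, 510))
  structure(list(name = name, blue_bands = blue, green_band = 555),
            class = "oc_variant")
}

#' Standard version-6 OC polynomial coefficients
#'
#' Fourth-order polynomial coefficients (a0..a4) of the version-6 OC
#' algorithms for SeaWiFS bands.
#'
#' @param name `"OC2"`, `"OC3"` or `"OC4"`.
#' @return Numeric vector of length 5.
#' @export
oc_standard_coefficients <- function(name = c("OC2", "OC3", "OC4")) {
  name <- match.arg(name)
  switch(name,
    OC2 = c(0.2511, -2.0853, 1.5035, -3.1747, 0.3383),
    OC3 = c(0.2515, -2.3798, 1.5823, -0.6372, -0.5692),
    OC4 = c(0.3272, -2.9940, 2.7218, -1.2259, -0.5683))
}

#' Maximum band-ratio predictor of the OC algorithms
#'
#' R = log10(max over blue bands of Rrs(blue)/Rrs(green)). Samples with a
#' non-positive Rrs at any required band cannot enter the log-ratio; they
#' are returned as NA and listed in the `"flagged"` attribute rather than
#' propagating silently.
#'
#' @param s a `spectrum_set` of kind `"RRS"`.
#' @param variant an [oc_variant()].
#' @return Numeric vector of per-sample R values with attribute `flagged`
#'   (character vector of excluded sample ids).
#' @export
oc_ratio <- function(s, variant) {
  if (s$kind != "RRS") stop("oc_ratio expects kind RRS; call to_rrs() first")
  stopifnot(inherits(variant, "oc_variant"))
  bi <- vapply(variant$blue_bands, function(b) band_index(s, b), integer(1))
  gi <- band_index(s, variant$green_band)
  blue <- s$values[, bi, drop = FALSE]
  green <- s$values[, gi]
  bad <- green <= 0 | apply(blue <= 0, 1, any)
  ratio <- apply(blue / green, 1, max)
  out <- log10(ratio)
  out[bad] <- NA_real_
  if (any(bad))
    message(sum(bad), " sample(s) flagged for non-positive Rrs at an OC band")
  attr(out, "flagged") <- s$sample_ids[bad]
  out
}

#' Predict chlorophyll-a from an OC band-ratio value
#'
#' log10(Chl-a) = a0 + a1 R + a2 R^2 + a3 R^3 + a4 R^4; the prediction is
#' 10 to that polynomial, hence strictly positive.
#'
#' @param R band-ratio predictor from [oc_ratio()].
#' @param coeffs numeric vector (a0..a4).
#' @return Predicted chlorophyll-a, ug/L (NA where R is NA).
#' @export
oc_predict <- function(R, coeffs) {
  if (length(coeffs) != 5 || any(!is.finite(coeffs)))
    stop("coeffs must be 5 finite values (a0..a4)")
  10^(coeffs[1] + coeffs[2] * R + coeffs[3] * R^2 +
        coeffs[4] * R^3 + coeffs[5] * R^4)
}

#' Recalibrate OC polynomial coefficients on local data
#'
#' Ordinary least squares of log10(chl) on (1, R, R^2, R^3, R^4) with R the
#' variant's maximum band ratio, the standard way of adapting the OC
#' polynomial to a local optical regime. Flagged samples are excluded.
#'
#' @param s a `spectrum_set` of kind `"RRS"`.
#' @param chl a [chl_table()] aligned with `s`.
#' @param variant an [oc_variant()].
#' @return List with `coefficients` (a0..a4), `n` used, `r2` of the log-log
#'   fit, and the `fit` lm object.
#' @export
oc_recalibrate <- function(s, chl, variant) {
  if (nrow(s$values) != nrow(chl))
    stop("spectra and chl table are misaligned (", nrow(s$values), " vs ",
         nrow(chl), " samples)")
  R <- oc_ratio(s, variant)
  ok <- is.finite(R) & is.finite(chl$chl) & chl$chl > 0
  if (sum(ok) < 6)
    stop("need at least 6 valid samples to fit 5 coefficients, got ", sum(ok))
  df <- data.frame(y = log10(chl$chl[ok]), R = R[ok])
  fit <- lm(y ~ R + I(R^2) + I(R^3) + I(R^4), data = df)
  if (any(is.na(coef(fit))))
    stop("rank-deficient polynomial design: band-ratio values are degenerate")
  resid <- df$y - unname(fitted(fit))
  list(coefficients = unname(coef(fit)), n = sum(ok),
       r2 = 1 - sum(resid^2) / sum((df$y - mean(df$y))^2), fit = fit)
}
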