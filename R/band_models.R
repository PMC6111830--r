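#' Three-band semi-analytical chlorophyll index
#'
#' Computes (1/R(l1) - 1/R(l2)) * R(l3) per sample. l1 sits in the red
#' chlorophyll absorption maximum (~660-670 nm), l2 in the NIR where
#' chlorophyll absorption is minimal, l3 further into the NIR where
#' absorption by any constituent is minimal, so the index isolates the
#' pigment signal and cancels backscatter. Samples with zero reflectance at
#' l1 or l2 are returned as NA and flagged.
#'
#' @param s a `spectrum_set` (kind `"RL"`; any reflectance-like kind works
#'   since the index is scale-invariant).
#' @param bands numeric (l1, l2, l3) in nm, l1 < l2 < l3.
#' @return Per-sample index values with attribute `flagged`.
#' @export
three_band_value <- function(s, bands) {
  if (length(bands) != 3) stop("bands must be (l1, l2, l3)")
  i <- vapply(bands, function(b) band_index(s, b), integer(1))
  r1 <- s$values[, i[1]]; r2 <- s$values[, i[2]]; r3 <- s$values[, i[3]]
  bad <- r1 == 0 | r2 == 0
  out <- (1 / r1 - 1 / r2) * r3
  out[bad] <- NA_real_
  attr(out, "flagged") <- s$sample_ids[bad]
  out
}

#' NIR/red two-band chlorophyll index
#'
#' Computes R(l_nir) / R(l_red) per sample: red reflectance drops with
#' chlorophyll absorption while the NIR band is dominated by backscatter,
#' so the ratio rises with concentration in productive waters.
#'
#' @param s a `spectrum_set`.
#' @param red red waveband, nm.
#' @param nir NIR waveband, nm.
#' @return Per-sample ratio with attribute `flagged` (zero red reflectance).
#' @export
two_band_value <- function(s, red, nir) {
  ir <- band_index(s, red); ii <- band_index(s, nir)
  rr <- s$values[, ir]
  bad <- rr == 0
  out <- s$values[, ii] / rr
  out[bad] <- NA_real_
  attr(out, "flagged") <- s$sample_ids[bad]
  out
}

cor_with_chl <- function(index, chl) {
  ok <- is.finite(index)
  if (sd(chl[ok]) == 0) stop("chl is constant; correlation undefined")
  if (sd(index[ok]) == 0) return(0)
  cor(index[ok], chl[ok])
}

scan_band <- function(s, chl, candidates, value_fn) {
  r <- vapply(candidates, function(b) cor_with_chl(value_fn(b), chl),
              numeric(1))
  # tie-break: smallest wavelength among |r| maxima (to numerical tolerance)
  mx <- max(abs(r))
  best <- candidates[abs(r) >= mx - 1e-9 * max(1, mx)][1]
  list(best = best, trace = data.frame(wavelength = candidates, r = r))
}

#' Stepwise spectral tuning of the three-band index
#'
#' Stage 1 scans l1 over `ranges$lambda1` with (l2, l3) held at
#' (`init_lambda2`, `init_lambda3`), keeping the band maximising the
#' absolute Pearson correlation between the index and chlorophyll. Stage 2
#' scans l2 with l1 fixed and l3 at its initial value; stage 3 scans l3
#' with l1 and l2 fixed. Single pass, no iteration.
#'
#' @param s a `spectrum_set`.
#' @param chl chlorophyll vector or [chl_table()].
#' @param ranges list with elements `lambda1`, `lambda2`, `lambda3`, each a
#'   (lo, hi) nm interval searched at the grid step.
#' @param init_lambda2,init_lambda3 initial NIR placements, nm.
#' @return A `tuning_result`: `selected` (named l1, l2, l3), `trace` (list of
#'   per-stage data.frames of candidate wavelength and r), `n_stages`.
#' @export
tune_three_band <- function(s, chl,
                            ranges = list(lambda1 = c(600, 700),
                                          lambda2 = c(680, 740),
                                          lambda3 = c(700, 800)),
                            init_lambda2 = 700, init_lambda3 = 750) {
  chl <- chl_values(chl)
  if (length(chl) != nrow(s$values)) stop("chl length mismatch")
  if (nrow(s$values) < 3) stop("need at least 3 samples")
  cand <- function(rg) {
    w <- s$wavelengths
    w[w >= rg[1] & w <= rg[2]]
  }
  s1 <- scan_band(s, chl, cand(ranges$lambda1), function(b)
    three_band_value(s, c(b, init_lambda2, init_lambda3)))
  s2 <- scan_band(s, chl, cand(ranges$lambda2), function(b)
    three_band_value(s, c(s1$best, b, init_lambda3)))
  s3 <- scan_band(s, chl, cand(ranges$lambda3), function(b)
    three_band_value(s, c(s1$best, s2$best, b)))
  structure(list(selected = c(lambda1 = s1$best, lambda2 = s2$best,
                              lambda3 = s3$best),
                 trace = list(lambda1 = s1$trace, lambda2 = s2$trace,
                              lambda3 = s3$trace),
                 n_stages = 3L, model = "three-band"),
            class = "tuning_result")
}

#' Stepwise spectral tuning of the NIR/red two-band index
#'
#' Stage 1 scans the red band over `red_range` with the NIR band held at
#' `init_nir`; stage 2 scans the NIR band over `nir_range` with the chosen
#' red band fixed. Selection maximises the absolute Pearson correlation
#' with chlorophyll.
#'
#' @param s a `spectrum_set`.
#' @param chl chlorophyll vector or [chl_table()].
#' @param red_range,nir_range (lo, hi) nm search intervals.
#' @param init_nir initial NIR band, nm.
#' @return A `tuning_result` with `selected` (named red, nir) and traces.
#' @export
tune_two_band <- function(s, chl, red_range = c(620, 680),
                          nir_range = c(680, 740), init_nir = 705) {
  chl <- chl_values(chl)
  if (length(chl) != nrow(s$values)) stop("chl length mismatch")
  if (nrow(s$values) < 3) stop("need at least 3 samples")
  cand <- function(rg) {
    w <- s$wavelengths
    w[w >= rg[1] & w <= rg[2]]
  }
  s1 <- scan_band(s, chl, cand(red_range), function(b)
    two_band_value(s, b, init_nir))
  s2 <- scan_band(s, chl, cand(nir_range), function(b)
    two_band_value(s, s1$best, b))
  structure(list(selected = c(red = s1$best, nir = s2$best),
                 trace = list(red = s1$trace, nir = s2$trace),
                 n_stages = 2L, model = "two-band"),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result %s: %s>\n", x$model,
              paste(names(x$selected), x$selected, sep = "=", collapse = ", ")))
  invisible(x)
}

chl_values <- function(chl) {
  if (inherits(chl, "chl_table") || is.data.frame(chl)) chl$chl else as.numeric(chl)
}

#' Linear calibration of an index against chlorophyll
#'
#' OLS fit chl = a * index + b with training-set diagnostics; on the
#' training set the intercept absorbs any mean offset, so bias is zero to
#' numerical precision.
#'
#' @param index per-sample index values (NAs excluded with their samples).
#' @param chl chlorophyll vector or [chl_table()].
#' @return A `linear_fit`: `a` (slope), `b` (intercept), `r2`, `rmse`,
#'   `bias`, `n`, `fitted`.
#' @export
calibrate_linear <- function(index, chl) {
  chl <- chl_values(chl)
  ok <- is.finite(index) & is.finite(chl)
  x <- index[ok]; y <- chl[ok]
  if (length(x) < 3) stop("need at least 3 samples")
  if (sd(x) == 0) stop("index is constant; cannot calibrate")
  fit <- lm(y ~ x)
  pred <- unname(fitted(fit))
  structure(list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
                 r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
                 rmse = sqrt(mean((y - pred)^2)),
                 bias = mean(pred - y), n = length(x), fitted = pred),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit: chl = %.4g * R + %.4g, R2 = %.3f, RMSE = %.3f, n = %d>\n",
              x$a, x$b, x$r2, x$rmse, x$n))
  invisible(x)
}

#' Exhaustive two-dimensional band-ratio R-squared matrix
#'
#' For every ordered pair (numerator band i, denominator band j) on the
#' analysis grid, the squared Pearson correlation between the per-sample
#' ratio R(li)/R(lj) and chlorophyll (equivalently the R-squared of the OLS
#' regression of chlorophyll on the ratio). The diagonal is undefined (NA).
#' On the 400-900 nm grid this is a 501 x 501 matrix.
#'
#' @param s a `spectrum_set` on the analysis grid.
#' @param chl chlorophyll vector or [chl_table()].
#' @return Matrix with wavelength dimnames; `[i, j]` uses band i as
#'   numerator and band j as denominator.
#' @export
ratio_matrix <- function(s, chl) {
  chl <- chl_values(chl)
  v <- s$values
  p <- ncol(v)
  out <- matrix(NA_real_, p, p,
                dimnames = list(as.character(s$wavelengths),
                                as.character(s$wavelengths)))
  for (j in seq_len(p)) {
    den <- v[, j]
    ratios <- v / den
    ratios[!is.finite(ratios)] <- NA
    r <- suppressWarnings(cor(ratios, chl, use = "pairwise.complete.obs"))
    out[, j] <- drop(r)^2
  }
  diag(out) <- NA_real_
  out
}
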