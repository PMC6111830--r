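#' Population-form standard deviation
#'
#' SD with the n divisor (rather than the sample n - 1 divisor). Used
#' inside the RPD so that RPD = SD/RMSE matches an RMSE that also uses the
#' n divisor.
#'
#' @param x numeric vector.
#' @return Scalar SD.
#' @export
sd_population <- function(x) sqrt(mean((x - mean(x))^2))

#' Convert a standard deviation between divisor conventions
#'
#' Rescales an SD computed with one divisor convention (sample, n - 1; or
#' population, n) to the other, given the sample size.
#'
#' @param s the SD value.
#' @param n sample size it was computed from.
#' @param from,to `"sample"` or `"population"`.
#' @return Converted SD.
#' @export
convert_sd <- function(s, n, from = c("sample", "population"),
                       to = c("population", "sample")) {
  from <- match.arg(from); to <- match.arg(to)
  if (from == to) return(s)
  if (from == "sample") s * sqrt((n - 1) / n) else s * sqrt(n / (n - 1))
}

#' Selected-waveband percentage
#'
#' Reporting convention for variable selection: the share of retained
#' wavebands in the full analysis grid, in percent, rounded to one decimal
#' (30 of 501 bands reports as 6.0).
#'
#' @param n_selected retained band count.
#' @param n_total grid band count (501 on the 400-900 nm analysis grid).
#' @return Percentage rounded to one decimal.
#' @export
selected_percentage <- function(n_selected, n_total = 501) {
  round(100 * n_selected / n_total, 1)
}

#' Prediction-quality metrics
#'
#' R2 is the squared Pearson correlation between observed and predicted
#' values; RMSE uses the n divisor; bias = mean(predicted - observed), so
#' underestimation is negative; RPD = SD(observed)/RMSE with the SD
#' convention chosen by `sd_convention` (population by default, the form
#' consistent with an n-divisor RMSE).
#'
#' @param y_obs observed values.
#' @param y_pred predicted values, same length.
#' @param sd_convention `"population"` (default) or `"sample"`.
#' @return A `metrics` list: `r2`, `rmse`, `bias`, `sd`, `rpd`, `n`.
#'   `rpd` is `Inf`-flagged as NA when RMSE is zero.
#' @export
compute_metrics <- function(y_obs, y_pred,
                            sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  if (length(y_obs) != length(y_pred)) stop("length mismatch")
  ok <- is.finite(y_obs) & is.finite(y_pred)
  y_obs <- y_obs[ok]; y_pred <- y_pred[ok]
  if (length(y_obs) < 2) stop("need at least 2 finite pairs")
  if (sd(y_obs) == 0) stop("constant y_obs: R2 undefined")
  rmse <- sqrt(mean((y_obs - y_pred)^2))
  s <- if (sd_convention == "population") sd_population(y_obs) else sd(y_obs)
  structure(list(r2 = cor(y_obs, y_pred)^2, rmse = rmse,
                 bias = mean(y_pred - y_obs), sd = s,
                 rpd = if (rmse > 0) s / rmse else NA_real_,
                 n = length(y_obs)),
            class = "metrics")
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf("<metrics: n=%d R2=%.3f RMSE=%.3f bias=%.3g RPD=%s>\n",
              x$n, x$r2, x$rmse, x$bias,
              if (is.na(x$rpd)) "NA" else sprintf("%.2f", x$rpd)))
  invisible(x)
}

#' Classify a model by its RPD
#'
#' RPD of at least 2 indicates good predictive ability, between 1.4 and 2
#' moderately good, below 1.4 poor. Boundary values are assigned upward.
#'
#' @param rpd non-negative RPD value(s).
#' @return Character vector in `{"good", "moderate", "poor"}`.
#' @export
rpd_class <- function(rpd) {
  if (any(rpd < 0, na.rm = TRUE)) stop("rpd must be non-negative")
  ifelse(rpd >= 2, "good", ifelse(rpd >= 1.4, "moderate", "poor"))
}

#' Descriptive statistics of chlorophyll by station
#'
#' Per-station and pooled (Total) rows of n, min, max, mean, sample SD
#' (n - 1 divisor) and CV = SD/mean. A single-sample group has undefined SD
#' and CV (reported as NA).
#'
#' @param chl a [chl_table()].
#' @return data.frame with one row per station plus a `Total` row.
#' @export
descriptive_table <- function(chl) {
  stopifnot(is.data.frame(chl))
  groups <- split(chl$chl, chl$station_id)
  row_of <- function(x, label) {
    s <- if (length(x) > 1) sd(x) else NA_real_
    data.frame(station = label, n = length(x), min = min(x), max = max(x),
               mean = mean(x), sd = s, cv = s / mean(x),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(names(groups), function(g) row_of(groups[[g]], g))
  out <- do.call(rbind, c(rows, list(row_of(chl$chl, "Total"))))
  rownames(out) <- NULL
  out
}

#' Configuration for a full model-comparison run
#'
#' Bundles the synthetic-generator (or file-input) settings, preprocessing
#' options and model settings consumed by [compare_models()], so a report
#' is fully reproducible from its config.
#'
#' @param params a [synthetic_params()] object, or NULL when reading files.
#' @param spectra_path,chl_path CSV inputs (used when `params` is NULL).
#' @param trim (lo, hi) analysis range, nm.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param max_nlv latent-variable cap for ISE-PLS.
#' @param exclude_stations station ids to drop before modelling.
#' @param rrs_convention `"divide"` or `"multiply"` (see [to_rrs()]).
#' @return A `run_config` list.
#' @export
run_config <- function(params = synthetic_params(), spectra_path = NULL,
                       chl_path = NULL, trim = c(400, 900), sg_window = 15,
                       sg_polyorder = 2, max_nlv = 10,
                       exclude_stations = NULL,
                       rrs_convention = "divide") {
  structure(list(params = params, spectra_path = spectra_path,
                 chl_path = chl_path, trim = trim, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, max_nlv = max_nlv,
                 exclude_stations = exclude_stations,
                 rrs_convention = rrs_convention),
            class = "run_config")
}

#' Run the full model comparison
#'
#' Orchestrates the whole pipeline on one dataset: preprocessing (smooth on
#' the full measured grid, trim to the analysis range, Rrs conversion,
#' first derivative), the three standard and three recalibrated OC
#' algorithms, the fixed (705/670 nm) and tuned NIR/red two-band models,
#' the tuned three-band model, and ISE-PLS on both reflectance and
#' derivative spectra. Deterministic given the config (and its seed).
#'
#' @param config a [run_config()].
#' @return A `model_comparison`: `table` (one row per model: model, bands,
#'   r2, rmse, bias), `isepls` (list of the two `ise_pls_result`s),
#'   `tuning` (three- and two-band `tuning_result`s), `descriptives`,
#'   `recalibrated` (per-variant coefficients), `config`, `data`.
#' @export
compare_models <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$spectra_path)) {
    loaded <- load_spectra(config$spectra_path, config$chl_path)
    spectra <- loaded$spectra; chl <- loaded$chl
  } else {
    ds <- generate_dataset(config$params)
    spectra <- ds$spectra; chl <- ds$chl
  }
  if (!is.null(config$exclude_stations)) {
    keep <- !(chl$station_id %in% as.character(config$exclude_stations))
    spectra <- spectrum_set(spectra$wavelengths,
                            spectra$values[keep, , drop = FALSE],
                            sample_ids = spectra$sample_ids[keep],
                            station_ids = spectra$station_ids[keep],
                            kind = spectra$kind)
    chl <- chl[keep, , drop = FALSE]
    class(chl) <- c("chl_table", "data.frame")
  }
  y <- chl$chl
  smoothed <- savgol_smooth(spectra, config$sg_window, config$sg_polyorder)
  rl <- trim_to_analysis_range(smoothed, config$trim[1], config$trim[2])
  rrs <- to_rrs(rl, config$rrs_convention)
  fdr <- first_derivative(rl)

  rows <- list()
  oc_row <- function(label, variant_name, coeffs) {
    v <- oc_variant(variant_name)
    pred <- oc_predict(oc_ratio(rrs, v), coeffs)
    m <- compute_metrics(y, pred)
    data.frame(model = label,
               bands = paste(c(v$blue_bands, v$green_band), collapse = "/"),
               r2 = m$r2, rmse = m$rmse, bias = m$bias,
               stringsAsFactors = FALSE)
  }
  recal <- list()
  for (v in c("OC2", "OC3", "OC4")) {
    rows[[v]] <- oc_row(v, v, oc_standard_coefficients(v))
    recal[[v]] <- oc_recalibrate(rrs, chl, oc_variant(v))
    rows[[paste0("Recalibrated ", v)]] <-
      oc_row(paste0("Recalibrated ", v), v, recal[[v]]$coefficients)
  }
  tb_tune <- tune_three_band(rl, y)
  tb_fit <- calibrate_linear(three_band_value(rl, tb_tune$selected), y)
  rows[["Three-band"]] <- data.frame(
    model = "Three-band", bands = paste(tb_tune$selected, collapse = "/"),
    r2 = tb_fit$r2, rmse = tb_fit$rmse, bias = tb_fit$bias,
    stringsAsFactors = FALSE)
  nr_fit <- calibrate_linear(two_band_value(rl, red = 670, nir = 705), y)
  rows[["NIR/red"]] <- data.frame(
    model = "NIR/red", bands = "705/670",
    r2 = nr_fit$r2, rmse = nr_fit$rmse, bias = nr_fit$bias,
    stringsAsFactors = FALSE)
  nr_tune <- tune_two_band(rl, y)
  nrt_fit <- calibrate_linear(
    two_band_value(rl, red = nr_tune$selected["red"],
                   nir = nr_tune$selected["nir"]), y)
  rows[["NIR/red tuning"]] <- data.frame(
    model = "NIR/red tuning",
    bands = paste(nr_tune$selected[c("nir", "red")], collapse = "/"),
    r2 = nrt_fit$r2, rmse = nrt_fit$rmse, bias = nrt_fit$bias,
    stringsAsFactors = FALSE)
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  isepls <- list(RL = run_ise_pls(rl, y, max_nlv = config$max_nlv),
                 FDR = run_ise_pls(fdr, y, max_nlv = config$max_nlv))
  structure(list(table = table, isepls = isepls,
                 tuning = list(three_band = tb_tune, two_band = nr_tune),
                 descriptives = descriptive_table(chl),
                 recalibrated = recal, config = config,
                 data = list(spectra = spectra, chl = chl, rl = rl,
                             rrs = rrs, fdr = fdr)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (", nrow(x$data$chl), " samples )\n\n", sep = "")
  tab <- x$table
  tab$r2 <- round(tab$r2, 2); tab$rmse <- round(tab$rmse, 2)
  tab$bias <- signif(tab$bias, 2)
  print(tab, row.names = FALSE)
  cat("\nISE-PLS:\n")
  for (r in x$isepls) print(r)
  invisible(x)
}
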