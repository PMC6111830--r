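#' Fit a PLS1 regression model
#'
#' NIPALS partial least squares with a single response, on mean-centered
#' (not autoscaled) data: y = b1 x1 + ... + bp xp + e with the coefficient
#' vector constrained to the span of the first `nlv` latent variables.
#' Deterministic; at `nlv = rank(X centered)` the coefficients coincide with
#' ordinary least squares.
#'
#' @param X numeric matrix, samples x bands.
#' @param y response vector (chlorophyll-a, ug/L).
#' @param nlv number of latent variables, `1 <= nlv <= min(n - 1, p)`.
#' @param wavelengths optional band wavelengths (nm) stored with the model.
#' @return A `pls_model`: `nlv`, `beta` (length p, centered scale),
#'   `intercept`, `x_mean`, `y_mean`, `beta_path` (p x nlv matrix of
#'   coefficient vectors for 1..nlv components), `ncomp` actually extracted,
#'   `wavelengths`, `residuals`.
#' @export
pls_fit <- function(X, y, nlv, wavelengths = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("y length must match rows of X")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (nlv < 1 || nlv > min(n - 1, p))
    stop("nlv must be between 1 and min(n - 1, p) = ", min(n - 1, p))
  if (sd(y) == 0) stop("y has zero variance")
  fit <- .pls1_path(X, y, as.integer(nlv))
  beta <- fit$beta[, nlv]
  intercept <- fit$y_mean - sum(fit$x_mean * beta)
  res <- y - (drop(X %*% beta) + intercept)
  structure(list(nlv = as.integer(nlv), beta = beta,
                 intercept = intercept, x_mean = drop(fit$x_mean),
                 y_mean = fit$y_mean, beta_path = fit$beta,
                 ncomp = fit$ncomp, wavelengths = wavelengths,
                 residuals = res),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d band(s), nlv = %d>\n", length(x$beta), x$nlv))
  invisible(x)
}

#' Predict from a PLS model
#'
#' Centering contract: predictions are `y_mean + (X - x_mean) %*% beta`.
#'
#' @param m a [pls_fit()] model.
#' @param X matrix with the same columns the model was fitted on.
#' @return Predicted response vector.
#' @export
pls_predict <- function(m, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(m$beta))
    stop("X has ", ncol(X), " columns; model expects ", length(m$beta))
  drop(sweep(X, 2, m$x_mean) %*% m$beta) + m$y_mean
}

#' Leave-one-out cross-validation of PLS
#'
#' Each sample is predicted by a model (including its centering) fitted on
#' the remaining n - 1 samples. RMSE is sqrt(mean((y_obs - y_pred)^2)); R2
#' is the squared Pearson correlation between observed and held-out
#' predicted values.
#'
#' @param X samples x bands matrix.
#' @param y response vector.
#' @param nlv number of latent variables.
#' @return A `cv_result`: `y_obs`, `y_pred`, `n`, `rmse`, `r2`.
#' @export
loo_rmse <- function(X, y, nlv) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples for LOO")
  if (nlv < 1 || nlv > min(n - 2, ncol(X)))
    stop("nlv infeasible for n - 1 training samples")
  pred <- .pls1_loo(X, as.numeric(y), as.integer(nlv))[, nlv]
  cv_result(y, pred)
}

cv_result <- function(y_obs, y_pred) {
  structure(list(y_obs = as.numeric(y_obs), y_pred = as.numeric(y_pred),
                 n = length(y_obs),
                 rmse = sqrt(mean((y_obs - y_pred)^2)),
                 r2 = if (sd(y_obs) == 0 || sd(y_pred) == 0) NA_real_
                      else cor(y_obs, y_pred)^2),
            class = "cv_result")
}

#' Choose the number of latent variables by LOO RMSE
#'
#' Computes the LOO RMSE for 1..`max_nlv` components (one cross-validation
#' pass yields all candidate counts) and returns the arg min; ties break to
#' the smaller count.
#'
#' @param X samples x bands matrix.
#' @param y response vector.
#' @param max_nlv largest candidate count (default 10, capped to what the
#'   data support).
#' @return Integer nlv with attribute `rmse` (vector over candidates).
#' @export
select_nlv_by_rmse <- function(X, y, max_nlv = 10) {
  X <- as.matrix(X)
  k <- min(max_nlv, nrow(X) - 2, ncol(X))
  if (k < 1) stop("no feasible latent-variable count")
  pred <- .pls1_loo(X, as.numeric(y), as.integer(k))
  rmse <- sqrt(colMeans((pred - as.numeric(y))^2))
  # ties (to numerical tolerance) resolve to the smallest count
  best <- which(rmse <= min(rmse) * (1 + 1e-9) + 1e-12)[1]
  structure(as.integer(best), rmse = rmse)
}

#' Predictor importance of a PLS model
#'
#' z_i = |beta_i| s_i / sum(|beta| s), with s_i the per-band sample
#' standard deviation of the predictor. The z vector is non-negative and
#' sums to one; a constant band has zero importance.
#'
#' @param m a [pls_fit()] model.
#' @param X the matrix the model was fitted on.
#' @return List `z` (importances), `s` (band SDs), `I` (band count).
#' @export
importance <- function(m, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(m$beta)) stop("X columns do not match the model")
  s <- apply(X, 2, sd)
  w <- abs(m$beta) * s
  tot <- sum(w)
  if (tot == 0) stop("all importance weights are zero; normalization undefined")
  list(z = w / tot, s = s, I = length(w))
}

#' Iterative stepwise elimination of wavebands (ISE)
#'
#' Repeats: fit PLS on the retained bands (the latent-variable count is
#' re-selected each cycle by LOO RMSE, capped at `max_nlv`), record the
#' cross-validated RMSE, compute predictor importances, and drop the single
#' band with minimum importance — until `min_bands` remain. The returned
#' model is refitted on the band set of the cycle with the global minimum
#' cross-validated RMSE (ties resolve to the later cycle, i.e. fewer bands).
#'
#' @param X samples x bands matrix.
#' @param y response vector.
#' @param max_nlv cap on latent variables (default 10).
#' @param min_bands elimination floor (default 2; the jaggedness criterion
#'   needs at least two coefficients).
#' @param wavelengths optional band wavelengths for bookkeeping.
#' @return List with `model` (refitted `pls_model`), `trace` (an
#'   `elimination_trace` data.frame: cycle, n_bands, nlv, rmse), `best_cycle`,
#'   `band_mask` (logical over the input bands), `bands` (list of retained
#'   band indices per cycle).
#' @export
ise_eliminate <- function(X, y, max_nlv = 10, min_bands = 2,
                          wavelengths = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  p0 <- ncol(X)
  if (p0 < min_bands) stop("fewer bands than min_bands")
  if (is.null(wavelengths)) wavelengths <- seq_len(p0)
  retained <- seq_len(p0)
  n_cycles <- p0 - min_bands + 1
  rec_nbands <- integer(n_cycles); rec_nlv <- integer(n_cycles)
  rec_rmse <- numeric(n_cycles); rec_bands <- vector("list", n_cycles)
  for (cyc in seq_len(n_cycles)) {
    Xr <- X[, retained, drop = FALSE]
    nlv <- select_nlv_by_rmse(Xr, y, max_nlv)
    rec_nbands[cyc] <- length(retained)
    rec_nlv[cyc] <- nlv
    rec_rmse[cyc] <- attr(nlv, "rmse")[nlv]
    rec_bands[[cyc]] <- retained
    if (length(retained) == min_bands) break
    m <- pls_fit(Xr, y, nlv)
    z <- importance(m, Xr)$z
    drop_local <- which.min(z)  # ties: first = smallest wavelength
    retained <- retained[-drop_local]
  }
  best <- max(which(rec_rmse == min(rec_rmse)))  # ties -> fewer bands
  best_bands <- rec_bands[[best]]
  model <- pls_fit(X[, best_bands, drop = FALSE], y, rec_nlv[best],
                   wavelengths = wavelengths[best_bands])
  trace <- data.frame(cycle = seq_len(n_cycles), n_bands = rec_nbands,
                      nlv = rec_nlv, rmse = rec_rmse)
  class(trace) <- c("elimination_trace", "data.frame")
  mask <- rep(FALSE, p0); mask[best_bands] <- TRUE
  list(model = model, trace = trace, best_cycle = best,
       band_mask = mask, bands = rec_bands)
}

#' Jaggedness of a coefficient vector
#'
#' Sum of squared successive differences of the PLS regression coefficients
#' taken in wavelength order over the retained bands (gaps ignored). A
#' roughness penalty: smooth coefficient profiles have small J.
#'
#' @param beta coefficient vector ordered by wavelength, length >= 2.
#' @return Scalar J >= 0.
#' @export
jaggedness <- function(beta) {
  if (length(beta) < 2) stop("jaggedness needs at least 2 coefficients")
  sum(diff(beta)^2)
}

rescale01 <- function(v) {
  rng <- range(v)
  if (rng[2] - rng[1] == 0) return(rep(0, length(v)))  # degenerate: all equal
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Final latent-variable selection by rescaled RMSE plus jaggedness
#'
#' For each candidate count j in 1..`max_nlv`, the LOO RMSE and the
#' jaggedness J_j of the j-component coefficient vector are computed on the
#' selected bands; both are rescaled to [0, 1] over the candidate set
#' ((v - min)/(max - min)) and the j minimising their sum is chosen,
#' trading predictive error against over-fitted, oscillatory coefficients.
#' Ties break to the smaller count; a degenerate (constant) column rescales
#' to all zeros.
#'
#' @param X samples x selected-bands matrix.
#' @param y response vector.
#' @param max_nlv largest candidate (default 10, capped by the data).
#' @return An `nlv_selection`: data.frame `table` (nlv, rmse, J, rmse_r,
#'   J_r, score) and `chosen_nlv`.
#' @export
select_final_nlv <- function(X, y, max_nlv = 10) {
  X <- as.matrix(X)
  k <- min(max_nlv, nrow(X) - 2, ncol(X))
  if (k < 1) stop("no feasible latent-variable count")
  pred <- .pls1_loo(X, as.numeric(y), as.integer(k))
  rmse <- sqrt(colMeans((pred - as.numeric(y))^2))
  path <- .pls1_path(X, as.numeric(y), as.integer(k))$beta
  J <- apply(path, 2, jaggedness)
  rmse_r <- rescale01(rmse)
  J_r <- rescale01(J)
  score <- rmse_r + J_r
  chosen <- which.min(score)
  tab <- data.frame(nlv = seq_len(k), rmse = rmse, J = J,
                    rmse_r = rmse_r, J_r = J_r, score = score)
  structure(list(table = tab, chosen_nlv = as.integer(chosen)),
            class = "nlv_selection")
}

#' @export
print.nlv_selection <- function(x, ...) {
  cat(sprintf("<nlv_selection: chosen nlv = %d of %d candidates>\n",
              x$chosen_nlv, nrow(x$table)))
  invisible(x)
}

#' Full ISE-PLS retrieval pipeline
#'
#' Runs waveband elimination ([ise_eliminate()]) on the spectra, selects the
#' final latent-variable count on the retained bands by the rescaled
#' RMSE + jaggedness criterion ([select_final_nlv()]), refits, and reports
#' calibration (training fit) and validation (leave-one-out) statistics
#' plus the selected-band count and its percentage of the analysis grid.
#'
#' @param spectra a `spectrum_set` (kind `"RL"` or `"FDR"`) on the analysis
#'   grid.
#' @param chl chlorophyll vector or [chl_table()] aligned with `spectra`.
#' @param max_nlv cap on latent variables (default 10).
#' @param min_bands elimination floor (default 2).
#' @return An `ise_pls_result`: `model`, `trace`, `nlv_selection`,
#'   `calibration` (r2, rmse), `validation` (`cv_result` plus rpd),
#'   `selected_wavelengths`, `n_selected`, `percentage`, `kind`.
#' @export
run_ise_pls <- function(spectra, chl, max_nlv = 10, min_bands = 2) {
  y <- chl_values(chl)
  X <- spectra$values
  if (length(y) != nrow(X)) stop("chl length mismatch")
  elim <- ise_eliminate(X, y, max_nlv = max_nlv, min_bands = min_bands,
                        wavelengths = spectra$wavelengths)
  Xs <- X[, elim$band_mask, drop = FALSE]
  sel <- select_final_nlv(Xs, y, max_nlv)
  model <- pls_fit(Xs, y, sel$chosen_nlv,
                   wavelengths = spectra$wavelengths[elim$band_mask])
  fitted <- pls_predict(model, Xs)
  calib <- list(r2 = cor(y, fitted)^2, rmse = sqrt(mean((y - fitted)^2)))
  val <- loo_rmse(Xs, y, sel$chosen_nlv)
  val$rpd <- sd_population(y) / val$rmse
  n_sel <- sum(elim$band_mask)
  structure(list(model = model, trace = elim$trace, nlv_selection = sel,
                 calibration = calib, validation = val,
                 selected_wavelengths = spectra$wavelengths[elim$band_mask],
                 n_selected = n_sel,
                 percentage = selected_percentage(n_sel, ncol(X)),
                 n = length(y), kind = spectra$kind),
            class = "ise_pls_result")
}

#' @export
print.ise_pls_result <- function(x, ...) {
  cat(sprintf(
    "<ise_pls_result %s: N=%d NLV=%d | calib R2=%.2f RMSE=%.2f | valid R2=%.2f RMSE=%.2f RPD=%.2f | bands=%d (%.1f%%)>\n",
    x$kind, x$n, x$model$nlv, x$calibration$r2, x$calibration$rmse,
    x$validation$r2, x$validation$rmse, x$validation$rpd,
    x$n_selected, x$percentage))
  invisible(x)
}
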