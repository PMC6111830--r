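test_that("spectrum_set validates its grid and values", {
  expect_error(spectrum_set(c(500, 499), matrix(1, 2, 2)), "increasing")
  expect_error(spectrum_set(c(400, 401, 403), matrix(1, 2, 3)), "constant step")
  expect_error(spectrum_set(400:402, matrix(1, 2, 2)), "match")
  expect_error(spectrum_set(400:401, matrix(-1, 2, 2)), "non-negative")
  expect_silent(spectrum_set(400:401, matrix(-1, 2, 2), kind = "FDR"))
  expect_error(spectrum_set(400:401, matrix(1, 2, 2), sample_ids = c("a", "a")),
               "duplicate")
})

test_that("spectra/chl CSV round trip preserves data and alignment", {
  ds <- generate_dataset(synthetic_params(n_samples = 8, seed = 3))
  sp_path <- tempfile(fileext = ".csv")
  chl_path <- tempfile(fileext = ".csv")
  write_spectra(ds$spectra, sp_path)
  write_chl_table(ds$chl, chl_path)
  loaded <- load_spectra(sp_path, chl_path)
  expect_equal(loaded$spectra$wavelengths, ds$spectra$wavelengths)
  expect_equal(unname(loaded$spectra$values), unname(ds$spectra$values),
               tolerance = 1e-12)
  expect_equal(loaded$chl$chl, ds$chl$chl, tolerance = 1e-12)
  expect_equal(loaded$chl$station_id, ds$chl$station_id)

  # samples lacking a chl value are dropped with a report
  chl_short <- ds$chl[-c(1, 2), ]
  class(chl_short) <- c("chl_table", "data.frame")
  write_chl_table(chl_short, chl_path)
  expect_message(l2 <- load_spectra(sp_path, chl_path), "s001")
  expect_equal(nrow(l2$spectra$values), 6)

  # chl rows with no spectrum are a misalignment error naming offenders
  bad_chl <- chl_table(c(ds$chl$sample_id, "ghost"), c(ds$chl$chl, 1))
  write_chl_table(bad_chl, chl_path)
  expect_error(load_spectra(sp_path, chl_path), "ghost")

  writeLines("", sp_path)
  expect_error(load_spectra(sp_path, chl_path))
})

test_that("trimming to the analysis range keeps inclusive bounds", {
  ds <- generate_dataset(synthetic_params(n_samples = 3, seed = 1))
  tr <- trim_to_analysis_range(ds$spectra)
  expect_length(tr$wavelengths, 501)
  expect_equal(tr$wavelengths[1], 400)
  expect_equal(tr$wavelengths[501], 900)

  one <- trim_to_analysis_range(ds$spectra, 500, 500)
  expect_length(one$wavelengths, 1)
  expect_error(trim_to_analysis_range(ds$spectra, 300, 900), "outside grid")
})

test_that("Savitzky-Golay smoothing preserves polynomials and damps noise", {
  wl <- 400:500
  quad <- outer(c(1, 2), wl^2 * 1e-6) + outer(c(0.5, 0.2), wl * 1e-3) + 0.01
  s <- spectrum_set(wl, quad)
  sm <- savgol_smooth(s)
  expect_equal(sm$values, s$values, tolerance = 1e-8)

  const <- spectrum_set(wl, matrix(0.02, 3, length(wl)))
  expect_equal(savgol_smooth(const)$values, const$values, tolerance = 1e-10)

  set.seed(4)
  noisy <- spectrum_set(wl, matrix(abs(rnorm(2 * length(wl), 1, 0.1)), 2))
  smn <- savgol_smooth(noisy)
  expect_lt(var(smn$values[1, ]), var(noisy$values[1, ]))
  expect_lt(var(smn$values[2, ]), var(noisy$values[2, ]))

  expect_error(savgol_smooth(s, window = 14), "odd")
  expect_error(savgol_smooth(s, window = 5, polyorder = 5), "polyorder")
})

test_that("first derivative is exact for affine spectra and keeps the grid", {
  wl <- 400:900
  m <- 2e-5; cc <- 0.01
  s <- spectrum_set(wl, rbind(m * wl + cc, 3 * m * wl + cc))
  d <- first_derivative(s)
  expect_equal(d$kind, "FDR")
  expect_length(d$wavelengths, 501)
  expect_equal(unname(d$values[1, ]), rep(m, 501), tolerance = 1e-12)
  expect_equal(unname(d$values[2, ]), rep(3 * m, 501), tolerance = 1e-12)

  const <- spectrum_set(wl, matrix(0.05, 2, length(wl)))
  expect_true(all(first_derivative(const)$values == 0))
  expect_error(first_derivative(spectrum_set(500, matrix(1, 2, 1))), "2 bands")
})

test_that("Rrs conversion follows the chosen pi convention and cancels in ratios", {
  wl <- 600:700
  s <- spectrum_set(wl, matrix(pi, 2, length(wl)))
  expect_equal(unname(to_rrs(s)$values), matrix(1, 2, 101))
  expect_equal(unname(to_rrs(s, "multiply")$values), matrix(pi^2, 2, 101))

  zero <- spectrum_set(wl, matrix(0, 2, length(wl)))
  expect_true(all(to_rrs(zero)$values == 0))
  expect_error(to_rrs(first_derivative(s)), "RL")
})

test_that("preprocessing is per-sample: row permutation commutes", {
  ds <- generate_dataset(synthetic_params(n_samples = 6, seed = 9))
  s <- ds$spectra
  perm <- c(4, 1, 6, 2, 5, 3)
  s_perm <- spectrum_set(s$wavelengths, s$values[perm, ],
                         sample_ids = s$sample_ids[perm], kind = "RL")
  chain <- function(x) first_derivative(trim_to_analysis_range(savgol_smooth(x)))
  expect_equal(unname(chain(s_perm)$values), unname(chain(s)$values[perm, ]),
               tolerance = 1e-12)
})

test_that("smoothing and trimming commute away from the trim boundary", {
  ds <- generate_dataset(synthetic_params(n_samples = 3, seed = 5))
  a <- trim_to_analysis_range(savgol_smooth(ds$spectra))
  b <- savgol_smooth(trim_to_analysis_range(ds$spectra))
  inner <- a$wavelengths >= 400 + 7 & a$wavelengths <= 900 - 7
  expect_equal(a$values[, inner], b$values[, inner], tolerance = 1e-10)
})
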