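test_that("snip_baseline follows the clipping recurrence", {
  # constant vector: baseline equals the input, corrected signal is zero
  y <- rep(5, 31)
  b <- snip_baseline(y, 5, use_lls = FALSE)
  expect_equal(b, y)
  s <- subtract_baseline(corrected_spectrum(seq_along(y), y), b)
  expect_equal(s$intensity, rep(0, 31))

  # single-width delta spike on zero background: baseline 0 at the spike
  y2 <- rep(0, 21); y2[11] <- 100
  expect_equal(snip_baseline(y2, 3, use_lls = FALSE)[11], 0)

  # fixed 9-point example against the literal two-loop oracle
  y3 <- c(0, 0, 1, 4, 9, 4, 1, 0, 0)
  expect_equal(snip_baseline(y3, 2, use_lls = FALSE), snip_oracle(y3, 2))

  # random vectors, with and without the LLS transform
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(9:64, 1)
    y <- stats::runif(n, 0, 100)
    it <- sample.int((n - 1) %/% 2, 1)
    for (lls in c(FALSE, TRUE)) {
      b <- snip_baseline(y, it, use_lls = lls)
      expect_equal(b, snip_oracle(y, it, use_lls = lls), tolerance = 1e-12)
      expect_true(all(b >= 0 & b <= y + 1e-12))
    }
  }

  # short vectors reduce the window with a warning instead of failing
  expect_warning(snip_baseline(stats::runif(9), 10), "reduced")
})

test_that("baseline subtraction recovers a planted peak on an exponential background", {
  mz <- seq(800, 1200, by = 1)
  s <- spectrum_model(mz, data.frame(mz = 1000, height = 50, sigma = 3),
                      baseline_amplitude = 40, baseline_decay = 0.004)
  corrected <- subtract_baseline(s, snip_baseline(s$intensity, 20))
  area <- sum(corrected$intensity)
  planted_area <- 50 * 3 * sqrt(2 * pi)
  expect_lt(abs(area - planted_area) / planted_area, 0.1)

  expect_equal(subtract_baseline(s, 0)$intensity, s$intensity)
  expect_error(subtract_baseline(s, numeric(3)), "length")

  # near-idempotence: a second SNIP pass on the corrected signal finds
  # almost nothing left to remove
  b1 <- snip_baseline(s$intensity, 20)
  b2 <- snip_baseline(pmax(s$intensity - b1, 0), 20)
  expect_lt(max(b2), 0.05 * max(b1))
})

test_that("tic normalization equalizes TIC to the chosen target", {
  mk <- function(vals) corrected_spectrum(seq_along(vals) + 799, vals)
  two <- list(mk(c(2, 3, 5)), mk(c(10, 10, 10)))
  res <- tic_normalize(two, target = "unit")
  expect_equal(res$factors, c(1 / 10, 1 / 30))
  expect_equal(vapply(res$spectra, spectrum_tic, numeric(1)), c(1, 1))

  set.seed(5)
  many <- lapply(1:12, function(i) mk(stats::runif(20, 0, 10)))
  res2 <- tic_normalize(many, target = "dataset_median")
  tics <- vapply(res2$spectra, spectrum_tic, numeric(1))
  expect_equal(tics, rep(res2$target_tic, 12), tolerance = 1e-9)
  expect_lt(stats::var(tics), 1e-12)

  # a zero-TIC spectrum is excluded and reported, not silently kept
  with_zero <- c(many, list(mk(c(0, 0, 0))))
  expect_warning(res3 <- tic_normalize(with_zero), "zero TIC")
  expect_equal(res3$rejects, 13L)
  expect_length(res3$spectra, 12)

  # stage order is enforced: raw spectra cannot be normalized
  raw <- list(mass_spectrum(1:3 + 799, c(1, 2, 3)))
  expect_error(tic_normalize(raw), "baseline")
})

test_that("reference selection picks the TIC closest to the 50th quantile", {
  mk <- function(tic) corrected_spectrum(c(800, 801), c(tic / 2, tic / 2))
  expect_equal(select_reference(list(mk(1), mk(2), mk(3))), 2L)
  # quantile of {1, 4} is 2.5: both distances equal, tie to lowest index
  expect_equal(select_reference(list(mk(1), mk(4))), 1L)
  expect_error(select_reference(list()), "empty")

  set.seed(77)
  tics <- stats::runif(101, 1, 100)
  sp <- lapply(tics, mk)
  q <- stats::quantile(tics, 0.5, names = FALSE)
  expect_equal(select_reference(sp), which.min(abs(tics - q)))
})

test_that("linear mass-axis alignment recovers planted shifts", {
  mz <- seq(2400, 3500, by = 1)
  centers <- seq(2450, 3450, by = 100)
  pk <- data.frame(mz = centers, height = 60, sigma = 2)
  ref <- subtract_baseline(spectrum_model(mz, pk), 0)
  # noiseless fixture: the zero-noise warning is expected throughout
  suppressWarnings({
  ref_peaks <- detect_peaks(ref, snr_threshold = 5)$mz_centers
  params <- preprocess_params()

  # self-alignment is the identity
  self <- align_spectrum(ref, ref_peaks, params)
  expect_equal(self$warp$slope, 1, tolerance = 1e-6)
  expect_equal(self$warp$intercept, 0, tolerance = 1e-3)
  expect_equal(self$spectrum$intensity, ref$intensity, tolerance = 1e-6)

  # planted +1.5 Da shift: fitted intercept approximately -1.5
  shifted <- subtract_baseline(spectrum_model(mz, pk, mass_shift = 1.5), 0)
  al <- align_spectrum(shifted, ref_peaks, params)
  expect_equal(al$warp$kind, "linear")
  expect_lt(abs(al$warp$intercept - (-1.5)), 0.1)
  post <- detect_peaks(al$spectrum, snr_threshold = 5)$mz_centers
  dev <- vapply(post, function(m) min(abs(m - ref_peaks)), numeric(1))
  expect_lt(stats::median(dev), 0.1)

  # too few landmarks: identity warp, flagged rather than fatal
  one_peak <- subtract_baseline(
    spectrum_model(mz, pk[1, , drop = FALSE], mass_shift = 1), 0)
  al2 <- align_spectrum(one_peak, ref_peaks[1], params)
  })
  expect_equal(al2$warp$kind, "identity")
  expect_lte(al2$warp$n_landmarks, 1)
})

test_that("alignment property: residual landmark deviation is under 10% of planted shifts", {
  cfg <- synthetic_config(n_cases_per_class = 13, spots_per_compartment = 1,
                          mz_min = 2400, mz_max = 3500, n_peaks = 10,
                          peak_height_meanlog = log(80),
                          baseline_amplitude = 15, baseline_decay = 5e-4,
                          noise_sd = 0.3,
                          case_gain_sd = 0, case_peak_sd = 0,
                          mass_shift_max = 2, seed = 21L)
  sim <- generate_dataset(cfg)   # 26 cases x 2 compartments = 52 spectra
  pre <- preprocess_dataset(sim$dataset)
  # the true landmarks on the reference axis: the reference-spectrum peaks
  # nearest each planted centre
  planted <- sim$ground_truth$planted_peak_table$mz
  rp <- pre$report$reference_peaks
  landmarks <- vapply(planted, function(c) rp[which.min(abs(rp - c))],
                      numeric(1))
  landmark_dev <- function(spectra) {
    unlist(lapply(spectra, function(s) {
      pk <- detect_peaks(s, snr_threshold = 5, check_stage = FALSE)$mz_centers
      vapply(landmarks, function(m) min(abs(pk - m)), numeric(1))
    }))
  }
  corrected <- lapply(sim$dataset$spectra, function(s)
    subtract_baseline(s, snip_baseline(s$intensity)))
  pre_dev <- landmark_dev(corrected)
  post_dev <- landmark_dev(pre$dataset$spectra)
  expect_lt(stats::median(post_dev), 0.1 * stats::median(pre_dev))
  expect_lt(stats::median(post_dev), 0.1 * mean(abs(sim$ground_truth$mass_shift)))
})

test_that("the preprocessing chain runs in its fixed order and reports warps", {
  sim <- generate_dataset(tiny_config())
  pre <- preprocess_dataset(sim$dataset)
  expect_length(pre$report$warps, length(sim$dataset$spectra))
  st <- pre$dataset$spectra[[1]]$stages
  expect_equal(st, c("baseline", "normalize", "align"))
  # out-of-order invocation refuses to run
  expect_error(mean_spectrum(sim$dataset$spectra) |> detect_peaks(),
               "baseline")
})
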