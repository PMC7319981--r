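test_that("mean_spectrum is the pointwise average on a common grid", {
  mz <- seq(800, 820, by = 1)
  y <- stats::runif(length(mz), 0, 10)
  s1 <- corrected_spectrum(mz, y)
  expect_equal(mean_spectrum(list(s1))$intensity, y)
  s3 <- corrected_spectrum(mz, 3 * y)
  expect_equal(mean_spectrum(list(s1, s3))$intensity, 2 * y)

  set.seed(8)
  many <- lapply(1:100, function(i) corrected_spectrum(mz, stats::runif(21)))
  oracle <- Reduce(`+`, lapply(many, `[[`, "intensity")) / 100
  expect_equal(mean_spectrum(many)$intensity, oracle, tolerance = 1e-9)

  other <- corrected_spectrum(mz + 0.5, y)
  expect_error(mean_spectrum(list(s1, other)), "align")
})

test_that("noise estimation is the Gaussian-scaled MAD", {
  set.seed(99)
  x <- stats::rnorm(1e5)
  expect_lt(abs(estimate_noise(x) - 1), 0.05)
  expect_equal(estimate_noise(rep(3, 20)), 0)
  # 1% huge outliers barely move the estimate
  x_out <- c(stats::rnorm(9900), stats::rnorm(100, 0, 100))
  inlier_mad <- stats::mad(x_out[1:9900])
  expect_lt(abs(estimate_noise(x_out) - inlier_mad) / inlier_mad, 0.1)
  expect_error(estimate_noise(1:5), "at least 10")
})

test_that("peak detection retains SNR-filtered local maxima", {
  mz <- seq(800, 1500, by = 1)
  flat <- corrected_spectrum(mz, rep(1, length(mz)))
  expect_length(detect_peaks(flat)$mz_centers, 0)

  # zero noise estimate: local maxima retained with infinite SNR + warning
  y_const <- rep(5, 30); y_const[c(10, 20)] <- c(6, 7)
  expect_warning(
    pk_inf <- detect_peaks(corrected_spectrum(seq_along(y_const) + 799,
                                              y_const)),
    "zero noise")
  expect_equal(pk_inf$snr, c(Inf, Inf))

  # one planted Gaussian at 10x the noise level
  set.seed(14)
  s <- spectrum_model(mz, data.frame(mz = 1000.4, height = 10, sigma = 1),
                      baseline_amplitude = 20, noise_sd = 1)
  cor <- subtract_baseline(s, snip_baseline(s$intensity))
  pk <- detect_peaks(cor, snr_threshold = 3)
  strong <- pk$mz_centers[pk$heights > 5]
  expect_length(strong, 1)
  expect_lt(abs(strong - 1000.4), 1)

  # plateau: leftmost index wins, one peak only
  y <- rep(0, 30); y[10:12] <- 8; y[20] <- 8
  pkp <- detect_peaks(corrected_spectrum(seq_along(y) + 799, y), noise = 1)
  expect_equal(pkp$index[1], 10L)
  expect_length(pkp$mz_centers, 2)

  # monotonicity: raising the threshold never adds peaks
  set.seed(15)
  noisy <- corrected_spectrum(mz, pmax(stats::rnorm(length(mz), 2, 1), 0))
  counts <- vapply(c(1, 2, 3, 5, 8),
                   function(th) length(detect_peaks(noisy, th)$mz_centers),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted peaks at SNR >= 5 are recovered at threshold 3 with few false calls", {
  centers <- seq(830, 1470, by = 45)  # 15 peaks
  recovered <- 0; spurious <- 0; planted_n <- 0
  for (seed in 1:20) {
    set.seed(seed)
    heights <- stats::runif(length(centers), 6, 12)
    s <- spectrum_model(seq(800, 1500, by = 1),
                        data.frame(mz = centers, height = heights, sigma = 2),
                        baseline_amplitude = 20, noise_sd = 1)
    cor <- subtract_baseline(s, snip_baseline(s$intensity))
    pk <- detect_peaks(cor, snr_threshold = 3)
    hits <- vapply(centers, function(m) any(abs(pk$mz_centers - m) <= 2),
                   logical(1))
    recovered <- recovered + sum(hits)
    planted_n <- planted_n + length(centers)
    spurious <- spurious +
      sum(vapply(pk$mz_centers, function(m) min(abs(m - centers)) > 2,
                 logical(1)))
  }
  expect_gte(recovered / planted_n, 0.93)
  expect_lte(spurious / max(recovered + spurious, 1), 0.05)
})

test_that("peak matrix lookup reproduces planted heights", {
  mz <- seq(800, 1200, by = 1)
  centers <- c(850, 1000, 1150)
  pk_tab <- data.frame(mz = centers, height = c(20, 35, 50), sigma = 2)
  base <- subtract_baseline(spectrum_model(mz, pk_tab), 0)
  pl <- detect_peaks(base, noise = 1)

  # a spectrum identical to the mean spectrum returns the peak heights
  pm1 <- build_peak_matrix(list(base), pl)
  expect_equal(unname(pm1$values[1, ]), pl$heights)

  # the all-zero spectrum gives an all-zero row (and no dropped rows)
  zero <- corrected_spectrum(mz, rep(0, length(mz)))
  pm2 <- build_peak_matrix(list(base, zero), pl)
  expect_equal(nrow(pm2$values), 2)
  expect_equal(unname(pm2$values[2, ]), rep(0, 3))

  # 50 noiseless synthetic spectra: matrix matches planted heights
  set.seed(4)
  gains <- stats::runif(50, 0.5, 2)
  sp <- lapply(gains, function(g)
    subtract_baseline(spectrum_model(mz, pk_tab, case_gain = g), 0))
  pm3 <- build_peak_matrix(sp, pl)
  expected <- outer(gains, pk_tab$height)
  expect_equal(unname(pm3$values), expected, tolerance = 1e-6)

  # empty peak list: zero columns is valid
  empty <- structure(list(mz_centers = numeric(0), heights = numeric(0),
                          snr = numeric(0), noise_level = 1,
                          index = integer(0)), class = "peak_list")
  pm4 <- build_peak_matrix(list(base), empty)
  expect_equal(ncol(pm4$values), 0)

  # determinism
  expect_identical(build_peak_matrix(sp, pl)$values, pm3$values)
})
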