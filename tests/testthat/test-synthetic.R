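test_that("spectrum model evaluates the planted-peak forward model", {
  mz <- seq(800, 900, by = 1)
  # empty model: all-zero intensities
  s0 <- spectrum_model(mz, data.frame(mz = numeric(0), height = numeric(0),
                                      sigma = numeric(0)))
  expect_equal(s0$intensity, rep(0, length(mz)))

  # a single noiseless Gaussian peaks at its planted centre
  s1 <- spectrum_model(mz, data.frame(mz = 850.3, height = 10, sigma = 2))
  expect_lte(abs(s1$mz[which.max(s1$intensity)] - 850.3), 1)

  # doubling the gain doubles the TIC exactly (model is linear in gain)
  pk <- data.frame(mz = 850, height = 10, sigma = 2)
  t1 <- spectrum_tic(spectrum_model(mz, pk, case_gain = 1))
  t2 <- spectrum_tic(spectrum_model(mz, pk, case_gain = 2))
  expect_equal(t2 / t1, 2, tolerance = 1e-9)

  # direct-summation oracle for the same configuration
  win <- mz[abs(mz - 850) <= 16]
  oracle <- sum(2 * 10 * exp(-0.5 * ((win - 850) / 2)^2))
  expect_equal(spectrum_tic(spectrum_model(mz, pk, case_gain = 2)),
               oracle, tolerance = 1e-9)

  expect_error(spectrum_model(c(2, 1, 3), pk), "increasing")
  expect_error(spectrum_model(c(1, 2, 4), pk), "uniform")
})

test_that("generated cohorts have the annotated-spot structure and planted effects", {
  cfg <- tiny_config(spots_per_compartment = 20)
  sim <- generate_dataset(cfg)
  meta <- dataset_meta(sim$dataset)
  counts <- table(meta$case_id, meta$compartment)
  expect_true(all(counts[, "epithelial"] == 20))
  expect_true(all(counts[, "stromal"] == 20))
  expect_equal(nrow(meta), 6 * 40)

  # identical config + seed reproduces the dataset bit for bit
  sim2 <- generate_dataset(tiny_config(spots_per_compartment = 20))
  expect_identical(sim$dataset, sim2$dataset)
  expect_identical(sim$ground_truth, sim2$ground_truth)

  # planted effect: with noiseless heights the LGP/FA ratio of planted
  # intensities on the discriminating peak is exactly 2^1
  cfg_fx <- tiny_config(n_discriminating_peaks = 1, effect_log2fc = 1,
                        noise_sd = 0, case_gain_sd = 0, case_peak_sd = 0,
                        effect_compartments = "stromal")
  simfx <- generate_dataset(cfg_fx)
  gt <- simfx$ground_truth
  j <- which(gt$planted_peak_table$discriminating)
  m <- dataset_meta(simfx$dataset)
  stro <- m$compartment == "stromal"
  r <- mean(gt$planted_intensity[stro & m$class_label == "LGP", j]) /
    mean(gt$planted_intensity[stro & m$class_label == "FA", j])
  expect_equal(r, 2, tolerance = 1e-12)
  expect_equal(gt$planted_peak_table$mz[j], gt$discriminating_peak_mzs)

  # null cohort: every peak's standardized planted class difference is
  # within the sampling bound 4/sqrt(n); planted heights are shared by
  # all spots of a case, so the bound applies at case level
  cfg0 <- tiny_config(n_cases_per_class = 10, n_discriminating_peaks = 0,
                      case_peak_sd = 0.1)
  sim0 <- generate_dataset(cfg0)
  g0 <- sim0$ground_truth
  m0 <- dataset_meta(sim0$dataset)
  first_spot <- !duplicated(m0$case_id)
  is_lgp <- m0$class_label[first_spot] == "LGP"
  n <- sum(is_lgp)
  for (j in seq_len(cfg0$n_peaks)) {
    case_vals <- g0$planted_intensity[first_spot, j]
    a <- case_vals[!is_lgp]
    b <- case_vals[is_lgp]
    pooled_sd <- sqrt((stats::var(a) + stats::var(b)) / 2)
    expect_lt(abs(mean(b) - mean(a)) / pooled_sd, 4 / sqrt(n))
  }
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(tiny_config(n_discriminating_peaks = 11), "n_discriminating")
  expect_error(tiny_config(mz_min = 2000, mz_max = 1000), "mz_min")
  expect_error(tiny_config(noise_sd = -1), "noise_sd")
})

test_that("synthetic clinical tables reproduce the printed cohort summaries", {
  t1 <- generate_clinical_table(31, 30, seed = 9)
  t2 <- generate_clinical_table(31, 30, seed = 9)
  expect_identical(t1, t2)

  big <- generate_clinical_table(1000, 1000, seed = 10)
  lgp <- big[big$group == "LGP", ]
  fa <- big[big$group == "FA", ]
  se <- stats::sd(lgp$age) / sqrt(nrow(lgp))
  expect_lt(abs(mean(lgp$age) - 35.5), 3 * se)
  expect_true(all(fa$tumor_size >= 1.2 & fa$tumor_size <= 5.1))
  expect_true(all(lgp$age >= 14 & lgp$age <= 63))
  expect_true(all(big$time_to_event <= big$followup_months))
  expect_true(all(!fa$recurrence))
})

test_that("synthetic IHC tables match the printed marker means and the reader-average rule", {
  ihc <- generate_ihc_table(n_fa = 1000, n_lgp = 1000, n_hgp = 1000,
                            seed = 12)
  expect_equal(ihc$mean_pct, (ihc$reader1_pct + ihc$reader2_pct) / 2)
  ki <- ihc[ihc$marker == "Ki67", ]
  targets <- c(FA = 2.5, LGP = 7.7, HGP = 45.0)
  for (g in names(targets)) {
    v <- ki$mean_pct[ki$group == g]
    expect_lt(abs(mean(v) - targets[[g]]), 3 * stats::sd(v) / sqrt(length(v)))
  }
  expect_true(all(ihc$mean_pct[ihc$marker == "E_cadherin"] == 0))
})
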