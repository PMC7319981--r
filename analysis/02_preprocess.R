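# Step 2: spectral preprocessing in the fixed order the workflow demands:
# SNIP baseline removal (20 iterations) -> TIC normalization to the dataset
# median -> selection of the reference spectrum (TIC closest to the 50th
# quantile) -> linear mass-axis re-alignment to its landmark peaks.

source("analysis/00_common.R")

pre <- preprocessed()
rep <- pre$report

tics <- vapply(pre$dataset$spectra, spectrum_tic, numeric(1))
cat(sprintf("preprocessed %d spectra; %d rejected for zero TIC\n",
            length(pre$dataset$spectra), length(rep$rejects)))
cat(sprintf("TIC after normalization: %.6g (between-spectrum sd %.2g)\n",
            mean(tics), sd(tics)))
cat(sprintf("reference spectrum index: %d (%d landmark peaks)\n",
            rep$reference_index, length(rep$reference_peaks)))
slopes <- vapply(rep$warps, `[[`, numeric(1), "slope")
ints <- vapply(rep$warps, `[[`, numeric(1), "intercept")
cat(sprintf("warp models: %d linear, %d identity fallback\n",
            sum(vapply(rep$warps, `[[`, character(1), "kind") == "linear"),
            rep$n_identity))
cat(sprintf("fitted shifts (intercepts): median %.2f Da, range %.2f to %.2f\n",
            median(ints), min(ints), max(ints)))

summary <- list(
  n_spectra = length(pre$dataset$spectra),
  rejected = length(rep$rejects),
  reference_index = rep$reference_index,
  n_reference_peaks = length(rep$reference_peaks),
  n_identity_warps = rep$n_identity,
  warp_slope_range = range(slopes),
  warp_intercept_range = range(ints),
  tic_target = rep$tic_target)
jsonlite::write_json(summary, file.path(RESULTS, "preprocess_report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote preprocess_report.json\n")
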