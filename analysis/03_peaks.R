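# Step 3: peak picking on the overall mean spectrum (all spectra pooled, as
# the workflow specifies) at signal-to-noise ratio above 3, then the
# spectra x peaks intensity matrix by windowed lookup.

source("analysis/00_common.R")

pk <- peaks_built()
cat(sprintf("mean spectrum over %d points; noise level %.4g\n",
            length(pk$mean_spec$mz), pk$peaklist$noise_level))
cat(sprintf("picked %d peaks at SNR > 3 (SNR range %.1f-%.1f)\n",
            length(pk$peaklist$mz_centers), min(pk$peaklist$snr),
            max(pk$peaklist$snr)))
cat(sprintf("peak matrix: %d spectra x %d peaks\n",
            nrow(pk$pm$values), length(pk$pm$mz)))

write.csv(data.frame(mz = pk$peaklist$mz_centers,
                     height = pk$peaklist$heights, snr = pk$peaklist$snr),
          file.path(RESULTS, "peaklist.csv"), row.names = FALSE)
write_peak_matrix(pk$pm, file.path(RESULTS, "peak_matrix.csv"))
cat("wrote peaklist.csv, peak_matrix.csv\n")
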