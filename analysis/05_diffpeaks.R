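# Step 5: differential-peak statistics on the study set: per-peak AUROC,
# volcano data (log2 fold change, Welch t, BH adjustment) and the mirrored
# butterfly comparison of class mean spectra, per compartment.

source("analysis/00_common.R")

pm <- peaks_built()$pm
ds <- preprocessed()$dataset
meta <- dataset_meta(ds)

for (comp in c("epithelial", "stromal")) {
  study <- meta$compartment == comp & meta$partition == "study"
  v <- volcano_stats(subset_peak_matrix(pm, study))
  cat(sprintf("[%s] %d peaks; %d beyond |log2FC| > 1 and p < 0.05; min BH-adjusted p %.3g\n",
              comp, nrow(v), attr(v, "n_significant"), min(v$p_adjusted)))
  cat(sprintf("    AUROC range %.2f-%.2f (0.5 = no separation)\n",
              min(v$auroc), max(v$auroc)))
  # spot-level spectra are pseudo-replicates (spots within a case are
  # correlated), which makes spot-level p-values wildly anticonservative;
  # the case-mean unit is the calibrated analysis
  vc <- volcano_stats(subset_peak_matrix(pm, study), unit = "case")
  cat(sprintf("    case-level t-tests: %d of %d raw p < 0.05 (spot-level: %d)\n",
              sum(vc$p_value < 0.05), nrow(vc), sum(v$p_value < 0.05)))
  write.csv(v, file.path(RESULTS, sprintf("volcano_%s.csv", comp)),
            row.names = FALSE)
  write.csv(vc, file.path(RESULTS, sprintf("volcano_%s_caselevel.csv", comp)),
            row.names = FALSE)

  bf <- butterfly_means(ds$spectra[meta$compartment == comp])
  write.csv(data.frame(mz = bf$mz, mean_fa = bf$mean_a,
                       mean_lgp_flipped = bf$mean_b_flipped,
                       abs_difference = bf$difference),
            file.path(RESULTS, sprintf("butterfly_%s.csv", comp)),
            row.names = FALSE)
  cat(sprintf("    butterfly max |difference| / max mean = %.3f\n",
              max(bf$difference) / max(bf$mean_a)))
}
cat("wrote volcano_*.csv, butterfly_*.csv\n")
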