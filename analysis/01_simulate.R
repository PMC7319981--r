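# Step 1: draw the synthetic cohort that stands in for the profiling study.
# Two classes with identical peak panels (no planted difference), 30 FA and
# 31 LGP cases, 20 epithelial + 20 stromal spot spectra per case, plus the
# matching clinical and two-reader IHC tables.

source("analysis/00_common.R")

sim <- simulated()
meta <- dataset_meta(sim$dataset)

cat(sprintf("cohort: %d spectra from %d cases (%d FA, %d LGP)\n",
            nrow(meta), length(unique(meta$case_id)),
            sum(sim$ground_truth$true_class_by_case == "FA"),
            sum(sim$ground_truth$true_class_by_case == "LGP")))
cat(sprintf("spots per case: %s epithelial / %s stromal\n",
            unique(table(meta$case_id, meta$compartment)[, "epithelial"]),
            unique(table(meta$case_id, meta$compartment)[, "stromal"])))
cat(sprintf("planted discriminating peaks: %d (null cohort)\n",
            length(sim$ground_truth$discriminating_peak_mzs)))

write_ground_truth(sim$ground_truth, file.path(RESULTS, "ground_truth.json"))

clinical <- generate_clinical_table(
  n_lgp = 31, n_fa = 30, seed = derive_seed(GLOBAL_SEED, "clinical"))
ihc <- generate_ihc_table(n_fa = 30, n_lgp = 31, n_hgp = 10,
                          seed = derive_seed(GLOBAL_SEED, "ihc"))
write.csv(clinical, file.path(RESULTS, "clinical.csv"), row.names = FALSE)
write.csv(ihc, file.path(RESULTS, "ihc.csv"), row.names = FALSE)

cat(sprintf("clinical: LGP age mean %.1f y, FA %.1f y; recurrences %d LGP / %d FA\n",
            mean(clinical$age[clinical$group == "LGP"]),
            mean(clinical$age[clinical$group == "FA"]),
            sum(clinical$recurrence[clinical$group == "LGP"]),
            sum(clinical$recurrence[clinical$group == "FA"])))
cat("wrote ground_truth.json, clinical.csv, ihc.csv\n")
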