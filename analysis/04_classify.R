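# Step 4: linear-SVM classification. Cost tuned by 5-fold case-grouped
# cross-validation on the study set (21 LGP + 20 FA cases), evaluated on
# the held-out validation cases (10 + 10) with case-level majority calls;
# epithelial and stromal compartments are modeled separately.

source("analysis/00_common.R")

cfg <- study_config()
pm <- peaks_built()$pm
ds <- preprocessed()$dataset
meta <- dataset_meta(ds)
truth <- simulated()$ground_truth$true_class_by_case

out <- list()
for (comp in c("epithelial", "stromal")) {
  study <- meta$compartment == comp & meta$partition == "study"
  valid <- meta$compartment == comp & meta$partition == "validation"
  fit <- tune_and_train(subset_peak_matrix(pm, study), cfg$svm)
  calls <- aggregate_cases(predict_spots(fit, subset_peak_matrix(pm, valid)),
                           truth)
  ev <- evaluate_cases(calls)
  cat(sprintf("[%s] tuned cost %.2g; validation accuracy %.0f%% (%d/%d)\n",
              comp, fit$tuned_cost, 100 * ev$overall_accuracy,
              sum(ev$per_class$correct), ev$n_cases))
  for (k in seq_len(nrow(ev$per_class)))
    cat(sprintf("    %s: %d of %d correct\n", ev$per_class$class[k],
                ev$per_class$correct[k], ev$per_class$total[k]))
  cat(sprintf("    fully consistent cases: %d of %d (%.0f%%); consistency range %.2f-%.2f\n",
              ev$n_fully_consistent, ev$n_cases,
              100 * ev$n_fully_consistent / ev$n_cases,
              min(calls$consistency), max(calls$consistency)))
  out[[comp]] <- list(tuned_cost = fit$tuned_cost,
                      cv_accuracy_by_cost = fit$cv_accuracy_by_cost,
                      evaluation = ev, case_calls = calls)
}

jsonlite::write_json(out, file.path(RESULTS, "classification.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     force = TRUE)
cat("wrote classification.json\n")
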