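#' Derive a per-stage seed from the global run seed
#'
#' Stable fan-out so a stage can be rerun in isolation and still match the
#' full run. Kept below 2^31 - 1.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return An integer seed specific to `(seed, stage)`.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Full run configuration
#'
#' Bundles every stage's parameters with a single global seed. Unknown
#' keys are rejected so a typo cannot silently fall back to a default.
#'
#' @param synthetic a [synthetic_config()].
#' @param preprocess a [preprocess_params()].
#' @param snr_threshold peak-picking SNR threshold (default 3).
#' @param window_ppm peak-matrix integration half-window (default 2000).
#' @param peaks_from `"all"` picks peaks on the mean spectrum of all
#'   spectra, study and validation pooled, exactly as the profiling
#'   workflow does (this leaks the peak panel, not the labels, into
#'   validation and is kept for fidelity); `"study_only"` restricts
#'   picking to the study set.
#' @param svm an [svm_config()].
#' @param n_study_per_class study-set sizes, named `c(LGP=, FA=)`
#'   (default `c(LGP = 21, FA = 20)`, the study design).
#' @param fc_line,p_line volcano guide thresholds (defaults 1 and 0.05).
#' @param seed global seed fanned out to the stages via [derive_seed()].
#' @param ... must be empty; unknown keys are an error.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       preprocess = preprocess_params(),
                       snr_threshold = 3, window_ppm = 2000,
                       peaks_from = c("all", "study_only"),
                       svm = svm_config(),
                       n_study_per_class = c(LGP = 21, FA = 20),
                       fc_line = 1, p_line = 0.05, seed = 1L, ...) {
  dots <- list(...)
  if (length(dots))
    stop("unknown configuration key(s): ",
         paste(names(dots), collapse = ", "), call. = FALSE)
  stopifnot(inherits(synthetic, "synthetic_config"),
            inherits(preprocess, "preprocess_params"),
            inherits(svm, "svm_config"))
  seed <- as.integer(seed)
  synthetic$seed <- derive_seed(seed, "simulate")
  svm$seed <- derive_seed(seed, "classify")
  structure(list(synthetic = synthetic, preprocess = preprocess,
                 snr_threshold = snr_threshold, window_ppm = window_ppm,
                 peaks_from = match.arg(peaks_from), svm = svm,
                 n_study_per_class = n_study_per_class,
                 fc_line = fc_line, p_line = p_line, seed = seed),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' The YAML mirrors the [run_config()] arguments, with `synthetic`,
#' `preprocess` and `svm` as nested maps. Unknown keys at any level are
#' rejected.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(vals, fun) {
    if (is.null(vals)) return(fun())
    bad <- setdiff(names(vals), names(formals(fun)))
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    do.call(fun, vals)
  }
  args <- raw
  args$synthetic <- build(raw$synthetic, synthetic_config)
  args$preprocess <- build(raw$preprocess, preprocess_params)
  args$svm <- build(raw$svm, svm_config)
  do.call(run_config, args)
}

#' Run the full profiling analysis end to end
#'
#' Executes the fixed stage order: simulate -> preprocess (baseline,
#' normalize, align) -> peak picking on the overall mean spectrum ->
#' study/validation split -> per-compartment linear-SVM training,
#' validation prediction and case-level aggregation -> per-compartment
#' volcano statistics on the study set -> synthetic clinical and IHC
#' tables with their comparison statistics. When `out_dir` is given the
#' peak matrix, reports and a reproducibility manifest (config hash,
#' derived seeds, record counts per stage) are written there.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list with elements `dataset`, `ground_truth`, `preprocess_report`,
#'   `peaklist`, `peak_matrix`, `models`, `case_calls`, `evaluation`,
#'   `volcano`, `clinical`, `ihc`, `clin_summary`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  sim <- generate_dataset(config$synthetic)
  pre <- preprocess_dataset(sim$dataset, config$preprocess)
  ds <- split_dataset(pre$dataset, config$n_study_per_class,
                      seed = derive_seed(config$seed, "split"))
  meta <- dataset_meta(ds)

  pick_idx <- if (config$peaks_from == "all") seq_len(nrow(meta))
              else which(meta$partition == "study")
  mspec <- mean_spectrum(ds$spectra[pick_idx])
  # averaging zero-truncated spectra re-acquires a small pedestal;
  # baseline-correct the mean spectrum before picking
  mspec <- subtract_baseline(
    mspec, snip_baseline(mspec$intensity, config$preprocess$snip_iterations,
                         config$preprocess$use_lls_transform))
  peaklist <- detect_peaks(mspec, snr_threshold = config$snr_threshold)
  pm <- build_peak_matrix(ds$spectra, peaklist,
                          window_ppm = config$window_ppm)

  truth <- sim$ground_truth$true_class_by_case
  models <- list(); case_calls <- list(); evaluation <- list()
  volcano <- list()
  for (comp in c("epithelial", "stromal")) {
    is_comp <- meta$compartment == comp
    study <- is_comp & meta$partition == "study"
    valid <- is_comp & meta$partition == "validation"
    fit <- tune_and_train(subset_peak_matrix(pm, study), config$svm)
    models[[comp]] <- fit
    if (any(valid)) {
      preds <- predict_spots(fit, subset_peak_matrix(pm, valid))
      calls <- aggregate_cases(preds, truth)
      case_calls[[comp]] <- calls
      evaluation[[comp]] <- evaluate_cases(calls)
    }
    volcano[[comp]] <- volcano_stats(subset_peak_matrix(pm, study),
                                     fc_line = config$fc_line,
                                     p_line = config$p_line)
  }

  n_lgp <- sum(sim$ground_truth$true_class_by_case == "LGP")
  n_fa <- sum(sim$ground_truth$true_class_by_case == "FA")
  clinical <- generate_clinical_table(n_lgp, n_fa,
                                      seed = derive_seed(config$seed,
                                                         "clinical"))
  ihc <- generate_ihc_table(n_fa = n_fa, n_lgp = n_lgp, n_hgp = 10,
                            seed = derive_seed(config$seed, "ihc"))
  clin_summary <- summarize_groups(clinical, ihc)

  manifest <- list(
    config_hash = hash_config(config),
    seed = config$seed,
    stage_seeds = list(simulate = config$synthetic$seed,
                       split = derive_seed(config$seed, "split"),
                       classify = config$svm$seed,
                       clinical = derive_seed(config$seed, "clinical"),
                       ihc = derive_seed(config$seed, "ihc")),
    counts = list(spectra = length(ds$spectra),
                  cases = length(truth),
                  peaks = length(peaklist$mz_centers),
                  matrix_rows = nrow(pm$values),
                  rejected_spectra = length(pre$report$rejects),
                  identity_warps = pre$report$n_identity),
    tuned_cost = lapply(models, `[[`, "tuned_cost"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  res <- list(dataset = ds, ground_truth = sim$ground_truth,
              preprocess_report = pre$report, peaklist = peaklist,
              peak_matrix = pm, models = models, case_calls = case_calls,
              evaluation = evaluation, volcano = volcano,
              clinical = clinical, ihc = ihc, clin_summary = clin_summary,
              manifest = manifest)
  if (!is.null(out_dir)) write_run_outputs(res, config, out_dir)
  res
}

# stable hash of the configuration (md5 of its canonical JSON)
hash_config <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass_deep(config), f, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(f))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

write_run_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_peak_matrix(res$peak_matrix, file.path(out_dir, "peak_matrix.csv"))
  for (comp in names(res$volcano))
    utils::write.csv(res$volcano[[comp]],
                     file.path(out_dir, sprintf("volcano_%s.csv", comp)),
                     row.names = FALSE)
  utils::write.csv(res$clinical, file.path(out_dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(res$ihc, file.path(out_dir, "ihc.csv"), row.names = FALSE)
  classif <- list(
    tuned_cost = lapply(res$models, `[[`, "tuned_cost"),
    cv_accuracy = lapply(res$models, `[[`, "cv_accuracy_by_cost"),
    evaluation = res$evaluation,
    case_calls = res$case_calls)
  jsonlite::write_json(classif, file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  write_ground_truth(res$ground_truth,
                     file.path(out_dir, "ground_truth.json"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
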