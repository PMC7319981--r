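# Shared setup for the analysis scripts: study-scale configuration and a
# small cache so later steps do not recompute the earlier ones.
# Run the scripts in order from the repository root:
#   Rscript analysis/01_simulate.R && Rscript analysis/02_preprocess.R && ...

suppressMessages(library(maldiprofiler))

RESULTS <- "results/analysis"
CACHE <- "scratch/analysis_cache"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
dir.create(CACHE, recursive = TRUE, showWarnings = FALSE)

GLOBAL_SEED <- 20200626L

# study-scale conditions: 30 FA + 31 LGP cases, 20 epithelial + 20 stromal
# annotated spots per case, tryptic-peptide m/z range; no planted class
# difference (the null that the study observed)
study_config <- function() run_config(
  synthetic = synthetic_config(),       # defaults are the study conditions
  n_study_per_class = c(LGP = 21, FA = 20),
  seed = GLOBAL_SEED)

cache_file <- function(name) file.path(CACHE, paste0(name, ".rds"))

with_cache <- function(name, expr) {
  f <- cache_file(name)
  if (file.exists(f)) return(readRDS(f))
  val <- expr
  saveRDS(val, f)
  val
}

simulated <- function() with_cache("simulated", {
  cfg <- study_config()
  generate_dataset(cfg$synthetic)
})

preprocessed <- function() with_cache("preprocessed", {
  cfg <- study_config()
  pre <- preprocess_dataset(simulated()$dataset, cfg$preprocess)
  pre$dataset <- split_dataset(pre$dataset, cfg$n_study_per_class,
                               seed = derive_seed(cfg$seed, "split"))
  pre
})

peaks_built <- function() with_cache("peaks", {
  cfg <- study_config()
  ds <- preprocessed()$dataset
  mspec <- mean_spectrum(ds$spectra)
  mspec <- subtract_baseline(
    mspec, snip_baseline(mspec$intensity, cfg$preprocess$snip_iterations))
  peaklist <- detect_peaks(mspec, snr_threshold = cfg$snr_threshold)
  pm <- build_peak_matrix(ds$spectra, peaklist,
                          window_ppm = cfg$window_ppm)
  list(mean_spec = mspec, peaklist = peaklist, pm = pm)
})
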