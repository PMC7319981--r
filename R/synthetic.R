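#' Configuration of the synthetic profiling-cohort generator
#'
#' The generator emulates the study design the pipeline assumes: two tumor
#' classes (FA = fibroadenoma, LGP = low-grade phyllodes tumor), ~30 cases
#' per class, each case annotated with 20 epithelial and 20 stromal spots,
#' one spectrum per spot. Spectra are sums of Gaussian peptide peaks on an
#' exponentially decaying chemical-noise baseline, with per-case
#' multiplicative gain (log-normal; exercises TIC normalization), a per-case
#' peak-height perturbation (tumor heterogeneity), a per-spectrum linear
#' mass shift (exercises re-alignment) and additive truncated-Gaussian
#' noise. The two classes share the same peak panel; only
#' `n_discriminating_peaks` of them differ, by `2^effect_log2fc`, in LGP
#' spectra of the compartments listed in `effect_compartments` (default
#' stromal, the compartment where the biology differs if anywhere). With
#' `n_discriminating_peaks = 0` the cohort is an exact null: the two
#' classes are draws from one distribution.
#'
#' @param n_cases_per_class cases per class: a single integer for a
#'   balanced cohort or a named pair `c(FA = , LGP = )` (default
#'   `c(FA = 30, LGP = 31)`, the emulated cohort sizes).
#' @param spots_per_compartment annotated spots per compartment per case
#'   (default 20, the annotation protocol's mark count).
#' @param mz_min,mz_max acquisition range, Da (default 800-3500, the
#'   tryptic-peptide MALDI range).
#' @param mz_step m/z grid spacing, Da (default 1).
#' @param n_peaks number of planted peaks (default 60).
#' @param n_discriminating_peaks peaks carrying a class effect (default 0).
#' @param effect_log2fc log2 fold change applied to discriminating peaks in
#'   class LGP (default 0).
#' @param effect_compartments compartments the effect applies to
#'   (default `"stromal"`).
#' @param peak_width_sigma Gaussian peak sigma, Da (default 2).
#' @param peak_height_meanlog,peak_height_sdlog log-normal parameters of
#'   the per-peak base heights (defaults log(50), 0.5).
#' @param baseline_amplitude,baseline_decay exponential baseline
#'   `A * exp(-d * (mz - mz_min))` (defaults 20 and 0.002).
#' @param noise_sd additive Gaussian noise sd (default 0.5).
#' @param case_gain_sd sd of the per-case log-normal gain (default 0.4).
#' @param case_peak_sd sd of the per-case log-normal peak-height
#'   perturbation (default 0.1; tumor heterogeneity).
#' @param mass_shift_max per-spectrum mass shift drawn uniform in
#'   `[-mass_shift_max, mass_shift_max]` Da (default 1).
#' @param seed integer RNG seed; identical config + seed gives a
#'   bit-identical dataset.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_cases_per_class = c(FA = 30, LGP = 31),
                             spots_per_compartment = 20,
                             mz_min = 800, mz_max = 3500, mz_step = 1,
                             n_peaks = 60, n_discriminating_peaks = 0,
                             effect_log2fc = 0,
                             effect_compartments = "stromal",
                             peak_width_sigma = 2,
                             peak_height_meanlog = log(50),
                             peak_height_sdlog = 0.5,
                             baseline_amplitude = 20, baseline_decay = 0.002,
                             noise_sd = 0.5, case_gain_sd = 0.4,
                             case_peak_sd = 0.1,
                             mass_shift_max = 1, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_discriminating_peaks < 0 || cfg$n_discriminating_peaks > cfg$n_peaks)
    stop("need 0 <= n_discriminating_peaks <= n_peaks", call. = FALSE)
  if (cfg$mz_min >= cfg$mz_max) stop("need mz_min < mz_max", call. = FALSE)
  for (f in c("peak_width_sigma", "baseline_amplitude", "baseline_decay",
              "noise_sd", "case_gain_sd", "case_peak_sd", "mass_shift_max"))
    if (cfg[[f]] < 0) stop(sprintf("%s must be >= 0", f), call. = FALSE)
  ncc <- cfg$n_cases_per_class
  if (length(ncc) == 1L) ncc <- c(FA = unname(ncc), LGP = unname(ncc))
  if (is.null(names(ncc)) || !setequal(names(ncc), c("FA", "LGP")))
    names(ncc) <- c("FA", "LGP")
  cfg$n_cases_per_class <- ncc
  if (any(ncc < 1) || cfg$spots_per_compartment < 1)
    stop("need at least one case and one spot per compartment", call. = FALSE)
  stopifnot(all(effect_compartments %in% c("epithelial", "stromal")))
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synthetic_config")
}

#' Evaluate the synthetic spectrum model
#'
#' Deterministic forward model of one spot spectrum:
#' `intensity = case_gain * (sum of Gaussians(center + mass_shift, sigma,
#' height) + baseline_amplitude * exp(-baseline_decay * (mz - min(mz)))) +
#' noise`, truncated at zero. Noise is drawn from the current RNG stream,
#' so callers control reproducibility with `set.seed()`.
#'
#' @param mz_axis strictly increasing, uniformly spaced m/z grid (Da).
#' @param planted_peaks data.frame with columns `mz`, `height`, `sigma`.
#' @param baseline_amplitude,baseline_decay exponential baseline parameters.
#' @param case_gain multiplicative gain.
#' @param mass_shift linear shift added to every peak centre, Da.
#' @param noise_sd additive Gaussian noise sd (0 = noiseless).
#' @param ... provenance fields passed to [mass_spectrum()].
#' @return A `mass_spectrum`.
#' @export
spectrum_model <- function(mz_axis, planted_peaks,
                           baseline_amplitude = 0, baseline_decay = 0,
                           case_gain = 1, mass_shift = 0, noise_sd = 0, ...) {
  mz_axis <- as.numeric(mz_axis)
  d <- diff(mz_axis)
  if (any(d <= 0)) stop("invalid axis: mz_axis must be strictly increasing",
                        call. = FALSE)
  if (diff(range(d)) > 1e-8 * mean(d))
    stop("invalid axis: mz_axis must be uniformly spaced", call. = FALSE)
  y <- rep(0, length(mz_axis))
  if (!is.null(planted_peaks) && nrow(planted_peaks) > 0) {
    for (k in seq_len(nrow(planted_peaks))) {
      ctr <- planted_peaks$mz[k] + mass_shift
      sg <- planted_peaks$sigma[k]
      # evaluate only within +/- 8 sigma of the centre
      win <- which(mz_axis >= ctr - 8 * sg & mz_axis <= ctr + 8 * sg)
      if (length(win))
        y[win] <- y[win] +
          planted_peaks$height[k] * exp(-0.5 * ((mz_axis[win] - ctr) / sg)^2)
    }
  }
  y <- y + baseline_amplitude * exp(-baseline_decay * (mz_axis - mz_axis[1]))
  y <- case_gain * y
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  mass_spectrum(mz_axis, pmax(y, 0), ...)
}

# internal: plant peak centres with a minimum separation so peaks resolve
plant_peak_centers <- function(cfg) {
  sep <- max(6 * cfg$peak_width_sigma, 8 * cfg$mz_step)
  lo <- cfg$mz_min + 5 * cfg$peak_width_sigma + cfg$mass_shift_max + 2
  hi <- cfg$mz_max - 5 * cfg$peak_width_sigma - cfg$mass_shift_max - 2
  slots <- seq(lo, hi, by = sep)
  if (length(slots) < cfg$n_peaks)
    stop(sprintf("m/z range supports at most %d resolvable peaks, %d requested",
                 length(slots), cfg$n_peaks), call. = FALSE)
  ctr <- sort(sample(slots, cfg$n_peaks)) +
    stats::runif(cfg$n_peaks, -sep / 4, sep / 4)
  ctr
}

#' Generate a synthetic two-class profiling cohort
#'
#' Draws a full cohort under [synthetic_config()] and returns both the
#' dataset and the ground truth needed to score downstream stages
#' (discriminating m/z values, per-case gains, per-spectrum mass shifts and
#' the planted per-spectrum peak heights before gain and noise).
#'
#' @param config a `synthetic_config`.
#' @return list with elements `dataset` (a [profile_dataset()]) and
#'   `ground_truth` (list: `discriminating_peak_mzs`, `true_class_by_case`,
#'   `planted_peak_table`, `case_gain`, `mass_shift`, `planted_intensity`
#'   matrix with one row per spectrum in dataset order).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  mz_axis <- seq(cfg$mz_min, cfg$mz_max, by = cfg$mz_step)
  centers <- plant_peak_centers(cfg)
  base_height <- stats::rlnorm(cfg$n_peaks, cfg$peak_height_meanlog,
                               cfg$peak_height_sdlog)
  disc <- sort(sample(cfg$n_peaks, cfg$n_discriminating_peaks))
  effect <- rep(1, cfg$n_peaks)
  effect[disc] <- 2^cfg$effect_log2fc

  n_fa <- cfg$n_cases_per_class[["FA"]]
  n_lgp <- cfg$n_cases_per_class[["LGP"]]
  classes <- c(rep("FA", n_fa), rep("LGP", n_lgp))
  case_ids <- sprintf("%s_%02d", classes, c(seq_len(n_fa), seq_len(n_lgp)))
  compartments <- c("epithelial", "stromal")

  spectra <- vector("list",
                    (n_fa + n_lgp) * 2 * cfg$spots_per_compartment)
  n_total <- length(spectra)
  planted <- matrix(0, n_total, cfg$n_peaks)
  shift_rec <- numeric(n_total)
  names_rec <- character(n_total)
  case_gain <- stats::setNames(
    stats::rlnorm(length(case_ids), 0, cfg$case_gain_sd), case_ids)

  i <- 0L
  for (ci in seq_along(case_ids)) {
    perturb <- stats::rlnorm(cfg$n_peaks, 0, cfg$case_peak_sd)
    for (comp in compartments) {
      eff <- if (classes[ci] == "LGP" && comp %in% cfg$effect_compartments)
        effect else rep(1, cfg$n_peaks)
      for (sp in seq_len(cfg$spots_per_compartment)) {
        i <- i + 1L
        h <- base_height * perturb * eff
        shift <- stats::runif(1, -cfg$mass_shift_max, cfg$mass_shift_max)
        spot_id <- sprintf("%s_%02d", substr(comp, 1, 3), sp)
        spectra[[i]] <- spectrum_model(
          mz_axis,
          data.frame(mz = centers, height = h, sigma = cfg$peak_width_sigma),
          baseline_amplitude = cfg$baseline_amplitude,
          baseline_decay = cfg$baseline_decay,
          case_gain = case_gain[ci], mass_shift = shift,
          noise_sd = cfg$noise_sd,
          case_id = case_ids[ci], spot_id = spot_id, compartment = comp,
          class_label = classes[ci])
        planted[i, ] <- h
        shift_rec[i] <- shift
        names_rec[i] <- paste(case_ids[ci], spot_id, sep = "/")
      }
    }
  }
  names(shift_rec) <- names_rec

  # per-class mean planted heights (stromal convention for the effect column)
  mean_fa <- base_height
  mean_lgp <- base_height * effect
  gt <- list(
    discriminating_peak_mzs = centers[disc],
    true_class_by_case = stats::setNames(classes, case_ids),
    planted_peak_table = data.frame(mz = centers,
                                    sigma = cfg$peak_width_sigma,
                                    mean_fa = mean_fa, mean_lgp = mean_lgp,
                                    discriminating = seq_len(cfg$n_peaks) %in% disc),
    case_gain = case_gain,
    mass_shift = shift_rec,
    planted_intensity = planted)
  list(dataset = profile_dataset(spectra), ground_truth = gt)
}

# per-group clinical sampling parameters; defaults follow the printed
# cohort summaries (means and ranges) of the study the pipeline emulates
clinical_defaults <- function() {
  list(
    LGP = list(age_mean = 35.5, age_sd = 12, age_range = c(14, 63),
               size_mean = 3.0, size_sd = 1.4, size_range = c(0.8, 7.0),
               fu_mean = 44.6, fu_sd = 35, fu_range = c(0, 131),
               recurrence_prob = 2 / 31, death_prob = 0,
               re_excision_prob = 24 / 31),
    FA = list(age_mean = 27.0, age_sd = 9, age_range = c(15, 49),
              size_mean = 2.7, size_sd = 1.0, size_range = c(1.2, 5.1),
              fu_mean = 59.2, fu_sd = 30, fu_range = c(0, 109),
              recurrence_prob = 0, death_prob = 0,
              re_excision_prob = 0))
}

clip <- function(x, range) pmin(pmax(x, range[1]), range[2])

#' Generate a synthetic clinical outcome table
#'
#' Ages, tumor sizes, follow-up and events are drawn from clipped normal /
#' Bernoulli distributions whose defaults match the printed group means and
#' ranges of the cohorts the pipeline emulates (LGP age mean 35.5 y, range
#' 14-63; FA age mean 27.0 y, range 15-49; sizes 3.0 cm [0.8-7.0] vs 2.7 cm
#' [1.2-5.1]; follow-up 44.6 vs 59.2 months; LGP recurrence probability
#' 2/31, no disease deaths in either group).
#'
#' @param n_lgp,n_fa group sizes (>= 1).
#' @param seed RNG seed.
#' @param params per-group parameter list as produced by
#'   `maldiprofiler:::clinical_defaults()`; override to change distributions.
#' @return data.frame of clinical records: case_id, group, age, tumor_size,
#'   followup_months, re_excision, recurrence, death_from_disease,
#'   time_to_event.
#' @export
generate_clinical_table <- function(n_lgp, n_fa, seed = 1L,
                                    params = clinical_defaults()) {
  stopifnot(n_lgp >= 1, n_fa >= 1)
  set.seed(as.integer(seed))
  one_group <- function(n, group, p) {
    age <- clip(stats::rnorm(n, p$age_mean, p$age_sd), p$age_range)
    size <- clip(stats::rnorm(n, p$size_mean, p$size_sd), p$size_range)
    fu <- clip(stats::rnorm(n, p$fu_mean, p$fu_sd), p$fu_range)
    rec <- stats::runif(n) < p$recurrence_prob
    death <- stats::runif(n) < p$death_prob
    tte <- ifelse(rec | death, round(stats::runif(n) * pmax(fu, 1), 1), fu)
    data.frame(case_id = sprintf("%s_%02d", group, seq_len(n)),
               group = group,
               age = round(age, 1), tumor_size = round(size, 1),
               followup_months = round(fu, 1),
               re_excision = stats::runif(n) < p$re_excision_prob,
               recurrence = rec, death_from_disease = death,
               time_to_event = pmin(tte, round(fu, 1)),
               stringsAsFactors = FALSE)
  }
  rbind(one_group(n_lgp, "LGP", params$LGP),
        one_group(n_fa, "FA", params$FA))
}

# marker-wise stromal positivity parameters (percent); means and ranges as
# printed for the three groups (FA, LGP, HGP)
ihc_defaults <- function() {
  list(
    Ki67 = list(FA = c(mean = 2.5, lo = 1, hi = 10),
                LGP = c(mean = 7.7, lo = 2, hi = 30),
                HGP = c(mean = 45.0, lo = 20, hi = 70)),
    p53 = list(FA = c(mean = 2.7, lo = 1, hi = 20),
               LGP = c(mean = 10.0, lo = 1, hi = 60),
               HGP = c(mean = 30.5, lo = 2, hi = 100)),
    beta_catenin = list(FA = c(mean = 38.2, lo = 0, hi = 80),
                        LGP = c(mean = 48.8, lo = 2, hi = 90),
                        HGP = c(mean = 9.5, lo = 0, hi = 40)),
    E_cadherin = list(FA = c(mean = 0, lo = 0, hi = 0),
                      LGP = c(mean = 0, lo = 0, hi = 0),
                      HGP = c(mean = 0, lo = 0, hi = 0)))
}

#' Generate a synthetic two-reader IHC scoring table
#'
#' Per-case stromal positivity percentages are drawn from scaled Beta
#' distributions on the printed per-group ranges with means matched exactly
#' to the printed group means (Ki-67 2.5/7.7/45.0; p53 2.7/10.0/30.5;
#' beta-catenin 38.2/48.8/9.5; E-cadherin uniformly 0). Two simulated
#' readers score each case symmetrically around the case value; the
#' analysis value is their average, as in the two-pathologist scoring
#' protocol.
#'
#' @param n_fa,n_lgp,n_hgp group sizes (0 allowed to omit a group).
#' @param seed RNG seed.
#' @param concentration Beta concentration (spread) parameter; larger =
#'   tighter around the group mean (default 4).
#' @param reader_sd sd of the between-reader half-difference, percent
#'   (default 1.5).
#' @return data.frame of IHC records: case_id, group, marker, reader1_pct,
#'   reader2_pct, mean_pct (always the two readers' average).
#' @export
generate_ihc_table <- function(n_fa, n_lgp, n_hgp = 0, seed = 1L,
                               concentration = 4, reader_sd = 1.5) {
  set.seed(as.integer(seed))
  defs <- ihc_defaults()
  out <- list()
  ns <- c(FA = n_fa, LGP = n_lgp, HGP = n_hgp)
  for (marker in names(defs)) {
    for (group in names(ns)) {
      n <- ns[[group]]
      if (n < 1) next
      p <- defs[[marker]][[group]]
      lo <- p[["lo"]]; hi <- p[["hi"]]
      if (hi > lo) {
        m <- (p[["mean"]] - lo) / (hi - lo)
        val <- lo + (hi - lo) *
          stats::rbeta(n, concentration * m, concentration * (1 - m))
      } else val <- rep(lo, n)
      d <- if (hi > lo) stats::rnorm(n, 0, reader_sd) else rep(0, n)
      r1 <- clip(val + d, c(0, 100))
      r2 <- clip(val - d, c(0, 100))
      out[[length(out) + 1L]] <- data.frame(
        case_id = sprintf("%s_%02d", group, seq_len(n)), group = group,
        marker = marker,
        reader1_pct = round(r1, 1), reader2_pct = round(r2, 1),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  tab$mean_pct <- (tab$reader1_pct + tab$reader2_pct) / 2
  rownames(tab) <- NULL
  tab
}
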