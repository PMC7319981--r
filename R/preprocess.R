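#' Preprocessing parameters
#'
#' @param snip_iterations SNIP clipping iterations (default 20, the
#'   workflow's standard setting).
#' @param use_lls_transform apply the log-log-square-root compression
#'   before clipping (default TRUE; stabilizes dynamic range).
#' @param tic_target normalization target: `"dataset_median"` scales every
#'   spectrum's TIC to the dataset median (keeps physical scale), `"unit"`
#'   to 1.
#' @param align_tolerance_ppm landmark matching tolerance (default 2000).
#' @param min_landmarks minimum matched landmarks for a non-identity warp
#'   (default 2).
#' @param landmark_snr SNR threshold for landmark peak detection
#'   (default 5).
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(snip_iterations = 20, use_lls_transform = TRUE,
                              tic_target = c("dataset_median", "unit"),
                              align_tolerance_ppm = 2000, min_landmarks = 2,
                              landmark_snr = 5) {
  if (snip_iterations < 1) stop("snip_iterations must be >= 1", call. = FALSE)
  if (align_tolerance_ppm <= 0)
    stop("align_tolerance_ppm must be > 0", call. = FALSE)
  structure(list(snip_iterations = as.integer(snip_iterations),
                 use_lls_transform = isTRUE(use_lls_transform),
                 tic_target = match.arg(tic_target),
                 align_tolerance_ppm = align_tolerance_ppm,
                 min_landmarks = as.integer(min_landmarks),
                 landmark_snr = landmark_snr),
            class = "preprocess_params")
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive nonlinear iterative peak clipping with a decreasing
#' window. Optionally the intensities are first compressed with the LLS
#' transform `v = ln(ln(sqrt(y + 1) + 1) + 1)`; then, for window half-width
#' `i` decreasing from `iterations` to 1, every interior point is replaced
#' by `min(v[m], (v[m-i] + v[m+i]) / 2)` (edges held fixed); finally the
#' transform is inverted and the result clipped into `[0, intensity]`.
#'
#' @param intensity numeric vector, finite, >= 0, length >= 3.
#' @param iterations maximal clipping half-width. If the vector is shorter
#'   than `2 * iterations + 1` the window is reduced to
#'   `floor((length - 1) / 2)` with a warning.
#' @param use_lls apply the LLS compression (default TRUE).
#' @return The estimated baseline, same length, `0 <= baseline <= intensity`.
#' @export
snip_baseline <- function(intensity, iterations = 20, use_lls = TRUE) {
  y <- as.numeric(intensity)
  n <- length(y)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (anyNA(y) || any(!is.finite(y)) || any(y < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  iterations <- as.integer(iterations)
  if (n < 2L * iterations + 1L) {
    iterations <- (n - 1L) %/% 2L
    warning(sprintf("vector shorter than 2*iterations+1; window reduced to %d",
                    iterations), call. = FALSE)
  }
  v <- if (use_lls) log(log(sqrt(y + 1) + 1) + 1) else y
  for (i in seq(iterations, 1L)) {
    m <- seq(i + 1L, n - i)
    v[m] <- pmin(v[m], (v[m - i] + v[m + i]) / 2)
  }
  b <- if (use_lls) (exp(exp(v) - 1) - 1)^2 - 1 else v
  pmin(pmax(b, 0), y)
}

#' Subtract a baseline from a spectrum
#'
#' @param spectrum a `mass_spectrum`.
#' @param baseline numeric vector of the same length (e.g. from
#'   [snip_baseline()]).
#' @return The baseline-corrected spectrum (intensities floored at 0);
#'   provenance preserved, stage `"baseline"` recorded.
#' @export
subtract_baseline <- function(spectrum, baseline) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (length(baseline) == 1L) baseline <- rep(baseline, length(spectrum$mz))
  if (length(baseline) != length(spectrum$intensity))
    stop("baseline length does not match the spectrum", call. = FALSE)
  out <- spectrum
  out$intensity <- pmax(spectrum$intensity - baseline, 0)
  out$stages <- unique(c(spectrum$stages, "baseline"))
  out
}

#' Total-ion-current normalization
#'
#' Scales each spectrum so its TIC equals the dataset target: the median of
#' the input TICs (`"dataset_median"`, keeps intensities on physical scale)
#' or 1 (`"unit"`). Spectra with non-positive TIC are excluded with a
#' warning and listed in the rejects report.
#'
#' @param spectra list of baseline-corrected `mass_spectrum` objects.
#' @param target `"dataset_median"` or `"unit"`.
#' @return list: `spectra` (normalized, stage `"normalize"` recorded),
#'   `factors` (scale factor per retained spectrum), `target_tic`,
#'   `rejects` (indices of excluded spectra).
#' @export
tic_normalize <- function(spectra, target = c("dataset_median", "unit")) {
  target <- match.arg(target)
  check_stages(spectra, "baseline", "tic_normalize")
  tics <- vapply(spectra, spectrum_tic, numeric(1))
  rejects <- which(tics <= 0)
  if (length(rejects)) {
    warning(sprintf("excluding %d spectrum(s) with zero TIC", length(rejects)),
            call. = FALSE)
    spectra <- spectra[-rejects]
    tics <- tics[-rejects]
  }
  if (!length(spectra)) stop("no spectra with positive TIC", call. = FALSE)
  target_tic <- if (target == "dataset_median") stats::median(tics) else 1
  factors <- target_tic / tics
  out <- Map(function(s, f) {
    s$intensity <- s$intensity * f
    s$stages <- unique(c(s$stages, "normalize"))
    s
  }, spectra, factors)
  list(spectra = out, factors = unname(factors), target_tic = target_tic,
       rejects = rejects)
}

#' Select the reference spectrum for mass-axis alignment
#'
#' The reference is the spectrum whose TIC is closest to the 50th quantile
#' of the TIC distribution; ties break to the lowest index.
#'
#' @param spectra non-empty list of `mass_spectrum` objects.
#' @return Integer index of the reference spectrum.
#' @export
select_reference <- function(spectra) {
  if (!length(spectra)) stop("empty spectrum list", call. = FALSE)
  tics <- vapply(spectra, spectrum_tic, numeric(1))
  q <- stats::quantile(tics, 0.5, names = FALSE)
  which.min(abs(tics - q))
}

# internal: one-to-one nearest matching of target peaks to reference peaks
# within a ppm tolerance, greedy by increasing distance
match_landmarks <- function(target_mz, reference_mz, tolerance_ppm) {
  if (!length(target_mz) || !length(reference_mz))
    return(data.frame(target = numeric(0), reference = numeric(0)))
  cand <- expand.grid(t = seq_along(target_mz), r = seq_along(reference_mz))
  cand$d <- abs(target_mz[cand$t] - reference_mz[cand$r])
  tol <- reference_mz[cand$r] * tolerance_ppm * 1e-6
  cand <- cand[cand$d <= tol, , drop = FALSE]
  cand <- cand[order(cand$d), , drop = FALSE]
  used_t <- logical(length(target_mz)); used_r <- logical(length(reference_mz))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_t[cand$t[k]] && !used_r[cand$r[k]]) {
      keep[k] <- TRUE
      used_t[cand$t[k]] <- TRUE; used_r[cand$r[k]] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(target = target_mz[cand$t], reference = reference_mz[cand$r])
}

#' Align one spectrum to reference landmark peaks
#'
#' Detects landmark peaks in the target at `landmark_snr`, matches them
#' one-to-one to the reference peaks within `align_tolerance_ppm`, and, if
#' at least `min_landmarks` pairs match, fits the global linear warp
#' `mz' = slope * mz + intercept` by least squares and re-interpolates the
#' intensities onto the original grid. Otherwise (or if the fitted slope
#' falls outside the (0.9, 1.1) sanity band) the identity warp is returned
#' and the spectrum flagged.
#'
#' @param spectrum a normalized `mass_spectrum`.
#' @param reference_peaks numeric vector of reference landmark m/z values
#'   (from [detect_peaks()] on the reference spectrum at `landmark_snr`).
#' @param params a [preprocess_params()].
#' @return list: `spectrum` (aligned, stage `"align"` recorded) and `warp`
#'   (kind, slope, intercept, n_landmarks, residuals of matched landmarks).
#' @export
align_spectrum <- function(spectrum, reference_peaks,
                           params = preprocess_params()) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  pk <- detect_peaks(spectrum, snr_threshold = params$landmark_snr,
                     check_stage = FALSE)
  m <- match_landmarks(pk$mz_centers, reference_peaks,
                       params$align_tolerance_ppm)
  out <- spectrum
  out$stages <- unique(c(out$stages, "align"))
  identity_warp <- list(kind = "identity", slope = 1, intercept = 0,
                        n_landmarks = nrow(m), residuals = numeric(0))
  if (nrow(m) < params$min_landmarks)
    return(list(spectrum = out, warp = identity_warp))
  fit <- stats::lm.fit(cbind(1, m$target), m$reference)
  intercept <- fit$coefficients[1]; slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope <= 0.9 || slope >= 1.1)
    return(list(spectrum = out, warp = identity_warp))
  warped_pos <- slope * spectrum$mz + intercept
  out$intensity <- pmax(stats::approx(warped_pos, spectrum$intensity,
                                      xout = spectrum$mz, rule = 2)$y, 0)
  list(spectrum = out,
       warp = list(kind = "linear", slope = unname(slope),
                   intercept = unname(intercept), n_landmarks = nrow(m),
                   residuals = unname(slope * m$target + intercept -
                                        m$reference)))
}

#' Run the full preprocessing chain on a dataset
#'
#' Applies the fixed stage order baseline -> TIC normalization ->
#' reference selection -> mass-axis alignment. Stage bookkeeping on each
#' spectrum makes out-of-order invocation of the stage functions an error.
#'
#' @param dataset a [profile_dataset()].
#' @param params a [preprocess_params()].
#' @return list: `dataset` (preprocessed) and `report` (reference index,
#'   normalization target and factors, per-spectrum warp models, rejects,
#'   number of identity-warp fallbacks).
#' @export
preprocess_dataset <- function(dataset, params = preprocess_params()) {
  stopifnot(inherits(dataset, "profile_dataset"),
            inherits(params, "preprocess_params"))
  corrected <- lapply(dataset$spectra, function(s)
    subtract_baseline(s, snip_baseline(s$intensity, params$snip_iterations,
                                       params$use_lls_transform)))
  norm <- tic_normalize(corrected, params$tic_target)
  ref_idx <- select_reference(norm$spectra)
  ref_peaks <- detect_peaks(norm$spectra[[ref_idx]],
                            snr_threshold = params$landmark_snr,
                            check_stage = FALSE)$mz_centers
  aligned <- lapply(norm$spectra, align_spectrum, reference_peaks = ref_peaks,
                    params = params)
  spectra <- lapply(aligned, `[[`, "spectrum")
  warps <- lapply(aligned, `[[`, "warp")
  cases <- unique(vapply(spectra, `[[`, character(1), "case_id"))
  list(dataset = profile_dataset(spectra,
                                 partition = dataset$partition[cases]),
       report = list(reference_index = ref_idx,
                     reference_peaks = ref_peaks,
                     tic_target = norm$target_tic,
                     tic_factors = norm$factors,
                     rejects = norm$rejects,
                     warps = warps,
                     n_identity = sum(vapply(warps, function(w)
                       w$kind == "identity", logical(1)))))
}
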