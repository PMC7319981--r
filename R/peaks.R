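#' Overall mean spectrum
#'
#' Pointwise arithmetic mean of intensities across spectra sharing a common
#' m/z grid (i.e. after alignment).
#'
#' @param spectra non-empty list of `mass_spectrum` objects on one grid.
#' @return A `mass_spectrum` with aggregate provenance markers.
#' @export
mean_spectrum <- function(spectra) {
  if (!length(spectra)) stop("empty spectrum list", call. = FALSE)
  mz <- spectra[[1]]$mz
  same <- vapply(spectra, function(s)
    length(s$mz) == length(mz) && all(s$mz == mz), logical(1))
  if (!all(same))
    stop("spectra are not on a common m/z grid; align them first",
         call. = FALSE)
  m <- rowMeans(vapply(spectra, `[[`, numeric(length(mz)), "intensity"))
  stages <- Reduce(intersect, lapply(spectra, `[[`, "stages"))
  mass_spectrum(mz, m, case_id = "(mean)", spot_id = "(mean)",
                stages = c(stages, "mean"))
}

#' Robust noise estimate of a spectrum
#'
#' Noise is estimated as the median absolute deviation of the intensities
#' scaled to the Gaussian sigma: `1.4826 * median(|y - median(y)|)`.
#'
#' @param intensity numeric vector, length >= 10.
#' @return Non-negative noise level (0 for an all-equal vector; callers
#'   must guard).
#' @export
estimate_noise <- function(intensity) {
  y <- as.numeric(intensity)
  if (length(y) < 10) stop("need at least 10 points", call. = FALSE)
  stats::mad(y)  # constant = 1.4826 by default
}

#' Detected peak list
#'
#' @param mean_spec baseline-corrected `mass_spectrum` (typically the
#'   overall mean spectrum).
#' @param snr_threshold retain peaks with height / noise strictly above
#'   this value (default 3, the workflow's picking threshold).
#' @param noise optional externally supplied noise level; default is
#'   [estimate_noise()] on the spectrum.
#' @param refine `"quadratic"` (default) refines each peak centre by a
#'   three-point parabola through the apex, giving sub-grid centres for
#'   alignment; `"none"` keeps grid positions.
#' @param check_stage require the `"baseline"` stage on the input
#'   (default TRUE).
#' @return An object of class `peak_list`: `mz_centers` (strictly
#'   increasing), `heights`, `snr`, `noise_level`, `index` (grid index of
#'   each apex).
#' @details Local maxima must be strictly greater than both neighbouring
#'   distinct values; a flat-topped plateau is counted once at its leftmost
#'   index. SNR is the robust z-score of the apex: height above the median
#'   intensity divided by the MAD noise (the median absorbs the small
#'   positive pedestal that SNIP-corrected noise retains). Retained peaks
#'   are at least two grid steps apart (the higher peak wins). A zero
#'   noise estimate retains all local maxima with infinite SNR and a
#'   warning.
#' @export
detect_peaks <- function(mean_spec, snr_threshold = 3, noise = NULL,
                         refine = c("quadratic", "none"),
                         check_stage = TRUE) {
  stopifnot(inherits(mean_spec, "mass_spectrum"))
  refine <- match.arg(refine)
  if (check_stage) check_stages(list(mean_spec), "baseline", "detect_peaks")
  y <- mean_spec$intensity
  mz <- mean_spec$mz
  n <- length(y)
  if (is.null(noise)) noise <- estimate_noise(y)
  # local maxima across plateaus: fill zero slopes from the right
  s <- sign(diff(y))
  nz <- s != 0
  if (!any(nz)) {
    return(structure(list(mz_centers = numeric(0), heights = numeric(0),
                          snr = numeric(0), noise_level = noise,
                          index = integer(0)), class = "peak_list"))
  }
  for (j in seq(length(s) - 1L, 1L)) if (s[j] == 0) s[j] <- s[j + 1L]
  apex <- which(diff(s) == -2L) + 1L
  apex <- apex[apex > 1L & apex < n]
  med <- stats::median(y)
  if (noise <= 0) {
    warning("zero noise estimate: retaining all local maxima with snr = Inf",
            call. = FALSE)
    snr <- rep(Inf, length(apex))
  } else snr <- (y[apex] - med) / noise
  keep <- snr > snr_threshold
  apex <- apex[keep]; snr <- snr[keep]
  # enforce minimum separation of 2 grid steps, keeping the higher peak
  if (length(apex) > 1L) {
    step <- stats::median(diff(mz))
    ord <- order(y[apex], decreasing = TRUE)
    sel <- logical(length(apex))
    for (k in ord) {
      if (!any(sel & abs(mz[apex] - mz[apex[k]]) < 2 * step)) sel[k] <- TRUE
    }
    apex <- sort(apex[sel])
    snr <- if (noise > 0) (y[apex] - med) / noise else rep(Inf, length(apex))
  }
  centers <- mz[apex]
  if (refine == "quadratic" && length(apex)) {
    step <- stats::median(diff(mz))
    for (k in seq_along(apex)) {
      i <- apex[k]
      if (i > 1L && i < n) {
        denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
        if (denom < 0) {
          delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
          if (is.finite(delta) && abs(delta) <= 0.5)
            centers[k] <- mz[i] + delta * step
        }
      }
    }
  }
  structure(list(mz_centers = centers, heights = y[apex], snr = snr,
                 noise_level = noise, index = apex),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks, noise %.4g\n", length(x$mz_centers),
              x$noise_level))
  invisible(x)
}

#' Build the spectra x peaks intensity matrix
#'
#' For each spectrum and each picked peak, the feature value is the maximum
#' (default) or summed intensity within `+/- window_ppm` of the peak
#' centre. Rows carry the spot provenance (case, spot, compartment, class).
#'
#' @param spectra list of aligned `mass_spectrum` objects.
#' @param peaklist a [detect_peaks()] result.
#' @param window_ppm half-window around each centre (default 2000, tied to
#'   the alignment tolerance).
#' @param integrate `"max"` (robust to residual misalignment, default) or
#'   `"sum"` (area-style).
#' @return An object of class `peak_matrix`: `values` (matrix, one row per
#'   spectrum), `meta` (provenance data.frame), `mz` (peak centres).
#' @export
build_peak_matrix <- function(spectra, peaklist, window_ppm = 2000,
                              integrate = c("max", "sum")) {
  integrate <- match.arg(integrate)
  stopifnot(inherits(peaklist, "peak_list"))
  p <- length(peaklist$mz_centers)
  vals <- matrix(0, length(spectra), p)
  if (p > 0) {
    for (i in seq_along(spectra)) {
      s <- spectra[[i]]
      for (j in seq_len(p)) {
        ctr <- peaklist$mz_centers[j]
        half <- ctr * window_ppm * 1e-6
        w <- which(s$mz >= ctr - half & s$mz <= ctr + half)
        if (length(w))
          vals[i, j] <- if (integrate == "max") max(s$intensity[w])
                        else sum(s$intensity[w])
      }
    }
  }
  meta <- data.frame(
    case_id = vapply(spectra, `[[`, character(1), "case_id"),
    spot_id = vapply(spectra, `[[`, character(1), "spot_id"),
    compartment = vapply(spectra, `[[`, character(1), "compartment"),
    class_label = vapply(spectra, `[[`, character(1), "class_label"),
    stringsAsFactors = FALSE)
  peak_matrix(vals, meta, peaklist$mz_centers)
}

#' Construct a peak matrix object
#'
#' @param values numeric matrix, spectra x peaks, >= 0.
#' @param meta data.frame with case_id, spot_id, compartment, class_label.
#' @param mz peak centres (strictly increasing), one per column.
#' @return An object of class `peak_matrix`.
#' @export
peak_matrix <- function(values, meta, mz) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(meta))
    stop("values and meta row counts differ", call. = FALSE)
  if (ncol(values) != length(mz))
    stop("values column count must equal length(mz)", call. = FALSE)
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("peak m/z centres must be strictly increasing", call. = FALSE)
  need <- c("case_id", "spot_id", "compartment", "class_label")
  if (!all(need %in% names(meta)))
    stop("meta must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  colnames(values) <- sprintf("mz_%.4f", mz)
  structure(list(values = values, meta = meta[, need, drop = FALSE],
                 mz = as.numeric(mz)), class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d spectra x %d peaks\n",
              nrow(x$values), length(x$mz)))
  invisible(x)
}

#' Subset rows of a peak matrix
#'
#' @param pm a `peak_matrix`.
#' @param idx row index (integer or logical).
#' @return The restricted `peak_matrix`.
#' @export
subset_peak_matrix <- function(pm, idx) {
  peak_matrix(pm$values[idx, , drop = FALSE], pm$meta[idx, , drop = FALSE],
              pm$mz)
}
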