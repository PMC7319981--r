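#' Area under the ROC curve for one peak
#'
#' AUROC = P(random draw from `b` exceeds a random draw from `a`) + half
#' the tie probability, computed through the rank-sum identity
#' `AUROC = U / (n_a * n_b)` with midranks for ties.
#'
#' @param intensities_a,intensities_b non-empty numeric vectors (reference
#'   class and comparison class).
#' @return AUROC in \[0, 1\]; 0.5 means no separation, values above 0.5
#'   mean `b` tends higher.
#' @export
peak_auroc <- function(intensities_a, intensities_b) {
  na <- length(intensities_a); nb <- length(intensities_b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(intensities_a, intensities_b))
  u_b <- sum(r[(na + 1):(na + nb)]) - nb * (nb + 1) / 2
  u_b / (na * nb)
}

#' Volcano-plot statistics for every peak
#'
#' For each peak: the log2 ratio of class mean intensities (LGP over FA by
#' default), the unpaired t statistic (Welch by default) with two-sided p,
#' the Benjamini-Hochberg adjusted p across peaks, and the AUROC. Analysis
#' unit is the spot-level spectrum by default; `unit = "case"` averages
#' spots within each case first (avoiding pseudo-replication at the cost
#' of power).
#'
#' @param pm a [peak_matrix()].
#' @param classes length-2 character vector `(reference, comparison)`;
#'   fold changes are comparison / reference (default `c("FA", "LGP")`).
#' @param fc_line,p_line guide thresholds used for the significance counts
#'   (defaults |log2 FC| = 1, i.e. 2-fold, and p = 0.05).
#' @param var_equal use the pooled-variance t-test instead of Welch
#'   (default FALSE).
#' @param unit `"spot"` (default) or `"case"`.
#' @return data.frame with one row per peak: mz, mean_a, mean_b, log2_fc,
#'   t_stat, p_value, p_adjusted, auroc, flag. Attribute `n_significant`
#'   counts peaks beyond both guide thresholds (raw p).
#' @export
volcano_stats <- function(pm, classes = c("FA", "LGP"), fc_line = 1,
                          p_line = 0.05, var_equal = FALSE,
                          unit = c("spot", "case")) {
  stopifnot(inherits(pm, "peak_matrix"))
  unit <- match.arg(unit)
  lab <- pm$meta$class_label
  x <- pm$values
  if (unit == "case") {
    key <- pm$meta$case_id
    x <- do.call(rbind, lapply(split(seq_along(key), key), function(i)
      colMeans(x[i, , drop = FALSE])))
    lab <- vapply(split(lab, key), `[[`, character(1), 1)
  }
  a <- x[lab == classes[1], , drop = FALSE]
  b <- x[lab == classes[2], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("need at least 2 observations per class", call. = FALSE)
  eps <- .Machine$double.eps
  rows <- lapply(seq_along(pm$mz), function(j) {
    va <- a[, j]; vb <- b[, j]
    ma <- mean(va); mb <- mean(vb)
    flag <- ""
    if (ma <= eps || mb <= eps) flag <- "zero_mean"
    lfc <- log2(max(mb, eps) / max(ma, eps))
    if (stats::var(va) == 0 && stats::var(vb) == 0) {
      t_stat <- 0; p <- 1
      flag <- paste0(flag, if (nzchar(flag)) ";", "zero_variance")
    } else {
      tt <- stats::t.test(vb, va, var.equal = var_equal)
      t_stat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(mz = pm$mz[j], mean_a = ma, mean_b = mb, log2_fc = lfc,
               t_stat = t_stat, p_value = p,
               auroc = peak_auroc(va, vb), flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[, c("mz", "mean_a", "mean_b", "log2_fc", "t_stat", "p_value",
                 "p_adjusted", "auroc", "flag")]
  attr(out, "n_significant") <-
    sum(abs(out$log2_fc) > fc_line & out$p_value < p_line)
  attr(out, "classes") <- classes
  out
}

#' Butterfly (mirrored) mean-spectra comparison
#'
#' Mean profile of each class on the common axis, with the second class
#' negated for mirrored plotting, plus their absolute difference profile.
#'
#' @param spectra list of aligned `mass_spectrum` objects.
#' @param classes length-2 character vector; the second class is flipped.
#' @return list: `mz`, `mean_a`, `mean_b_flipped` (negated), `difference`
#'   (absolute difference of the unflipped means).
#' @export
butterfly_means <- function(spectra, classes = c("FA", "LGP")) {
  lab <- vapply(spectra, `[[`, character(1), "class_label")
  if (!all(classes %in% lab))
    stop("both classes must be present", call. = FALSE)
  ma <- mean_spectrum(spectra[lab == classes[1]])
  mb <- mean_spectrum(spectra[lab == classes[2]])
  list(mz = ma$mz, mean_a = ma$intensity, mean_b_flipped = -mb$intensity,
       difference = abs(ma$intensity - mb$intensity))
}
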