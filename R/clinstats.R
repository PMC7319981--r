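#' Wilcoxon-Mann-Whitney test
#'
#' Two-sided WMW test with midranks. The p-value is exact when both
#' samples are small (`min(n) <= 8`) and tie-free, and uses the normal
#' approximation with tie and continuity correction otherwise. The U
#' statistic is oriented as the number of (x, y) pairs with x > y (plus
#' half-ties), so `U = 0` when every x is below every y.
#'
#' @param x,y non-empty numeric samples.
#' @return list: `U`, `p` (two-sided), `method` (`"exact"` or
#'   `"normal_approx"`).
#' @export
wmw_test <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1, method = "degenerate"))
  ties <- any(duplicated(c(x, y)))
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Fisher exact test for a 2x2 table
#'
#' Conditional two-sided p-value (sum of table probabilities at most the
#' observed one under the hypergeometric null). The reported odds ratio is
#' the sample odds ratio `(a*d)/(b*c)`; if any cell is zero, 0.5 is added
#' to every cell for the odds ratio only (flagged), never for the p-value.
#' A zero margin gives p = 1 and an undefined odds ratio.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list: `odds_ratio`, `p`, `or_continuity` (logical),
#'   `or_defined` (logical).
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2x2 table of non-negative integer counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p = 1, or_continuity = FALSE,
                or_defined = FALSE))
  p <- stats::fisher.test(tab)$p.value
  cont <- any(tab == 0)
  t2 <- if (cont) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = or, p = p, or_continuity = cont, or_defined = TRUE)
}

#' Proportion as a printed percentage
#'
#' @param events,n numerator and denominator counts.
#' @param digits decimals to report (default 1, the usual table precision).
#' @return `100 * events / n` rounded to `digits`.
#' @export
prop_pct <- function(events, n, digits = 1) {
  stopifnot(n > 0, events >= 0, events <= n)
  round(100 * events / n, digits)
}

#' Kaplan-Meier product-limit survival curve
#'
#' `S(t) = prod over event times <= t of (1 - d_i / n_i)`; censored
#' observations decrement the risk set without a drop, and at tied
#' event/censor times the event is processed first (standard convention).
#'
#' @param times non-negative follow-up times.
#' @param event_flags logical event indicators (TRUE = event,
#'   FALSE = censored).
#' @return An object of class `km_curve`: `times` (starting at 0),
#'   `survival` (non-increasing, starts at 1), `n_at_risk`, `n_event`.
#' @export
km_curve <- function(times, event_flags) {
  if (!length(times)) stop("empty input", call. = FALSE)
  stopifnot(length(times) == length(event_flags), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(event_flags)) ~ 1)
  structure(list(times = c(0, fit$time), survival = c(1, fit$surv),
                 n_at_risk = c(length(times), fit$n.risk),
                 n_event = c(0, fit$n.event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d subjects, %d events, S(max t) = %.3f\n",
              x$n_at_risk[1], sum(x$n_event), min(x$survival)))
  invisible(x)
}

#' Log-rank test between two survival groups
#'
#' Standard 1-df log-rank chi-square over the pooled event times; if
#' neither group has any event the statistic is 0 and p = 1.
#'
#' @param times_a,event_flags_a first group.
#' @param times_b,event_flags_b second group.
#' @return list: `chi2`, `p`.
#' @export
logrank_test <- function(times_a, event_flags_a, times_b, event_flags_b) {
  if (!length(times_a) || !length(times_b))
    stop("both groups must be non-empty", call. = FALSE)
  ev <- c(as.integer(event_flags_a), as.integer(event_flags_b))
  if (sum(ev) == 0) return(list(chi2 = 0, p = 1))
  tm <- c(times_a, times_b)
  g <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(tm, ev) ~ g)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Group comparison summary of clinical and IHC tables
#'
#' Produces the standard descriptive-plus-test layout: per group and
#' marker the mean / median / range of the two-reader average positivity
#' with pairwise WMW p-values; WMW comparisons of age and tumor size; and
#' Kaplan-Meier / log-rank comparisons of disease-free and overall
#' survival for the two-group clinical cohort. Markers that are uniformly
#' zero (stromal E-cadherin) are rendered with p = 1 rather than failing;
#' markers absent in a group yield NA cells.
#'
#' @param clinical clinical data.frame as from [generate_clinical_table()]
#'   or [read_clinical_table()] (may be NULL to skip clinical parts).
#' @param ihc IHC data.frame as from [generate_ihc_table()] or
#'   [read_ihc_table()] (may be NULL to skip the marker table).
#' @return list: `ihc_summary` (marker x group descriptives), `ihc_tests`
#'   (marker, pairwise comparisons, p), `clinical_tests` (variable,
#'   comparison, p), `survival` (endpoint, chi2, p, per-group curves).
#' @export
summarize_groups <- function(clinical = NULL, ihc = NULL) {
  out <- list()
  if (!is.null(ihc)) {
    groups <- unique(ihc$group)
    markers <- unique(ihc$marker)
    desc <- list(); tests <- list()
    for (mk in markers) {
      d <- ihc[ihc$marker == mk, ]
      row <- data.frame(marker = mk, stringsAsFactors = FALSE)
      for (g in groups) {
        v <- d$mean_pct[d$group == g]
        row[[paste0("mean_", g)]] <- if (length(v)) mean(v) else NA_real_
        row[[paste0("median_", g)]] <- if (length(v)) stats::median(v) else NA_real_
        row[[paste0("min_", g)]] <- if (length(v)) min(v) else NA_real_
        row[[paste0("max_", g)]] <- if (length(v)) max(v) else NA_real_
      }
      desc[[mk]] <- row
      if (length(groups) >= 2) {
        prs <- utils::combn(groups, 2, simplify = FALSE)
        for (pr in prs) {
          va <- d$mean_pct[d$group == pr[1]]
          vb <- d$mean_pct[d$group == pr[2]]
          p <- if (length(va) && length(vb)) wmw_test(va, vb)$p else NA_real_
          tests[[length(tests) + 1L]] <- data.frame(
            marker = mk, comparison = paste(pr, collapse = " vs "), p = p,
            stringsAsFactors = FALSE)
        }
      }
    }
    out$ihc_summary <- do.call(rbind, desc)
    rownames(out$ihc_summary) <- NULL
    out$ihc_tests <- if (length(tests)) do.call(rbind, tests) else NULL
  }
  if (!is.null(clinical)) {
    groups <- unique(clinical$group)
    if (length(groups) >= 2) {
      prs <- utils::combn(groups, 2, simplify = FALSE)
      ct <- list()
      for (pr in prs) {
        for (var in c("age", "tumor_size")) {
          va <- clinical[[var]][clinical$group == pr[1]]
          vb <- clinical[[var]][clinical$group == pr[2]]
          ct[[length(ct) + 1L]] <- data.frame(
            variable = var, comparison = paste(pr, collapse = " vs "),
            p = wmw_test(va, vb)$p, stringsAsFactors = FALSE)
        }
      }
      out$clinical_tests <- do.call(rbind, ct)
      if (length(groups) == 2) {
        a <- clinical[clinical$group == groups[1], ]
        b <- clinical[clinical$group == groups[2], ]
        dfs <- logrank_test(a$time_to_event, a$recurrence,
                            b$time_to_event, b$recurrence)
        os <- logrank_test(a$followup_months, a$death_from_disease,
                           b$followup_months, b$death_from_disease)
        out$survival <- list(
          disease_free = c(dfs, list(
            curves = stats::setNames(list(
              km_curve(a$time_to_event, a$recurrence),
              km_curve(b$time_to_event, b$recurrence)), groups))),
          overall = c(os, list(
            curves = stats::setNames(list(
              km_curve(a$followup_months, a$death_from_disease),
              km_curve(b$followup_months, b$death_from_disease)), groups))))
      }
    } else {
      out$clinical_tests <- NULL
    }
    desc <- do.call(rbind, lapply(split(clinical, clinical$group), function(d)
      data.frame(group = d$group[1], n = nrow(d),
                 age_mean = mean(d$age), age_median = stats::median(d$age),
                 size_mean = mean(d$tumor_size),
                 size_median = stats::median(d$tumor_size),
                 fu_median = stats::median(d$followup_months),
                 n_recurrence = sum(d$recurrence),
                 n_death = sum(d$death_from_disease))))
    rownames(desc) <- NULL
    out$clinical_summary <- desc
  }
  out
}
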