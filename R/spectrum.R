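#' Mass spectrum with spot provenance
#'
#' A single profiling spectrum acquired at one annotated tissue spot.
#' The m/z axis must be strictly increasing and intensities finite and
#' non-negative. Provenance fields tie the spectrum to its case, spot and
#' histologic compartment; `stages` records which preprocessing steps have
#' been applied (used to enforce the fixed baseline -> normalize -> align
#' order of the pipeline).
#'
#' @param mz numeric vector of m/z values (Da), strictly increasing,
#'   length >= 2.
#' @param intensity numeric vector of intensities (arbitrary units),
#'   same length as `mz`, finite and >= 0.
#' @param case_id,spot_id character identifiers (de-identified).
#' @param compartment one of `"epithelial"`, `"stromal"`,
#'   `"reference_stroma"` or `NA`.
#' @param class_label one of `"FA"`, `"LGP"`, `"HGP"`, `"unknown"` or `NA`.
#' @param stages character vector of applied preprocessing stages.
#' @param extra named list of passthrough metadata.
#' @return An object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, case_id = NA_character_,
                          spot_id = NA_character_, compartment = NA_character_,
                          class_label = NA_character_, stages = character(),
                          extra = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (length(mz) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (anyNA(mz) || any(!is.finite(mz)))
    stop("mz values must be finite", call. = FALSE)
  if (any(diff(mz) <= 0))
    stop("mz axis must be strictly increasing", call. = FALSE)
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  if (any(intensity < 0))
    stop("intensities must be >= 0", call. = FALSE)
  if (!is.na(compartment))
    compartment <- match.arg(compartment,
                             c("epithelial", "stromal", "reference_stroma"))
  if (!is.na(class_label))
    class_label <- match.arg(class_label, c("FA", "LGP", "HGP", "unknown"))
  structure(list(mz = mz, intensity = intensity,
                 case_id = as.character(case_id),
                 spot_id = as.character(spot_id),
                 compartment = compartment, class_label = class_label,
                 stages = stages, extra = extra),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %s / %s [%s] %s\n  %d points, m/z %.1f-%.1f, TIC %.3g, stages: %s\n",
              x$case_id, x$spot_id, x$compartment %||% "?", x$class_label %||% "?",
              length(x$mz), min(x$mz), max(x$mz), sum(x$intensity),
              if (length(x$stages)) paste(x$stages, collapse = " > ") else "(raw)"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Total ion current of a spectrum
#'
#' @param spectrum a `mass_spectrum`.
#' @return The sum of its intensities.
#' @export
spectrum_tic <- function(spectrum) sum(spectrum$intensity)

#' Annotation mark on a scanned histology slide
#'
#' Circular annotation placed by a pathologist on the reference H&E scan;
#' coordinates are micrometres in slide space with origin at the top-left.
#' Coordinates are carried as metadata only (the slide-registration step is
#' out of scope).
#'
#' @param case_id,spot_id identifiers.
#' @param compartment annotated compartment.
#' @param x,y mark centre, um.
#' @param diameter mark diameter, um (default 300, the protocol's mark size).
#' @return An object of class `annotation_mark`.
#' @export
annotation_mark <- function(case_id, spot_id, compartment, x, y,
                            diameter = 300) {
  if (diameter <= 0) stop("diameter must be > 0", call. = FALSE)
  compartment <- match.arg(compartment,
                           c("epithelial", "stromal", "reference_stroma"))
  structure(list(case_id = case_id, spot_id = spot_id,
                 compartment = compartment, x = x, y = y,
                 diameter = diameter),
            class = "annotation_mark")
}

#' Collection of spot spectra with a study/validation partition
#'
#' @param spectra list of `mass_spectrum` objects.
#' @param partition named character vector mapping each case id to
#'   `"study"`, `"validation"` or `"unassigned"`. Defaults to all
#'   `"unassigned"`.
#' @return An object of class `profile_dataset`.
#' @export
profile_dataset <- function(spectra, partition = NULL) {
  stopifnot(is.list(spectra), length(spectra) > 0)
  ok <- vapply(spectra, inherits, logical(1), "mass_spectrum")
  if (!all(ok)) stop("all elements must be mass_spectrum objects", call. = FALSE)
  cases <- unique(vapply(spectra, `[[`, character(1), "case_id"))
  if (is.null(partition)) {
    partition <- rep("unassigned", length(cases))
    names(partition) <- cases
  }
  if (!all(cases %in% names(partition)))
    stop("every spectrum's case_id must appear in the partition", call. = FALSE)
  if (!all(partition %in% c("study", "validation", "unassigned")))
    stop("partition values must be study/validation/unassigned", call. = FALSE)
  # a case's spectra must all share one class label
  for (cs in cases) {
    labs <- unique(vapply(spectra[vapply(spectra, function(s) s$case_id == cs,
                                         logical(1))],
                          `[[`, character(1), "class_label"))
    if (length(labs) > 1)
      stop(sprintf("case %s carries conflicting class labels: %s",
                   cs, paste(labs, collapse = ", ")), call. = FALSE)
  }
  structure(list(spectra = spectra, partition = partition),
            class = "profile_dataset")
}

#' @export
print.profile_dataset <- function(x, ...) {
  meta <- dataset_meta(x)
  by_case <- meta$class_label[!duplicated(meta$case_id)]
  cat(sprintf("<profile_dataset> %d spectra, %d cases (%s)\n",
              nrow(meta), length(unique(meta$case_id)),
              paste(sprintf("%s=%d", names(table(by_case)),
                            as.integer(table(by_case))), collapse = ", ")))
  cat(sprintf("  partition: %s\n",
              paste(sprintf("%s=%d", names(table(x$partition)),
                            as.integer(table(x$partition))), collapse = ", ")))
  invisible(x)
}

#' Per-spectrum provenance table of a dataset
#'
#' @param dataset a `profile_dataset`.
#' @return data.frame with one row per spectrum: case_id, spot_id,
#'   compartment, class_label, partition.
#' @export
dataset_meta <- function(dataset) {
  stopifnot(inherits(dataset, "profile_dataset"))
  meta <- data.frame(
    case_id = vapply(dataset$spectra, `[[`, character(1), "case_id"),
    spot_id = vapply(dataset$spectra, `[[`, character(1), "spot_id"),
    compartment = vapply(dataset$spectra, `[[`, character(1), "compartment"),
    class_label = vapply(dataset$spectra, `[[`, character(1), "class_label"),
    stringsAsFactors = FALSE)
  meta$partition <- unname(dataset$partition[meta$case_id])
  meta
}

#' Restrict a dataset to a subset of spectra
#'
#' @param dataset a `profile_dataset`.
#' @param idx integer or logical index over spectra.
#' @return A `profile_dataset` holding the selected spectra (partition
#'   entries of retained cases are kept).
#' @export
subset_spectra <- function(dataset, idx) {
  sp <- dataset$spectra[idx]
  cases <- unique(vapply(sp, `[[`, character(1), "case_id"))
  profile_dataset(sp, partition = dataset$partition[cases])
}

# internal: require that preprocessing stages were applied in order
check_stages <- function(spectra, required, op) {
  done <- lapply(spectra, `[[`, "stages")
  miss <- !vapply(done, function(st) all(required %in% st), logical(1))
  if (any(miss))
    stop(sprintf(
      "%s requires prior stage(s) %s; run the preprocessing chain in order (baseline -> normalize -> align)",
      op, paste(required, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
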