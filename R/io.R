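#' Write spectra in the native tabular dialect
#'
#' Long-format delimited text: one row per (spectrum, m/z) with columns
#' case_id, spot_id, compartment, class_label, mz, intensity. Chosen for
#' diffability; lossless at full double precision.
#'
#' @param spectra list of `mass_spectrum` objects.
#' @param path output file.
#' @export
write_spectra <- function(spectra, path) {
  rows <- lapply(spectra, function(s)
    data.frame(case_id = s$case_id, spot_id = s$spot_id,
               compartment = s$compartment, class_label = s$class_label,
               mz = s$mz, intensity = s$intensity, stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df$mz <- format(df$mz, digits = 17, trim = TRUE, scientific = FALSE)
  df$intensity <- format(df$intensity, digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read spectra from file
#'
#' @param path input file. For `"imzml"` the binary `.ibd` companion must
#'   sit next to the XML file.
#' @param format `"native_tabular"` (the package's long-format CSV),
#'   `"mzml"` or `"imzml"` (read-only standard formats).
#' @return list of `mass_spectrum` objects. All readers validate the
#'   spectrum invariants (strictly increasing m/z, non-negative finite
#'   intensities) and fail on violations rather than repairing them.
#' @export
read_spectra <- function(path, format = c("native_tabular", "mzml", "imzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         native_tabular = read_spectra_native(path),
         mzml = read_spectra_mzml(path),
         imzml = read_spectra_imzml(path))
}

read_spectra_native <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "spot_id", "compartment", "class_label", "mz",
            "intensity")
  if (!all(need %in% names(df)))
    stop("parse error: expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) return(list())
  if (!is.numeric(df$mz) || !is.numeric(df$intensity))
    stop("parse error: mz and intensity must be numeric", call. = FALSE)
  key <- paste(df$case_id, df$spot_id, df$compartment, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                function(i) {
    d <- df[i, ]
    rec <- sprintf("%s/%s", d$case_id[1], d$spot_id[1])
    if (any(d$intensity < 0))
      stop("validation error in record ", rec, ": negative intensity",
           call. = FALSE)
    if (any(diff(d$mz) <= 0))
      stop("validation error in record ", rec, ": non-increasing m/z",
           call. = FALSE)
    mass_spectrum(d$mz, d$intensity, case_id = d$case_id[1],
                  spot_id = d$spot_id[1], compartment = d$compartment[1],
                  class_label = d$class_label[1])
  })
  unname(out)
}

# decode one mzML <binaryDataArray> node
decode_binary_array <- function(node) {
  acc <- xml2::xml_attr(xml2::xml_find_all(node, ".//cvParam"), "accession")
  b64 <- xml2::xml_text(xml2::xml_find_first(node, ".//binary"))
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  if ("MS:1000574" %in% acc) raw <- memDecompress(raw, type = "gzip")
  size <- if ("MS:1000521" %in% acc) 4L else 8L
  what <- "double"
  vals <- readBin(raw, what, n = length(raw) %/% size, size = size,
                  endian = "little")
  kind <- if ("MS:1000514" %in% acc) "mz"
          else if ("MS:1000515" %in% acc) "intensity" else "other"
  list(kind = kind, values = vals)
}

read_spectra_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, "//spectrumList/spectrum")
  if (!length(nodes)) stop("parse error: no spectra in ", path, call. = FALSE)
  lapply(seq_along(nodes), function(i) {
    nd <- nodes[[i]]
    id <- xml2::xml_attr(nd, "id")
    arrays <- lapply(xml2::xml_find_all(nd, ".//binaryDataArray"),
                     decode_binary_array)
    kinds <- vapply(arrays, `[[`, character(1), "kind")
    if (!all(c("mz", "intensity") %in% kinds))
      stop("parse error in spectrum ", id %||% i,
           ": missing m/z or intensity array", call. = FALSE)
    mz <- arrays[[match("mz", kinds)]]$values
    it <- arrays[[match("intensity", kinds)]]$values
    if (any(diff(mz) <= 0))
      stop("validation error in spectrum ", id %||% i,
           ": non-increasing m/z", call. = FALSE)
    mass_spectrum(mz, it, case_id = basename(path), spot_id = id %||% as.character(i),
                  extra = list(source = "mzml"))
  })
}

read_spectra_imzml <- function(path) {
  ibd <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd))
    stop("parse error: companion .ibd file not found for ", path,
         call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  # referenceable param groups describe array precision
  grp <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  grp_size <- list()
  for (g in grp) {
    acc <- xml2::xml_attr(xml2::xml_find_all(g, ".//cvParam"), "accession")
    grp_size[[xml2::xml_attr(g, "id")]] <-
      if ("MS:1000521" %in% acc) 4L else 8L
  }
  continuous <- length(xml2::xml_find_all(
    doc, "//fileContent/cvParam[@accession='IMS:1000030']")) > 0
  con <- file(ibd, "rb")
  on.exit(close(con))
  nodes <- xml2::xml_find_all(doc, "//spectrumList/spectrum")
  if (!length(nodes)) stop("parse error: no spectra in ", path, call. = FALSE)
  read_ext <- function(nd_arr, size) {
    cv <- xml2::xml_find_all(nd_arr, ".//cvParam")
    acc <- xml2::xml_attr(cv, "accession")
    val <- xml2::xml_attr(cv, "value")
    offset <- as.numeric(val[match("IMS:1000102", acc)])
    len <- as.integer(val[match("IMS:1000103", acc)])
    seek(con, offset)
    readBin(con, "double", n = len, size = size, endian = "little")
  }
  shared_mz <- NULL
  lapply(seq_along(nodes), function(i) {
    nd <- nodes[[i]]
    id <- xml2::xml_attr(nd, "id")
    arrs <- xml2::xml_find_all(nd, ".//binaryDataArray")
    mz <- NULL; it <- NULL
    for (a in arrs) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(a, ".//referenceableParamGroupRef"), "ref")
      if (is.na(ref))
        stop("parse error in spectrum ", id %||% i,
             ": binaryDataArray without referenceableParamGroupRef",
             call. = FALSE)
      size <- grp_size[[ref]] %||% 8L
      vals <- read_ext(a, size)
      if (grepl("mz", ref, ignore.case = TRUE)) mz <- vals else it <- vals
    }
    if (is.null(mz)) {
      if (continuous && !is.null(shared_mz)) mz <- shared_mz
      else stop("parse error in spectrum ", id %||% i, ": no m/z array",
                call. = FALSE)
    }
    if (continuous && is.null(shared_mz)) shared_mz <<- mz
    if (any(diff(mz) <= 0))
      stop("validation error in spectrum ", id %||% i,
           ": non-increasing m/z", call. = FALSE)
    mass_spectrum(mz, it, case_id = basename(path),
                  spot_id = id %||% as.character(i),
                  extra = list(source = "imzml"))
  })
}

#' Write a peak matrix as delimited text
#'
#' One row per spectrum; columns case_id, spot_id, compartment,
#' class_label, then one column per peak named `mz_<centre>` with the
#' centre printed to 4 decimals.
#'
#' @param pm a [peak_matrix()].
#' @param path output file.
#' @export
write_peak_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "peak_matrix"))
  df <- cbind(pm$meta, as.data.frame(pm$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a peak matrix written by [write_peak_matrix()]
#'
#' @param path input file.
#' @return A [peak_matrix()].
#' @export
read_peak_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  metacols <- c("case_id", "spot_id", "compartment", "class_label")
  if (!all(metacols %in% names(df)))
    stop("schema error: expected columns ", paste(metacols, collapse = ", "),
         call. = FALSE)
  peakcols <- setdiff(names(df), metacols)
  mz <- as.numeric(sub("^mz_", "", peakcols))
  if (length(peakcols) && anyNA(mz))
    stop("schema error: peak columns must be named mz_<centre>",
         call. = FALSE)
  vals <- as.matrix(df[, peakcols, drop = FALSE])
  peak_matrix(vals, df[, metacols, drop = FALSE], mz)
}

check_columns <- function(df, mandatory, what) {
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop(sprintf("schema error in %s: missing column(s) %s; expected %s",
                 what, paste(miss, collapse = ", "),
                 paste(mandatory, collapse = ", ")), call. = FALSE)
}

#' Read a clinical outcome table
#'
#' Delimited text with header; mandatory columns case_id, group, age,
#' tumor_size; follow-up columns (followup_months, recurrence,
#' death_from_disease, time_to_event) may contain missing values, which
#' are flagged in the `"missing_followup"` attribute.
#'
#' @param path input file.
#' @return data.frame of clinical records.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(df)
  check_columns(df, c("case_id", "group", "age", "tumor_size"),
                "clinical table")
  for (v in c("age", "tumor_size"))
    if (!is.numeric(df[[v]]))
      stop(sprintf("schema error: column %s must be numeric", v),
           call. = FALSE)
  fu <- intersect(c("followup_months", "recurrence", "death_from_disease",
                    "time_to_event"), names(df))
  miss <- which(rowSums(is.na(df[, fu, drop = FALSE])) > 0)
  for (v in c("recurrence", "death_from_disease", "re_excision"))
    if (v %in% names(df)) df[[v]] <- as.logical(df[[v]])
  attr(df, "missing_followup") <- miss
  df
}

#' Read a two-reader IHC scoring table
#'
#' Mandatory columns case_id, group, marker, reader1_pct, reader2_pct;
#' the analysis value mean_pct is (re)computed as the reader average.
#'
#' @param path input file.
#' @return data.frame of IHC records.
#' @export
read_ihc_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(df)
  check_columns(df, c("case_id", "group", "marker", "reader1_pct",
                      "reader2_pct"), "IHC table")
  for (v in c("reader1_pct", "reader2_pct")) {
    if (!is.numeric(df[[v]]))
      stop(sprintf("schema error: column %s must be numeric", v),
           call. = FALSE)
    if (any(df[[v]] < 0 | df[[v]] > 100, na.rm = TRUE))
      stop(sprintf("schema error: %s outside [0, 100]", v), call. = FALSE)
  }
  df$mean_pct <- (df$reader1_pct + df$reader2_pct) / 2
  df
}

#' Write ground truth as a JSON sidecar
#'
#' @param ground_truth the `ground_truth` element of [generate_dataset()].
#' @param path output file.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  gt$planted_intensity <- NULL  # bulky; regenerable from config + seed
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
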