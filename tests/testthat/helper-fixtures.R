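# Small in-code fixtures shared across test files.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_cases_per_class = 3, spots_per_compartment = 3,
                   mz_min = 800, mz_max = 1400, n_peaks = 10,
                   noise_sd = 0.2, case_gain_sd = 0.3, case_peak_sd = 0,
                   mass_shift_max = 0.5, seed = 11L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# a raw spectrum marked as baseline-corrected (for stage-gated operations)
corrected_spectrum <- function(mz, intensity, ...) {
  subtract_baseline(mass_spectrum(mz, intensity, ...), 0)
}

b64_doubles <- function(x)
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))

# minimal two-spectrum mzML document built from the schema
write_mini_mzml <- function(path, arrays) {
  spec_xml <- function(i, mz, it) {
    emz <- b64_doubles(mz); eit <- b64_doubles(it)
    sprintf(
      paste0('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
             '<binaryDataArrayList count="2">',
             '<binaryDataArray encodedLength="%d">',
             '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
             '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
             '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
             '<binary>%s</binary></binaryDataArray>',
             '<binaryDataArray encodedLength="%d">',
             '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
             '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
             '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
             '<binary>%s</binary></binaryDataArray>',
             '</binaryDataArrayList></spectrum>'),
      i, i + 1, length(mz), nchar(emz), emz, nchar(eit), eit)
  }
  body <- paste0(mapply(function(i, a) spec_xml(i - 1, a$mz, a$intensity),
                        seq_along(arrays), arrays),
                 collapse = "")
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="x"/></cvList>',
    '<run id="r"><spectrumList count="%d">%s</spectrumList></run></mzML>'),
    length(arrays), body)
  writeLines(doc, path)
  path
}

# minimal processed-mode imzML + .ibd pair
write_mini_imzml <- function(path, arrays) {
  ibd <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  con <- file(ibd, "wb")
  offsets <- list()
  pos <- 0
  for (i in seq_along(arrays)) {
    a <- arrays[[i]]
    writeBin(as.numeric(a$mz), con, size = 8, endian = "little")
    writeBin(as.numeric(a$intensity), con, size = 8, endian = "little")
    offsets[[i]] <- c(mz = pos, it = pos + 8 * length(a$mz))
    pos <- pos + 8 * (length(a$mz) + length(a$intensity))
  }
  close(con)
  arr_xml <- function(ref, offset, len) sprintf(
    paste0('<binaryDataArray encodedLength="0">',
           '<referenceableParamGroupRef ref="%s"/>',
           '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
           '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
           '</binaryDataArray>'), ref, offset, len)
  spec_xml <- function(i, a, off) sprintf(
    '<spectrum index="%d" id="spot=%d" defaultArrayLength="%d"><binaryDataArrayList count="2">%s%s</binaryDataArrayList></spectrum>',
    i - 1, i, length(a$mz),
    arr_xml("mzArray", off[["mz"]], length(a$mz)),
    arr_xml("intensityArray", off[["it"]], length(a$intensity)))
  body <- paste0(mapply(spec_xml, seq_along(arrays), arrays, offsets),
                 collapse = "")
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2"><cv id="MS" fullName="PSI-MS" URI="x"/>',
    '<cv id="IMS" fullName="IMS" URI="x"/></cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<run id="r"><spectrumList count="%d">%s</spectrumList></run></mzML>'),
    length(arrays), body)
  writeLines(doc, path)
  path
}
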