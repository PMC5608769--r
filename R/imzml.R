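# imzML 1.1.0 reader/writer. The format is an XML index (.imzML) plus a binary
# sibling (.ibd) holding the m/z and intensity arrays; the first 16 bytes of
# the ibd are a UUID echoed in the XML. Both "continuous" (shared m/z axis)
# and "processed" (per-pixel peak lists) binary modes are read; only processed
# is written, since peak lists are this pipeline's native form.

IMZML_ACC <- list(
  continuous   = "IMS:1000030",
  processed    = "IMS:1000031",
  uuid         = "IMS:1000080",
  position_x   = "IMS:1000050",
  position_y   = "IMS:1000051",
  ext_offset   = "IMS:1000102",
  ext_arr_len  = "IMS:1000103",
  ext_enc_len  = "IMS:1000104",
  mz_array     = "MS:1000514",
  int_array    = "MS:1000515",
  float64      = "MS:1000523",
  float32      = "MS:1000521",
  pos_scan     = "MS:1000130",
  neg_scan     = "MS:1000129"
)

ibd_sibling <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".ibd")
}

#' Read an imzML/ibd file pair
#'
#' Parses the XML index, decodes each spectrum's m/z and intensity arrays from
#' the ibd sibling, and returns one [msi_spectrum()] per listed pixel. Grid
#' extents are the maxima of the pixel coordinates; scan polarity is taken
#' from the metadata when present and left unset otherwise.
#'
#' @param path path to a `.imzML` file whose `.ibd` sibling sits next to it.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ibd <- ibd_sibling(path)
  if (!file.exists(ibd)) {
    stop(sprintf("missing ibd sibling: %s", ibd), call. = FALSE)
  }
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop(sprintf("malformed imzML XML in %s: %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  xml2::xml_ns_strip(doc)

  acc_of <- function(node) xml2::xml_attr(xml2::xml_find_all(node, ".//cvParam"), "accession")

  # encoding per referenceable param group (keyed by group id)
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  group_info <- list()
  for (g in groups) {
    accs <- acc_of(g)
    kind <- if (IMZML_ACC$mz_array %in% accs) "mz"
            else if (IMZML_ACC$int_array %in% accs) "intensity"
            else NA_character_
    bytes <- if (IMZML_ACC$float64 %in% accs) 8L
             else if (IMZML_ACC$float32 %in% accs) 4L
             else NA_integer_
    group_info[[xml2::xml_attr(g, "id")]] <- list(kind = kind, bytes = bytes)
  }

  doc_accs <- xml2::xml_attr(xml2::xml_find_all(doc, ".//cvParam"), "accession")
  polarity <- if (IMZML_ACC$pos_scan %in% doc_accs) "positive"
              else if (IMZML_ACC$neg_scan %in% doc_accs) "negative"
              else NA_character_

  # Vectorised extraction: one document-order XPath query per attribute is
  # far cheaper than per-spectrum queries on large files.
  all_acc <- function(xpath) {
    xml2::xml_attr(xml2::xml_find_all(doc, xpath), "value")
  }
  xs <- as.integer(all_acc(sprintf(".//run//spectrum//cvParam[@accession='%s']",
                                   IMZML_ACC$position_x)))
  ys <- as.integer(all_acc(sprintf(".//run//spectrum//cvParam[@accession='%s']",
                                   IMZML_ACC$position_y)))
  n_spec <- length(xml2::xml_find_all(doc, ".//run//spectrum"))
  if (length(xs) != n_spec || length(ys) != n_spec || any(is.na(xs)) || any(is.na(ys))) {
    stop("spectra lack pixel position cvParams", call. = FALSE)
  }
  if (n_spec == 0L) return(msi_dataset(list(), polarity = polarity, source_path = path))

  ba_nodes <- xml2::xml_find_all(doc, ".//run//spectrum//binaryDataArray")
  if (length(ba_nodes) != 2L * n_spec) {
    stop("expected exactly one m/z and one intensity array per spectrum", call. = FALSE)
  }
  offsets <- as.numeric(all_acc(sprintf(
    ".//run//spectrum//binaryDataArray/cvParam[@accession='%s']", IMZML_ACC$ext_offset)))
  lens <- as.integer(all_acc(sprintf(
    ".//run//spectrum//binaryDataArray/cvParam[@accession='%s']", IMZML_ACC$ext_arr_len)))
  refs <- xml2::xml_attr(xml2::xml_find_all(
    doc, ".//run//spectrum//binaryDataArray/referenceableParamGroupRef"), "ref")
  if (length(offsets) != length(ba_nodes) || length(lens) != length(ba_nodes)) {
    stop("binary data arrays lack external offset/length cvParams", call. = FALSE)
  }

  kind_bytes <- function(i) {
    if (length(refs) == length(ba_nodes) && !is.null(group_info[[refs[i]]])) {
      info <- group_info[[refs[i]]]
    } else {
      accs <- acc_of(ba_nodes[[i]])
      info <- list(
        kind = if (IMZML_ACC$mz_array %in% accs) "mz"
               else if (IMZML_ACC$int_array %in% accs) "intensity" else NA_character_,
        bytes = if (IMZML_ACC$float64 %in% accs) 8L
                else if (IMZML_ACC$float32 %in% accs) 4L else NA_integer_)
    }
    if (is.na(info$kind)) stop("binary data array of unknown kind", call. = FALSE)
    if (is.na(info$bytes)) {
      stop("unsupported binary encoding: only 32-bit and 64-bit floats are handled",
           call. = FALSE)
    }
    info
  }
  info1 <- kind_bytes(1L); info2 <- kind_bytes(2L)

  con <- file(ibd, "rb")
  on.exit(close(con))
  read_array <- function(i, bytes) {
    seek(con, where = offsets[i], origin = "start")
    readBin(con, "double", n = lens[i], size = bytes, endian = "little")
  }
  spectra <- vector("list", n_spec)
  for (s in seq_len(n_spec)) {
    i1 <- 2L * s - 1L; i2 <- 2L * s
    a1 <- read_array(i1, info1$bytes); a2 <- read_array(i2, info2$bytes)
    if (info1$kind == "mz") {
      spectra[[s]] <- msi_spectrum(a1, a2, x = xs[s], y = ys[s])
    } else {
      spectra[[s]] <- msi_spectrum(a2, a1, x = xs[s], y = ys[s])
    }
  }
  msi_dataset(spectra, polarity = polarity, source_path = path)
}

# Content-derived 16-byte identifier: deterministic so identical datasets give
# byte-identical file pairs (an actual random UUID would break reproducibility).
content_uuid <- function(dataset) {
  sums <- vapply(dataset$spectra, function(s) {
    c(sum(s$mz), sum(s$intensity), sum(s$mz * s$intensity), s$x * 1e6 + s$y)
  }, numeric(4))
  vals <- c(length(dataset$spectra), dataset$grid, if (length(sums)) rowSums(sums) else numeric(4))
  raw <- writeBin(as.numeric(c(sum(vals), sum(vals^2) %% 1e15, prod(1 + abs(vals) %% 97))),
                  raw(), size = 8, endian = "little")
  out <- raw(16)
  for (i in seq_along(raw)) {
    j <- ((i - 1L) %% 16L) + 1L
    out[j] <- as.raw(bitwXor(as.integer(out[j]), as.integer(raw[i])))
  }
  out
}

format_uuid <- function(raw16) {
  h <- paste(format(raw16), collapse = "")
  sprintf("{%s-%s-%s-%s-%s}", substr(h, 1, 8), substr(h, 9, 12),
          substr(h, 13, 16), substr(h, 17, 20), substr(h, 21, 32))
}

#' Write a dataset as a processed-mode imzML/ibd file pair
#'
#' Emits imzML 1.1.0 with per-pixel peak lists ("processed" binary mode) and
#' external arrays in the ibd sibling. Default encoding is 64-bit m/z and
#' 32-bit intensity, the common imzML practice: mass accuracy survives
#' losslessly while intensities tolerate float32 rounding. Writing is fully
#' deterministic (the embedded UUID is derived from the data), so identical
#' datasets produce byte-identical files.
#'
#' @param dataset an [msi_dataset()].
#' @param path output `.imzML` path; the `.ibd` sibling is written next to it.
#' @param mz_bytes,intensity_bytes 4 or 8 (32- or 64-bit IEEE floats).
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path, mz_bytes = 8L, intensity_bytes = 4L) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (!mz_bytes %in% c(4L, 8L) || !intensity_bytes %in% c(4L, 8L)) {
    stop("mz_bytes and intensity_bytes must be 4 or 8", call. = FALSE)
  }
  ibd <- ibd_sibling(path)
  uuid_raw <- content_uuid(dataset)
  uuid_str <- format_uuid(uuid_raw)

  bcon <- tryCatch(suppressWarnings(file(ibd, "wb")),
                   error = function(e) stop(sprintf("cannot write %s", ibd), call. = FALSE))
  writeBin(uuid_raw, bcon)
  offset <- 16
  offsets <- vector("list", length(dataset$spectra))
  for (i in seq_along(dataset$spectra)) {
    s <- dataset$spectra[[i]]
    n <- length(s$mz)
    writeBin(as.numeric(s$mz), bcon, size = mz_bytes, endian = "little")
    writeBin(as.numeric(s$intensity), bcon, size = intensity_bytes, endian = "little")
    offsets[[i]] <- list(mz_off = offset, int_off = offset + n * mz_bytes, n = n)
    offset <- offset + n * (mz_bytes + intensity_bytes)
  }
  close(bcon)

  enc_name <- function(bytes) if (bytes == 8L) c(IMZML_ACC$float64, "64-bit float")
                              else c(IMZML_ACC$float32, "32-bit float")
  mz_enc <- enc_name(mz_bytes); int_enc <- enc_name(intensity_bytes)
  pol_param <- if (identical(dataset$polarity, "positive")) {
    sprintf('        <cvParam cvRef="MS" accession="%s" name="positive scan"/>\n', IMZML_ACC$pos_scan)
  } else if (identical(dataset$polarity, "negative")) {
    sprintf('        <cvParam cvRef="MS" accession="%s" name="negative scan"/>\n', IMZML_ACC$neg_scan)
  } else ""

  spec_xml <- character(length(dataset$spectra))
  for (i in seq_along(dataset$spectra)) {
    s <- dataset$spectra[[i]]
    o <- offsets[[i]]
    spec_xml[i] <- sprintf(
'      <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">
        <referenceableParamGroupRef ref="spectrum1"/>
        <scanList count="1">
          <scan>
            <cvParam cvRef="IMS" accession="%s" name="position x" value="%d"/>
            <cvParam cvRef="IMS" accession="%s" name="position y" value="%d"/>
          </scan>
        </scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="mzArray"/>
            <cvParam cvRef="IMS" accession="%s" name="external offset" value="%s"/>
            <cvParam cvRef="IMS" accession="%s" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="%s" name="external encoded length" value="%s"/>
            <binary/>
          </binaryDataArray>
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="intensityArray"/>
            <cvParam cvRef="IMS" accession="%s" name="external offset" value="%s"/>
            <cvParam cvRef="IMS" accession="%s" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="%s" name="external encoded length" value="%s"/>
            <binary/>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>',
      i - 1L, i, o$n,
      IMZML_ACC$position_x, s$x, IMZML_ACC$position_y, s$y,
      IMZML_ACC$ext_offset, format(o$mz_off, scientific = FALSE),
      IMZML_ACC$ext_arr_len, o$n,
      IMZML_ACC$ext_enc_len, format(o$n * mz_bytes, scientific = FALSE),
      IMZML_ACC$ext_offset, format(o$int_off, scientific = FALSE),
      IMZML_ACC$ext_arr_len, o$n,
      IMZML_ACC$ext_enc_len, format(o$n * intensity_bytes, scientific = FALSE))
  }

  xml <- sprintf(
'<?xml version="1.0" encoding="ISO-8859-1"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
  <cvList count="3">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>
    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>
    <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="IMS" accession="%s" name="processed"/>
      <cvParam cvRef="IMS" accession="%s" name="universally unique identifier" value="%s"/>
      <cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum"/>
    </fileContent>
  </fileDescription>
  <referenceableParamGroupList count="3">
    <referenceableParamGroup id="spectrum1">
      <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>
%s    </referenceableParamGroup>
    <referenceableParamGroup id="mzArray">
      <cvParam cvRef="MS" accession="%s" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
      <cvParam cvRef="MS" accession="%s" name="%s"/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="intensityArray">
      <cvParam cvRef="MS" accession="%s" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
      <cvParam cvRef="MS" accession="%s" name="%s"/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
  </referenceableParamGroupList>
  <softwareList count="1">
    <software id="lipidmsi" version="0.1.0"/>
  </softwareList>
  <scanSettingsList count="1">
    <scanSettings id="scanSettings1">
      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>
    </scanSettings>
  </scanSettingsList>
  <instrumentConfigurationList count="1">
    <instrumentConfiguration id="IC1"/>
  </instrumentConfigurationList>
  <dataProcessingList count="1">
    <dataProcessing id="export">
      <processingMethod order="1" softwareRef="lipidmsi">
        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>
      </processingMethod>
    </dataProcessing>
  </dataProcessingList>
  <run id="run1" defaultInstrumentConfigurationRef="IC1">
    <spectrumList count="%d" defaultDataProcessingRef="export">
%s
    </spectrumList>
  </run>
</mzML>
',
    IMZML_ACC$processed, IMZML_ACC$uuid, uuid_str,
    pol_param,
    IMZML_ACC$mz_array, mz_enc[1], mz_enc[2],
    IMZML_ACC$int_array, int_enc[1], int_enc[2],
    dataset$grid[["n_x"]], dataset$grid[["n_y"]],
    length(dataset$spectra), paste(spec_xml, collapse = "\n"))

  ok <- tryCatch({ writeLines(xml, path, sep = ""); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write %s", path), call. = FALSE)
  invisible(path)
}
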