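#' Read MRM/SRM chromatograms from an mzML file
#'
#' Extracts selected-reaction-monitoring chromatograms (one per Q1/Q3
#' transition) from an mzML file into a trace tibble. Decoding is done with
#' \pkg{mzR} (ProteoWizard backend); the stored time unit is read from the
#' mzML itself and times are converted to minutes regardless of whether the
#' file stores seconds or minutes.
#'
#' @param path Path to an mzML file containing a chromatogram list with
#'   SRM precursor/product isolation-window metadata.
#' @param wanted Optional data frame of transitions to extract, with columns
#'   `precursor_mz` and `product_mz` (optionally `label` to relabel the
#'   matched trace). `NULL` (default) extracts all SRM chromatograms.
#' @param tol Transition match tolerance in Th (default 0.05); a stored
#'   transition matches a wanted one when both Q1 and Q3 differ by at most
#'   `tol`.
#' @param sample_id Sample identifier for the returned traces. Defaults to
#'   an identifier embedded in the chromatogram id (written by
#'   [write_mzml_chromatograms()]) or, failing that, the file name.
#'
#' @return A trace tibble (see [trace_tbl()]), one trace per matched
#'   chromatogram.
#' @export
read_mzml_chromatograms <- function(path, wanted = NULL, tol = 0.05,
                                    sample_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("mzML file not found: ", path), class = "pcisr_io_error")
  }
  handle <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::chromatogramHeader(handle)
  is_srm <- !is.na(hdr$precursorIsolationWindowTargetMZ) &
    !is.na(hdr$productIsolationWindowTargetMZ)
  if (!any(is_srm)) {
    abort(paste0("no SRM chromatograms with Q1/Q3 metadata in ", path),
          class = "pcisr_data_error")
  }
  hdr <- hdr[is_srm, , drop = FALSE]
  time_in_seconds <- mzml_time_unit_is_seconds(path)

  parse_one <- function(i) {
    row <- hdr[i, ]
    chrom <- mzR::chromatogram(handle, row$chromatogramIndex)
    t <- chrom[[1]]
    if (time_in_seconds[[row$chromatogramId]] %||% FALSE) t <- t / 60
    meta <- parse_chromatogram_id(row$chromatogramId)
    tibble::tibble(
      sample_id = sample_id %||% meta$sample_id %||%
        sub("\\.mzML$", "", basename(path), ignore.case = TRUE),
      label = meta$label %||% row$chromatogramId,
      precursor_mz = row$precursorIsolationWindowTargetMZ,
      product_mz = row$productIsolationWindowTargetMZ,
      polarity = c("negative", "positive")[match(row$polarity, c(0, 1))] %||%
        "positive",
      time_min = t,
      intensity = chrom[[2]]
    )
  }
  traces <- purrr::map_dfr(seq_len(nrow(hdr)), parse_one)
  traces$polarity[is.na(traces$polarity)] <- "positive"

  if (!is.null(wanted)) {
    traces <- match_transitions(traces, wanted, tol = tol)
  }
  validate_traces(traces)
}

# Restrict traces to wanted transitions (Q1 and Q3 within tol); errors with
# the available transition list when a wanted key matches nothing.
match_transitions <- function(traces, wanted, tol = 0.05) {
  stopifnot(all(c("precursor_mz", "product_mz") %in% names(wanted)))
  keys <- dplyr::distinct(traces, .data$sample_id, .data$label,
                          .data$precursor_mz, .data$product_mz)
  picked <- purrr::map_dfr(seq_len(nrow(wanted)), function(i) {
    w <- wanted[i, ]
    eps <- 1e-9  # guard the tolerance boundary against fp representation
    hit <- dplyr::filter(keys,
                         abs(.data$precursor_mz - w$precursor_mz) <= tol + eps,
                         abs(.data$product_mz - w$product_mz) <= tol + eps)
    if (nrow(hit) == 0) {
      avail <- paste(sprintf("%.4g -> %.4g", keys$precursor_mz,
                             keys$product_mz), collapse = "; ")
      abort(paste0("transition not found: ", w$precursor_mz, " -> ",
                   w$product_mz, " (available: ", avail, ")"),
            class = "pcisr_transition_error")
    }
    w_label <- if ("label" %in% names(w)) w$label else NULL
    if (!is.null(w_label) && !is.na(w_label)) hit$new_label <- w_label
    hit
  })
  out <- dplyr::semi_join(
    traces, picked,
    by = c("sample_id", "label", "precursor_mz", "product_mz")
  )
  if ("new_label" %in% names(picked)) {
    relab <- dplyr::select(picked, "sample_id", "label", "new_label")
    out <- out |>
      dplyr::left_join(relab, by = c("sample_id", "label")) |>
      dplyr::mutate(label = dplyr::coalesce(.data$new_label, .data$label)) |>
      dplyr::select(-"new_label")
  }
  out
}

# Chromatogram ids written by this package carry sample/label metadata:
# "SRM SIC Q1=350.3 Q3=269.2 sample=s1 label=AEA".
parse_chromatogram_id <- function(id) {
  grab <- function(key) {
    m <- regmatches(id, regexec(paste0(key, "=([^ ]+)"), id))[[1]]
    if (length(m) == 2) utils::URLdecode(m[2]) else NULL
  }
  list(sample_id = grab("sample"), label = grab("label"))
}

# Map chromatogram id -> TRUE when its time array is stored in seconds.
# mzR does not expose the unit, so it is read from the XML directly.
mzml_time_unit_is_seconds <- function(path) {
  doc <- xml2::read_xml(path)
  chroms <- xml2::xml_find_all(doc, "//*[local-name()='chromatogram']")
  out <- list()
  for (ch in chroms) {
    id <- xml2::xml_attr(ch, "id")
    time_param <- xml2::xml_find_first(
      ch, ".//*[local-name()='cvParam'][@accession='MS:1000595']")
    unit <- if (inherits(time_param, "xml_missing")) NA_character_ else
      xml2::xml_attr(time_param, "unitAccession")
    out[[id]] <- identical(unit, "UO:0000010")
  }
  out
}

#' Write traces to an mzML chromatogram file
#'
#' Serializes a trace tibble as an mzML 1.1.0 chromatogram list (one SRM
#' chromatogram per trace, uncompressed 64-bit float arrays, times stored
#' in minutes). The sample id and label are embedded in each chromatogram
#' id so that [read_mzml_chromatograms()] round-trips them.
#'
#' @param traces A trace tibble.
#' @param path Output path (conventionally `.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml_chromatograms <- function(traces, path) {
  traces <- validate_traces(traces)
  parts <- trace_split(traces)

  doc <- xml2::xml_new_root("mzML",
                            xmlns = "http://psi.hupo.org/ms/mzml",
                            version = "1.1.0")
  cvl <- xml2::xml_add_child(doc, "cvList", count = "2")
  xml2::xml_add_child(cvl, "cv", id = "MS",
    fullName = "Proteomics Standards Initiative Mass Spectrometry Ontology",
    URI = "https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo")
  xml2::xml_add_child(cvl, "cv", id = "UO", fullName = "Unit Ontology",
    URI = "https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo")
  fd <- xml2::xml_add_child(doc, "fileDescription")
  fc <- xml2::xml_add_child(fd, "fileContent")
  cv(fc, "MS:1001473", "selected reaction monitoring chromatogram")
  sl <- xml2::xml_add_child(doc, "softwareList", count = "1")
  sw <- xml2::xml_add_child(sl, "software", id = "SW1", version = "0")
  cv(sw, "MS:1000799", "custom unreleased software tool", value = "pcisr")
  icl <- xml2::xml_add_child(doc, "instrumentConfigurationList", count = "1")
  ic <- xml2::xml_add_child(icl, "instrumentConfiguration", id = "IC1")
  cv(ic, "MS:1000031", "instrument model")
  dpl <- xml2::xml_add_child(doc, "dataProcessingList", count = "1")
  dp <- xml2::xml_add_child(dpl, "dataProcessing", id = "DP1")
  pm <- xml2::xml_add_child(dp, "processingMethod", order = "1",
                            softwareRef = "SW1")
  cv(pm, "MS:1000544", "Conversion to mzML")

  run <- xml2::xml_add_child(doc, "run", id = "run1",
                             defaultInstrumentConfigurationRef = "IC1")
  cl <- xml2::xml_add_child(run, "chromatogramList",
                            count = as.character(length(parts)),
                            defaultDataProcessingRef = "DP1")
  for (i in seq_along(parts)) {
    tr <- parts[[i]]
    id <- sprintf("SRM SIC Q1=%s Q3=%s sample=%s label=%s",
                  format(tr$precursor_mz[1], digits = 10),
                  format(tr$product_mz[1], digits = 10),
                  utils::URLencode(tr$sample_id[1], reserved = TRUE),
                  utils::URLencode(tr$label[1], reserved = TRUE))
    ch <- xml2::xml_add_child(cl, "chromatogram",
                              index = as.character(i - 1), id = id,
                              defaultArrayLength = as.character(nrow(tr)))
    cv(ch, "MS:1001473", "selected reaction monitoring chromatogram")
    if (identical(tr$polarity[1], "negative")) {
      cv(ch, "MS:1000129", "negative scan")
    } else {
      cv(ch, "MS:1000130", "positive scan")
    }
    pre <- xml2::xml_add_child(ch, "precursor")
    iw <- xml2::xml_add_child(pre, "isolationWindow")
    cv(iw, "MS:1000827", "isolation window target m/z",
       value = format(tr$precursor_mz[1], digits = 10),
       unitCvRef = "MS", unitAccession = "MS:1000040", unitName = "m/z")
    prod <- xml2::xml_add_child(ch, "product")
    iw2 <- xml2::xml_add_child(prod, "isolationWindow")
    cv(iw2, "MS:1000827", "isolation window target m/z",
       value = format(tr$product_mz[1], digits = 10),
       unitCvRef = "MS", unitAccession = "MS:1000040", unitName = "m/z")
    bal <- xml2::xml_add_child(ch, "binaryDataArrayList", count = "2")
    add_binary_array(bal, tr$time_min, kind = "time")
    add_binary_array(bal, tr$intensity, kind = "intensity")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

cv <- function(node, accession, name, value = "", ...) {
  xml2::xml_add_child(node, "cvParam", cvRef = "MS", accession = accession,
                      name = name, value = value, ...)
}

add_binary_array <- function(parent, x, kind = c("time", "intensity")) {
  kind <- match.arg(kind)
  enc <- jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                       endian = "little"))
  enc <- gsub("\n", "", enc, fixed = TRUE)
  b <- xml2::xml_add_child(parent, "binaryDataArray",
                           encodedLength = as.character(nchar(enc)))
  cv(b, "MS:1000523", "64-bit float")
  cv(b, "MS:1000576", "no compression")
  if (kind == "time") {
    cv(b, "MS:1000595", "time array",
       unitCvRef = "UO", unitAccession = "UO:0000031", unitName = "minute")
  } else {
    cv(b, "MS:1000515", "intensity array", unitCvRef = "MS",
       unitAccession = "MS:1000131", unitName = "number of detector counts")
  }
  xml2::xml_add_child(b, "binary", enc)
}
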