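# Minimal imzML I/O. The format is an mzML-flavoured XML index
# (".imzML") over an external binary file (".ibd") holding the m/z and
# intensity arrays; spectra carry integer grid positions. Both storage
# modes are supported: "continuous" (one shared m/z axis) and
# "processed" (per-spectrum axes). Only 32/64-bit float, uncompressed
# arrays are handled, which covers converter output in practice.

IMS_CV <- c(
  position_x = "IMS:1000050", position_y = "IMS:1000051",
  offset = "IMS:1000102", length = "IMS:1000103", encoded_length = "IMS:1000104",
  continuous = "IMS:1000030", processed = "IMS:1000031",
  pixel_x = "IMS:1000046", pixel_y = "IMS:1000047",
  scan_x_um = "IMS:1000040"
)

#' Read an imzML file into an [msi_spectra]
#'
#' @param path path to the `.imzML` file; the `.ibd` binary is expected
#'   alongside with the same stem.
#' @param stepsize_um,pixelsize_um grid geometry; read from the scan
#'   settings when present, otherwise these defaults apply.
#' @return An [msi_spectra].
#' @export
read_imzml <- function(path, stepsize_um = NULL, pixelsize_um = NULL) {
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  if (!file.exists(ibd_path)) stop("missing .ibd binary next to ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  cv_in <- function(node, accession) {
    length(xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", accession))) > 0
  }
  cv_value <- function(node, accession) {
    n <- xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", accession))
    if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_attr(n, "value")
  }

  # per-array referenceable param groups: which is m/z, and at what precision
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  ginfo <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    kind <- if (cv_in(g, "MS:1000514")) "mz" else if (cv_in(g, "MS:1000515")) "intensity" else NA
    bytes <- if (cv_in(g, "MS:1000523")) 8L else 4L
    ginfo[[id]] <- list(kind = kind, bytes = bytes)
  }

  scan_px <- as.numeric(cv_value(doc, IMS_CV[["scan_x_um"]]))
  if (is.null(stepsize_um)) stepsize_um <- if (!is.na(scan_px)) scan_px else 1
  if (is.null(pixelsize_um)) pixelsize_um <- stepsize_um

  con <- file(ibd_path, "rb")
  on.exit(close(con))
  spectra_nodes <- xml2::xml_find_all(doc, ".//spectrum")
  n <- length(spectra_nodes)
  col <- integer(n); row <- integer(n)
  mzl <- vector("list", n); intl <- vector("list", n)
  read_array <- function(offset, len, bytes) {
    seek(con, where = offset, origin = "start")
    readBin(con, "double", n = len, size = bytes, endian = "little")
  }
  for (i in seq_len(n)) {
    sp <- spectra_nodes[[i]]
    scan <- xml2::xml_find_first(sp, ".//scan")
    col[i] <- as.integer(cv_value(scan, IMS_CV[["position_x"]]))
    row[i] <- as.integer(cv_value(scan, IMS_CV[["position_y"]]))
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(xml2::xml_find_first(bda, ".//referenceableParamGroupRef"), "ref")
      info <- ginfo[[ref]]
      if (is.null(info)) { # param group inline instead of referenced
        info <- list(kind = if (cv_in(bda, "MS:1000514")) "mz" else "intensity",
                     bytes = if (cv_in(bda, "MS:1000523")) 8L else 4L)
      }
      off <- as.numeric(cv_value(bda, IMS_CV[["offset"]]))
      len <- as.integer(cv_value(bda, IMS_CV[["length"]]))
      v <- read_array(off, len, info$bytes)
      if (identical(info$kind, "mz")) mzl[[i]] <- v else intl[[i]] <- v
    }
  }
  msi_spectra(col, row, mzl, intl, stepsize_um, pixelsize_um)
}

#' Write an [msi_spectra] to imzML
#'
#' @param spectra an [msi_spectra].
#' @param path output `.imzML` path; the `.ibd` is written alongside.
#' @param mode `"processed"` (per-spectrum m/z axes) or `"continuous"`
#'   (requires identical m/z axes across spectra, stored once).
#' @return `path`, invisibly.
#' @export
write_imzml <- function(spectra, path, mode = c("processed", "continuous")) {
  stopifnot(inherits(spectra, "msi_spectra"))
  mode <- match.arg(mode)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  if (mode == "continuous") {
    ax <- spectra$mz[[1]]
    same <- all(vapply(spectra$mz, function(m) identical(m, ax), TRUE))
    if (!same) stop("continuous mode requires identical m/z axes")
  }

  uuid <- as.raw(sample.int(256, 16, replace = TRUE) - 1L)
  con <- file(ibd_path, "wb")
  writeBin(uuid, con)
  offset <- 16
  entries <- vector("list", nrow(spectra))
  write_arr <- function(v, bytes) {
    writeBin(as.double(v), con, size = bytes, endian = "little")
    rec <- list(offset = offset, length = length(v), enc = length(v) * bytes)
    offset <<- offset + rec$enc
    rec
  }
  shared_mz <- NULL
  for (i in seq_len(nrow(spectra))) {
    if (mode == "continuous") {
      if (is.null(shared_mz)) shared_mz <- write_arr(spectra$mz[[i]], 8L)
      mz_rec <- shared_mz
    } else {
      mz_rec <- write_arr(spectra$mz[[i]], 8L)
    }
    int_rec <- write_arr(spectra$intensity[[i]], 4L)
    entries[[i]] <- list(mz = mz_rec, int = int_rec)
  }
  close(con)
  uuid_str <- paste(format(uuid), collapse = "")

  cv <- function(acc, name, value = NULL, unit = NULL) {
    v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
    cvref <- if (startsWith(acc, "IMS")) "IMS" else "MS"
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>', cvref, acc, name, v)
  }
  bda <- function(rec, ref) {
    paste0(
      '<binaryDataArray encodedLength="0">',
      sprintf('<referenceableParamGroupRef ref="%s"/>', ref),
      cv(IMS_CV[["offset"]], "external offset", rec$offset),
      cv(IMS_CV[["length"]], "external array length", rec$length),
      cv(IMS_CV[["encoded_length"]], "external encoded length", rec$enc),
      "<binary/></binaryDataArray>")
  }
  spectra_xml <- vapply(seq_len(nrow(spectra)), function(i) {
    e <- entries[[i]]
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1, i, e$int$length),
      '<scanList count="1">', '<scan>',
      cv(IMS_CV[["position_x"]], "position x", spectra$col[i]),
      cv(IMS_CV[["position_y"]], "position y", spectra$row[i]),
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      bda(e$mz, "mzArray"), bda(e$int, "intensityArray"),
      "</binaryDataArrayList></spectrum>")
  }, "")

  mode_cv <- if (mode == "continuous") {
    cv(IMS_CV[["continuous"]], "continuous")
  } else cv(IMS_CV[["processed"]], "processed")
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="MS" URI="http://psi.hupo.org"/>',
    '<cv id="IMS" fullName="IMS" URI="https://ms-imaging.org"/>',
    "</cvList>",
    "<fileDescription><fileContent>",
    mode_cv,
    cv("IMS:1000080", "universally unique identifier", paste0("{", uuid_str, "}")),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv("MS:1000514", "m/z array"), cv("MS:1000523", "64-bit float"),
    cv("MS:1000576", "no compression"),
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    cv("MS:1000515", "intensity array"), cv("MS:1000521", "32-bit float"),
    cv("MS:1000576", "no compression"),
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    '<scanSettingsList count="1"><scanSettings id="scan1">',
    cv(IMS_CV[["pixel_x"]], "max count of pixels x", max(spectra$col)),
    cv(IMS_CV[["pixel_y"]], "max count of pixels y", max(spectra$row)),
    cv(IMS_CV[["scan_x_um"]], "pixel size (x)", attr(spectra, "stepsize_um")),
    "</scanSettings></scanSettingsList>",
    '<run id="run1">',
    sprintf('<spectrumList count="%d">', nrow(spectra)),
    paste(spectra_xml, collapse = ""),
    "</spectrumList></run></mzML>")
  writeLines(xml, path)
  invisible(path)
}

#' Write a binned stack with a grid-geometry sidecar
#'
#' Channels are written as pages of a multi-page TIFF (values min-max
#' scaled per channel, missing as 0) next to a JSON sidecar holding the
#' grid indices, geometry and per-channel scale needed to reconstruct
#' the quantitative values.
#'
#' @param stack an [msi_stack].
#' @param path output `.tiff` path; sidecar written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "msi_stack"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF output")
  }
  pages <- lapply(seq_len(ncol(stack$values)), function(k) {
    img <- stack_channel_image(stack, k)
    img[is.na(img)] <- 0
    mx <- max(img)
    if (mx > 0) img / mx else img
  })
  scales <- vapply(seq_len(ncol(stack$values)), function(k) {
    m <- suppressWarnings(max(stack$values[, k], na.rm = TRUE))
    if (is.finite(m)) m else 0
  }, 0)
  tiff::writeTIFF(pages, path)
  jsonlite::write_json(
    list(channels = stack$channels, channel_names = stack$channel_names,
         stepsize_um = stack$stepsize_um, pixelsize_um = stack$pixelsize_um,
         col = stack$col, row = stack$row, channel_max = scales),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
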