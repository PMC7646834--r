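# imzML 1.1 input/output.
#
# An imzML dataset is a pair of files: an XML part (.imzML) describing the
# acquisition and per-spectrum byte offsets, and a binary part (.ibd)
# holding the arrays. The first 16 bytes of the .ibd are a UUID that must
# match the UUID declared in the XML; an MD5 checksum of the whole .ibd is
# declared alongside. Continuous-mode files store the shared m/z axis once;
# processed-mode files store one axis per pixel.
#
# Precision follows the common vendor export dialect: float64 m/z,
# float32 intensities.

CV_CONTINUOUS <- "IMS:1000030"
CV_PROCESSED <- "IMS:1000031"
CV_UUID <- "IMS:1000080"
CV_MD5 <- "IMS:1000090"
CV_POS_X <- "IMS:1000050"
CV_POS_Y <- "IMS:1000051"
CV_OFFSET <- "IMS:1000102"
CV_ARR_LEN <- "IMS:1000103"
CV_ENC_LEN <- "IMS:1000104"

format_uuid <- function(bytes) {
  h <- paste(sprintf("%02x", as.integer(bytes)), collapse = "")
  sprintf("{%s-%s-%s-%s-%s}",
          substr(h, 1, 8), substr(h, 9, 12), substr(h, 13, 16),
          substr(h, 17, 20), substr(h, 21, 32))
}

cv <- function(accession, name, value = "") {
  sprintf('<cvParam cvRef="%s" accession="%s" name="%s" value="%s"/>',
          if (startsWith(accession, "IMS")) "IMS" else "MS",
          accession, name, value)
}

#' Write an MSI dataset to an imzML file pair
#'
#' Produces `<path>.imzML` and `<path>.ibd` (continuous or processed
#' binary mode following the dataset's mode), with the UUID written to both
#' files and an MD5 checksum of the binary part recorded in the XML.
#' m/z values are stored as 64-bit floats, intensities as 32-bit floats,
#' so a write/read round trip preserves intensities to float32 precision.
#'
#' @param dataset an [msi_dataset()]; must contain at least one pixel.
#' @param path output path; a trailing `.imzML` extension is stripped.
#' @return invisibly, a list with elements `imzml` and `ibd` (file paths).
#' @export
write_imzml <- function(dataset, path) {
  if (!inherits(dataset, "msi_dataset")) stopf("dataset must be an msi_dataset")
  n <- n_pixels(dataset)
  if (n == 0) stopf("cannot write an empty dataset")
  path <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  ibd_path <- paste0(path, ".ibd")
  xml_path <- paste0(path, ".imzML")

  uuid_bytes <- with_seed(
    derive_seed(n, "imzml-uuid", length(unlist(dataset$mz))),
    sample(0:255, 16, replace = TRUE)
  )

  con <- file(ibd_path, "wb")
  writeBin(as.raw(uuid_bytes), con)
  offset <- 16
  write_array <- function(x, size) {
    writeBin(as.double(x), con, size = size)
    start <- offset
    offset <<- offset + length(x) * size
    c(offset = start, length = length(x), encoded = length(x) * size)
  }
  if (dataset$mode == "continuous") {
    mz_ref <- write_array(dataset$mz, 8)
    int_refs <- lapply(seq_len(n), function(i) {
      write_array(dataset$intensities[i, ], 4)
    })
    mz_refs <- rep(list(mz_ref), n)
  } else {
    mz_refs <- vector("list", n)
    int_refs <- vector("list", n)
    for (i in seq_len(n)) {
      mz_refs[[i]] <- write_array(dataset$mz[[i]], 8)
      int_refs[[i]] <- write_array(dataset$intensities[[i]], 4)
    }
  }
  close(con)
  md5 <- unname(tools::md5sum(ibd_path))

  mode_cv <- if (dataset$mode == "continuous") {
    cv(CV_CONTINUOUS, "continuous")
  } else {
    cv(CV_PROCESSED, "processed")
  }

  array_block <- function(ref, group) {
    paste0(
      '<binaryDataArray encodedLength="0">',
      sprintf('<referenceableParamGroupRef ref="%s"/>', group),
      cv(CV_OFFSET, "external offset", ref[["offset"]]),
      cv(CV_ARR_LEN, "external array length", ref[["length"]]),
      cv(CV_ENC_LEN, "external encoded length", ref[["encoded"]]),
      "<binary/></binaryDataArray>"
    )
  }
  spectra <- vapply(seq_len(n), function(i) {
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1, i, int_refs[[i]][["length"]]),
      "<scanList count=\"1\"><scan>",
      cv(CV_POS_X, "position x", dataset$coords$x[i]),
      cv(CV_POS_Y, "position y", dataset$coords$y[i]),
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      array_block(mz_refs[[i]], "mzArray"),
      array_block(int_refs[[i]], "intensityArray"),
      "</binaryDataArrayList></spectrum>"
    )
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology"/></cvList>',
    "<fileDescription><fileContent>",
    mode_cv,
    cv(CV_UUID, "universally unique identifier", format_uuid(uuid_bytes)),
    cv(CV_MD5, "ibd MD5", toupper(md5)),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv("MS:1000514", "m/z array"),
    cv("MS:1000523", "64-bit float"),
    cv("IMS:1000101", "external data", "true"),
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    cv("MS:1000515", "intensity array"),
    cv("MS:1000521", "32-bit float"),
    cv("IMS:1000101", "external data", "true"),
    "</referenceableParamGroup></referenceableParamGroupList>",
    "<run id=\"run1\">",
    sprintf('<spectrumList count="%d">', n),
    paste(spectra, collapse = ""),
    "</spectrumList></run></mzML>"
  )
  writeLines(xml, xml_path)
  invisible(list(imzml = xml_path, ibd = ibd_path))
}

#' Read an imzML file pair into an MSI dataset
#'
#' Loads all pixels of a continuous- or processed-mode imzML file. The
#' binary mode is taken from the file's declared access type (falling back
#' to axis comparison when absent). The .ibd UUID must match the XML's
#' declared UUID and, when an MD5 checksum is declared, the .ibd must match
#' it; mismatches and truncated binaries raise format errors.
#'
#' @param path path to the `.imzML` file (the `.ibd` must sit next to it).
#' @param patient_id,condition optional metadata attached to the result.
#' @param validate_checksum verify the declared ibd MD5 (default TRUE).
#' @return an [msi_dataset()].
#' @export
read_imzml <- function(path, patient_id = NULL, condition = NULL,
                       validate_checksum = TRUE) {
  if (!file.exists(path)) stopf("imzML file not found: %s", path)
  ibd_path <- paste0(sub("\\.imzML$", "", path, ignore.case = TRUE), ".ibd")
  if (!file.exists(ibd_path)) stopf("missing .ibd file: %s", ibd_path)

  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  param <- function(node, accession) {
    xml2::xml_attr(
      xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", accession)),
      "value"
    )
  }
  has_param <- function(node, accession) {
    !is.na(xml2::xml_attr(
      xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", accession)),
      "accession"
    ))
  }

  content <- xml2::xml_find_first(doc, ".//fileContent")
  declared_mode <- if (has_param(content, CV_CONTINUOUS)) "continuous"
                   else if (has_param(content, CV_PROCESSED)) "processed"
                   else NA_character_

  ibd_size <- file.info(ibd_path)$size
  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  ibd_uuid <- readBin(con, "raw", 16)
  declared_uuid <- param(content, CV_UUID)
  if (!is.na(declared_uuid) && nzchar(declared_uuid)) {
    if (!identical(tolower(gsub("[{}-]", "", declared_uuid)),
                   paste(sprintf("%02x", as.integer(ibd_uuid)), collapse = ""))) {
      stopf("imzML format error: .ibd UUID does not match the declared UUID")
    }
  }
  if (validate_checksum) {
    declared_md5 <- param(content, CV_MD5)
    if (!is.na(declared_md5) && nzchar(declared_md5)) {
      actual <- toupper(unname(tools::md5sum(ibd_path)))
      if (!identical(actual, toupper(declared_md5))) {
        stopf("imzML format error: .ibd MD5 checksum mismatch")
      }
    }
  }

  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(spectra) == 0) stopf("imzML format error: no spectra")

  # Map referenceable param groups to array roles so binaryDataArray nodes
  # can be resolved either via group references or inline cvParams.
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  group_role <- vapply(groups, function(g) {
    if (has_param(g, "MS:1000514")) "mz"
    else if (has_param(g, "MS:1000515")) "intensity"
    else NA_character_
  }, character(1))
  names(group_role) <- xml2::xml_attr(groups, "id")

  read_array <- function(node) {
    offset <- as.numeric(param(node, CV_OFFSET))
    len <- as.integer(param(node, CV_ARR_LEN))
    enc <- as.numeric(param(node, CV_ENC_LEN))
    ref <- xml2::xml_attr(
      xml2::xml_find_first(node, ".//referenceableParamGroupRef"), "ref"
    )
    role <- if (!is.na(ref) && ref %in% names(group_role)) group_role[[ref]]
            else if (has_param(node, "MS:1000514")) "mz"
            else if (has_param(node, "MS:1000515")) "intensity"
            else NA_character_
    size <- as.integer(enc / len)
    if (!size %in% c(4L, 8L)) stopf("imzML format error: unsupported precision")
    if (offset + enc > ibd_size) {
      stopf("imzML format error: array at offset %.0f runs past end of .ibd (truncated file?)",
            offset)
    }
    seek(con, where = offset, origin = "start")
    values <- readBin(con, "double", n = len, size = size)
    if (length(values) != len) stopf("imzML format error: truncated .ibd")
    list(role = role, offset = offset, values = values)
  }

  n <- length(spectra)
  xs <- integer(n); ys <- integer(n)
  mz_list <- vector("list", n); int_list <- vector("list", n)
  mz_offsets <- numeric(n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    xs[i] <- as.integer(param(sp, CV_POS_X))
    ys[i] <- as.integer(param(sp, CV_POS_Y))
    arrays <- lapply(xml2::xml_find_all(sp, ".//binaryDataArray"), read_array)
    roles <- vapply(arrays, `[[`, character(1), "role")
    if (!all(c("mz", "intensity") %in% roles)) {
      stopf("imzML format error: spectrum %d lacks m/z or intensity array", i)
    }
    mzi <- arrays[[match("mz", roles)]]
    mz_list[[i]] <- mzi$values
    mz_offsets[i] <- mzi$offset
    int_list[[i]] <- pmax(arrays[[match("intensity", roles)]]$values, 0)
  }

  mode <- if (!is.na(declared_mode)) declared_mode
          else if (length(unique(mz_offsets)) == 1) "continuous" else "processed"

  if (mode == "continuous") {
    msi_dataset(
      coords = data.frame(x = xs, y = ys),
      mz = mz_list[[1]],
      intensities = do.call(rbind, int_list),
      mode = "continuous",
      patient_id = patient_id, condition = condition
    )
  } else {
    msi_dataset(
      coords = data.frame(x = xs, y = ys),
      mz = mz_list, intensities = int_list, mode = "processed",
      patient_id = patient_id, condition = condition
    )
  }
}
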