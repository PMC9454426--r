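#' Write an MSI dataset as continuous-mode imzML
#'
#' Produces an `.imzML`/`.ibd` file pair: the shared m/z axis is stored
#' once as 64-bit floats, each spectrum's intensities as 32-bit floats
#' (the common imzML convention). Internal 0-based pixel coordinates are
#' shifted to imzML's 1-based grid. The `.ibd` starts with the 16-byte
#' UUID echoed in the XML, and an MD5 checksum of the binary file is
#' recorded.
#'
#' @param dataset An [msi_dataset()].
#' @param path Output path; the `.imzML` suffix is added if absent and
#'   the `.ibd` is written alongside.
#' @return Invisibly, the `.imzML` path.
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "msi_dataset"))
  path <- sub("\\.imzml$", ".imzML", path, ignore.case = TRUE)
  if (!grepl("\\.imzML$", path)) path <- paste0(path, ".imzML")
  ibd_path <- sub("\\.imzML$", ".ibd", path)

  n_px <- nrow(dataset$intensities)
  nb <- length(dataset$mz)
  uuid_bytes <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  uuid_str <- format_uuid(uuid_bytes)

  con <- file(ibd_path, "wb")
  ok <- FALSE
  tryCatch({
    writeBin(uuid_bytes, con)
    writeBin(as.numeric(dataset$mz), con, size = 8, endian = "little")
    if (n_px > 0) {
      for (i in seq_len(n_px)) {
        writeBin(as.numeric(dataset$intensities[i, ]), con, size = 4,
                 endian = "little")
      }
    }
    ok <- TRUE
  }, finally = close(con))
  if (!ok) stop("write_imzml: failed writing ", ibd_path)
  md5 <- unname(tools::md5sum(ibd_path))

  mz_offset <- 16
  int_offsets <- mz_offset + nb * 8 + (seq_len(n_px) - 1) * nb * 4
  W <- if (n_px) max(dataset$pixels$x) + 1L else 0L
  H <- if (n_px) max(dataset$pixels$y) + 1L else 0L

  spec_xml <- character(n_px)
  for (i in seq_len(n_px)) {
    spec_xml[i] <- sprintf(
      paste0(
        '    <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">\n',
        '     <scanList count="1">\n',
        '      <cvParam cvRef="MS" accession="MS:1000795" name="no combination"/>\n',
        '      <scan>\n',
        '       <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
        '       <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
        '      </scan>\n',
        '     </scanList>\n',
        '     <binaryDataArrayList count="2">\n',
        '      <binaryDataArray encodedLength="0">\n',
        '       <referenceableParamGroupRef ref="mzArray"/>\n',
        '       <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
        '       <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n',
        '       <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
        '       <binary/>\n',
        '      </binaryDataArray>\n',
        '      <binaryDataArray encodedLength="0">\n',
        '       <referenceableParamGroupRef ref="intensityArray"/>\n',
        '       <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
        '       <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n',
        '       <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
        '       <binary/>\n',
        '      </binaryDataArray>\n',
        '     </binaryDataArrayList>\n',
        '    </spectrum>'),
      i, i - 1L, nb,
      dataset$pixels$x[i] + 1L, dataset$pixels$y[i] + 1L,
      nb, nb * 8, mz_offset,
      nb, nb * 4, int_offsets[i])
  }

  header <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    ' <cvList count="3">\n',
    '  <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '  <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
    '  <cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>\n',
    ' </cvList>\n',
    ' <fileDescription>\n',
    '  <fileContent>\n',
    '   <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="%s"/>\n',
    '  </fileContent>\n',
    ' </fileDescription>\n',
    ' <referenceableParamGroupList count="2">\n',
    '  <referenceableParamGroup id="mzArray">\n',
    '   <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
    '   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '   <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '  </referenceableParamGroup>\n',
    '  <referenceableParamGroup id="intensityArray">\n',
    '   <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
    '   <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>\n',
    '   <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '  </referenceableParamGroup>\n',
    ' </referenceableParamGroupList>\n',
    ' <softwareList count="1"><software id="maldinet" version="0.1.0"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="maldinet"/></software></softwareList>\n',
    ' <scanSettingsList count="1">\n',
    '  <scanSettings id="scansettings1">\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n',
    '  </scanSettings>\n',
    ' </scanSettingsList>\n',
    ' <instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>\n',
    ' <dataProcessingList count="1">\n',
    '  <dataProcessing id="DP1">\n',
    '   <processingMethod order="1" softwareRef="maldinet">\n',
    '    <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>\n',
    '   </processingMethod>\n',
    '  </dataProcessing>\n',
    ' </dataProcessingList>\n',
    ' <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '  <spectrumList count="%d" defaultDataProcessingRef="DP1">\n'),
    uuid_str, md5, W, H, n_px)

  footer <- '  </spectrumList>\n </run>\n</mzML>\n'
  writeLines(c(header, spec_xml, footer), path, sep = "")
  invisible(path)
}

format_uuid <- function(bytes) {
  h <- paste(format(bytes), collapse = "")
  sprintf("{%s-%s-%s-%s-%s}", substr(h, 1, 8), substr(h, 9, 12),
          substr(h, 13, 16), substr(h, 17, 20), substr(h, 21, 32))
}

#' Read an imzML file pair
#'
#' Parses continuous- or processed-mode imzML 1.1 with external binary
#' data. All spectra must share one m/z axis (always true for
#' continuous mode; for processed mode, pass `scheme` to re-bin each
#' spectrum onto a common axis while reading). Coordinates are shifted
#' to the package's 0-based convention.
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit next to it).
#' @param annotations Optional `core_annotations` from
#'   [read_annotations()]; without it all pixels are grouped into a
#'   single unlabeled pseudo-core.
#' @param scheme Optional [binning_scheme()] applied on the fly
#'   (required for processed-mode files with non-uniform axes).
#' @return An [msi_dataset()] (raw axis unless `scheme` was applied).
#' @export
read_imzml <- function(path, annotations = NULL, scheme = NULL) {
  if (!file.exists(path)) stop("read_imzml: no such file: ", path)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  if (!file.exists(ibd_path)) {
    stop("read_imzml: missing binary file: ", ibd_path)
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  # dtype lookup from the referenceable param groups
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  gsize <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    acc <- xml2::xml_attr(xml2::xml_find_all(g, "./cvParam"), "accession")
    size <- if ("MS:1000523" %in% acc) 8L
            else if ("MS:1000521" %in% acc) 4L
            else NA_integer_
    gsize[[id]] <- size
  }

  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  n_px <- length(spectra)
  cv_val <- function(node, accession) {
    nd <- xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']", accession))
    xml2::xml_attr(nd, "value")
  }

  xs <- ys <- integer(n_px)
  mz_meta <- vector("list", n_px)
  int_meta <- vector("list", n_px)
  for (i in seq_len(n_px)) {
    sp <- spectra[[i]]
    xs[i] <- as.integer(cv_val(sp, "IMS:1000050")) - 1L
    ys[i] <- as.integer(cv_val(sp, "IMS:1000051")) - 1L
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    for (a in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(a, "./referenceableParamGroupRef"), "ref")
      acc <- xml2::xml_attr(xml2::xml_find_all(a, "./cvParam"), "accession")
      is_mz <- identical(ref, "mzArray") || "MS:1000514" %in% acc
      size <- if (!is.na(ref) && !is.null(gsize[[ref]])) gsize[[ref]]
              else if ("MS:1000523" %in% acc) 8L
              else if ("MS:1000521" %in% acc) 4L else NA_integer_
      meta <- list(
        offset = as.numeric(cv_val(a, "IMS:1000102")),
        n = as.integer(cv_val(a, "IMS:1000103")),
        size = size)
      if (is.na(meta$size)) stop("read_imzml: unsupported binary data type")
      if (is_mz) mz_meta[[i]] <- meta else int_meta[[i]] <- meta
    }
  }

  if (n_px == 0) {
    return(msi_dataset(matrix(0, 0, 0),
                       data.frame(x = integer(0), y = integer(0),
                                  core_id = character(0),
                                  tissue = integer(0)),
                       data.frame(core_id = character(0),
                                  label = character(0)),
                       mz = numeric(0), class_order = character(0)))
  }

  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  read_array <- function(meta) {
    seek(con, where = meta$offset, origin = "start")
    readBin(con, what = "double", n = meta$n, size = meta$size,
            endian = "little")
  }

  mz_cache <- new.env(parent = emptyenv())
  get_mz <- function(meta) {
    key <- sprintf("o%.0f", meta$offset)
    if (!is.null(mz_cache[[key]])) return(mz_cache[[key]])
    v <- read_array(meta)
    if (is.unsorted(v, strictly = FALSE)) {
      stop("read_imzml: non-monotone m/z array")
    }
    mz_cache[[key]] <- v
    v
  }

  if (is.null(scheme)) {
    mz0 <- get_mz(mz_meta[[1]])
    ints <- matrix(0, n_px, length(mz0))
    for (i in seq_len(n_px)) {
      mzi <- get_mz(mz_meta[[i]])
      if (!isTRUE(all.equal(mzi, mz0))) {
        stop("read_imzml: spectra have differing m/z axes; pass `scheme` ",
             "to re-bin processed-mode data on the fly")
      }
      ints[i, ] <- read_array(int_meta[[i]])
    }
    axis <- mz0
    out_scheme <- NULL
  } else {
    stopifnot(inherits(scheme, "binning_scheme"))
    ints <- matrix(0, n_px, scheme$n_bins)
    for (i in seq_len(n_px)) {
      mzi <- get_mz(mz_meta[[i]])
      vi <- read_array(int_meta[[i]])
      bin <- mz_to_bin(scheme, mzi)
      keep <- !is.na(bin)
      if (any(keep)) {
        agg <- rowsum(vi[keep], bin[keep])
        ints[i, as.integer(rownames(agg))] <- agg[, 1]
      }
    }
    axis <- bin_centers(scheme)
    out_scheme <- scheme
  }

  px <- data.frame(x = xs, y = ys, stringsAsFactors = FALSE)
  if (is.null(annotations)) {
    px$core_id <- "core_all"
    px$tissue <- 1L
    cores <- data.frame(core_id = "core_all", label = "unlabeled",
                        stringsAsFactors = FALSE)
    cls <- "unlabeled"
  } else {
    stopifnot(inherits(annotations, "core_annotations"))
    if (is.null(annotations$mask)) {
      stop("read_imzml: annotations carry no per-pixel mask")
    }
    key <- paste(annotations$mask$x, annotations$mask$y)
    idx <- match(paste(xs, ys), key)
    if (anyNA(idx)) {
      stop("read_imzml: ", sum(is.na(idx)),
           " pixel(s) missing from the annotation mask")
    }
    px$core_id <- annotations$mask$core_id[idx]
    px$tissue <- annotations$mask$tissue[idx]
    cores <- annotations$cores
    cls <- annotations$classes
  }
  msi_dataset(ints, px, cores, mz = axis, scheme = out_scheme,
              class_order = cls)
}

#' Save / load the package's fast single-file container
#'
#' imzML is the interchange format; for repeated local use a dataset can
#' be stored as one compressed binary `.msid` file, which round-trips
#' exactly and loads much faster than XML-adjacent formats.
#'
#' @param dataset An [msi_dataset()].
#' @param path File path (conventionally `.msid`).
#' @return `write_msid`: the path, invisibly. `read_msid`: the dataset.
#' @export
write_msid <- function(dataset, path) {
  stopifnot(inherits(dataset, "msi_dataset"))
  saveRDS(list(format = "maldinet-msid", version = 1L, dataset = dataset),
          path)
  invisible(path)
}

#' @rdname write_msid
#' @export
read_msid <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "maldinet-msid")) {
    stop("read_msid: not a maldinet msid file")
  }
  validate_msi_dataset(obj$dataset)
}
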