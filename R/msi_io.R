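#' @title MSI datacube containers and input/output
#' @description Core array types for pixel spectra and datacubes, plus
#'   readers/writers for the imzML interchange format (processed/centroided
#'   mode) and integer label masks (TSV or PNG).
#' @name msi_io
NULL

#' Construct a pixel spectrum
#'
#' One centroided mass spectrum recorded at one raster position.
#' Coordinates are 0-based `(row, col)` in memory; the imzML writer maps
#' them to the format's 1-based x/y convention (`x = col + 1`,
#' `y = row + 1`).
#'
#' @param mz Numeric vector of m/z values (Da), strictly ascending.
#' @param intensity Numeric vector of non-negative finite intensities,
#'   same length as `mz`.
#' @param coord Integer vector `c(row, col)`, 0-based.
#' @return Object of class `pixel_spectrum`.
#' @export
pixel_spectrum <- function(mz, intensity, coord) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  coord <- as.integer(coord)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity lengths differ", call. = FALSE)
  }
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    stop("mz must be strictly ascending", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (length(coord) != 2 || any(is.na(coord)) || any(coord < 0)) {
    stop("coord must be a non-negative (row, col) pair", call. = FALSE)
  }
  structure(list(mz = mz, intensity = intensity, coord = coord),
            class = "pixel_spectrum")
}

#' Construct an MSI datacube
#'
#' A grid of centroided pixel spectra. Background pixels carry no spectrum
#' (processed-mode semantics): only tissue positions appear in `spectra`.
#'
#' @param spectra List of [pixel_spectrum()] objects.
#' @param grid_shape Integer `c(rows, cols)`.
#' @param pixel_size Raster size in micrometres (default 25).
#' @param polarity `"negative"` (the only mode the pipeline handles).
#' @return Object of class `msi_datacube`.
#' @export
msi_datacube <- function(spectra, grid_shape, pixel_size = 25,
                         polarity = "negative") {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(grid_shape < 1)) {
    stop("grid_shape must be positive (rows, cols)", call. = FALSE)
  }
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  coords <- t(vapply(spectra, function(s) s$coord, integer(2)))
  if (length(spectra) > 0) {
    if (any(coords[, 1] >= grid_shape[1]) || any(coords[, 2] >= grid_shape[2])) {
      stop("spectrum coordinate outside grid", call. = FALSE)
    }
    key <- coords[, 1] * grid_shape[2] + coords[, 2]
    if (anyDuplicated(key)) {
      stop("coordinate collision: duplicate pixel coordinates", call. = FALSE)
    }
  }
  structure(list(spectra = spectra, grid_shape = grid_shape,
                 pixel_size = pixel_size, polarity = polarity),
            class = "msi_datacube")
}

#' @export
print.msi_datacube <- function(x, ...) {
  cat(sprintf("<msi_datacube> %d x %d grid, %d spectra, %g um pixels, %s mode\n",
              x$grid_shape[1], x$grid_shape[2], length(x$spectra),
              x$pixel_size, x$polarity))
  invisible(x)
}

#' Number of pixel spectra in a datacube
#' @param cube An `msi_datacube`.
#' @return Integer count of non-background pixels.
#' @export
n_pixels <- function(cube) length(cube$spectra)

.cube_coords <- function(cube) {
  t(vapply(cube$spectra, function(s) s$coord, integer(2)))
}

# deterministic pseudo-UUID for the imzML/ibd pair, derived from the cube
# geometry (the format requires one; cryptographic uniqueness is not needed
# for files the package itself pairs on disk)
.cube_uuid <- function(cube) {
  h <- c(cube$grid_shape, length(cube$spectra),
         as.integer(cube$pixel_size * 100))
  x <- rep_len(as.integer(h), 16)
  x <- (x * 37L + seq_len(16) * 101L) %% 256L
  hex <- paste(sprintf("%02x", x), collapse = "")
  paste(substr(hex, 1, 8), substr(hex, 9, 12), substr(hex, 13, 16),
        substr(hex, 17, 20), substr(hex, 21, 32), sep = "-")
}

.uuid_bytes <- function(uuid) {
  hex <- gsub("-", "", uuid)
  as.raw(strtoi(substring(hex, seq(1, 31, 2), seq(2, 32, 2)), 16L))
}

#' Write a datacube as an imzML/ibd pair
#'
#' Writes processed (centroided) mode imzML: m/z as 64-bit floats,
#' intensities as 32-bit floats, external binary data in the companion
#' `.ibd` file prefixed by the 16-byte UUID the imzML header declares.
#'
#' @param cube An [msi_datacube()] with at least one spectrum.
#' @param path Output path; the `.imzML`/`.ibd` extension is replaced or
#'   appended as needed.
#' @return Invisibly, the path of the `.imzML` file.
#' @export
write_imzml <- function(cube, path) {
  if (!inherits(cube, "msi_datacube")) stop("not an msi_datacube",
                                            call. = FALSE)
  if (length(cube$spectra) == 0) stop("cannot write an empty datacube",
                                      call. = FALSE)
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  imzml_path <- paste0(base, ".imzML")
  ibd_path <- paste0(base, ".ibd")
  uuid <- .cube_uuid(cube)

  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(.uuid_bytes(uuid), con)
  offset <- 16
  meta <- vector("list", length(cube$spectra))
  for (i in seq_along(cube$spectra)) {
    s <- cube$spectra[[i]]
    n <- length(s$mz)
    writeBin(as.numeric(s$mz), con, size = 8, endian = "little")
    mz_off <- offset; mz_len <- 8L * n; offset <- offset + mz_len
    writeBin(as.numeric(s$intensity), con, size = 4, endian = "little")
    int_off <- offset; int_len <- 4L * n; offset <- offset + int_len
    meta[[i]] <- list(n = n, mz_off = mz_off, mz_len = mz_len,
                      int_off = int_off, int_len = int_len,
                      x = s$coord[2] + 1L, y = s$coord[1] + 1L)
  }

  cv <- function(ref, acc, name, value = NULL) {
    v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>',
            ref, acc, name, v)
  }
  spectra_xml <- vapply(seq_along(meta), function(i) {
    m <- meta[[i]]
    paste0(
      sprintf('<spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">',
              i, i - 1L, m$n),
      cv("MS", "MS:1000129", "negative scan"),
      cv("MS", "MS:1000127", "centroid spectrum"),
      '<scanList count="1">', cv("MS", "MS:1000795", "no combination"),
      '<scan>',
      cv("IMS", "IMS:1000050", "position x", m$x),
      cv("IMS", "IMS:1000051", "position y", m$y),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      cv("IMS", "IMS:1000103", "external array length", m$n),
      cv("IMS", "IMS:1000104", "external encoded length", m$mz_len),
      cv("IMS", "IMS:1000102", "external offset", m$mz_off),
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      cv("IMS", "IMS:1000103", "external array length", m$n),
      cv("IMS", "IMS:1000104", "external encoded length", m$int_len),
      cv("IMS", "IMS:1000102", "external offset", m$int_off),
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, character(1))

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    cv("IMS", "IMS:1000031", "processed"),
    cv("IMS", "IMS:1000080", "universally unique identifier",
       paste0("{", uuid, "}")),
    cv("MS", "MS:1000127", "centroid spectrum"),
    cv("MS", "MS:1000129", "negative scan"),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv("MS", "MS:1000514", "m/z array"),
    cv("MS", "MS:1000523", "64-bit float"),
    cv("MS", "MS:1000576", "no compression"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    cv("MS", "MS:1000515", "intensity array"),
    cv("MS", "MS:1000521", "32-bit float"),
    cv("MS", "MS:1000576", "no compression"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<scanSettingsList count="1"><scanSettings id="scansettings1">',
    cv("IMS", "IMS:1000042", "max count of pixels x", cube$grid_shape[2]),
    cv("IMS", "IMS:1000043", "max count of pixels y", cube$grid_shape[1]),
    cv("IMS", "IMS:1000046", "pixel size (x)", cube$pixel_size),
    '</scanSettings></scanSettingsList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    '</instrumentConfigurationList>',
    '<run id="run1">',
    sprintf('<spectrumList count="%d">', length(meta)),
    paste(spectra_xml, collapse = ""),
    '</spectrumList></run></mzML>\n')
  writeLines(doc, imzml_path, sep = "")
  invisible(imzml_path)
}

#' Read an imzML/ibd pair into a datacube
#'
#' Only processed (centroided) mode is supported; a continuous-mode file
#' raises an error. File coordinates (1-based x/y) become 0-based
#' `(row, col) = (y - 1, x - 1)`.
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit next to it).
#' @return An [msi_datacube()].
#' @export
read_imzml <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  doc <- xml2::read_xml(paste0(base, ".imzML"))
  xml2::xml_ns_strip(doc)

  mode_nodes <- xml2::xml_find_all(
    doc, "//fileContent/cvParam[@accession='IMS:1000030' or @accession='IMS:1000031']")
  modes <- xml2::xml_attr(mode_nodes, "accession")
  if ("IMS:1000030" %in% modes) {
    stop("continuous-mode imzML is not supported", call. = FALSE)
  }
  if (!"IMS:1000031" %in% modes) {
    stop("file does not declare processed mode", call. = FALSE)
  }

  rows <- as.integer(xml2::xml_attr(xml2::xml_find_first(
    doc, "//scanSettings/cvParam[@accession='IMS:1000043']"), "value"))
  cols <- as.integer(xml2::xml_attr(xml2::xml_find_first(
    doc, "//scanSettings/cvParam[@accession='IMS:1000042']"), "value"))
  px_node <- xml2::xml_find_first(
    doc, "//scanSettings/cvParam[@accession='IMS:1000046']")
  pixel_size <- if (inherits(px_node, "xml_missing")) 25 else
    as.numeric(xml2::xml_attr(px_node, "value"))

  ibd <- file(paste0(base, ".ibd"), "rb")
  on.exit(close(ibd), add = TRUE)

  spectra_nodes <- xml2::xml_find_all(doc, "//run/spectrumList/spectrum")
  spectra <- lapply(spectra_nodes, function(sp) {
    x <- as.integer(xml2::xml_attr(xml2::xml_find_first(
      sp, ".//scan/cvParam[@accession='IMS:1000050']"), "value"))
    y <- as.integer(xml2::xml_attr(xml2::xml_find_first(
      sp, ".//scan/cvParam[@accession='IMS:1000051']"), "value"))
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    vals <- list()
    for (arr in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, "./referenceableParamGroupRef"), "ref")
      off <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
        arr, "./cvParam[@accession='IMS:1000102']"), "value"))
      n <- as.integer(xml2::xml_attr(xml2::xml_find_first(
        arr, "./cvParam[@accession='IMS:1000103']"), "value"))
      seek(ibd, where = off, origin = "start")
      size <- if (ref == "mzArray") 8L else 4L
      vals[[ref]] <- readBin(ibd, what = "numeric", n = n, size = size,
                             endian = "little")
    }
    pixel_spectrum(vals$mzArray, vals$intensityArray,
                   coord = c(y - 1L, x - 1L))
  })

  coords <- t(vapply(spectra, function(s) s$coord, integer(2)))
  if (is.na(rows)) rows <- max(coords[, 1]) + 1L
  if (is.na(cols)) cols <- max(coords[, 2]) + 1L
  msi_datacube(spectra, c(rows, cols), pixel_size = pixel_size)
}

#' Write / read an integer label mask
#'
#' Label images attach tissue-type annotations to a datacube grid
#' (0 = background). TSV stores the grid as plain integers; PNG stores
#' labels as 8-bit grayscale values.
#'
#' @param grid Integer matrix of labels.
#' @param path Output path; format chosen by extension (`.tsv` or `.png`).
#' @return `read_label_mask()` returns the integer matrix;
#'   `write_label_mask()` returns `path` invisibly.
#' @export
write_label_mask <- function(grid, path) {
  if (any(grid != round(grid)) || any(grid < 0)) {
    stop("mask labels must be non-negative integers", call. = FALSE)
  }
  grid <- matrix(as.integer(grid), nrow(grid), ncol(grid))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(grid) > 255) stop("PNG masks support labels up to 255",
                              call. = FALSE)
    png::writePNG(grid / 255, path)
  } else {
    utils::write.table(grid, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    grid <- round(img * 255)
  } else {
    grid <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  }
  if (any(grid != round(grid)) || any(grid < 0)) {
    stop("mask contains non-integer pixel values", call. = FALSE)
  }
  grid <- matrix(as.integer(round(grid)), nrow(grid), ncol(grid))
  dimnames(grid) <- NULL
  if (all(grid == 0L)) warning("mask is all background")
  grid
}
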