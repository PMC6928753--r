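## File formats: PLY/PCD point clouds (with per-point reflectance as
## "refl_<wavelength>" float properties), multi-page TIFF + JSON sidecar and
## ENVI hdr/raw spectral cubes, 16-bit depth images, aligned channel stacks,
## spectra CSV and selection-result JSON.

## ---- PLY --------------------------------------------------------------------

.plyTypeSize <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                  float = 4L, float32 = 4L, double = 8L, float64 = 8L)

#' Write a point cloud to PLY or PCD
#'
#' PLY carries x/y/z as float, colours as uchar red/green/blue, and per-band
#' reflectance as float properties named \code{refl_<wavelength>} (invalid
#' reflectance written as NaN). The format is chosen by file extension.
#'
#' @param cloud a [MultispectralPointCloud-class].
#' @param path output file (.ply or .pcd).
#' @param binary write binary little-endian (PLY only; default FALSE =
#'   ASCII).
#' @return \code{path}, invisibly.
#' @export
writePointCloud <- function(cloud, path, binary = FALSE) {
  stopifnot(is(cloud, "MultispectralPointCloud"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "pcd") return(.writePCD(cloud, path))
  if (ext != "ply") .mspStop("msp_io_error", "unsupported extension (use .ply/.pcd)")
  n <- nPoints(cloud)
  hasRGB <- nrow(cloud@rgb) > 0
  B <- ncol(cloud@reflectance)
  refl <- cloud@reflectance
  if (length(refl)) refl[!cloud@reflValid] <- NaN
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              sprintf("element vertex %d", n),
              "property float x", "property float y", "property float z",
              if (hasRGB) c("property uchar red", "property uchar green",
                            "property uchar blue"),
              if (B) sprintf("property float refl_%.2f", cloud@wavelengths),
              "end_header")
  con <- file(path, if (binary) "wb" else "w")
  on.exit(close(con))
  writeLines(header, con)
  if (!n) return(invisible(path))
  if (binary) {
    rgbRaw <- if (hasRGB) round(cloud@rgb * 255) else NULL
    for (i in seq_len(n)) {
      writeBin(as.numeric(coords(cloud)[i, ]), con, size = 4, endian = "little")
      if (hasRGB) writeBin(as.integer(rgbRaw[i, ]), con, size = 1)
      if (B) writeBin(as.numeric(refl[i, ]), con, size = 4, endian = "little")
    }
  } else {
    cols <- list(coords(cloud))
    fmt <- c("%.7g", "%.7g", "%.7g")
    if (hasRGB) { cols <- c(cols, list(round(cloud@rgb * 255)))
                  fmt <- c(fmt, "%d", "%d", "%d") }
    if (B) { cols <- c(cols, list(refl)); fmt <- c(fmt, rep("%.7g", B)) }
    m <- do.call(cbind, cols)
    lines <- do.call(sprintf, c(list(paste(fmt, collapse = " ")),
                                lapply(seq_len(ncol(m)), function(k) {
                                  if (fmt[k] == "%d") as.integer(m[, k]) else m[, k]
                                })))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a point cloud from PLY or PCD
#'
#' Supports ASCII and binary little-endian PLY. Colour (uchar or float
#' red/green/blue) and \code{refl_<wavelength>} float properties are mapped
#' back onto the cloud; clouds without reflectance load with it absent. NaN
#' reflectance entries become invalid points.
#'
#' @param path input file (.ply or .pcd).
#' @return A [MultispectralPointCloud-class].
#' @export
readPointCloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pcd") return(.readPCD(path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(); repeat {
    l <- readLines(con, 1)
    if (!length(l)) .mspStop("msp_parse_error",
                             sprintf("PLY header truncated (line %d)", length(hdr) + 1))
    hdr <- c(hdr, l)
    if (l == "end_header") break
    if (length(hdr) > 200) .mspStop("msp_parse_error", "runaway PLY header")
  }
  if (hdr[1] != "ply")
    .mspStop("msp_parse_error", "not a PLY file (line 1)")
  fmt <- sub("^format ", "", grep("^format ", hdr, value = TRUE)[1])
  binary <- grepl("^binary_little_endian", fmt)
  if (!binary && !grepl("^ascii", fmt))
    .mspStop("msp_parse_error", "unsupported PLY format (line 2)")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", hdr, value = TRUE)[1]))
  if (is.na(nv)) .mspStop("msp_parse_error", "missing 'element vertex' line")
  vStart <- grep("^element vertex ", hdr)
  vEnd <- c(grep("^element ", hdr), length(hdr))
  vEnd <- min(vEnd[vEnd > vStart])
  props <- hdr[seq(vStart + 1, vEnd - 1)]
  props <- props[grepl("^property ", props)]
  ptype <- sub("^property (\\S+) .*$", "\\1", props)
  pname <- sub("^property \\S+ (\\S+)$", "\\1", props)
  if (any(ptype == "list"))
    .mspStop("msp_parse_error", "list properties are not supported")
  np <- length(pname)
  if (nv == 0) {
    dat <- matrix(numeric(), 0, np)
  } else if (binary) {
    sizes <- .plyTypeSize[ptype]
    raw <- readBin(con, "raw", n = nv * sum(sizes))
    dat <- matrix(0, nv, np)
    offs <- cumsum(c(0, sizes))
    stride <- sum(sizes)
    for (k in seq_len(np)) {
      idx <- as.vector(outer(seq_len(sizes[k]), (seq_len(nv) - 1) * stride + offs[k], "+"))
      bytes <- raw[idx]
      what <- if (ptype[k] %in% c("float", "float32", "double", "float64"))
        "double" else "integer"
      dat[, k] <- readBin(bytes, what, n = nv, size = sizes[k],
                          endian = "little",
                          signed = !(ptype[k] %in% c("uchar", "uint8", "ushort", "uint16")))
    }
  } else {
    txt <- readLines(con, nv)
    dat <- matrix(scan(text = txt, quiet = TRUE, na.strings = c("nan", "NaN")),
                  nv, np, byrow = TRUE)
  }
  colnames(dat) <- pname
  need <- c("x", "y", "z")
  if (!all(need %in% pname))
    .mspStop("msp_parse_error", "PLY lacks x/y/z vertex properties")
  xyz <- dat[, need, drop = FALSE]
  rgb <- NULL
  if (all(c("red", "green", "blue") %in% pname)) {
    rgb <- dat[, c("red", "green", "blue"), drop = FALSE]
    if (any(ptype[match(c("red", "green", "blue"), pname)] %in%
            c("uchar", "uint8"))) rgb <- rgb / 255
  }
  rIdx <- grep("^refl_", pname)
  refl <- NULL; wl <- numeric()
  if (length(rIdx)) {
    wl <- as.numeric(sub("^refl_", "", pname[rIdx]))
    o <- order(wl)
    refl <- dat[, rIdx[o], drop = FALSE]
    wl <- wl[o]
  }
  MultispectralPointCloud(xyz, rgb = rgb, reflectance = refl,
                          reflValid = if (!is.null(refl)) is.finite(refl),
                          wavelengths = wl)
}

.writePCD <- function(cloud, path) {
  B <- ncol(cloud@reflectance)
  fields <- c("x", "y", "z",
              if (B) sprintf("refl_%.2f", cloud@wavelengths))
  n <- nPoints(cloud)
  refl <- cloud@reflectance
  if (length(refl)) refl[!cloud@reflValid] <- NaN
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format", "VERSION 0.7",
           paste("FIELDS", paste(fields, collapse = " ")),
           paste("SIZE", paste(rep(4, length(fields)), collapse = " ")),
           paste("TYPE", paste(rep("F", length(fields)), collapse = " ")),
           paste("COUNT", paste(rep(1, length(fields)), collapse = " ")),
           paste("WIDTH", n), "HEIGHT 1", "VIEWPOINT 0 0 0 1 0 0 0",
           paste("POINTS", n), "DATA ascii")
  m <- cbind(coords(cloud), if (B) refl)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  if (n) writeLines(apply(m, 1, function(r) paste(sprintf("%.7g", r), collapse = " ")), con)
  invisible(path)
}

.readPCD <- function(path) {
  lines <- readLines(path)
  dstart <- grep("^DATA ", lines)
  if (!length(dstart)) .mspStop("msp_parse_error", "PCD lacks a DATA line")
  if (!grepl("ascii", lines[dstart]))
    .mspStop("msp_parse_error", "only ascii PCD is supported")
  fields <- strsplit(sub("^FIELDS ", "", grep("^FIELDS ", lines, value = TRUE)[1]), " ")[[1]]
  body <- lines[-seq_len(dstart)]
  body <- body[nzchar(body)]
  dat <- if (length(body))
    matrix(scan(text = body, quiet = TRUE, na.strings = c("nan", "NaN")),
           length(body), length(fields), byrow = TRUE)
  else matrix(numeric(), 0, length(fields))
  colnames(dat) <- fields
  rIdx <- grep("^refl_", fields)
  wl <- as.numeric(sub("^refl_", "", fields[rIdx]))
  MultispectralPointCloud(dat[, c("x", "y", "z"), drop = FALSE],
                          reflectance = if (length(rIdx)) dat[, rIdx, drop = FALSE],
                          wavelengths = wl)
}

## ---- spectral cubes ---------------------------------------------------------

.sidecarPath <- function(path) paste0(path, ".json")

#' Write / read a spectral cube (multi-page TIFF + JSON sidecar, or ENVI)
#'
#' TIFF route: one 32-bit float page per band plus a final 0/1 mask page,
#' with a JSON sidecar \code{<path>.json} holding the wavelengths and layout.
#' ENVI route (extension .envi/.dat/.raw or \code{format = "envi"}): binary
#' float raw with a text \code{.hdr} (BSQ or BIL interleave) and wavelengths
#' in the header.
#'
#' @param cube a [SpectralCube-class].
#' @param path output path.
#' @param format "tiff", "envi" or NULL (by extension).
#' @param interleave ENVI interleave, "bsq" or "bil".
#' @return \code{path}, invisibly (write); a [SpectralCube-class] (read).
#' @export
writeSpectralCube <- function(cube, path, format = NULL, interleave = "bsq") {
  stopifnot(is(cube, "SpectralCube"))
  ext <- tolower(tools::file_ext(path))
  format <- format %||% if (ext %in% c("tif", "tiff")) "tiff" else "envi"
  d <- dim(cube@values)
  if (format == "tiff") {
    pages <- lapply(seq_len(d[3]), function(b) {
      v <- cube@values[, , b]; v[is.na(v)] <- 0; v
    })
    pages <- c(pages, list(cube@mask * 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    jsonlite::write_json(list(wavelengths_nm = cube@wavelengths,
                              n_bands = d[3], mask_page = d[3] + 1L),
                         .sidecarPath(path), digits = NA, auto_unbox = TRUE)
  } else {
    vals <- cube@values
    vals[is.na(vals)] <- 0
    con <- file(path, "wb"); on.exit(close(con))
    if (interleave == "bsq") {
      for (b in seq_len(d[3])) writeBin(as.numeric(t(vals[, , b])), con,
                                        size = 4, endian = "little")
    } else if (interleave == "bil") {
      ## per line: band-sequential runs of samples
      for (r in seq_len(d[1])) writeBin(as.numeric(vals[r, , ]), con,
                                        size = 4, endian = "little")
    } else .mspStop("msp_io_error", "interleave must be bsq or bil")
    hdr <- c("ENVI", sprintf("samples = %d", d[2]), sprintf("lines = %d", d[1]),
             sprintf("bands = %d", d[3]), "header offset = 0",
             "data type = 4", sprintf("interleave = %s", interleave),
             "byte order = 0",
             sprintf("wavelength = { %s }",
                     paste(sprintf("%.6g", cube@wavelengths), collapse = ", ")))
    writeLines(hdr, paste0(path, ".hdr"))
  }
  invisible(path)
}

#' @param path input path (TIFF needs its \code{.json} sidecar; ENVI its
#'   \code{.hdr}).
#' @rdname writeSpectralCube
#' @export
readSpectralCube <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    sc <- .sidecarPath(path)
    if (!file.exists(sc))
      .mspStop("msp_io_error", sprintf("missing sidecar file: %s", sc))
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    nb <- meta$n_bands
    if (length(meta$wavelengths_nm) != nb)
      .mspStop("msp_io_error", "sidecar wavelength count mismatch")
    if (length(pages) < nb)
      .mspStop("msp_io_error", "TIFF has fewer pages than bands")
    vals <- array(0, c(dim(pages[[1]]), nb))
    for (b in seq_len(nb)) vals[, , b] <- pages[[b]]
    mask <- if (length(pages) >= meta$mask_page %||% Inf)
      pages[[meta$mask_page]] > 0.5
    else matrix(TRUE, dim(pages[[1]])[1], dim(pages[[1]])[2])
    vals[array(!mask, dim(vals))] <- NA_real_
    SpectralCube(vals, meta$wavelengths_nm, mask = mask)
  } else {
    hdrPath <- paste0(path, ".hdr")
    if (!file.exists(hdrPath))
      .mspStop("msp_io_error", sprintf("missing ENVI header: %s", hdrPath))
    hdr <- readLines(hdrPath)
    g <- function(key) {
      l <- grep(sprintf("^%s\\s*=", key), hdr, value = TRUE)
      if (!length(l)) .mspStop("msp_parse_error", sprintf("header lacks '%s'", key))
      trimws(sub("^[^=]*=", "", l[1]))
    }
    ns <- as.integer(g("samples")); nl <- as.integer(g("lines"))
    nb <- as.integer(g("bands"))
    inter <- g("interleave")
    wl <- as.numeric(strsplit(gsub("[{}]", "", g("wavelength")), ",")[[1]])
    if (length(wl) != nb)
      .mspStop("msp_io_error", "wavelength count does not match band count")
    raw <- readBin(path, "numeric", n = ns * nl * nb, size = 4,
                   endian = "little")
    vals <- array(0, c(nl, ns, nb))
    if (inter == "bsq") {
      vals <- aperm(array(raw, c(ns, nl, nb)), c(2, 1, 3))
    } else if (inter == "bil") {
      vals <- aperm(array(raw, c(ns, nb, nl)), c(3, 1, 2))
    } else .mspStop("msp_parse_error", "unsupported interleave")
    SpectralCube(vals, wl)
  }
}

## ---- depth images and channel stacks ---------------------------------------

#' Read / write a 16-bit depth image (mm)
#'
#' Reading accepts 16-bit PNG or TIFF (values are rescaled from the [0, 1]
#' decoder convention back to integer mm). Writing uses 16-bit TIFF.
#'
#' @param path image path (.png/.tif/.tiff).
#' @param depth rows x cols matrix of depth in mm (0 = missing),
#'   0..65535.
#' @return matrix (read) / \code{path} invisibly (write).
#' @export
readDepthImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  round(img * 65535)
}

#' @rdname readDepthImage
#' @export
writeDepthImage <- function(depth, path) {
  if (max(depth) > 65535 || min(depth) < 0)
    .mspStop("msp_value_error", "depth must fit 16 bits (0..65535 mm)")
  tiff::writeTIFF(depth / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Write / read an aligned channel stack (multi-page TIFF + JSON sidecar)
#'
#' Serialises the array produced by [stackRegistered()]: one 32-bit float
#' page per channel plus a final spectral-validity page; channel names and
#' wavelengths go to the \code{<path>.json} sidecar. The round trip is exact
#' at float32 precision.
#'
#' @param stack channel stack from [stackRegistered()].
#' @param path output TIFF path.
#' @return \code{path} invisibly (write); a channel stack (read).
#' @export
writeChannelStack <- function(stack, path) {
  chan <- attr(stack, "channels")
  pages <- lapply(seq_len(dim(stack)[3]), function(k) {
    v <- stack[, , k]
    if (max(v) > 1) v / 65535 else v     # depth channel scaled into [0,1]
  })
  scale <- vapply(seq_len(dim(stack)[3]),
                  function(k) if (max(stack[, , k]) > 1) 65535 else 1,
                  numeric(1))
  pages <- c(pages, list((attr(stack, "spectralMask") %||%
                            matrix(TRUE, dim(stack)[1], dim(stack)[2])) * 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(channels = chan, channel_scale = scale,
                            wavelengths_nm = attr(stack, "wavelengths"),
                            mask_page = dim(stack)[3] + 1L),
                       .sidecarPath(path), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeChannelStack
#' @export
readChannelStack <- function(path) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc))
    .mspStop("msp_io_error", sprintf("missing sidecar file: %s", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- length(meta$channels)
  out <- array(0, c(dim(pages[[1]]), nc))
  for (k in seq_len(nc)) out[, , k] <- pages[[k]] * meta$channel_scale[k]
  mask <- pages[[meta$mask_page]] > 0.5
  structure(out, channels = meta$channels,
            wavelengths = meta$wavelengths_nm, spectralMask = mask)
}

## ---- spectra CSV and selection JSON ----------------------------------------

#' Write / read a spectra matrix as CSV
#'
#' First column is the sample id, remaining columns are wavelengths (header
#' row holds the wavelengths in nm).
#'
#' @param spectra a [SpectraMatrix-class].
#' @param path CSV path.
#' @return \code{path} invisibly (write); a [SpectraMatrix-class] (read).
#' @export
writeSpectraCsv <- function(spectra, path) {
  stopifnot(is(spectra, "SpectraMatrix"))
  df <- data.frame(sample_id = spectra@sampleIds,
                   reflectance(spectra), check.names = FALSE)
  colnames(df) <- c("sample_id", sprintf("%.4f", wavelengths(spectra)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectraCsv
#' @export
readSpectraCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- as.numeric(colnames(df)[-1])
  SpectraMatrix(as.matrix(df[, -1, drop = FALSE]), wl, df[[1]])
}

#' Write / read a wavelength selection result (JSON)
#'
#' @param result a [SelectionResult-class].
#' @param path JSON path.
#' @return \code{path} invisibly (write); a [SelectionResult-class] (read).
#' @export
writeSelectionResult <- function(result, path) {
  stopifnot(is(result, "SelectionResult"))
  jsonlite::write_json(
    list(nutrient = result@nutrient, method = "PCA-CC-RF",
         number = length(result@wavelengths),
         wavelengths_nm = result@wavelengths,
         provenance = result@provenance),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSelectionResult
#' @export
readSelectionResult <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SelectionResult", nutrient = x$nutrient,
      wavelengths = as.numeric(x$wavelengths_nm),
      provenance = as.character(x$provenance))
}
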