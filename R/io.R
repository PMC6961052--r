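#' @include AllClasses.R
NULL

## ENVI header + raw binary (BIL interleave, float32 little-endian).
## No installed package reads ENVI, so the reader/writer is implemented
## here; only the fields this pipeline needs are supported.

#' Write an HSCube as an ENVI header + raw binary pair
#'
#' Writes \code{<basePath>.hdr} (text header including the wavelength list
#' in nm) and \code{<basePath>.raw} (float32, BIL interleave, little
#' endian).
#'
#' @param cube An \linkS4class{HSCube}.
#' @param basePath Path without extension.
#' @return Invisibly, the two file paths.
#' @export
writeENVI <- function(cube, basePath) {
  d <- dim(cube@values)
  hdr <- c(
    "ENVI",
    sprintf("description = {patient=%s image=%s calibrated=%d normalized=%d}",
            cube@patientId, cube@imageId,
            as.integer(cube@calibrated), as.integer(cube@normalized)),
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bil",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(sprintf("%.6f", wavelengths(cube)), collapse = ", ")))
  writeLines(hdr, paste0(basePath, ".hdr"))
  ## BIL: per line, per band, all samples. values is lines x samples x bands.
  vec <- as.vector(aperm(cube@values, c(2L, 3L, 1L)))
  con <- file(paste0(basePath, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(vec), con, size = 4L, endian = "little")
  invisible(paste0(basePath, c(".hdr", ".raw")))
}

.parseEnviHeader <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  getNum <- function(key) {
    m <- regmatches(txt, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), txt))
    if (!length(m)) stop("missing ENVI header field: ", key)
    as.integer(sub(".*=\\s*", "", m))
  }
  m <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt))
  if (!length(m)) stop("missing ENVI wavelength list")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}", "", m), ",")[[1]])
  desc <- regmatches(txt, regexpr("description\\s*=\\s*\\{[^}]*\\}", txt))
  meta <- c(patient = "P000", image = "im00", calibrated = "0",
            normalized = "0")
  if (length(desc)) {
    kv <- regmatches(desc, gregexpr("[a-z]+=[^ }]+", desc))[[1]]
    for (pair in kv) {
      p <- strsplit(pair, "=")[[1]]
      if (p[1] %in% names(meta)) meta[p[1]] <- p[2]
    }
  }
  list(samples = getNum("samples"), lines = getNum("lines"),
       bands = getNum("bands"), interleave = "bil", wavelengths = wl,
       meta = meta)
}

#' Read an ENVI header + raw binary pair into an HSCube
#'
#' @param basePath Path without extension (expects .hdr and .raw).
#' @return An \linkS4class{HSCube}.
#' @export
readENVI <- function(basePath) {
  h <- .parseEnviHeader(paste0(basePath, ".hdr"))
  n <- h$samples * h$lines * h$bands
  con <- file(paste0(basePath, ".raw"), "rb")
  on.exit(close(con))
  vec <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  if (length(vec) != n) stop("raw file truncated")
  vals <- aperm(array(vec, dim = c(h$samples, h$bands, h$lines)),
                c(3L, 1L, 2L))
  hsCube(vals, spectralGrid(h$wavelengths),
         patientId = h$meta[["patient"]], imageId = h$meta[["image"]],
         calibrated = h$meta[["calibrated"]] == "1",
         normalized = h$meta[["normalized"]] == "1")
}

#' Write a ground-truth map as a single-channel PNG
#'
#' Class codes 0/1/2/3 plus 255 for unlabeled, stored as 8-bit gray.
#'
#' @param map Integer matrix of class codes.
#' @param path Output .png path.
#' @export
writeGroundTruthPNG <- function(map, path) {
  if (!all(map %in% c(0:3, .UNLABELED)))
    stop("map contains invalid class codes")
  png::writePNG(map / 255, path)
  invisible(path)
}

#' Read a ground-truth PNG written by \code{writeGroundTruthPNG}
#'
#' @param path Input .png path.
#' @return Integer matrix of class codes.
#' @export
readGroundTruthPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  m <- matrix(as.integer(round(img * 255)), nrow = nrow(img))
  if (!all(m %in% c(0:3, .UNLABELED)))
    stop("PNG does not encode a valid ground-truth map")
  m
}

#' Write a LabeledDataset as a tabular CSV
#'
#' One row per pixel: patient_id, image_id, class, then one reflectance
#' column per band named \code{b<wavelength>} (6 decimals).
#'
#' @param data A \linkS4class{LabeledDataset}.
#' @param path Output .csv path.
#' @export
writeDatasetCSV <- function(data, path) {
  M <- t(spectra(data))
  colnames(M) <- sprintf("b%.6f", wavelengths(data))
  dt <- data.table::data.table(
    patient_id = patientIds(data), image_id = imageIds(data),
    class = pixelLabels(data))
  data.table::fwrite(cbind(dt, data.table::as.data.table(M)), path)
  invisible(path)
}

#' Read a LabeledDataset written by \code{writeDatasetCSV}
#'
#' @param path Input .csv path.
#' @return A \linkS4class{LabeledDataset}.
#' @export
readDatasetCSV <- function(path) {
  dt <- data.table::fread(path)
  bcols <- grep("^b[0-9]", names(dt), value = TRUE)
  wl <- as.numeric(sub("^b", "", bcols))
  labeledDataset(t(as.matrix(dt[, bcols, with = FALSE])),
                 dt$class, dt$patient_id, dt$image_id, spectralGrid(wl))
}
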