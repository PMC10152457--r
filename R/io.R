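# Cube containers. Cubes are written in an ENVI-style layout (plain-text
# .hdr + band-sequential binary .dat, little-endian doubles) with a JSON
# sidecar carrying the masks and provenance; ground truth travels as CSV
# (row, col, class_name).

#' Write a spectral cube in ENVI-style layout
#'
#' Writes `<prefix>.hdr` (text header with the wavelength list),
#' `<prefix>.dat` (band-sequential little-endian 64-bit floats) and
#' `<prefix>.json` (pixel/channel masks and provenance).
#'
#' @param cube a [spectral_cube()]
#' @param prefix path prefix (no extension)
#' @return `prefix`, invisibly
#' @export
write_envi_cube <- function(cube, prefix) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$absorbance)
  hdr <- c(
    "ENVI",
    "description = { ftirmetrics spectral cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = cm-1",
    sprintf("wavelength = { %s }",
            paste(format(cube$wavenumbers, trim = TRUE, digits = 15),
                  collapse = ", "))
  )
  writeLines(hdr, paste0(prefix, ".hdr"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: sample (column) fastest, then line, then band
  writeBin(as.vector(aperm(cube$absorbance, c(2, 1, 3))), con,
           size = 8, endian = "little")
  jsonlite::write_json(
    list(pixel_mask = unclass(cube$pixel_mask),
         channel_mask = cube$channel_mask,
         provenance = cube$provenance),
    paste0(prefix, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(prefix)
}

#' Read a cube written by [write_envi_cube()]
#' @param prefix path prefix (no extension)
#' @return a [spectral_cube()]
#' @export
read_envi_cube <- function(prefix) {
  hdr <- readLines(paste0(prefix, ".hdr"))
  get_num <- function(key) {
    ln <- grep(sprintf("^%s = ", key), hdr, value = TRUE)
    as.integer(sub(".* = ", "", ln[1]))
  }
  samples <- get_num("samples"); lines <- get_num("lines"); bands <- get_num("bands")
  wl_line <- grep("^wavelength = ", hdr, value = TRUE)
  wl <- as.numeric(strsplit(gsub("^wavelength = \\{\\s*|\\s*\\}$", "", wl_line),
                            ",\\s*")[[1]])
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = samples * lines * bands, size = 8,
                 endian = "little")
  cube_arr <- aperm(array(raw, c(samples, lines, bands)), c(2, 1, 3))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pm <- matrix(as.logical(side$pixel_mask), lines, samples)
  spectral_cube(cube_arr, wl, pixel_mask = pm,
                channel_mask = as.logical(side$channel_mask),
                provenance = as.character(side$provenance))
}

#' Write per-pixel class labels as CSV
#'
#' Long format: one row per pixel with columns `row`, `col`, `class_name`.
#'
#' @param labels character matrix of class names
#' @param path output CSV file
#' @return `path`, invisibly
#' @export
write_labels_csv <- function(labels, path) {
  d <- dim(labels)
  df <- data.frame(row = rep(seq_len(d[1]), d[2]),
                   col = rep(seq_len(d[2]), each = d[1]),
                   class_name = as.vector(labels))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read labels written by [write_labels_csv()]
#' @param path CSV file
#' @return character matrix of class names
#' @export
read_labels_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  d <- c(max(df$row), max(df$col))
  m <- matrix(NA_character_, d[1], d[2])
  m[cbind(df$row, df$col)] <- df$class_name
  m
}

#' Write a label map (labels + confidence) as CSV
#' @param labels a [label_map()]
#' @param path output CSV file
#' @return `path`, invisibly
#' @export
write_label_map_csv <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  d <- labels$shape
  df <- data.frame(row = rep(seq_len(d[1]), d[2]),
                   col = rep(seq_len(d[2]), each = d[1]),
                   label = as.vector(labels$label),
                   confidence = as.vector(labels$confidence))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
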