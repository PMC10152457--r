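# Rendering: single-metric ratio images and multi-class pseudo-colour maps
# where hue encodes the predicted tissue class and saturation encodes the
# prediction confidence.

#' Per-pixel label map
#'
#' @param label character matrix of class names (or `"excluded"`)
#' @param confidence numeric matrix in `[0, 1]`, 0 for excluded pixels
#' @return an object of class `label_map`
#' @export
label_map <- function(label, confidence) {
  if (!identical(dim(label), dim(confidence))) stopf("shape mismatch")
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE)) {
    stopf("confidence must lie in [0, 1]")
  }
  structure(list(shape = dim(label), label = label, confidence = confidence),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d pixels\n", x$shape[1], x$shape[2]))
  print(table(x$label))
  invisible(x)
}

#' Single-metric ratio image
#'
#' The classic one-metric visualisation: per-pixel absorbance ratio at two
#' wavenumbers (default 1252/1285 cm^-1, the pair used to flag epithelial
#' tissue). Masked pixels and undefined ratios (denominator below `eps`)
#' are `NA`. The finite value range is attached for colour scaling.
#'
#' @param cube a [spectral_cube()]
#' @param num_wn,den_wn numerator/denominator wavenumbers; must lie on the
#'   stored grid and differ
#' @param eps denominator guard
#' @return numeric matrix of ratios with attribute `range = c(min, max)`
#' @export
ratio_image <- function(cube, num_wn = 1252, den_wn = 1285, eps = 1e-6) {
  stopifnot(inherits(cube, "spectral_cube"))
  i <- match_channel(cube$wavenumbers, num_wn, on_grid = TRUE, what = "numerator")
  j <- match_channel(cube$wavenumbers, den_wn, on_grid = TRUE, what = "denominator")
  if (i == j) stopf("numerator and denominator resolve to the same channel")
  num <- cube$absorbance[, , i]
  den <- cube$absorbance[, , j]
  img <- num / den
  img[abs(den) < eps] <- NA_real_
  img[!cube$pixel_mask] <- NA_real_
  fin <- img[is.finite(img)]
  attr(img, "range") <- if (length(fin)) range(fin) else c(NA_real_, NA_real_)
  attr(img, "wavenumbers") <- c(num = cube$wavenumbers[i],
                                den = cube$wavenumbers[j])
  img
}

#' Default class palette
#'
#' Maximally spaced hues at full saturation and value: with `K` classes the
#' hue spacing is `360/K` degrees (>= 20 degrees for up to 18 classes), so
#' classes remain recoverable from the rendered hue.
#'
#' @param classes character vector of class names
#' @param excluded colour for excluded pixels
#' @return named character vector of sRGB hex colours (plus `"excluded"`)
#' @export
default_palette <- function(classes, excluded = "#3B3B3B") {
  K <- length(classes)
  cols <- hsv(h = (seq_len(K) - 1) / K, s = 1, v = 1)
  c(setNames(cols, classes), excluded = excluded)
}

#' Render a pseudo-colour tissue map
#'
#' Each pixel takes its class's base colour with the HSV saturation channel
#' scaled by `confidence^gamma` (linear by default); the value channel is
#' preserved, so zero confidence gives a grey of the same brightness.
#' Excluded pixels get the palette's excluded colour unchanged.
#'
#' @param labels a [label_map()]
#' @param palette named colour vector covering every label present (see
#'   [default_palette()])
#' @param gamma exponent on confidence (1 = linear saturation mapping)
#' @return `rows x cols x 3` numeric array of sRGB values in `[0, 1]`
#' @export
render_pseudocolour <- function(labels, palette, gamma = 1) {
  stopifnot(inherits(labels, "label_map"))
  present <- unique(as.vector(labels$label))
  missing <- setdiff(present, names(palette))
  if (length(missing)) {
    stopf("palette has no entry for label '%s'", missing[1])
  }
  hsv_base <- rgb2hsv(col2rgb(palette))  # 3 x n, in [0, 1]
  colnames(hsv_base) <- names(palette)
  d <- labels$shape
  lab <- as.vector(labels$label)
  conf <- as.vector(labels$confidence)
  h <- hsv_base["h", lab]
  s <- hsv_base["s", lab]
  v <- hsv_base["v", lab]
  scale <- ifelse(lab == "excluded", 1, conf^gamma)
  cols <- t(col2rgb(hsv(h, s * scale, v))) / 255
  array(c(matrix(cols[, 1], d[1], d[2]),
          matrix(cols[, 2], d[1], d[2]),
          matrix(cols[, 3], d[1], d[2])), c(d[1], d[2], 3))
}

#' Write a raster array as PNG
#'
#' @param raster `rows x cols x 3` array in `[0, 1]` (8-bit quantisation on
#'   write)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_raster_png <- function(raster, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stopf("the 'png' package is required to write PNG files")
  }
  png::writePNG(raster, path)
  invisible(path)
}

#' Recover labels from a rendered pseudo-colour raster
#'
#' Inverts [render_pseudocolour()] by nearest hue: pixels with saturation
#' above `min_saturation` are assigned the palette class of closest hue
#' (circular distance); the rest become `"excluded"`. Used to verify the
#' hue-encodes-class round trip.
#'
#' @param raster `rows x cols x 3` sRGB array in `[0, 1]`
#' @param palette the palette used for rendering
#' @param min_saturation below this the pixel is treated as unlabelled
#' @return character matrix of class names
#' @export
labels_from_raster <- function(raster, palette, min_saturation = 0.02) {
  cls <- setdiff(names(palette), "excluded")
  hue_of <- rgb2hsv(col2rgb(palette[cls]))["h", ]
  d <- dim(raster)
  flat <- matrix(raster, d[1] * d[2], 3)
  hsvs <- rgb2hsv(t(flat), maxColorValue = 1)
  out <- rep("excluded", d[1] * d[2])
  ok <- hsvs["s", ] > min_saturation
  if (any(ok)) {
    dh <- abs(outer(hsvs["h", ok], hue_of, "-"))
    dh <- pmin(dh, 1 - dh)  # circular hue distance
    out[ok] <- cls[max.col(-dh, ties.method = "first")]
  }
  matrix(out, d[1], d[2])
}
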