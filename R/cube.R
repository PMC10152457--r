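#' Spectral cube container
#'
#' A hyperspectral absorbance cube: a pixel grid by wavenumber axis, with a
#' per-pixel usability mask, a per-channel analysis mask, and a provenance
#' trail of applied processing steps.
#'
#' @param absorbance numeric array `rows x cols x channels` (absorbance, AU)
#' @param wavenumbers strictly increasing numeric vector (cm^-1), one per
#'   channel
#' @param pixel_mask logical `rows x cols` matrix, `TRUE` = usable pixel
#' @param channel_mask logical vector, `TRUE` = channel used in analysis
#' @param provenance character vector of processing steps applied so far
#'
#' @return an object of class `spectral_cube`
#' @export
spectral_cube <- function(absorbance, wavenumbers,
                          pixel_mask = NULL, channel_mask = NULL,
                          provenance = character()) {
  if (length(dim(absorbance)) != 3L) {
    stopf("absorbance must be a rows x cols x channels array")
  }
  d <- dim(absorbance)
  if (length(wavenumbers) != d[3]) {
    stopf("wavenumbers length (%d) != number of channels (%d)",
          length(wavenumbers), d[3])
  }
  if (d[3] > 1 && any(diff(wavenumbers) <= 0)) {
    stopf("wavenumbers must be strictly increasing")
  }
  pixel_mask <- pixel_mask %||% matrix(TRUE, d[1], d[2])
  channel_mask <- channel_mask %||% rep(TRUE, d[3])
  if (!identical(dim(pixel_mask), d[1:2])) stopf("pixel_mask shape mismatch")
  if (length(channel_mask) != d[3]) stopf("channel_mask length mismatch")
  structure(
    list(absorbance = absorbance, wavenumbers = as.numeric(wavenumbers),
         pixel_mask = pixel_mask, channel_mask = channel_mask,
         provenance = provenance),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$absorbance)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d channels (%g-%g cm^-1)\n",
              d[1], d[2], d[3], min(x$wavenumbers), max(x$wavenumbers)))
  cat(sprintf("  usable pixels: %d/%d; analysis channels: %d/%d\n",
              sum(x$pixel_mask), length(x$pixel_mask),
              sum(x$channel_mask), length(x$channel_mask)))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Single-pixel spectrum
#'
#' @param values numeric absorbance sequence (AU)
#' @param wavenumbers matching wavenumber grid (cm^-1)
#' @return an object of class `spectrum`
#' @export
new_spectrum <- function(values, wavenumbers) {
  if (length(values) != length(wavenumbers)) {
    stopf("values and wavenumbers lengths differ")
  }
  structure(list(values = as.numeric(values),
                 wavenumbers = as.numeric(wavenumbers)),
            class = "spectrum")
}

#' Labelled spectra set
#'
#' Holds spectra as a matrix (one row per spectrum) plus parallel class
#' labels and image/patient identifiers, the unit the metric engine and the
#' evaluation protocol operate on.
#'
#' @param values numeric matrix, `n_spectra x channels`
#' @param wavenumbers channel grid (cm^-1)
#' @param labels character/factor vector of class names, length `n_spectra`
#' @param image_id per-spectrum image identifier
#' @param patient_id per-spectrum patient identifier
#' @param channel_mask logical, `TRUE` = analysis channel
#' @return an object of class `labelled_spectra`
#' @export
labelled_spectra <- function(values, wavenumbers, labels,
                             image_id = rep("img1", nrow(values)),
                             patient_id = rep("p1", nrow(values)),
                             channel_mask = rep(TRUE, ncol(values))) {
  values <- as.matrix(values)
  if (ncol(values) != length(wavenumbers)) stopf("wavenumber length mismatch")
  n <- nrow(values)
  labels <- as.character(labels)
  if (length(labels) != n) stopf("labels length (%d) != n spectra (%d)",
                                 length(labels), n)
  if (length(image_id) != n) stopf("image_id length mismatch")
  if (length(patient_id) != n) stopf("patient_id length mismatch")
  if (length(channel_mask) != ncol(values)) stopf("channel_mask length mismatch")
  structure(
    list(values = values, wavenumbers = as.numeric(wavenumbers),
         labels = labels, image_id = as.character(image_id),
         patient_id = as.character(patient_id), channel_mask = channel_mask),
    class = "labelled_spectra"
  )
}

#' @export
print.labelled_spectra <- function(x, ...) {
  cat(sprintf("<labelled_spectra> %d spectra, %d channels, %d classes, %d image(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels)),
              length(unique(x$image_id))))
  print(table(x$labels))
  invisible(x)
}

#' Subset a labelled spectra set by row index
#' @param data a `labelled_spectra` object
#' @param idx integer or logical row index
#' @return a `labelled_spectra` object
#' @export
subset_spectra <- function(data, idx) {
  labelled_spectra(data$values[idx, , drop = FALSE], data$wavenumbers,
                   data$labels[idx], data$image_id[idx], data$patient_id[idx],
                   data$channel_mask)
}

#' Flatten the usable pixels of a cube into a labelled spectra set
#'
#' @param cube a (typically preprocessed) `spectral_cube`
#' @param labels character matrix of per-pixel class names, same pixel grid
#' @param image_id,patient_id identifiers attached to every extracted
#'   spectrum
#' @return a `labelled_spectra` with one row per usable (unmasked) pixel;
#'   pixel coordinates are kept in attributes `row`/`col`
#' @export
cube_to_labelled <- function(cube, labels, image_id = "img1", patient_id = "p1") {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$absorbance)
  if (!identical(dim(labels), d[1:2])) stopf("labels shape mismatch")
  keep <- which(cube$pixel_mask)  # column-major pixel index
  flat <- matrix(cube$absorbance, d[1] * d[2], d[3])
  out <- labelled_spectra(flat[keep, , drop = FALSE], cube$wavenumbers,
                          as.character(labels)[keep],
                          image_id = rep(image_id, length(keep)),
                          patient_id = rep(patient_id, length(keep)),
                          channel_mask = cube$channel_mask)
  attr(out, "row") <- ((keep - 1L) %% d[1]) + 1L
  attr(out, "col") <- ((keep - 1L) %/% d[1]) + 1L
  out
}

#' Merge several labelled spectra sets
#' @param ... `labelled_spectra` objects on identical grids
#' @return one combined `labelled_spectra`
#' @export
bind_spectra <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "labelled_spectra")) {
    parts <- parts[[1]]
  }
  ref <- parts[[1]]
  for (p in parts[-1]) {
    if (!isTRUE(all.equal(p$wavenumbers, ref$wavenumbers))) {
      stopf("wavenumber grids differ between parts")
    }
  }
  labelled_spectra(do.call(rbind, lapply(parts, `[[`, "values")),
                   ref$wavenumbers,
                   unlist(lapply(parts, `[[`, "labels")),
                   unlist(lapply(parts, `[[`, "image_id")),
                   unlist(lapply(parts, `[[`, "patient_id")),
                   ref$channel_mask)
}
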