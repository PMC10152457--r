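# Spectral preprocessing chain for FFPE tissue cubes, applied in fixed
# order: Amide I quality gate -> truncation to the fingerprint region with
# paraffin-band omission -> rubber-band baseline correction -> vector
# normalisation over the analysis channels.

#' Amide I quality-pixel gate
#'
#' Masks out pixels whose Amide I absorbance (channel nearest 1650 cm^-1)
#' is below `low` or above `high` — outlier spectra from sub-optimal sample
#' thickness. The inequalities are strict: values exactly equal to the
#' bounds are kept. Absorbance values are never altered.
#'
#' @param cube a [spectral_cube()]
#' @param low,high gate bounds in absorbance units (defaults 0.1 and 2)
#' @param lookup `"nearest"` uses the channel nearest 1650 cm^-1;
#'   `"window_max"` uses the per-pixel maximum within `window` cm^-1 of 1650
#' @param window half-width (cm^-1) for `lookup = "window_max"`
#' @return the cube with `pixel_mask` updated and provenance appended
#' @export
quality_filter <- function(cube, low = 0.1, high = 2.0,
                           lookup = c("nearest", "window_max"), window = 10) {
  stopifnot(inherits(cube, "spectral_cube"))
  lookup <- match.arg(lookup)
  wn <- cube$wavenumbers
  ch <- match_channel(wn, AMIDE_I_WN, what = "Amide I centre")
  a <- if (lookup == "nearest") {
    cube$absorbance[, , ch]
  } else {
    sel <- which(abs(wn - AMIDE_I_WN) <= window)
    apply(cube$absorbance[, , sel, drop = FALSE], c(1, 2), max)
  }
  bad <- a < low | a > high
  cube$pixel_mask <- cube$pixel_mask & !bad
  cube$provenance <- c(cube$provenance,
                       sprintf("quality_filter(low=%g, high=%g, channel=%g cm^-1)",
                               low, high, wn[ch]))
  cube
}

#' Truncate the wavenumber range and mask the paraffin region
#'
#' Channels outside `keep` are dropped from storage. Channels inside `omit`
#' (closed interval, both endpoints omitted) stay in storage — so ratio
#' images can still be rendered there — but have `channel_mask = FALSE` and
#' are excluded from all downstream analysis (normalisation, metrics).
#'
#' @param cube a [spectral_cube()]
#' @param keep numeric `(lo, hi)` wavenumber range to retain (cm^-1)
#' @param omit numeric `(lo, hi)` analysis-excluded range, or `NULL` to
#'   omit nothing; default is the paraffin-dominated 1350-1500 cm^-1
#' @return the truncated cube with updated `channel_mask`
#' @export
truncate_and_mask <- function(cube, keep = c(900, 1800), omit = c(1350, 1500)) {
  stopifnot(inherits(cube, "spectral_cube"))
  wn <- cube$wavenumbers
  sel <- wn >= keep[1] & wn <= keep[2]
  if (!any(sel)) stopf("keep range [%g, %g] does not intersect the grid",
                       keep[1], keep[2])
  cube$absorbance <- cube$absorbance[, , sel, drop = FALSE]
  cube$wavenumbers <- wn[sel]
  cube$channel_mask <- cube$channel_mask[sel]
  if (!is.null(omit) && length(omit) == 2L) {
    cube$channel_mask[cube$wavenumbers >= omit[1] &
                        cube$wavenumbers <= omit[2]] <- FALSE
  }
  if (!any(cube$channel_mask)) stopf("no analysis channels left after masking")
  cube$provenance <- c(cube$provenance,
                       sprintf("truncate_and_mask(keep=[%g,%g], omit=[%s])",
                               keep[1], keep[2],
                               if (is.null(omit)) "" else paste(omit, collapse = ",")))
  cube
}

#' Rubber-band baseline correction
#'
#' Subtracts the greatest convex minorant of the spectrum (the lower convex
#' hull boundary through the points, linearly interpolated between hull
#' vertices). The corrected spectrum is non-negative (within floating-point
#' slack) and exactly zero at the first and last channel and at every hull
#' vertex.
#'
#' @param spectrum a [new_spectrum()] object, or a numeric vector if
#'   `wavenumbers` is supplied
#' @param wavenumbers optional grid when `spectrum` is a bare vector
#' @return corrected spectrum of the same type as the input
#' @export
rubberband_baseline <- function(spectrum, wavenumbers = NULL) {
  if (inherits(spectrum, "spectrum")) {
    v <- spectrum$values; wn <- spectrum$wavenumbers
  } else {
    v <- as.numeric(spectrum); wn <- wavenumbers
    if (is.null(wn)) stopf("wavenumbers required for a bare numeric spectrum")
  }
  if (length(v) < 3L) stopf("rubber-band correction needs at least 3 channels")
  if (!all(is.finite(v))) stopf("spectrum contains non-finite values")
  corrected <- v - .lower_convex_minorant(wn, v)
  if (inherits(spectrum, "spectrum")) new_spectrum(corrected, wn) else corrected
}

#' Vector normalisation over analysis channels
#'
#' Scales the spectrum so its Euclidean norm over the unmasked (analysis)
#' channels is 1. Masked channels are scaled by the same factor, keeping the
#' stored spectrum internally consistent for display.
#'
#' @param spectrum a [new_spectrum()] or numeric vector
#' @param channel_mask logical vector, `TRUE` = analysis channel; default
#'   all channels
#' @return normalised spectrum of the same type as the input
#' @export
vector_normalise <- function(spectrum, channel_mask = NULL) {
  v <- if (inherits(spectrum, "spectrum")) spectrum$values else as.numeric(spectrum)
  channel_mask <- channel_mask %||% rep(TRUE, length(v))
  if (length(channel_mask) != length(v)) stopf("channel_mask length mismatch")
  nrm <- sqrt(sum(v[channel_mask]^2))
  if (nrm == 0) stopf("zero norm over analysis channels (dead pixel?)")
  out <- v / nrm
  if (inherits(spectrum, "spectrum")) new_spectrum(out, spectrum$wavenumbers) else out
}

#' Preprocessing parameter set
#'
#' @param amide_low,amide_high Amide I quality-gate bounds (AU)
#' @param keep retained wavenumber range (cm^-1)
#' @param omit analysis-omitted range (cm^-1), `NULL` for none
#' @param amide_lookup `"nearest"` or `"window_max"` (see [quality_filter()])
#' @param amide_window window half-width for `"window_max"`
#' @return a named list of parameters
#' @export
preprocess_params <- function(amide_low = 0.1, amide_high = 2.0,
                              keep = c(900, 1800), omit = c(1350, 1500),
                              amide_lookup = "nearest", amide_window = 10) {
  list(amide_low = amide_low, amide_high = amide_high, keep = keep,
       omit = omit, amide_lookup = amide_lookup, amide_window = amide_window)
}

#' Full preprocessing chain
#'
#' Applies, in order: [quality_filter()], [truncate_and_mask()], per-pixel
#' [rubberband_baseline()] over the retained channels (paraffin channels
#' included, so the hull is computed on a contiguous range), then
#' [vector_normalise()] with the norm taken over analysis channels only.
#' Masked pixels are left untouched.
#'
#' @param cube a [spectral_cube()]
#' @param params a [preprocess_params()] list
#' @return the processed cube; provenance lists all four steps
#' @export
preprocess_cube <- function(cube, params = preprocess_params()) {
  cube <- quality_filter(cube, params$amide_low, params$amide_high,
                         lookup = params$amide_lookup, window = params$amide_window)
  cube <- truncate_and_mask(cube, params$keep, params$omit)
  d <- dim(cube$absorbance)
  flat <- matrix(cube$absorbance, d[1] * d[2], d[3])
  wn <- cube$wavenumbers
  mask <- cube$channel_mask
  for (i in which(cube$pixel_mask)) {
    v <- flat[i, ] - .lower_convex_minorant(wn, flat[i, ])
    nrm <- sqrt(sum(v[mask]^2))
    if (nrm == 0) stopf("zero norm over analysis channels (dead pixel?)")
    flat[i, ] <- v / nrm
  }
  cube$absorbance <- array(flat, d)
  cube$provenance <- c(cube$provenance, "rubberband_baseline", "vector_normalise")
  cube
}
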