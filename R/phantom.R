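# Synthetic tissue phantoms: hyperspectral cubes with known ground truth,
# built from Gaussian absorption bands, smooth baseline drift, paraffin
# contamination and additive detector noise, plus planted quality-gate
# violators. Every downstream stage of the pipeline is testable on these.

AMIDE_I_WN <- 1650
GATE_LOW <- 0.1
GATE_HIGH <- 2.0
# CH-bend paraffin contamination bands inside the omitted 1350-1500 region
PARAFFIN_BANDS <- data.frame(centre = c(1378, 1462), rel_amp = c(0.8, 1.0),
                             sigma = c(10, 12))

#' Tissue spectral profile
#'
#' Defines the noise-free spectrum of one tissue class as a sum of Gaussian
#' absorption bands plus a smooth polynomial baseline, with an additive
#' noise scale. Every profile must contain an Amide I band at 1650 cm^-1 so
#' the Amide I quality gate is meaningful on generated data.
#'
#' @param class_name class label
#' @param bands data frame with columns `centre` (cm^-1), `amplitude` (AU,
#'   >= 0) and `sigma` (cm^-1, > 0; Gaussian standard deviation)
#' @param baseline_coeffs polynomial coefficients (intercept first) in the
#'   scaled coordinate u = (wn - min) / (max - min) in `[0, 1]`
#' @param noise_sigma additive zero-mean Gaussian noise sd per channel (AU)
#' @return an object of class `tissue_profile`
#' @export
tissue_profile <- function(class_name, bands,
                           baseline_coeffs = 0, noise_sigma = 0) {
  bands <- as.data.frame(bands)
  need <- c("centre", "amplitude", "sigma")
  if (!all(need %in% names(bands))) {
    stopf("bands must have columns centre, amplitude, sigma")
  }
  if (any(bands$amplitude < 0)) stopf("invalid bands: amplitudes must be >= 0")
  if (any(bands$sigma <= 0)) stopf("invalid bands: widths (sigma) must be > 0")
  if (noise_sigma < 0) stopf("invalid noise_sigma: must be >= 0")
  if (!any(abs(bands$centre - AMIDE_I_WN) < 1e-9)) {
    stopf("invalid bands: profile '%s' must include an Amide I band at %g cm^-1",
          class_name, AMIDE_I_WN)
  }
  structure(list(class_name = as.character(class_name), bands = bands,
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 noise_sigma = noise_sigma),
            class = "tissue_profile")
}

#' Phantom specification
#'
#' @param class_profiles list of [tissue_profile()] objects
#' @param image_shape integer `(rows, cols)`
#' @param region_layout either the string `"stripes"` (vertical stripes, one
#'   per class, in profile order) or a character matrix of class names of
#'   shape `image_shape` covering every pixel
#' @param n_outlier_pixels number of planted Amide I quality-gate violators
#' @param paraffin_band amplitude (AU) of the paraffin contamination bands
#'   added inside 1350-1500 cm^-1 (0 = no contamination)
#' @param wavenumber_grid numeric `(from, to, step)` in cm^-1
#' @param seed integer RNG seed used by [generate_phantom()]
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(class_profiles, image_shape = c(42, 49),
                         region_layout = "stripes", n_outlier_pixels = 0,
                         paraffin_band = 0,
                         wavenumber_grid = c(900, 1800, 4), seed = 1) {
  if (!length(class_profiles) ||
      !all(vapply(class_profiles, inherits, TRUE, "tissue_profile"))) {
    stopf("invalid class_profiles: must be a non-empty list of tissue_profile")
  }
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 1L)) {
    stopf("invalid image_shape: need two positive integers")
  }
  npix <- prod(image_shape)
  classes <- vapply(class_profiles, `[[`, "", "class_name")
  if (anyDuplicated(classes)) stopf("invalid class_profiles: duplicate class names")
  if (is.matrix(region_layout)) {
    if (!identical(dim(region_layout), image_shape)) {
      stopf("invalid region_layout: matrix shape != image_shape")
    }
    if (!all(region_layout %in% classes)) {
      stopf("invalid region_layout: contains unknown class names")
    }
  } else if (!identical(region_layout, "stripes")) {
    stopf("invalid region_layout: must be \"stripes\" or a class-name matrix")
  }
  if (n_outlier_pixels < 0 || n_outlier_pixels > npix) {
    stopf("invalid n_outlier_pixels: must be in [0, total pixels]")
  }
  if (paraffin_band < 0) stopf("invalid paraffin_band: must be >= 0")
  if (length(wavenumber_grid) != 3L || wavenumber_grid[3] <= 0 ||
      wavenumber_grid[2] <= wavenumber_grid[1]) {
    stopf("invalid wavenumber_grid: need (from, to, step) with to > from, step > 0")
  }
  structure(list(class_profiles = class_profiles, image_shape = image_shape,
                 region_layout = region_layout,
                 n_outlier_pixels = as.integer(n_outlier_pixels),
                 paraffin_band = paraffin_band,
                 wavenumber_grid = as.numeric(wavenumber_grid),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Evaluate a profile's clean (noise-free) spectrum on a grid.
profile_spectrum <- function(profile, wn, paraffin_band = 0) {
  u <- if (length(wn) > 1) (wn - min(wn)) / (max(wn) - min(wn)) else wn * 0
  v <- rep(0, length(wn))
  for (i in seq_len(nrow(profile$bands))) {
    b <- profile$bands[i, ]
    v <- v + b$amplitude * exp(-(wn - b$centre)^2 / (2 * b$sigma^2))
  }
  for (k in seq_along(profile$baseline_coeffs)) {
    v <- v + profile$baseline_coeffs[k] * u^(k - 1)
  }
  if (paraffin_band > 0) {
    for (i in seq_len(nrow(PARAFFIN_BANDS))) {
      pb <- PARAFFIN_BANDS[i, ]
      v <- v + paraffin_band * pb$rel_amp * exp(-(wn - pb$centre)^2 / (2 * pb$sigma^2))
    }
  }
  v
}

# Expand the layout into a rows x cols class-name matrix.
layout_matrix <- function(spec) {
  if (is.matrix(spec$region_layout)) return(spec$region_layout)
  classes <- vapply(spec$class_profiles, `[[`, "", "class_name")
  cols <- spec$image_shape[2]
  stripe <- classes[ceiling(seq_len(cols) / (cols / length(classes)))]
  matrix(rep(stripe, each = spec$image_shape[1]), spec$image_shape[1], cols)
}

#' Generate a hyperspectral tissue phantom
#'
#' Builds a cube whose pixels are class spectra (Gaussian bands + polynomial
#' baseline + shared paraffin contamination) plus independent additive
#' Gaussian channel noise, then plants exactly `n_outlier_pixels` quality-gate
#' violators by rescaling whole pixel spectra so their Amide I (1650 cm^-1)
#' absorbance falls below 0.1 (half of them) or above 2 (the rest).
#' Non-outlier pixels whose noise draw would itself breach the gate have
#' their noise redrawn, so the planted count is exact for any noise level.
#' Generation is fully reproducible from `spec$seed`.
#'
#' @param spec a [phantom_spec()]
#' @return list with elements `cube` (a [spectral_cube()]) and
#'   `ground_truth` (character matrix of per-pixel class names)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  wn <- seq(spec$wavenumber_grid[1], spec$wavenumber_grid[2],
            by = spec$wavenumber_grid[3])
  rows <- spec$image_shape[1]; cols <- spec$image_shape[2]
  npix <- rows * cols; p <- length(wn)
  amide_ch <- match_channel(wn, AMIDE_I_WN)
  layout <- layout_matrix(spec)
  classes <- vapply(spec$class_profiles, `[[`, "", "class_name")
  clean <- t(vapply(spec$class_profiles, profile_spectrum,
                    numeric(p), wn = wn, paraffin_band = spec$paraffin_band))
  rownames(clean) <- classes
  noise_sd <- setNames(vapply(spec$class_profiles, `[[`, 0, "noise_sigma"), classes)

  with_seed(spec$seed, {
    cls_idx <- match(as.vector(layout), classes)
    flat <- clean[cls_idx, , drop = FALSE] +
      matrix(rnorm(npix * p), npix, p) * noise_sd[cls_idx]

    # planted gate violators: rescale whole spectra at the Amide I channel
    out_idx <- if (spec$n_outlier_pixels > 0) {
      sample.int(npix, spec$n_outlier_pixels)
    } else {
      integer()
    }
    n_low <- ceiling(length(out_idx) / 2)
    targets <- c(rep(GATE_LOW / 2, n_low),
                 rep(GATE_HIGH * 1.25, length(out_idx) - n_low))
    for (k in seq_along(out_idx)) {
      i <- out_idx[k]
      a <- flat[i, amide_ch]
      if (!is.finite(a) || a <= 0) {  # degenerate pixel: rebuild from clean
        flat[i, ] <- clean[cls_idx[i], ]
        a <- flat[i, amide_ch]
      }
      flat[i, ] <- flat[i, ] * (targets[k] / a)
    }

    # redraw noise for non-outliers pushed outside the gate by noise alone
    nonout <- setdiff(seq_len(npix), out_idx)
    bad <- nonout[flat[nonout, amide_ch] < GATE_LOW |
                    flat[nonout, amide_ch] > GATE_HIGH]
    for (i in bad) {
      for (attempt in 1:100) {
        flat[i, ] <- clean[cls_idx[i], ] + rnorm(p) * noise_sd[cls_idx[i]]
        a <- flat[i, amide_ch]
        if (a >= GATE_LOW && a <= GATE_HIGH) break
        if (attempt == 100) flat[i, amide_ch] <- clean[cls_idx[i], amide_ch]
      }
    }
  })

  cube <- spectral_cube(array(flat, c(rows, cols, p)), wn,
                        provenance = sprintf("generate_phantom(seed=%d)", spec$seed))
  list(cube = cube, ground_truth = layout)
}

#' Default seven-class phantom specification
#'
#' Mirrors the tissue roster of an oral-cancer FTIR study: OSCC (carcinoma),
#' CS (inflamed tumour stroma), BL/ML (progenitor and maturation epithelial
#' layers), NS (pre-existing normal stroma), SM (submucosa, e.g. skeletal
#' muscle) and LYM (lymphoid tissue). All classes share Amide I/II and
#' fingerprint bands; each carries two class-specific bands at wavenumbers
#' in the amide shoulder regions where real tissue contrasts concentrate.
#' The profiles are deterministic; `seed` only drives noise realisation and
#' outlier placement in [generate_phantom()].
#'
#' @param seed integer seed stored in the returned spec
#' @param noise_sigma additive channel noise sd (AU); the documented default
#'   0.012 is about 1.3% of the Amide I peak
#' @param image_shape pixel grid, default `c(42, 49)` so seven equal-width
#'   class stripes tile the image
#' @param n_outlier_pixels planted quality-gate violators, default 12
#' @param paraffin_band paraffin contamination amplitude, default 0.25
#' @return a [phantom_spec()] with seven classes
#' @export
default_seven_class_spec <- function(seed = 1, noise_sigma = 0.012,
                                     image_shape = c(42, 49),
                                     n_outlier_pixels = 12,
                                     paraffin_band = 0.25) {
  common <- data.frame(
    centre = c(1650, 1540, 1240, 1080, 1030),
    amplitude = c(0.90, 0.52, 0.22, 0.18, 0.12),
    sigma = c(28, 22, 30, 25, 20)
  )
  extras <- list(
    OSCC = data.frame(centre = c(1562, 1170), amplitude = c(0.18, 0.10), sigma = c(8, 12)),
    CS   = data.frame(centre = c(1570, 1684), amplitude = c(0.16, 0.14), sigma = c(8, 9)),
    BL   = data.frame(centre = c(1518, 1632), amplitude = c(0.16, 0.14), sigma = c(8, 9)),
    ML   = data.frame(centre = c(1699, 1514), amplitude = c(0.15, 0.12), sigma = c(8, 8)),
    NS   = data.frame(centre = c(1514, 1680), amplitude = c(0.18, 0.12), sigma = c(8, 9)),
    SM   = data.frame(centre = c(1643, 1510), amplitude = c(0.16, 0.14), sigma = c(8, 8)),
    LYM  = data.frame(centre = c(1715, 1703), amplitude = c(0.16, 0.12), sigma = c(8, 8))
  )
  drift <- list(OSCC = c(0.05, 0.02), CS = c(0.04, 0.03), BL = c(0.05, -0.02),
                ML = c(0.03, 0.02), NS = c(0.04, 0.01), SM = c(0.05, 0.03),
                LYM = c(0.03, -0.01))
  profiles <- lapply(names(extras), function(cl) {
    tissue_profile(cl, rbind(common, extras[[cl]]),
                   baseline_coeffs = drift[[cl]], noise_sigma = noise_sigma)
  })
  phantom_spec(profiles, image_shape = image_shape,
               region_layout = "stripes", n_outlier_pixels = n_outlier_pixels,
               paraffin_band = paraffin_band,
               wavenumber_grid = c(900, 1800, 4), seed = seed)
}

#' Two-class phantom differing at exactly two channels
#'
#' Both classes share the same band set; class `A` adds one very narrow band
#' at `wn_a` and class `B` one at `wn_b` (sigma 1 cm^-1, so on a 4 cm^-1
#' grid the difference is confined to those two channels). Used to test
#' that metric ranking recovers a planted two-channel signal.
#'
#' @param seed integer seed
#' @param wn_a,wn_b on-grid wavenumbers carrying the class contrast
#' @param delta amplitude of the class-specific bands (AU)
#' @param noise_sigma additive channel noise sd (AU)
#' @param image_shape pixel grid, default `c(14, 14)`
#' @return a two-class [phantom_spec()]
#' @export
two_channel_contrast_spec <- function(seed = 1, wn_a = 1600, wn_b = 1700,
                                      delta = 0.25, noise_sigma = 0.15,
                                      image_shape = c(14, 14)) {
  common <- data.frame(centre = c(1650, 1540, 1240),
                       amplitude = c(0.90, 0.50, 0.20),
                       sigma = c(28, 22, 30))
  pa <- tissue_profile("A", rbind(common, data.frame(
    centre = wn_a, amplitude = delta, sigma = 1)), noise_sigma = noise_sigma)
  pb <- tissue_profile("B", rbind(common, data.frame(
    centre = wn_b, amplitude = delta, sigma = 1)), noise_sigma = noise_sigma)
  phantom_spec(list(pa, pb), image_shape = image_shape,
               region_layout = "stripes", n_outlier_pixels = 0,
               paraffin_band = 0, wavenumber_grid = c(900, 1800, 4),
               seed = seed)
}
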