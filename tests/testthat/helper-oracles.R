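# Independent oracles and small fixture builders used across the suite.

# Exhaustive Mann-Whitney pair counting: P(pos > neg) + P(pos == neg)/2.
brute_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# O(n^2) greatest-convex-minorant oracle: the lower hull boundary at x_k is
# the minimum over all chords (i <= k <= j) of the chord value at x_k.
gcm_oracle <- function(x, y) {
  n <- length(y)
  base <- y
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ks <- i:j
      chord <- y[i] + (y[j] - y[i]) * (x[ks] - x[i]) / (x[j] - x[i])
      base[ks] <- pmin(base[ks], chord)
    }
  }
  base
}

# Small labelled set with given per-class channel means plus noise.
make_labelled <- function(class_means, n_per_class = 20, noise = 0.05,
                          seed = 1, wavenumbers = NULL) {
  classes <- rownames(class_means)
  p <- ncol(class_means)
  wavenumbers <- wavenumbers %||% seq(1000, by = 4, length.out = p)
  set.seed(seed)
  values <- do.call(rbind, lapply(classes, function(cl) {
    matrix(rep(class_means[cl, ], each = n_per_class), n_per_class, p) +
      matrix(rnorm(n_per_class * p, sd = noise), n_per_class, p)
  }))
  labelled_spectra(values, wavenumbers,
                   labels = rep(classes, each = n_per_class))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny cube with prescribed Amide I (1650 cm^-1) values per pixel.
cube_with_amide <- function(amide_values, p = 26) {
  rows <- nrow(amide_values); cols <- ncol(amide_values)
  wn <- seq(1600, by = 4, length.out = p)
  ch <- which.min(abs(wn - 1650))
  arr <- array(0.5, c(rows, cols, p))
  arr[, , ch] <- amide_values
  spectral_cube(arr, wn)
}

# Deterministic committee model over two classes with prescribed PDFs,
# built from explicit training ratios.
toy_two_class_model <- function() {
  wn <- c(1000, 1004, 1008)
  set.seed(42)
  va <- cbind(rnorm(30, 2, 0.1), rnorm(30, 1, 0.05), runif(30, 0.4, 0.6))
  vb <- cbind(rnorm(30, 1, 0.1), rnorm(30, 2, 0.05), runif(30, 0.4, 0.6))
  train <- labelled_spectra(rbind(va, vb), wn, rep(c("A", "B"), each = 30))
  mets <- generate_metrics(train)
  ranked <- rank_metrics(mets, train)
  build_model(ranked, k = 2, metadata = list(wavenumbers = wn))
}
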