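# Class-conditional probability density estimators for ratio values.
# Default is a Gaussian kernel density (Silverman bandwidth) tabulated on a
# 512-point grid spanning the central 99.9% of the training ratios padded by
# four bandwidths, renormalised to integrate to exactly 1 over its support,
# with a small floor so no likelihood is ever zero.

PDF_FLOOR <- 1e-12

#' Fit a ratio probability density
#'
#' @param x numeric training ratio values (undefined ratios already removed)
#' @param estimator `"kernel"` (Gaussian KDE, Silverman bandwidth) or
#'   `"histogram"`
#' @param bw optional bandwidth override (kernel estimator)
#' @param n_grid tabulation grid size
#' @return an object of class `ratio_pdf`, or `NULL` when `x` is empty (an
#'   "empty PDF": the metric cannot represent that class)
#' @export
fit_ratio_pdf <- function(x, estimator = c("kernel", "histogram"),
                          bw = NULL, n_grid = 512) {
  estimator <- match.arg(estimator)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NULL)
  if (estimator == "kernel") {
    if (is.null(bw)) {
      bw <- if (n >= 2 && sd(x) > 0) {
        stats::bw.nrd0(x)
      } else {
        # degenerate sample (single point or zero spread): bandwidth scales
        # with the ratio magnitude so distinct degenerate classes remain
        # distinguishable
        max(abs(mean(x)) * 1e-3, 1e-12)
      }
    }
    core <- if (n > 2) quantile(x, c(5e-4, 1 - 5e-4), names = FALSE) else range(x)
    support <- c(core[1] - 4 * bw, core[2] + 4 * bw)
    d <- stats::density(x, bw = bw, from = support[1], to = support[2],
                        n = n_grid)
    gx <- d$x; gy <- pmax(d$y, 0)
  } else {
    bw <- NULL
    rng <- range(x)
    pad <- max(diff(rng), abs(mean(x)), 1e-6) * 0.05
    support <- c(rng[1] - pad, rng[2] + pad)
    breaks <- seq(support[1], support[2], length.out = max(11L, ceiling(sqrt(n)) + 1L))
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    gx <- seq(support[1], support[2], length.out = n_grid)
    gy <- h$density[pmin(pmax(findInterval(gx, h$breaks, all.inside = TRUE), 1L),
                         length(h$density))]
  }
  # renormalise so the tabulated density integrates to 1 over the support
  area <- sum((gy[-1] + gy[-length(gy)]) / 2 * diff(gx))
  if (area > 0) gy <- gy / area
  structure(list(kind = estimator, x = gx, y = gy, support = support,
                 bw = bw, n_train = n, floor = PDF_FLOOR),
            class = "ratio_pdf")
}

#' Evaluate a fitted ratio density
#'
#' Linear interpolation on the tabulated grid; outside the support the
#' density takes the floor value, and everywhere the result is at least the
#' floor (no zero likelihoods in committee voting).
#'
#' @param pdf a `ratio_pdf` (or `NULL`, giving the floor everywhere)
#' @param x numeric evaluation points
#' @return numeric densities `>= pdf$floor`
#' @export
eval_pdf <- function(pdf, x) {
  if (is.null(pdf)) return(rep(PDF_FLOOR, length(x)))
  y <- approx(pdf$x, pdf$y, xout = x, yleft = pdf$floor, yright = pdf$floor,
              rule = 2)$y
  y[x < pdf$support[1] | x > pdf$support[2]] <- pdf$floor
  pmax(y, pdf$floor)
}

#' @export
print.ratio_pdf <- function(x, ...) {
  cat(sprintf("<ratio_pdf> %s estimator, n_train=%d, support [%.4g, %.4g]%s\n",
              x$kind, x$n_train, x$support[1], x$support[2],
              if (!is.null(x$bw)) sprintf(", bw=%.4g", x$bw) else ""))
  invisible(x)
}

# Trapezoid integral of a tabulated pdf over its support (for tests/checks).
pdf_mass <- function(pdf, lo = pdf$support[1], hi = pdf$support[2]) {
  sel <- pdf$x >= lo & pdf$x <= hi
  gx <- pdf$x[sel]; gy <- pdf$y[sel]
  if (length(gx) < 2) return(0)
  sum((gy[-1] + gy[-length(gy)]) / 2 * diff(gx))
}
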