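# The metric engine. A metric is an ordered wavenumber pair (numerator,
# denominator); its value on a spectrum is the ratio of absorbances at the
# two channels, characterised per class by a fitted PDF of training ratios.
# Metrics are generated for every ordered pair of analysis channels, scored
# by one-vs-rest ROC AUC on held-out spectra (Mann-Whitney tie convention,
# orientation-free: max(a, 1 - a)), and ranked per class.

#' Construct a metric (wavenumber pair)
#'
#' @param num_wn,den_wn numerator and denominator wavenumbers (cm^-1); must
#'   differ
#' @param class_pdfs named list of [fit_ratio_pdf()] objects (may be empty)
#' @param auc oriented AUC score, or `NA` if unscored
#' @param rank rank within a per-class ordering, or `NA`
#' @return an object of class `ftir_metric`
#' @export
metric_pair <- function(num_wn, den_wn, class_pdfs = list(), auc = NA_real_,
                        rank = NA_integer_) {
  if (isTRUE(all.equal(num_wn, den_wn))) {
    stopf("numerator and denominator wavenumbers must differ")
  }
  structure(list(num_wn = num_wn, den_wn = den_wn, class_pdfs = class_pdfs,
                 auc = auc, rank = rank),
            class = "ftir_metric")
}

#' @export
print.ftir_metric <- function(x, ...) {
  cat(sprintf("<metric> %g/%g cm^-1%s%s\n", x$num_wn, x$den_wn,
              if (!is.na(x$auc)) sprintf(", AUC=%.4f", x$auc) else "",
              if (!is.na(x$rank)) sprintf(", rank %d", x$rank) else ""))
  invisible(x)
}

#' Absorbance ratio of a spectrum at two wavenumbers
#'
#' Returns `value(num) / value(den)` using nearest-channel lookup. When the
#' denominator magnitude is below `eps` the ratio is undefined and `NA` is
#' returned: callers must exclude such spectra from that metric's PDF and
#' scoring rather than impute.
#'
#' @param spectrum a [new_spectrum()] or numeric vector (with `wavenumbers`)
#' @param num_wn,den_wn wavenumbers (cm^-1); must resolve to different
#'   channels
#' @param eps denominator guard, default `1e-6` on the vector-normalised
#'   scale
#' @param wavenumbers grid when `spectrum` is a bare vector
#' @param channel_mask optional analysis mask; both channels must be
#'   unmasked if given
#' @return the ratio, or `NA_real_` (undefined)
#' @export
ratio_value <- function(spectrum, num_wn, den_wn, eps = 1e-6,
                        wavenumbers = NULL, channel_mask = NULL) {
  if (inherits(spectrum, "spectrum")) {
    v <- spectrum$values; wn <- spectrum$wavenumbers
  } else {
    v <- as.numeric(spectrum); wn <- wavenumbers
    if (is.null(wn)) stopf("wavenumbers required for a bare numeric spectrum")
  }
  i <- match_channel(wn, num_wn, what = "numerator")
  j <- match_channel(wn, den_wn, what = "denominator")
  if (i == j) stopf("numerator and denominator resolve to the same channel")
  if (!is.null(channel_mask) && (!channel_mask[i] || !channel_mask[j])) {
    stopf("metric wavenumbers must resolve to unmasked analysis channels")
  }
  if (abs(v[j]) < eps) return(NA_real_)
  v[i] / v[j]
}

# Ordered-pair table in the same num-major order as the C++ scan.
ordered_pairs <- function(channels) {
  p <- length(channels)
  num <- rep(seq_len(p), each = p - 1L)
  den <- unlist(lapply(seq_len(p), function(i) setdiff(seq_len(p), i)))
  data.frame(num_idx = num, den_idx = den,
             num_wn = channels[num], den_wn = channels[den])
}

# Column index of the analysis channels of a labelled_spectra set.
analysis_channels <- function(train, channels = NULL) {
  if (is.null(channels)) {
    idx <- which(train$channel_mask)
  } else {
    idx <- vapply(channels, match_channel, 0L, wavenumbers = train$wavenumbers)
    if (any(!train$channel_mask[idx])) {
      stopf("requested channels include masked (non-analysis) channels")
    }
  }
  idx
}

#' Generate a metric for every ordered wavenumber pair
#'
#' For `n` analysis channels this returns exactly `n * (n - 1)` metrics
#' (both orderings are distinct metrics), each carrying one fitted ratio
#' PDF per class present in the training data. Spectra with an undefined
#' ratio (denominator below `eps`) are excluded from that metric's PDFs; a
#' class with no usable ratio gets an empty (`NULL`) PDF and the metric is
#' excluded from ranking for every class.
#'
#' @param train a [labelled_spectra()] training set (at least 2 classes)
#' @param channels wavenumbers to pair up; default all analysis channels
#' @param eps denominator guard
#' @param estimator PDF estimator, see [fit_ratio_pdf()]
#' @return list of [metric_pair()] objects
#' @export
generate_metrics <- function(train, channels = NULL, eps = 1e-6,
                             estimator = "kernel") {
  stopifnot(inherits(train, "labelled_spectra"))
  classes <- sort(unique(train$labels))
  if (length(classes) < 2L) stopf("need at least 2 classes to train metrics")
  idx <- analysis_channels(train, channels)
  if (length(idx) < 2L) stopf("need at least 2 analysis channels")
  pairs <- ordered_pairs(idx)
  wn <- train$wavenumbers
  V <- train$values
  lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$num_idx[k]; j <- pairs$den_idx[k]
    ok <- abs(V[, j]) >= eps
    r <- V[ok, i] / V[ok, j]
    lab <- train$labels[ok]
    pdfs <- lapply(classes, function(cl) fit_ratio_pdf(r[lab == cl],
                                                       estimator = estimator))
    names(pdfs) <- classes
    metric_pair(wn[i], wn[j], class_pdfs = pdfs)
  })
}

# Mann-Whitney AUC (ties count 1/2) of values `v` for positives `pos`.
rank_auc <- function(v, pos) {
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) {
    stopf("AUC needs at least one positive and one negative defined ratio")
  }
  rk <- rank(v)  # average ranks implement the tie = 1/2 convention
  (sum(rk[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Score a metric by held-out one-vs-rest ROC AUC
#'
#' Computes the ratio of every test spectrum, drops undefined ratios, and
#' returns the oriented AUC `max(a, 1 - a)` of the positive-vs-rest
#' separation, with ties counted 1/2 (Mann-Whitney convention). The raw
#' (unoriented) AUC is attached as attribute `"raw"`.
#'
#' @param metric a [metric_pair()]
#' @param test a [labelled_spectra()] held-out set
#' @param positive_class class treated as positive
#' @param eps denominator guard
#' @return oriented AUC in `[0.5, 1]`, with attribute `raw`
#' @export
score_metric_auc <- function(metric, test, positive_class, eps = 1e-6) {
  i <- match_channel(test$wavenumbers, metric$num_wn)
  j <- match_channel(test$wavenumbers, metric$den_wn)
  ok <- abs(test$values[, j]) >= eps
  r <- test$values[ok, i] / test$values[ok, j]
  a <- rank_auc(r, test$labels[ok] == positive_class)
  structure(max(a, 1 - a), raw = a)
}

#' Rank metrics per class by oriented AUC
#'
#' Metrics are scored with [score_metric_auc()] for each class and sorted in
#' decreasing oriented AUC; ties are broken by lower numerator then lower
#' denominator wavenumber, so rankings are fully deterministic. Metrics with
#' an empty PDF for any class are excluded. Each returned metric has its
#' `auc` (for that class) and `rank` fields set.
#'
#' @param metrics list of [metric_pair()] from [generate_metrics()]
#' @param test held-out [labelled_spectra()] used for scoring
#' @param per_class if `FALSE`, a single global ranking by the best AUC over
#'   classes is returned under the name `"global"`
#' @param eps denominator guard
#' @return named list: class -> list of ranked metrics
#' @export
rank_metrics <- function(metrics, test, per_class = TRUE, eps = 1e-6) {
  classes <- sort(unique(test$labels))
  usable <- vapply(metrics, function(m) {
    length(m$class_pdfs) == 0L || !any(vapply(m$class_pdfs, is.null, TRUE))
  }, TRUE)
  metrics <- metrics[usable]
  auc <- vapply(classes, function(cl) {
    vapply(metrics, function(m) as.numeric(score_metric_auc(m, test, cl, eps)),
           0)
  }, numeric(length(metrics)))
  auc <- matrix(auc, nrow = length(metrics),
                dimnames = list(NULL, classes))
  num <- vapply(metrics, `[[`, 0, "num_wn")
  den <- vapply(metrics, `[[`, 0, "den_wn")
  rank_one <- function(a) {
    ord <- order(-a, num, den)
    lapply(seq_along(ord), function(r) {
      m <- metrics[[ord[r]]]
      m$auc <- a[ord[r]]
      m$rank <- r
      m
    })
  }
  if (per_class) {
    setNames(lapply(classes, function(cl) rank_one(auc[, cl])), classes)
  } else {
    list(global = rank_one(apply(auc, 1, max)))
  }
}

#' Fast per-class ranking of all channel pairs
#'
#' Compiled scan over every ordered pair of analysis channels: for each pair
#' and class it computes the oriented one-vs-rest AUC of the scoring-set
#' ratios (same arithmetic as [score_metric_auc()], verified in the test
#' suite). Returns a ranking table rather than metric objects, so exhaustive
#' scans over tens of thousands of pairs stay cheap; use
#' [committee_from_ranking()] to materialise the top metrics with PDFs.
#'
#' @param score a [labelled_spectra()] scoring set
#' @param channels wavenumbers to pair; default all analysis channels
#' @param eps denominator guard
#' @return data frame with columns `class`, `rank`, `num_wn`, `den_wn`,
#'   `auc`, sorted by class then rank (AUC descending, wavenumber
#'   tie-break); pairs unscorable for a class (no defined positive or
#'   negative ratio) are dropped from that class's ranking, and the total
#'   number of scanned ordered pairs `n (n - 1)` is kept in attribute
#'   `n_pairs`
#' @export
rank_channel_pairs <- function(score, channels = NULL, eps = 1e-6) {
  stopifnot(inherits(score, "labelled_spectra"))
  classes <- sort(unique(score$labels))
  if (length(classes) < 2L) stopf("need at least 2 classes")
  idx <- analysis_channels(score, channels)
  pairs <- ordered_pairs(score$wavenumbers[idx])
  cls <- match(score$labels, classes)
  auc <- .all_pairs_auc(score$values[, idx, drop = FALSE],
                        as.integer(cls), length(classes), eps)
  out <- do.call(rbind, lapply(seq_along(classes), function(c) {
    a <- auc[, c]
    keep <- which(!is.na(a))
    ord <- keep[order(-a[keep], pairs$num_wn[keep], pairs$den_wn[keep])]
    data.frame(class = classes[c], rank = seq_along(ord),
               num_wn = pairs$num_wn[ord], den_wn = pairs$den_wn[ord],
               auc = a[ord])
  }))
  rownames(out) <- NULL
  # every ordered pair was scanned even if unscorable for some class
  attr(out, "n_pairs") <- nrow(pairs)
  out
}

#' Wavenumber importance histogram of top-ranked metrics
#'
#' Counts how often each wavenumber appears among the numerators and
#' denominators of the five top-ranked metrics of each class (so counts per
#' class sum to 10), the standard importance summary for this analysis.
#'
#' @param top_metrics named list: class -> exactly 5 metrics (objects with
#'   `num_wn`/`den_wn` fields)
#' @return named list: class -> named integer vector of counts, sorted by
#'   decreasing count then increasing wavenumber
#' @export
importance_histogram <- function(top_metrics) {
  lapply(top_metrics, function(ms) {
    if (length(ms) != 5L) {
      stopf("importance histogram requires exactly 5 metrics per class, got %d",
            length(ms))
    }
    wns <- unlist(lapply(ms, function(m) c(m$num_wn, m$den_wn)))
    tab <- table(wns)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    counts[order(-counts, as.numeric(names(counts)))]
  })
}
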