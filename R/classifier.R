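# Committee-vote multi-class classifier. The top-k metrics per class form a
# committee; each metric turns a spectrum's ratio into class likelihoods via
# its per-class PDFs, the likelihoods become a per-metric posterior
# (likelihood x prior, normalised over classes), and the class scores are
# the mean posterior over all committee metrics with a defined ratio.

#' Build a committee discriminator model
#'
#' @param ranked named list class -> ranked metrics (from [rank_metrics()]
#'   or [committee_from_ranking()]); each metric must carry a non-empty PDF
#'   for every class
#' @param k committee size per class (default 5)
#' @param prior per-class prior weights (default uniform); normalised
#'   internally
#' @param eps denominator guard used at prediction time
#' @param combine `"mean_posterior"` (equal-weight vote) or `"log_likelihood"`
#'   (sum of log likelihoods across committee metrics)
#' @param metadata free-form list (preprocessing parameters, seed, ...)
#' @return an object of class `discriminator_model`
#' @export
build_model <- function(ranked, k = 5, prior = NULL, eps = 1e-6,
                        combine = c("mean_posterior", "log_likelihood"),
                        metadata = list()) {
  combine <- match.arg(combine)
  classes <- names(ranked)
  if (length(classes) < 2L) stopf("model needs at least 2 classes")
  committee <- lapply(classes, function(cl) {
    ms <- ranked[[cl]]
    if (length(ms) < k) {
      stopf("class '%s' has only %d ranked metrics, need k = %d",
            cl, length(ms), k)
    }
    ms <- ms[seq_len(k)]
    for (m in ms) {
      if (!all(classes %in% names(m$class_pdfs)) ||
          any(vapply(m$class_pdfs[classes], is.null, TRUE))) {
        stopf("class '%s' committee contains a metric with an empty PDF", cl)
      }
    }
    ms
  })
  names(committee) <- classes
  prior <- prior %||% rep(1 / length(classes), length(classes))
  if (length(prior) != length(classes) || any(prior <= 0)) {
    stopf("prior must be a positive weight per class")
  }
  structure(list(classes = classes, k = k, committee = committee,
                 prior = prior / sum(prior), eps = eps, combine = combine,
                 metadata = metadata),
            class = "discriminator_model")
}

#' @export
print.discriminator_model <- function(x, ...) {
  cat(sprintf("<discriminator_model> %d classes, k=%d (%d committee slots), %s vote\n",
              length(x$classes), x$k, x$k * length(x$classes), x$combine))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

# Flat list of all committee metrics (duplicates across classes allowed).
committee_metrics <- function(model) unlist(model$committee, recursive = FALSE)

# Core vote: values = n x p matrix on the model's grid. Returns an n x K
# probability matrix (rows sum to 1); rows where every metric abstained are
# all-NA (unclassifiable).
committee_vote_matrix <- function(model, values, wavenumbers) {
  mets <- committee_metrics(model)
  K <- length(model$classes)
  n <- nrow(values)
  acc <- matrix(0, n, K, dimnames = list(NULL, model$classes))
  nvote <- numeric(n)
  loglik <- model$combine == "log_likelihood"
  if (loglik) acc[] <- 0  # accumulates log-likelihood + log-prior later
  for (m in mets) {
    i <- match_channel(wavenumbers, m$num_wn)
    j <- match_channel(wavenumbers, m$den_wn)
    dn <- values[, j]
    ok <- abs(dn) >= model$eps
    if (!any(ok)) next
    r <- values[ok, i] / dn[ok]
    lik <- vapply(model$classes, function(cl) eval_pdf(m$class_pdfs[[cl]], r),
                  numeric(length(r)))
    lik <- matrix(lik, ncol = K)
    if (loglik) {
      acc[ok, ] <- acc[ok, ] + log(lik)
    } else {
      post <- lik * rep(model$prior, each = nrow(lik))
      acc[ok, ] <- acc[ok, ] + post / rowSums(post)
    }
    nvote[ok] <- nvote[ok] + 1
  }
  out <- matrix(NA_real_, n, K, dimnames = list(NULL, model$classes))
  voted <- nvote > 0
  if (any(voted)) {
    if (loglik) {
      ll <- acc[voted, , drop = FALSE] +
        rep(log(model$prior), each = sum(voted))
      ll <- ll - apply(ll, 1, max)
      w <- exp(ll)
      out[voted, ] <- w / rowSums(w)
    } else {
      s <- acc[voted, , drop = FALSE] / nvote[voted]
      out[voted, ] <- s / rowSums(s)
    }
  }
  out
}

#' Committee class probabilities for one spectrum
#'
#' Every committee metric with a defined ratio votes; metrics whose
#' denominator falls below the guard abstain. The returned probabilities
#' sum to 1. If all metrics abstain the spectrum is unclassifiable and
#' `NULL` is returned (callers mark the pixel unlabelled).
#'
#' @param model a [build_model()] object
#' @param spectrum a [new_spectrum()] on the model's preprocessed grid, or
#'   a numeric vector
#' @return named numeric vector of class probabilities, or `NULL`
#' @export
committee_probabilities <- function(model, spectrum) {
  v <- if (inherits(spectrum, "spectrum")) spectrum$values else as.numeric(spectrum)
  wn <- if (inherits(spectrum, "spectrum")) spectrum$wavenumbers else
    model$metadata$wavenumbers
  if (is.null(wn)) stopf("spectrum has no wavenumber grid and model metadata stores none")
  pr <- committee_vote_matrix(model, matrix(v, 1), wn)[1, ]
  if (anyNA(pr)) return(NULL)
  pr
}

#' Predict the class of a spectrum
#'
#' The predicted label is the argmax of the committee probabilities (exact
#' ties broken by model class order); the confidence is the maximum
#' probability divided by the sum of all probabilities.
#'
#' @param object a `discriminator_model`
#' @param newdata a [new_spectrum()], numeric vector, or
#'   [labelled_spectra()] (predicts every row)
#' @param ... unused
#' @return for a single spectrum, a `prediction` object (fields
#'   `class_probabilities`, `predicted`, `confidence`); for a spectra set, a
#'   data frame with one row per spectrum plus a `probabilities` attribute
#' @export
predict.discriminator_model <- function(object, newdata, ...) {
  if (inherits(newdata, "labelled_spectra")) {
    pr <- committee_vote_matrix(object, newdata$values, newdata$wavenumbers)
    return(prediction_frame(object, pr))
  }
  pr <- committee_probabilities(object, newdata)
  if (is.null(pr)) {
    return(structure(list(class_probabilities = NULL,
                          predicted = NA_character_, confidence = NA_real_,
                          unclassifiable = TRUE),
                     class = "prediction"))
  }
  pick <- which.max(pr)  # first maximum = model class order tie-break
  structure(list(class_probabilities = pr,
                 predicted = object$classes[pick],
                 confidence = unname(pr[pick] / sum(pr)),
                 unclassifiable = FALSE),
            class = "prediction")
}

prediction_frame <- function(model, pr) {
  n <- nrow(pr)
  predicted <- rep(NA_character_, n)
  confidence <- rep(NA_real_, n)
  ok <- !is.na(pr[, 1])
  if (any(ok)) {
    pick <- max.col(pr[ok, , drop = FALSE], ties.method = "first")
    predicted[ok] <- model$classes[pick]
    sub <- pr[ok, , drop = FALSE]
    confidence[ok] <- sub[cbind(seq_len(nrow(sub)), pick)] / rowSums(sub)
  }
  structure(data.frame(predicted = predicted, confidence = confidence),
            probabilities = pr)
}

#' @export
print.prediction <- function(x, ...) {
  if (isTRUE(x$unclassifiable)) {
    cat("<prediction> unclassifiable (all committee metrics abstained)\n")
  } else {
    cat(sprintf("<prediction> %s (confidence %.3f)\n", x$predicted, x$confidence))
  }
  invisible(x)
}

#' Classify every pixel of a preprocessed cube
#'
#' @param model a `discriminator_model`
#' @param cube a [spectral_cube()] preprocessed with the model's stored
#'   parameters; its wavenumber grid must match the model metadata grid if
#'   one is stored
#' @return a [label_map()]: per-pixel predicted class and confidence;
#'   masked and unclassifiable pixels are labelled `"excluded"` with
#'   confidence 0
#' @export
predict_cube <- function(model, cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  mwn <- model$metadata$wavenumbers
  if (!is.null(mwn) && !isTRUE(all.equal(as.numeric(mwn), cube$wavenumbers))) {
    stopf("cube wavenumber grid does not match the model's stored grid")
  }
  d <- dim(cube$absorbance)
  flat <- matrix(cube$absorbance, d[1] * d[2], d[3])
  keep <- which(cube$pixel_mask)
  lab <- matrix("excluded", d[1], d[2])
  conf <- matrix(0, d[1], d[2])
  if (length(keep)) {
    pr <- committee_vote_matrix(model, flat[keep, , drop = FALSE],
                                cube$wavenumbers)
    pf <- prediction_frame(model, pr)
    ok <- !is.na(pf$predicted)
    lab[keep[ok]] <- pf$predicted[ok]
    conf[keep[ok]] <- pf$confidence[ok]
  }
  label_map(lab, conf)
}

#' Materialise committee metrics from a fast ranking table
#'
#' Takes the top `k` pairs per class from a [rank_channel_pairs()] table and
#' fits full per-class ratio PDFs on the metric-training set, giving the
#' per-class ranked metric lists [build_model()] expects.
#'
#' @param train metric-training [labelled_spectra()] (PDF fitting)
#' @param ranking data frame from [rank_channel_pairs()]
#' @param k committee size
#' @param eps denominator guard
#' @param estimator PDF estimator
#' @return named list class -> list of k ranked metrics with PDFs
#' @export
committee_from_ranking <- function(train, ranking, k = 5, eps = 1e-6,
                                   estimator = "kernel") {
  classes <- sort(unique(ranking$class))
  data_classes <- sort(unique(train$labels))
  setNames(lapply(classes, function(cl) {
    sub <- ranking[ranking$class == cl, ]
    picked <- list()
    r <- 0L
    # walk down the ranking, skipping pairs whose training ratios leave any
    # class without a PDF (e.g. a denominator channel pinned to zero by the
    # baseline correction for a whole class)
    while (length(picked) < k && r < nrow(sub)) {
      r <- r + 1L
      i <- match_channel(train$wavenumbers, sub$num_wn[r])
      j <- match_channel(train$wavenumbers, sub$den_wn[r])
      ok <- abs(train$values[, j]) >= eps
      ratios <- train$values[ok, i] / train$values[ok, j]
      lab <- train$labels[ok]
      pdfs <- setNames(lapply(data_classes, function(c2) {
        fit_ratio_pdf(ratios[lab == c2], estimator = estimator)
      }), data_classes)
      if (any(vapply(pdfs, is.null, TRUE))) next
      picked[[length(picked) + 1L]] <-
        metric_pair(sub$num_wn[r], sub$den_wn[r], class_pdfs = pdfs,
                    auc = sub$auc[r], rank = length(picked) + 1L)
    }
    if (length(picked) < k) {
      stopf("class '%s' has only %d usable ranked metrics, need k = %d",
            cl, length(picked), k)
    }
    picked
  }), classes)
}

#' Serialise a model to JSON
#'
#' The whole model (classes, committee wavenumbers, tabulated PDF grids,
#' prior, guard, metadata) is written as a single JSON document at full
#' double precision, so a save/load round trip reproduces predictions
#' bit-identically.
#'
#' @param model a `discriminator_model`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_model <- function(model, path) {
  ser_pdf <- function(p) {
    if (is.null(p)) return(NULL)
    list(kind = p$kind, x = p$x, y = p$y, support = p$support,
         bw = p$bw, n_train = p$n_train, floor = p$floor)
  }
  doc <- list(
    container = "ftirmetrics_model", version = 1L,
    classes = model$classes, k = model$k, prior = model$prior,
    eps = model$eps, combine = model$combine, metadata = model$metadata,
    committee = lapply(model$committee, function(ms) lapply(ms, function(m) {
      list(num_wn = m$num_wn, den_wn = m$den_wn, auc = m$auc, rank = m$rank,
           class_pdfs = lapply(m$class_pdfs, ser_pdf))
    }))
  )
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a model written by [write_model()]
#' @param path JSON file
#' @return a `discriminator_model`
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(doc$container, "ftirmetrics_model")) {
    stopf("not an ftirmetrics model container: %s", path)
  }
  de_pdf <- function(p) {
    if (is.null(p)) return(NULL)
    structure(list(kind = p$kind, x = as.numeric(p$x), y = as.numeric(p$y),
                   support = as.numeric(p$support), bw = p$bw,
                   n_train = as.integer(p$n_train), floor = p$floor),
              class = "ratio_pdf")
  }
  committee <- lapply(doc$committee, function(ms) lapply(ms, function(m) {
    metric_pair(m$num_wn, m$den_wn,
                class_pdfs = lapply(m$class_pdfs, de_pdf),
                auc = m$auc %||% NA_real_,
                rank = as.integer(m$rank %||% NA_integer_))
  }))
  structure(list(classes = unlist(doc$classes), k = doc$k,
                 committee = committee, prior = as.numeric(doc$prior),
                 eps = doc$eps, combine = doc$combine,
                 metadata = doc$metadata),
            class = "discriminator_model")
}
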