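# Training/testing protocol: equal per-image sampling, class x patient
# stratified five-fold cross-validation, and per-class one-vs-rest
# sensitivity/specificity reporting with fold-to-fold uncertainties.

#' Equal per-image random sampling
#'
#' Samples exactly `n_per_image` spectra from each image without
#' replacement, mitigating image-related bias. Reproducible given `seed`.
#'
#' @param data a [labelled_spectra()]
#' @param n_per_image spectra to draw from each image
#' @param seed integer seed
#' @return the sampled [labelled_spectra()]
#' @export
sample_balanced <- function(data, n_per_image, seed = 1) {
  stopifnot(inherits(data, "labelled_spectra"))
  by_img <- split(seq_along(data$image_id), data$image_id)
  small <- names(by_img)[vapply(by_img, length, 0L) < n_per_image]
  if (length(small)) {
    stopf("image '%s' has fewer than n_per_image = %d spectra",
          small[1], n_per_image)
  }
  idx <- with_seed(seed, {
    unlist(lapply(by_img, function(ix) sort(sample(ix, n_per_image))),
           use.names = FALSE)
  })
  subset_spectra(data, idx)
}

#' Class- and patient-stratified k-fold split
#'
#' Every spectrum lands in exactly one test fold. Within each class x
#' patient cell, shuffled indices are dealt round-robin with a rotating
#' starting fold, so every fold's share of each cell is within one spectrum
#' of every other fold's.
#'
#' @param data a [labelled_spectra()]
#' @param seed integer seed
#' @param n_folds number of folds (default 5)
#' @return list of `n_folds` elements, each `list(train = idx, test = idx)`
#' @export
five_fold_split <- function(data, seed = 1, n_folds = 5) {
  stopifnot(inherits(data, "labelled_spectra"))
  n <- length(data$labels)
  too_small <- names(which(table(data$labels) < n_folds))
  if (length(too_small)) {
    stopf("class '%s' has fewer than %d spectra", too_small[1], n_folds)
  }
  fold_of <- integer(n)
  offset <- 0L
  with_seed(seed, {
    for (cl in sort(unique(data$labels))) {
      for (pt in sort(unique(data$patient_id[data$labels == cl]))) {
        cell <- which(data$labels == cl & data$patient_id == pt)
        cell <- cell[sample.int(length(cell))]
        fold_of[cell] <- ((offset + seq_along(cell) - 1L) %% n_folds) + 1L
        offset <- (offset + length(cell)) %% n_folds
      }
    }
  })
  lapply(seq_len(n_folds), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Per-class sensitivity and specificity from a confusion matrix
#'
#' One-vs-rest reading of a multi-class confusion matrix (rows = true
#' class, columns = predicted; extra columns such as an "unclassified"
#' column are allowed and count against both measures):
#' sensitivity = 100 TP / (TP + FN), specificity = 100 TN / (TN + FP).
#'
#' @param confusion numeric matrix with named rows (true classes) and named
#'   columns covering at least the row classes
#' @return data frame: `class`, `sensitivity`, `specificity` (percent)
#' @export
sensitivity_specificity <- function(confusion) {
  confusion <- as.matrix(confusion)
  classes <- rownames(confusion)
  if (is.null(classes) || !all(classes %in% colnames(confusion))) {
    stopf("confusion matrix must have named rows and matching columns")
  }
  if (any(confusion < 0)) stopf("confusion counts must be non-negative")
  total <- sum(confusion)
  out <- lapply(classes, function(cl) {
    tp <- confusion[cl, cl]
    fn <- sum(confusion[cl, ]) - tp
    fp <- sum(confusion[, cl]) - tp
    tn <- total - tp - fn - fp
    if (tp + fn == 0) stopf("class '%s' has no positive test spectra", cl)
    if (tn + fp == 0) stopf("class '%s' has no negative test spectra", cl)
    data.frame(class = cl, sensitivity = 100 * tp / (tp + fn),
               specificity = 100 * tn / (tn + fp))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-validation parameters
#'
#' @param k committee size per class
#' @param eps ratio denominator guard
#' @param estimator PDF estimator (see [fit_ratio_pdf()])
#' @param inner_frac fraction of each training fold used for metric
#'   training (PDF fitting); the rest scores AUCs. Class-stratified.
#' @param n_folds cross-validation folds
#' @param combine committee vote rule (see [build_model()])
#' @param uncertainty `"sd"` (fold-to-fold standard deviation) or `"sem"`
#' @return a named parameter list
#' @export
cv_params <- function(k = 5, eps = 1e-6, estimator = "kernel",
                      inner_frac = 0.5, n_folds = 5,
                      combine = "mean_posterior", uncertainty = "sd") {
  list(k = k, eps = eps, estimator = estimator, inner_frac = inner_frac,
       n_folds = n_folds, combine = combine, uncertainty = uncertainty)
}

# Class-stratified two-way split of an index set.
inner_split <- function(labels, idx, frac, seed) {
  with_seed(seed, {
    first <- unlist(lapply(split(idx, labels[idx]), function(ix) {
      ix <- ix[sample.int(length(ix))]
      ix[seq_len(max(1L, round(length(ix) * frac)))]
    }), use.names = FALSE)
    list(train = sort(first), score = sort(setdiff(idx, first)))
  })
}

#' Train a committee model with the three-stage protocol
#'
#' Splits the data (class-stratified, `params$inner_frac`) into a
#' metric-training set for PDF fitting and a metric-scoring set for AUC
#' ranking, then assembles the top-k committee per class. This is exactly
#' the model-fitting step [cross_validate()] applies inside each fold.
#'
#' @param data a [labelled_spectra()]
#' @param params a [cv_params()] list
#' @param seed integer seed for the internal split
#' @return a `discriminator_model` (see [build_model()])
#' @export
train_committee <- function(data, params = cv_params(), seed = 1) {
  fit_stage_model(data, seq_along(data$labels), params, seed)
}

# Fit the three-stage model (PDF training / AUC scoring / committee) on one
# index set.
fit_stage_model <- function(data, idx, params, seed) {
  sp <- inner_split(data$labels, idx, params$inner_frac, seed)
  mtrain <- subset_spectra(data, sp$train)
  mscore <- subset_spectra(data, sp$score)
  ranking <- rank_channel_pairs(mscore, eps = params$eps)
  ranked <- committee_from_ranking(mtrain, ranking, k = params$k,
                                   eps = params$eps,
                                   estimator = params$estimator)
  build_model(ranked, k = params$k, eps = params$eps,
              combine = params$combine,
              metadata = list(wavenumbers = data$wavenumbers, seed = seed))
}

#' Cross-validated sensitivity/specificity of the metric pipeline
#'
#' For each fold: the training portion is split (class-stratified, default
#' 50/50) into a metric-training set (PDF fitting) and a metric-scoring set
#' (AUC ranking); the top-k metrics per class form the committee model,
#' which labels the held-out fold. Per-class sensitivity and specificity
#' are reported as mean +/- uncertainty across folds.
#'
#' @param data a [labelled_spectra()]
#' @param params a [cv_params()] list
#' @param seed integer seed driving fold assignment and inner splits
#' @return an object of class `cv_report`: `per_class` data frame, `folds`
#'   (per-fold confusion matrices), `params`, `seed`
#' @export
cross_validate <- function(data, params = cv_params(), seed = 1) {
  stopifnot(inherits(data, "labelled_spectra"))
  classes <- sort(unique(data$labels))
  folds <- five_fold_split(data, seed = seed, n_folds = params$n_folds)
  cols <- c(classes, "unclassified")
  confusions <- vector("list", length(folds))
  sens <- spec <- matrix(NA_real_, length(folds), length(classes),
                         dimnames = list(NULL, classes))
  for (f in seq_along(folds)) {
    model <- fit_stage_model(data, folds[[f]]$train, params,
                             seed = stage_seed(seed, 100 + f))
    test <- subset_spectra(data, folds[[f]]$test)
    pred <- predict(model, test)$predicted
    pred[is.na(pred)] <- "unclassified"
    cm <- table(factor(test$labels, levels = classes),
                factor(pred, levels = cols))
    cm <- matrix(as.integer(cm), length(classes), length(cols),
                 dimnames = list(classes, cols))
    confusions[[f]] <- cm
    ss <- sensitivity_specificity(cm)
    sens[f, ss$class] <- ss$sensitivity
    spec[f, ss$class] <- ss$specificity
  }
  scale <- if (identical(params$uncertainty, "sem")) {
    1 / sqrt(length(folds))
  } else {
    1
  }
  per_class <- data.frame(
    class = classes,
    n_spectra = as.integer(table(data$labels)[classes]),
    n_images = vapply(classes, function(cl) {
      length(unique(data$image_id[data$labels == cl]))
    }, 0L),
    sensitivity_mean = colMeans(sens),
    sensitivity_sd = apply(sens, 2, sd) * scale,
    specificity_mean = colMeans(spec),
    specificity_sd = apply(spec, 2, sd) * scale,
    row.names = NULL
  )
  structure(list(per_class = per_class, folds = confusions, params = params,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold cross-validation, seed %d\n",
              length(x$folds), x$seed))
  pc <- x$per_class
  cat(sprintf("  %-6s %9s %8s  %-14s %-14s\n",
              "class", "n_spectra", "n_images", "sensitivity(%)",
              "specificity(%)"))
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-6s %9d %8d  %5.1f +/- %-5.1f  %5.1f +/- %-5.1f\n",
                pc$class[i], pc$n_spectra[i], pc$n_images[i],
                pc$sensitivity_mean[i], pc$sensitivity_sd[i],
                pc$specificity_mean[i], pc$specificity_sd[i]))
  }
  invisible(x)
}

#' Write a cross-validation report
#'
#' `report.json` carries the full report; the CSV is a per-class table
#' (tissue, n_spectra, n_images, sensitivity +/- sd, specificity +/- sd).
#'
#' @param report a `cv_report`
#' @param json_path,csv_path output files (`NULL` to skip either)
#' @return `report`, invisibly
#' @export
write_cv_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(container = "ftirmetrics_cv_report", seed = report$seed,
           params = report$params, per_class = report$per_class,
           folds = lapply(report$folds, function(m) {
             list(true_classes = rownames(m), predicted = colnames(m),
                  counts = unclass(m))
           })),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(csv_path)) {
    write.csv(report$per_class, csv_path, row.names = FALSE)
  }
  invisible(report)
}
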