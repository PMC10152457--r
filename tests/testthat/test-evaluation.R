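# Evaluation protocol: balanced sampling, stratified folds, sensitivity/
# specificity arithmetic, cross-validation behaviour.

make_multi_image <- function(sizes, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  labelled_spectra(matrix(runif(n * 4), n, 4), seq(1000, 1012, 4),
                   labels = sample(c("A", "B"), n, replace = TRUE),
                   image_id = rep(names(sizes), sizes),
                   patient_id = rep("p1", n))
}

test_that("balanced sampling draws exactly n_per_image from each image", {
  d <- make_multi_image(c(img1 = 120, img2 = 150, img3 = 100))
  s <- sample_balanced(d, 100, seed = 5)
  expect_identical(as.vector(table(s$image_id)[c("img1", "img2", "img3")]),
                   rep(100L, 3))
  expect_identical(nrow(s$values), 300L)
  # determinism
  s2 <- sample_balanced(d, 100, seed = 5)
  expect_identical(s$values, s2$values)
  # sampling without replacement: boundary case includes the whole image
  s3 <- sample_balanced(d, 100, seed = 6)
  expect_identical(sum(s3$image_id == "img3"), 100L)
  expect_error(sample_balanced(d, 130, seed = 1), "img")
})

test_that("five-fold split partitions the data, stratified by class", {
  set.seed(2)
  d <- labelled_spectra(matrix(runif(500 * 3), 500, 3), c(1000, 1004, 1008),
                        labels = rep(c("A", "B", "C", "D", "E"), each = 100))
  folds <- five_fold_split(d, seed = 4)
  tests <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(tests)), 1:500)          # exhaustive
  expect_identical(sum(duplicated(unlist(tests))), 0L)  # disjoint
  for (f in folds) {
    expect_identical(sort(unique(c(f$train, f$test))), 1:500)
    expect_identical(as.vector(table(d$labels[f$test])), rep(20L, 5))
  }
})

test_that("patients are equally represented across folds within +/- 1", {
  d <- labelled_spectra(matrix(runif(100 * 3), 100, 3), c(1000, 1004, 1008),
                        labels = rep("A", 100),
                        patient_id = rep(c("p1", "p2"), each = 50))
  folds <- five_fold_split(d, seed = 9)
  for (f in folds) {
    counts <- table(factor(d$patient_id[f$test], levels = c("p1", "p2")))
    expect_true(all(abs(counts - 10) <= 1))
  }
  expect_error(five_fold_split(subset_spectra(d, 1:3), seed = 1), "fewer than")
})

test_that("sensitivity/specificity follow the one-vs-rest formulas", {
  cm <- matrix(c(9, 10, 1, 90), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  ss <- sensitivity_specificity(cm)
  expect_equal(ss$sensitivity[ss$class == "A"], 90)
  expect_equal(ss$specificity[ss$class == "A"], 90)
  # perfect classifier
  perfect <- diag(c(5, 8, 11))
  dimnames(perfect) <- list(c("A", "B", "C"), c("A", "B", "C"))
  ssp <- sensitivity_specificity(perfect)
  expect_equal(ssp$sensitivity, rep(100, 3))
  expect_equal(ssp$specificity, rep(100, 3))
  # degenerate: everything predicted as class A
  allA <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  allA[, "A"] <- c(10, 20, 30)
  ssa <- sensitivity_specificity(allA)
  expect_equal(ssa$sensitivity, c(100, 0, 0))
  expect_equal(ssa$specificity[ssa$class == "A"], 0)
  expect_error(sensitivity_specificity(matrix(-1, 1, 1,
                                              dimnames = list("A", "A"))),
               "non-negative")
})

test_that("a noise-free well-separated phantom cross-validates at 100%", {
  mk_prof <- function(name, extra_centre) {
    tissue_profile(name, data.frame(centre = c(1650, extra_centre),
                                    amplitude = c(0.9, 0.4),
                                    sigma = c(25, 10)),
                   noise_sigma = 0)
  }
  spec <- phantom_spec(list(mk_prof("A", 1100), mk_prof("B", 1250),
                            mk_prof("C", 1600)),
                       image_shape = c(10, 12), n_outlier_pixels = 0,
                       wavenumber_grid = c(900, 1800, 8), seed = 6)
  ph <- generate_phantom(spec)
  d <- cube_to_labelled(preprocess_cube(ph$cube), ph$ground_truth)
  rep <- cross_validate(d, cv_params(k = 3), seed = 2)
  expect_equal(rep$per_class$sensitivity_mean, rep(100, 3))
  expect_equal(rep$per_class$specificity_mean, rep(100, 3))
})

test_that("cross-validation is deterministic and its confusion rows sum to test counts", {
  ph <- generate_phantom(default_seven_class_spec(seed = 19,
                                                  image_shape = c(14, 21),
                                                  n_outlier_pixels = 0))
  d <- cube_to_labelled(preprocess_cube(ph$cube), ph$ground_truth)
  r1 <- cross_validate(d, cv_params(), seed = 5)
  r2 <- cross_validate(d, cv_params(), seed = 5)
  expect_identical(r1$per_class, r2$per_class)
  expect_identical(r1$folds, r2$folds)
  folds <- five_fold_split(d, seed = 5)
  for (f in seq_along(folds)) {
    cm <- r1$folds[[f]]
    truth <- table(factor(d$labels[folds[[f]]$test],
                          levels = rownames(cm)))
    expect_identical(unname(rowSums(cm)), as.numeric(truth))
  }
})

test_that("sensitivity does not improve as phantom noise grows", {
  sens_at <- function(noise, seeds) {
    mean(vapply(seeds, function(s) {
      spec <- default_seven_class_spec(seed = s, noise_sigma = noise,
                                       image_shape = c(10, 14),
                                       n_outlier_pixels = 0,
                                       paraffin_band = 0)
      spec$wavenumber_grid <- c(1500, 1756, 8)  # compact grid keeps this cheap
      ph <- generate_phantom(spec)
      d <- cube_to_labelled(preprocess_cube(ph$cube,
                                            preprocess_params(keep = c(1500, 1756),
                                                              omit = NULL)),
                            ph$ground_truth)
      mean(cross_validate(d, cv_params(k = 3), seed = s)$per_class$sensitivity_mean)
    }, 0))
  }
  seeds <- 1:10
  low <- sens_at(0.01, seeds)
  high <- sens_at(0.6, seeds)
  expect_gte(low, high)
})
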