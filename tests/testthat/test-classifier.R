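# Committee classifier: vote arithmetic, prediction contract, cube
# labelling, serialisation.

# Model with hand-set PDFs so vote arithmetic can be checked exactly:
# uniform densities on chosen supports.
flat_pdf <- function(lo, hi) {
  structure(list(kind = "kernel", x = c(lo, hi),
                 y = rep(1 / (hi - lo), 2), support = c(lo, hi),
                 bw = NULL, n_train = 10L, floor = 1e-12),
            class = "ratio_pdf")
}

hand_model <- function(metrics, classes = c("A", "B")) {
  ranked <- setNames(lapply(classes, function(cl) {
    lapply(seq_along(metrics), function(i) {
      m <- metrics[[i]]; m$rank <- i; m
    })
  }), classes)
  build_model(ranked, k = length(metrics),
              metadata = list(wavenumbers = c(1000, 1004, 1008)))
}

test_that("a single metric gives likelihood-normalised probabilities", {
  # ratio = 2: density 0.8 under A (support [1.75, 3] -> 0.8), 0.2 under B
  m <- metric_pair(1000, 1004,
                   class_pdfs = list(A = flat_pdf(1.75, 3), B = flat_pdf(1, 6)))
  model <- hand_model(list(m))
  pr <- committee_probabilities(model, new_spectrum(c(2, 1, 1), c(1000, 1004, 1008)))
  expect_equal(unname(pr), c(0.8, 0.2))
})

test_that("two metrics combine by the mean of per-metric posteriors", {
  m1 <- metric_pair(1000, 1004,
                    class_pdfs = list(A = flat_pdf(1.75, 3), B = flat_pdf(1, 6)))
  # second metric: ratio 1008/1004 = 1; posteriors 0.6 / 0.4
  m2 <- metric_pair(1008, 1004,
                    class_pdfs = list(A = flat_pdf(0.5, 1.5), B = flat_pdf(0.25, 1.75)))
  model <- hand_model(list(m1, m2))
  pr <- committee_probabilities(model, new_spectrum(c(2, 1, 1), c(1000, 1004, 1008)))
  expect_equal(unname(pr), c((0.8 + 0.6) / 2, (0.2 + 0.4) / 2))
  expect_equal(sum(pr), 1, tolerance = 1e-9)
})

test_that("equal densities for all classes give uniform probabilities", {
  m <- metric_pair(1000, 1004,
                   class_pdfs = list(A = flat_pdf(0, 5), B = flat_pdf(0, 5),
                                     C = flat_pdf(0, 5)))
  model <- hand_model(list(m), classes = c("A", "B", "C"))
  pr <- committee_probabilities(model, new_spectrum(c(2, 1, 1), c(1000, 1004, 1008)))
  expect_equal(unname(pr), rep(1 / 3, 3))
})

test_that("prediction takes the argmax with first-in-class-order tie-break", {
  m <- metric_pair(1000, 1004,
                   class_pdfs = list(A = flat_pdf(1.75, 3), B = flat_pdf(1, 6)))
  model <- hand_model(list(m))
  p <- predict(model, new_spectrum(c(2, 1, 1), c(1000, 1004, 1008)))
  expect_s3_class(p, "prediction")
  expect_identical(p$predicted, "A")
  expect_equal(p$confidence, 0.8)
  # exact tie: identical PDFs -> first class in model order wins
  mt <- metric_pair(1000, 1004,
                    class_pdfs = list(B2 = flat_pdf(0, 5), A2 = flat_pdf(0, 5)))
  tie_model <- hand_model(list(mt), classes = c("B2", "A2"))
  pt <- predict(tie_model, new_spectrum(c(2, 1, 1), c(1000, 1004, 1008)))
  expect_identical(pt$predicted, "B2")
  expect_equal(pt$confidence, 0.5)
})

test_that("metrics with undefined ratios abstain; all abstaining is unclassifiable", {
  m <- metric_pair(1000, 1004,
                   class_pdfs = list(A = flat_pdf(1.75, 3), B = flat_pdf(1, 6)))
  model <- hand_model(list(m))
  expect_null(committee_probabilities(model, new_spectrum(c(2, 0, 1),
                                                          c(1000, 1004, 1008))))
  p <- predict(model, new_spectrum(c(2, 0, 1), c(1000, 1004, 1008)))
  expect_true(p$unclassifiable)
})

test_that("probabilities are normalised and confidence bounded on real committees", {
  model <- toy_two_class_model()
  set.seed(8)
  for (i in 1:25) {
    s <- new_spectrum(c(runif(1, 0.5, 3), runif(1, 0.5, 3), runif(1, 0.4, 0.6)),
                      c(1000, 1004, 1008))
    pr <- committee_probabilities(model, s)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    p <- predict(model, s)
    expect_gte(p$confidence, 1 / length(model$classes))
    expect_lte(p$confidence, 1)
    expect_equal(p$confidence, max(pr))  # max/sum with sum == 1
  }
})

test_that("permuting class order permutes probabilities identically", {
  pa <- flat_pdf(1.75, 3); pb <- flat_pdf(1, 6); pc <- flat_pdf(0.5, 4)
  m1 <- metric_pair(1000, 1004, class_pdfs = list(A = pa, B = pb, C = pc))
  m2 <- metric_pair(1000, 1004, class_pdfs = list(C = pc, A = pa, B = pb))
  mod1 <- hand_model(list(m1), classes = c("A", "B", "C"))
  mod2 <- hand_model(list(m2), classes = c("C", "A", "B"))
  s <- new_spectrum(c(2, 1, 1), c(1000, 1004, 1008))
  pr1 <- committee_probabilities(mod1, s)
  pr2 <- committee_probabilities(mod2, s)
  expect_equal(pr2[c("A", "B", "C")], pr1[c("A", "B", "C")])
})

test_that("build_model validates committee size and PDFs", {
  model <- toy_two_class_model()
  expect_identical(length(committee_metrics <- unlist(model$committee,
                                                      recursive = FALSE)),
                   2L * 2L)
  ranked <- setNames(lapply(c("A", "B"), function(cl) {
    list(metric_pair(1000, 1004, class_pdfs = list(A = flat_pdf(0, 1),
                                                   B = flat_pdf(0, 1))))
  }), c("A", "B"))
  expect_error(build_model(ranked, k = 5), "only 1 ranked metrics")
  bad <- ranked
  bad$A[[1]]$class_pdfs$B <- NULL
  expect_error(build_model(bad, k = 1), "empty PDF")
})

test_that("model JSON round trip reproduces predictions bit-identically", {
  model <- toy_two_class_model()
  path <- tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  set.seed(99)
  vals <- cbind(runif(40, 0.5, 3), runif(40, 0.5, 3), runif(40, 0.4, 0.6))
  d <- labelled_spectra(vals, c(1000, 1004, 1008), rep("A", 40))
  p1 <- predict(model, d)
  p2 <- predict(back, d)
  expect_identical(p1$predicted, p2$predicted)
  expect_identical(p1$confidence, p2$confidence)
  expect_identical(attr(p1, "probabilities"), attr(p2, "probabilities"))
})

test_that("predict_cube labels usable pixels and excludes masked ones", {
  ph <- generate_phantom(default_seven_class_spec(seed = 21,
                                                  image_shape = c(14, 21),
                                                  n_outlier_pixels = 5))
  cube <- preprocess_cube(ph$cube)
  d <- cube_to_labelled(cube, ph$ground_truth)
  model <- ftirmetrics:::fit_stage_model(d, seq_along(d$labels),
                                         cv_params(), seed = 4)
  lm1 <- predict_cube(model, cube)
  expect_identical(lm1$shape, c(14L, 21L))
  expect_identical(sum(lm1$label == "excluded"), 5L)
  expect_true(all(lm1$confidence >= 0 & lm1$confidence <= 1))
  # accuracy comfortably above chance on usable pixels
  ok <- lm1$label != "excluded"
  acc <- mean(lm1$label[ok] == ph$ground_truth[ok])
  expect_gt(acc, 1 / 7)
  # determinism
  lm2 <- predict_cube(model, cube)
  expect_identical(lm1, lm2)
  # all-masked cube
  cube2 <- cube
  cube2$pixel_mask[] <- FALSE
  lm3 <- predict_cube(model, cube2)
  expect_true(all(lm3$label == "excluded"))
  expect_true(all(lm3$confidence == 0))
  # grid mismatch is rejected
  cube3 <- cube
  cube3$wavenumbers <- cube3$wavenumbers + 2
  expect_error(predict_cube(model, cube3), "does not match")
})
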