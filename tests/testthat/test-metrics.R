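# Metric engine: ratios, exhaustive pair generation, AUC scoring, ranking,
# importance histograms.

test_that("ratio_value computes guarded nearest-channel ratios", {
  wn <- c(1000, 1004, 1008)
  s <- new_spectrum(c(0.5, 0.25, 1e-15), wn)
  expect_equal(ratio_value(s, 1000, 1004), 2.0)
  expect_error(ratio_value(s, 1000, 1000), "same channel")
  expect_true(is.na(ratio_value(s, 1000, 1008)))  # denominator under guard
  expect_error(ratio_value(s, 1000, 1004, channel_mask = c(TRUE, FALSE, TRUE)),
               "unmasked")
})

test_that("generate_metrics enumerates every ordered pair with per-class PDFs", {
  d <- make_labelled(matrix(c(1, 2, 3, 3, 2, 1), 2, 3,
                            dimnames = list(c("A", "B"), NULL)))
  mets <- generate_metrics(d)
  expect_length(mets, 6L)  # 3 channels -> 3 * 2 ordered pairs
  for (m in mets) {
    expect_setequal(names(m$class_pdfs), c("A", "B"))
    expect_false(any(vapply(m$class_pdfs, is.null, TRUE)))
  }
  # counting law n(n-1) at another size
  d2 <- make_labelled(matrix(runif(2 * 7), 2, 7,
                             dimnames = list(c("A", "B"), NULL)))
  expect_length(generate_metrics(d2), 7L * 6L)
})

test_that("degenerate training ratios concentrate the class PDF", {
  va <- cbind(rep(2, 15), rep(1, 15))
  vb <- cbind(rnorm(15, 1, 0.1), rnorm(15, 2, 0.1))
  d <- labelled_spectra(rbind(va, vb), c(1000, 1004),
                        rep(c("A", "B"), each = 15))
  m <- generate_metrics(d)[[1]]  # ratio 1000/1004: class A always exactly 2
  pdf <- m$class_pdfs$A
  expect_gte(ftirmetrics:::pdf_mass(pdf, 2 - 4 * pdf$bw, 2 + 4 * pdf$bw), 0.99)
})

test_that("AUC scoring follows exhaustive pair counting with ties at 1/2", {
  wn <- c(1000, 1004)
  mk <- function(vals, labs) {
    labelled_spectra(cbind(vals, 1), wn, labs)
  }
  m <- metric_pair(1000, 1004)
  # perfect separation
  a <- score_metric_auc(m, mk(c(0.5, 0.6, 0.2, 0.3), c("P", "P", "N", "N")), "P")
  expect_equal(as.numeric(a), 1.0)
  # worked 4-point example: raw 0.25, oriented 0.75
  b <- score_metric_auc(m, mk(c(0.1, 0.5, 0.3, 0.7), c("P", "P", "N", "N")), "P")
  expect_equal(as.numeric(b), 0.75)
  expect_equal(attr(b, "raw"), 0.25)
  # single tied pair
  cc <- score_metric_auc(m, mk(c(0.4, 0.4), c("P", "N")), "P")
  expect_equal(attr(cc, "raw"), 0.5)
  expect_error(score_metric_auc(m, mk(c(1, 2), c("P", "P")), "P"),
               "positive and one negative")
})

test_that("AUC equals the brute-force oracle on random tied data", {
  set.seed(11)
  m <- metric_pair(1000, 1004)
  for (rep in 1:50) {
    np <- sample(50, 1); nn <- sample(50, 1)
    # lattice values force plenty of ties
    pos <- sample(seq(0, 2, 0.25), np, replace = TRUE)
    neg <- sample(seq(0, 2, 0.25), nn, replace = TRUE)
    d <- labelled_spectra(cbind(c(pos, neg), 1), c(1000, 1004),
                          rep(c("P", "N"), c(np, nn)))
    got <- attr(score_metric_auc(m, d, "P"), "raw")
    expect_equal(got, brute_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("the compiled all-pairs scan agrees with single-metric scoring", {
  set.seed(23)
  means <- matrix(runif(3 * 6, 0.5, 2), 3, 6,
                  dimnames = list(c("A", "B", "C"), NULL))
  d <- make_labelled(means, n_per_class = 15, noise = 0.2)
  tab <- rank_channel_pairs(d)
  expect_identical(nrow(tab), 3L * 6L * 5L)
  for (k in sample(nrow(tab), 25)) {
    m <- metric_pair(tab$num_wn[k], tab$den_wn[k])
    expect_equal(tab$auc[k],
                 as.numeric(score_metric_auc(m, d, tab$class[k])),
                 tolerance = 1e-12)
  }
})

test_that("oriented AUC is invariant under ratio inversion on tie-free data", {
  set.seed(3)
  v <- runif(40, 0.2, 3)
  labs <- rep(c("P", "N"), each = 20)
  auc_of <- function(vals) {
    d <- labelled_spectra(cbind(vals, 1), c(1000, 1004), labs)
    as.numeric(score_metric_auc(metric_pair(1000, 1004), d, "P"))
  }
  expect_equal(auc_of(v), auc_of(1 / v), tolerance = 1e-12)
})

test_that("ranking is AUC-descending with deterministic wavenumber tie-breaks", {
  set.seed(5)
  # class contrast only on channel 1 -> pairs using channel 1 rank high
  means <- matrix(c(2, 1, 1, 1, 1, 1), 2, 3, byrow = FALSE,
                  dimnames = list(c("A", "B"), NULL))
  d <- make_labelled(means, n_per_class = 25, noise = 0.1)
  mets <- generate_metrics(d)
  ranked <- rank_metrics(mets, d)
  aucs <- vapply(ranked$A, `[[`, 0, "auc")
  expect_true(all(diff(aucs) <= 0))
  expect_identical(vapply(ranked$A, `[[`, 0L, "rank"), 1:6)
  # exact ties (noise-free symmetric data) resolve by (num, den) order
  d0 <- labelled_spectra(rbind(c(2, 1, 1), c(1, 2, 2)), seq(1000, 1008, 4),
                         c("A", "B"))
  r0 <- rank_metrics(generate_metrics(d0), d0)
  tied <- vapply(r0$A, function(m) paste(m$num_wn, m$den_wn), "")
  aucs0 <- vapply(r0$A, `[[`, 0, "auc")
  # four pairs touch the informative channel and tie at AUC 1
  expect_identical(tied[aucs0 == 1],
                   c("1000 1004", "1000 1008", "1004 1000", "1008 1000"))
})

test_that("importance histogram counts top-five wavenumber appearances", {
  mk <- function(pairs) lapply(pairs, function(p) metric_pair(p[1], p[2]))
  oscc <- mk(list(c(1562, 1539), c(1539, 1562), c(1566, 1539),
                  c(1539, 1566), c(1562, 1543)))
  lym <- mk(list(c(1715, 1703), c(1703, 1715), c(1703, 1719),
                 c(1707, 1715), c(1715, 1707)))
  h <- importance_histogram(list(OSCC = oscc, LYM = lym))
  expect_identical(h$OSCC,
                   c(`1539` = 4L, `1562` = 3L, `1566` = 2L, `1543` = 1L))
  expect_identical(h$LYM,
                   c(`1715` = 4L, `1703` = 3L, `1707` = 2L, `1719` = 1L))
  expect_identical(sum(h$OSCC), 10L)
  # degenerate: five copies of one metric
  h2 <- importance_histogram(list(X = mk(rep(list(c(1200, 1300)), 5))))
  expect_identical(h2$X, c(`1200` = 5L, `1300` = 5L))
  expect_error(importance_histogram(list(X = mk(list(c(1, 2))))), "exactly 5")
})

test_that("undefined ratios exclude spectra rather than poisoning PDFs", {
  v <- rbind(c(1, 0), c(2, 1), c(3, 1), c(1, 2), c(2, 2))  # first: den = 0
  d <- labelled_spectra(v, c(1000, 1004), c("A", "A", "A", "B", "B"))
  m <- generate_metrics(d)[[1]]  # 1000/1004
  expect_identical(m$class_pdfs$A$n_train, 2L)
  expect_identical(m$class_pdfs$B$n_train, 2L)
})
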