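make_spectra <- function(n = 6, npt = 101, seed = 1) {
  set.seed(seed)
  wn <- seq(4000, 4000 + 8 * (npt - 1), by = 8)
  X <- outer(rep(1, n), 1.5 + sin(wn / 300)) +
    matrix(rnorm(n * npt, 0, 0.05), n)
  spectra_set(wn, X, class_labels = rep(c("NSF", "SF"), length.out = n))
}

test_that("SNV standardizes every row and is idempotent", {
  s <- make_spectra()
  p <- preprocess(s, "snv")
  expect_equal(unname(rowMeans(p$absorbance)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(p$absorbance, 1, sd)), rep(1, 6),
               tolerance = 1e-12)
  expect_equal(preprocess(p, "snv")$absorbance, p$absorbance,
               tolerance = 1e-12)
  flat <- spectra_set(s$wavenumbers,
                      rbind(rep(1, length(s$wavenumbers))))
  expect_error(preprocess(flat, "snv"), "constant spectrum")
})

test_that("MSC with the spectrum itself as reference is the identity", {
  s <- make_spectra(n = 1)
  p <- preprocess(s, "msc", params = list(msc_reference = s$absorbance[1, ]))
  expect_equal(p$absorbance, s$absorbance, tolerance = 1e-10)
})

test_that("MSC undoes the affine scatter model", {
  s <- make_spectra(n = 1, seed = 2)
  ref <- drop(s$absorbance)
  distorted <- rbind(ref, 1.3 * ref + 0.2, 0.7 * ref - 0.1)
  sd2 <- spectra_set(s$wavenumbers, distorted)
  p <- preprocess(sd2, "msc", params = list(msc_reference = ref))
  for (i in 1:3) {
    expect_equal(unname(p$absorbance[i, ]), unname(ref), tolerance = 1e-10)
  }
})

test_that("SG first derivative of a linear spectrum is its slope per cm-1", {
  wn <- seq(4000, 4800, by = 8)
  slope <- 0.002                       # absorbance per cm-1
  s <- spectra_set(wn, rbind(1 + slope * (wn - 4000)))
  p <- preprocess(s, preprocess_spec("sg", window = 9, polyorder = 2,
                                     deriv = 1))
  interior <- 5:(length(wn) - 4)
  expect_equal(unname(p$absorbance[1, interior]),
               rep(slope, length(interior)), tolerance = 1e-12)
})

test_that("SG central coefficients match the classical quadratic weights", {
  expect_equal(sg_coefficients(-2:2, polyorder = 2, deriv = 0),
               c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
})

test_that("SG coefficients match signal::sgolay and a least-squares oracle", {
  skip_if_not_installed("signal")
  for (case in list(c(9, 2, 0), c(9, 2, 1), c(11, 3, 2))) {
    w <- case[1]; p <- case[2]; d <- case[3]
    h <- (w - 1) / 2
    ours <- sg_coefficients(-h:h, p, d)
    ref <- signal::sgolay(p, w, m = d)[h + 1, ]
    expect_equal(ours, unclass(ref), tolerance = 1e-9, ignore_attr = TRUE)
    # brute-force: fit the polynomial explicitly on an arbitrary signal
    set.seed(d + 1)
    y <- rnorm(w)
    fit <- lm(y ~ poly(-h:h, p, raw = TRUE))
    expect_equal(sum(ours * y),
                 unname(coef(fit)[d + 1]) * factorial(d), tolerance = 1e-9)
  }
})

test_that("SG smoothing preserves polynomials up to the fit order", {
  wn <- seq(4000, 4400, by = 8)
  x <- seq_along(wn)
  y <- 2 + 0.3 * x - 0.01 * x^2
  s <- spectra_set(wn, rbind(y))
  p <- preprocess(s, preprocess_spec("sg", window = 11, polyorder = 2,
                                     deriv = 0))
  expect_equal(unname(p$absorbance[1, ]), unname(y), tolerance = 1e-9)
})

test_that("baseline, normalization and ST behave as documented", {
  s <- make_spectra()
  b <- preprocess(s, "baseline")
  # residual after removing a straight line is orthogonal to that line
  i <- seq_len(ncol(b$absorbance))
  expect_lt(max(abs(apply(b$absorbance, 1, function(r)
    coef(lm(r ~ i))[2]))), 1e-12)
  nrm <- preprocess(s, "normalization")
  expect_equal(unname(sqrt(rowSums(nrm$absorbance^2))), rep(1, 6),
               tolerance = 1e-12)
  st <- preprocess(s, "st")
  expect_equal(st$absorbance, log10(1 / s$absorbance))
  neg <- spectra_set(s$wavenumbers,
                     rbind(seq(-1, 1, length.out = length(s$wavenumbers))))
  expect_error(preprocess(neg, "st"), "positive")
})

test_that("wavelet denoising removes noise without flattening structure", {
  set.seed(4)
  wn <- seq(4000, 10000, by = 8)
  clean <- 0.5 * exp(-(wn - 5100)^2 / (2 * 120^2)) +
    0.3 * exp(-(wn - 7000)^2 / (2 * 300^2))
  noisy <- clean + rnorm(length(wn), 0, 0.01)
  s <- spectra_set(wn, rbind(noisy))
  p <- preprocess(s, "wds")
  rmse_before <- sqrt(mean((noisy - clean)^2))
  rmse_after <- sqrt(mean((p$absorbance[1, ] - clean)^2))
  # soft universal thresholding trades some signal bias for noise removal;
  # the net error must still drop substantially
  expect_lt(rmse_after, 0.8 * rmse_before)
  # and the band structure must survive (peak location/height)
  expect_lt(abs(max(p$absorbance[1, ]) - max(clean)), 0.05)
})

test_that("preprocessing never changes sample count or labels", {
  s <- generate_spectra(synthetic_config(n_batches = 3))
  for (sp in default_preprocess_bank()) {
    p <- preprocess(s, sp)
    expect_equal(dim(p$absorbance), dim(s$absorbance))
    expect_equal(p$class_labels, s$class_labels)
  }
})

test_that("the preprocessing comparison tabulates every method", {
  s <- generate_spectra(synthetic_config())
  tab <- compare_preprocessing(s, n_cal = 16, n_lv_max = 6)
  expect_equal(nrow(tab), length(default_preprocess_bank()))
  ok <- tab$status == "ok"
  expect_true(all(is.finite(as.matrix(tab[ok, c("RMSECV", "RMSEC", "RMSEP",
                                                "Se", "Sp", "Accuracy")]))))
  # ranked by RMSECV
  expect_true(!is.unsorted(tab$RMSECV[ok]))
})

test_that("with the default strong signal the best method classifies perfectly", {
  s <- generate_spectra(synthetic_config(seed = 11))
  tab <- compare_preprocessing(s, n_cal = 16, n_lv_max = 10)
  expect_equal(tab$Accuracy[1], 1)
})

test_that("no method beats chance on permuted labels", {
  hits <- 0
  for (seed in 1:3) {
    s <- generate_spectra(synthetic_config(seed = seed))
    set.seed(seed + 500)
    s$class_labels <- sample(s$class_labels)
    tab <- suppressWarnings(compare_preprocessing(s, n_cal = 16,
                                                  n_lv_max = 5))
    # 9/10 correct on the validation set is the 5% binomial bar at n = 10
    hits <- hits + any(tab$Accuracy >= 0.9, na.rm = TRUE)
  }
  expect_lte(hits, 1)
})
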