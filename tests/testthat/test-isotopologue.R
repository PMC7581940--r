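test_that("enrichment fraction is the intensity-weighted label share", {
  expect_equal(enrichment_fraction(c(0, 0, 0, 0, 0, 100)), 1)
  expect_equal(enrichment_fraction(c(100, 0, 0, 0, 0, 0)), 0)
  expect_equal(enrichment_fraction(rep(1, 6)), 0.5)  # 15 labels / 30 carbons
  expect_error(enrichment_fraction(rep(0, 6)), "all-zero")
  # invariant under uniform scaling
  set.seed(5)
  for (i in 1:20) {
    x <- runif(6)
    expect_equal(enrichment_fraction(x), enrichment_fraction(x * 137.5))
  }
})

test_that("natural-abundance operator is the binomial convolution", {
  M <- natural_abundance_matrix(5, 0.0107)
  expect_equal(M[2, 1], 5 * 0.0107 * 0.9893^4, tolerance = 1e-12)
  expect_equal(natural_abundance_matrix(4, 0), diag(5))
  set.seed(13)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    p <- runif(1, 0, 0.49)
    M <- natural_abundance_matrix(n, p)
    expect_lt(max(abs(colSums(M) - 1)), 1e-12)
    expect_true(all(M[upper.tri(M)] == 0))  # shifts only move mass up
  }
  expect_error(natural_abundance_matrix(5, 0.6), "0.5")
})

test_that("natural-abundance correction inverts the convolution", {
  expect_equal(correct_natural_abundance(c(3, 1, 4), p = 0)$intensities,
               c(3, 1, 4))
  set.seed(17)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    x <- runif(n + 1, 0, 100)
    obs <- convolve_natural_abundance(isotopologue_spectrum(x), p = 0.0107)
    back <- correct_natural_abundance(obs, p = 0.0107)
    expect_equal(back$intensities, x, tolerance = 1e-9)
    # convolution conserves total intensity
    expect_equal(sum(obs$intensities), sum(x), tolerance = 1e-9)
  }
  # a purely unlabeled analyte corrects to pure M+0
  obs <- convolve_natural_abundance(c(100, 0, 0, 0, 0, 0))
  expect_equal(correct_natural_abundance(obs)$intensities,
               c(100, 0, 0, 0, 0, 0), tolerance = 1e-9)
})

test_that("correction lowers the apparent enrichment of labeled spectra", {
  set.seed(19)
  for (i in 1:10) {
    x <- runif(6, 0, 10)
    obs <- convolve_natural_abundance(isotopologue_spectrum(x))
    expect_lte(enrichment_fraction(correct_natural_abundance(obs)),
               enrichment_fraction(obs) + 1e-12)
  }
})

test_that("heavy clamping in the correction is reported", {
  # an observed spectrum incompatible with the operator: all signal at M+1
  # with nothing at M+0 forces a strongly negative M+0 solution
  expect_warning(correct_natural_abundance(c(0, 100, 0, 0, 0, 0), p = 0.2),
                 "clamped")
})

test_that("standard addition scales the spike by the signal increment", {
  expect_equal(standard_addition_amount(100, 200, 25), 25)
  expect_equal(standard_addition_amount(0, 50, 25), 0)
  expect_equal(standard_addition_amount(300, 500, 25), 37.5)
  # homogeneous in the signals
  expect_equal(standard_addition_amount(30, 50, 25),
               standard_addition_amount(300, 500, 25))
  expect_error(standard_addition_amount(500, 500, 25), "not recovered")
  expect_error(standard_addition_amount(300, 500, 0), "positive")
})

test_that("external-standard quantification matches closed-form OLS", {
  expect_equal(as.numeric(external_standard_quantify(50, c(0, 10), c(0, 100))),
               5)
  conc <- c(1.25, 5, 20); sig <- c(130, 495, 2010)
  # independent closed-form least squares
  sxx <- sum((conc - mean(conc))^2)
  sxy <- sum((conc - mean(conc)) * (sig - mean(sig)))
  b <- sxy / sxx; a <- mean(sig) - b * mean(conc)
  est <- external_standard_quantify(1000, conc, sig)
  expect_equal(as.numeric(est), (1000 - a) / b, tolerance = 1e-12)
  expect_false(attr(est, "extrapolated"))
  expect_warning(external_standard_quantify(5000, conc, sig),
                 "extrapolation")
  expect_error(external_standard_quantify(10, c(2, 2), c(1, 5)), "distinct")
})

test_that("isoprene channels map m/z 69+k to the M+k isotopologue", {
  only74 <- c(mz69 = 0, mz70 = 0, mz71 = 0, mz72 = 0, mz73 = 0, mz74 = 10)
  expect_equal(enrichment_fraction(isoprene_channels_to_spectrum(only74)), 1)
  only69 <- c(mz69 = 10, mz70 = 0, mz71 = 0, mz72 = 0, mz73 = 0, mz74 = 0)
  expect_equal(enrichment_fraction(isoprene_channels_to_spectrum(only69)), 0)
  flat <- setNames(rep(10, 6), paste0("mz", 69:74))
  expect_equal(enrichment_fraction(isoprene_channels_to_spectrum(flat)), 0.5)
  # mapping + enrichment equals the C5 formula applied to raw channels
  set.seed(23)
  for (i in 1:10) {
    ch <- runif(6, 0, 50)
    direct <- sum((0:5) * ch) / (5 * sum(ch))
    expect_equal(enrichment_fraction(isoprene_channels_to_spectrum(ch)),
                 direct)
  }
})

test_that("ptrms_trace validates its channel set", {
  expect_error(
    ptrms_trace(1, data.frame(mz69 = 1, mz70 = 1), 1e5, 1e4, 2.2),
    "missing PTR-MS channel"
  )
  tr <- ptrms_trace(c(0, 1), data.frame(mz69 = c(1, 2), mz70 = 0, mz71 = 0,
                                        mz72 = 0, mz73 = 0, mz74 = c(3, 4)),
                    9e5, 5e4, 2.2)
  sp <- isoprene_channels_to_spectrum(tr, t_index = 2)
  expect_equal(sp$intensities, c(2, 0, 0, 0, 0, 4))
  expect_error(isoprene_channels_to_spectrum(tr, t_index = 3), "out of range")
})

test_that("ncps normalization references primary ion and drift pressure", {
  expect_equal(normalize_ptrms(123, 9.5e5, 5e4, 2.2), 123)
  expect_equal(normalize_ptrms(123, 2 * 9.5e5, 2 * 5e4, 2.2), 61.5)
  expect_equal(normalize_ptrms(500, 4.5e5, 5e4, 2.2), 1000)
  expect_error(normalize_ptrms(1, 0, 0, 2.2), "positive")
  expect_error(normalize_ptrms(1, 1e5, 0, 0), "positive")
})

test_that("emission rate is background-subtracted and per dry weight", {
  expect_equal(emission_rate(1000, 1000, 0.01, 0.5), 0)
  expect_equal(emission_rate(1000, 200, 0.01, 0.5), 16)
  expect_equal(emission_rate(1000, 200, 0.01, 1), 8)
  expect_warning(out <- emission_rate(100, 200, 0.01, 0.5), "floored")
  expect_equal(out, 0)
  expect_error(emission_rate(1000, 200, 0.01, 0), "positive")
})
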