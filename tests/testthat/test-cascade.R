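test_that("parameter constructor enforces the model's domain", {
  expect_error(cascade_params(0, 1, 0.5, 0.2, 0.85), "positive")
  expect_error(cascade_params(2, 1, 0.5, -0.1, 0.85), "non-negative")
  expect_error(cascade_params(2, 1, 0.5, 0.2, 1.2), "\\[0, 1\\]")
  p <- cascade_params(2, 1, 0.5, 0.2, 0.85)
  expect_s3_class(p, "cascade_params")
})

test_that("labeling starts at zero and saturates at the plateau", {
  p <- cascade_params(2, 1, 0.5, flux = 0.2, plateau = 0.85)
  expect_equal(cascade_fraction(0, p), 0)
  expect_equal(cascade_fraction(1e6, p), 0.85, tolerance = 1e-9)
  expect_error(cascade_fraction(-1, p), "non-negative")
  # zero flux or zero plateau carries no label
  expect_equal(cascade_fraction(10, cascade_params(2, 1, 0.5, 0, 0.85)), 0)
  expect_equal(cascade_fraction(10, cascade_params(2, 1, 0.5, 0.2, 0)), 0)
})

test_that("partial-fraction coefficients sum to one for distinct pools", {
  set.seed(11)
  for (p in rand_cascade_params(1000, min_gap = 1e-4)) {
    expect_lt(abs(sum(cascade_coefs(p)) - 1), 1e-10)
  }
})

test_that("closed form agrees with the ODE oracle", {
  p <- cascade_params(2, 1, 0.5, flux = 0.1, plateau = 1)
  expect_equal(cascade_fraction(10, p), cascade_fraction_ode(10, p),
               tolerance = 1e-6)
  set.seed(21)
  ts <- c(0.1, 1, 5, 20, 50, 200)
  for (p in rand_cascade_params(100, min_gap = 1e-4)) {
    dev <- abs(cascade_fraction(ts, p) - cascade_fraction_ode(ts, p))
    expect_lt(max(dev), 1e-6)
  }
})

test_that("confluent pool sizes reproduce the Erlang step response", {
  # A = B = C = 1, J = 1, m = 1: f(t) = 1 - e^-t (1 + t + t^2/2)
  p <- cascade_params(1, 1, 1, flux = 1, plateau = 1)
  erlang3 <- function(t) 1 - exp(-t) * (1 + t + t^2 / 2)
  expect_equal(cascade_fraction_ode(1, p), erlang3(1), tolerance = 1e-8)
  expect_equal(cascade_fraction(1, p), erlang3(1), tolerance = 1e-8)
  expect_equal(cascade_fraction(c(0.5, 2, 8), p), erlang3(c(0.5, 2, 8)),
               tolerance = 1e-7)
  # near-confluent pools evaluate smoothly (no cancellation blow-up)
  p_near <- cascade_params(1, 1 + 1e-9, 1 - 1e-9, flux = 1, plateau = 1)
  expect_equal(cascade_fraction(2, p_near), erlang3(2), tolerance = 1e-6)
})

test_that("labeling curve is monotone in time, flux and pool sizes", {
  set.seed(31)
  ts <- seq(0, 60, by = 2)
  for (p in rand_cascade_params(30, min_gap = 1e-3)) {
    f <- cascade_fraction(ts, p)
    expect_true(all(diff(f) >= -1e-12))
    # larger flux labels faster
    p_hi <- cascade_params(p$pool_dxp, p$pool_mecdp, p$pool_idpdmadp,
                           p$flux * 2 + 0.01, p$plateau)
    expect_true(all(cascade_fraction(ts, p_hi) >= f - 1e-12))
    # a larger pool dilutes label and slows the rise
    p_big <- cascade_params(p$pool_dxp * 3, p$pool_mecdp, p$pool_idpdmadp,
                            p$flux, p$plateau)
    expect_true(all(cascade_fraction(ts, p_big) <= f + 1e-12))
  }
})

test_that("only pool/flux ratios enter: joint rescaling leaves f unchanged", {
  set.seed(41)
  ts <- c(1, 7, 23, 50)
  for (p in rand_cascade_params(20, min_gap = 1e-3)) {
    for (s in c(0.1, 3, 40)) {
      ps <- cascade_params(p$pool_dxp * s, p$pool_mecdp * s,
                           p$pool_idpdmadp * s, p$flux * s, p$plateau)
      expect_equal(cascade_fraction(ts, ps), cascade_fraction(ts, p),
                   tolerance = 1e-9)
    }
  }
})

test_that("plastidial partition scales totals by the enrichment ratio", {
  expect_equal(plastidial_pool(10, 0.5, 0.5), 10)
  expect_equal(plastidial_pool(10, 0.75, 0.87), 10 * 0.75 / 0.87)
  expect_equal(round(plastidial_pool(10, 0.75, 0.87), 2), 8.62)
  expect_error(plastidial_pool(10, 0.5, 0), "unlabeled")
  expect_warning(out <- plastidial_pool(10, 0.9, 0.87), "capped")
  expect_equal(out, 10)
})

test_that("flux percent change matches its definition", {
  expect_equal(flux_percent_change(1, 1), 0)
  expect_equal(flux_percent_change(1, 0), 100)
  expect_equal(flux_percent_change(0.8, 0.504), 37)
  expect_error(flux_percent_change(0, 1), "positive")
})
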