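truth <- cascade_params(2, 1, 0.5, flux = 0.2, plateau = 0.85)

test_that("time-course simulation is seeded and noise-free at CV 0", {
  grid <- seq(0, 50, length.out = 25)
  tc0 <- simulate_time_course(truth, grid, cv = 0, floor = 0, seed = 1)
  expect_equal(tc0$fractions, cascade_fraction(grid, truth))
  a <- simulate_time_course(truth, grid, cv = 0.03, seed = 99)
  b <- simulate_time_course(truth, grid, cv = 0.03, seed = 99)
  expect_identical(a$fractions, b$fractions)
  c <- simulate_time_course(truth, grid, cv = 0.03, seed = 100)
  expect_false(identical(a$fractions, c$fractions))
  expect_true(all(a$fractions >= 0 & a$fractions <= 1))
  expect_error(simulate_time_course(truth, grid, cv = 0.03), "mandatory")
})

test_that("simulated noise is centred on the model curve", {
  grid <- c(5, 15, 30, 50)
  f <- cascade_fraction(grid, truth)
  sims <- sapply(1:400, function(s)
    simulate_time_course(truth, grid, cv = 0.03, floor = 0,
                         seed = s)$fractions)
  mn <- rowMeans(sims)
  se <- apply(sims, 1, sd) / sqrt(ncol(sims))
  expect_true(all(abs(mn - f) < 3 * se + 1e-12))
})

test_that("simulated spectra honour the binomial + natural-abundance model", {
  s1 <- simulate_spectrum(1, n = 5, p_natural = 0, cv = 0, seed = 1)
  expect_equal(s1$intensities[6], sum(s1$intensities))
  s0 <- simulate_spectrum(0, n = 5, p_natural = 0, cv = 0, seed = 1)
  expect_equal(s0$intensities[1], sum(s0$intensities))
  # noiseless round trip: correction recovers the target enrichment exactly
  s <- simulate_spectrum(0.85, n = 5, p_natural = 0.0107, cv = 0, seed = 1)
  expect_equal(enrichment_fraction(correct_natural_abundance(s)), 0.85,
               tolerance = 1e-12)
  # convolution conserves intensity
  expect_equal(sum(s$intensities), 1e4, tolerance = 1e-9)
})

test_that("simulated PTR-MS traces close the processing loop", {
  tr0 <- simulate_ptrms(cascade_params(2, 1, 0.5, flux = 0, plateau = 0),
                        grid = c(0, 10), emission_ncps = 0,
                        background_cps = 5, cv = 0, seed = 1)
  expect_true(all(as.matrix(tr0$channel_cps) == 5))
  tr <- simulate_ptrms(truth, grid = seq(0, 50, length.out = 11),
                       emission_ncps = 1e4, background_cps = 0,
                       cv = 0.05, seed = 7)
  f_true <- attr(tr, "truth")
  # late in the run the fully labeled molecule dominates
  late <- as.numeric(tr$channel_cps[11, ])
  expect_equal(which.max(late), 6L)
  # channel mapping + correction + enrichment recovers f(t) within noise
  rec <- vapply(seq_along(tr$times), function(i) {
    sp <- isoprene_channels_to_spectrum(tr, i)
    # counting noise can push corrected components slightly negative;
    # the documented clamping warning is expected here
    enrichment_fraction(suppressWarnings(correct_natural_abundance(sp)))
  }, numeric(1))
  expect_lt(max(abs(rec - f_true)), 0.05)
})

test_that("pot-weight drydown follows the exponential closed form", {
  pw0 <- simulate_pot_weights(10000, 6000, decay_rate = 0, days = 10)
  expect_true(all(pw0$weight_g == 10000))
  expect_true(all(ftsw(pw0$weight_g, 10000, 6000) == 1))
  pw <- simulate_pot_weights(10000, 6000, decay_rate = 0.2, days = 15,
                             round_g = FALSE)
  expect_true(all(diff(pw$weight_g) <= 0))
  f <- ftsw(pw$weight_g, 10000, 6000)
  expect_equal(f, exp(-0.2 * (0:15)), tolerance = 1e-9)
  pwr <- simulate_pot_weights(10000, 6000, decay_rate = 0.2, days = 15)
  fr <- ftsw(pwr$weight_g, 10000, 6000)
  expect_lt(max(abs(fr - exp(-0.2 * (0:15)))), 1 / 4000)
  expect_error(simulate_pot_weights(6000, 10000), "exceed")
})

test_that("a full experiment is reproducible and internally consistent", {
  cfg <- scenario_config(seed = 5, n_replicates = 3)
  ex1 <- simulate_experiment(cfg)
  ex2 <- simulate_experiment(cfg)
  expect_identical(ex1$time_courses, ex2$time_courses)
  expect_identical(ex1$spectra, ex2$spectra)
  expect_identical(ex1$measurements, ex2$measurements)
  expect_equal(nrow(ex1$manifest), 9L)
  # manifest truth is recoverable by the fitter for control trees
  ctrl <- ex1$time_courses[ex1$time_courses$treatment == "control", ]
  fits <- fit_flux_table(ctrl, pools = c(2, 1, 0.5))
  expect_lt(median(abs(fits$J_hat - 0.2) / 0.2), 0.05)
  # physiology table carries the configured effect sizes
  ph <- ex1$measurements[ex1$measurements$variable_id == "photosynthesis", ]
  es <- effect_summary(ph$value, ph$treatment, control = "control")
  expect_equal(es$pct_change[es$group == "moderate"], 70, tolerance = 0.12)
  expect_equal(es$pct_change[es$group == "severe"], 96, tolerance = 0.05)
})
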