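#' Scenario configuration for a synthetic drought-labeling experiment
#'
#' Fixes the conditions of a simulated 13CO2 labeling study: per-treatment
#' cascade parameters, species plateaus, replicate counts, the sampling
#' grid, noise magnitudes and pot-weight drydown. Defaults mirror the study
#' conditions the model was built for: a 50-min labeling window sampled at
#' 25 points; control plateaus around 0.85 (isoprene), 0.87 (IDP + DMADP)
#' and 0.75 (DXP, MEcDP); moderate drought plateaus near 0.60 with flux
#' reduced by 37%; severe drought with plateau 0.15 and collapsed flux, so
#' little label arrives within the window; five trees per treatment;
#' 3% multiplicative noise on fractions and 5% on intensities.
#'
#' @param treatments Named list of per-treatment settings; each element is a
#'   list with `pools` (length-3 `c(A, B, C)`, nmol g^-1 DW), `flux`
#'   (nmol g^-1 DW min^-1) and `plateaus` (named fractions for `dxp`,
#'   `mecdp`, `idp_dmadp`, `isoprene`).
#' @param n_replicates Trees per treatment.
#' @param time_grid Sampling times, minutes.
#' @param cv_fraction Multiplicative CV of fractional-enrichment noise.
#' @param floor_fraction Additive (absolute) noise floor on fractions.
#' @param cv_intensity Multiplicative CV of spectral intensity noise.
#' @param p13c Natural 13C abundance used in simulated spectra.
#' @param pot_initial,pot_final,pot_decay,pot_days Pot-weight drydown:
#'   initial and final weights (g), exponential decay rate (day^-1), days.
#' @param seed Integer seed; mandatory, every simulated quantity is
#'   reproducible from (config, seed).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(
    treatments = list(
      control = list(pools = c(2, 1, 0.5), flux = 0.2,
                     plateaus = c(dxp = 0.75, mecdp = 0.75,
                                  idp_dmadp = 0.87, isoprene = 0.85)),
      moderate = list(pools = c(1.2, 0.6, 0.5), flux = 0.126,
                      plateaus = c(dxp = 0.45, mecdp = 0.45,
                                   idp_dmadp = 0.60, isoprene = 0.60)),
      severe = list(pools = c(1, 0.55, 0.5), flux = 0.02,
                    plateaus = c(dxp = 0.15, mecdp = 0.15,
                                 idp_dmadp = 0.15, isoprene = 0.15))
    ),
    n_replicates = 5L,
    time_grid = seq(0, 50, length.out = 25L),
    cv_fraction = 0.03,
    floor_fraction = 0.005,
    cv_intensity = 0.05,
    p13c = 0.0107,
    pot_initial = 10000,
    pot_final = 6000,
    pot_decay = 0.15,
    pot_days = 20L,
    seed = 1L) {
  if (is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  for (tr in names(treatments)) {
    s <- treatments[[tr]]
    if (any(s$pools <= 0) || s$flux < 0 ||
        any(s$plateaus < 0 | s$plateaus > 1)) {
      stop("invalid settings for treatment '", tr, "'", call. = FALSE)
    }
  }
  if (cv_fraction < 0 || cv_intensity < 0 || floor_fraction < 0) {
    stop("noise magnitudes must be >= 0", call. = FALSE)
  }
  structure(
    list(treatments = treatments, n_replicates = as.integer(n_replicates),
         time_grid = time_grid, cv_fraction = cv_fraction,
         floor_fraction = floor_fraction, cv_intensity = cv_intensity,
         p13c = p13c, pot_initial = pot_initial, pot_final = pot_final,
         pot_decay = pot_decay, pot_days = as.integer(pot_days),
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulate a noisy labeling time course
#'
#' Draws a fractional-enrichment time course from the cascade model with
#' multiplicative Gaussian noise and an additive noise floor:
#' `f_obs = f(t) (1 + e1) + e2`, `e1 ~ N(0, cv)`, `e2 ~ N(0, floor)`,
#' clipped to `[0, 1]`.
#'
#' @param params A [cascade_params()] object.
#' @param grid Sampling times, minutes.
#' @param cv Multiplicative coefficient of variation (0 = noiseless).
#' @param floor Additive noise SD on the fraction scale.
#' @param seed Integer seed (mandatory).
#' @param species_id,replicate_id Labels stored in the result.
#' @return A [labeling_time_course()]. The deterministic model curve is
#'   attached as attribute `truth`.
#' @export
simulate_time_course <- function(params, grid = seq(0, 50, length.out = 25L),
                                 cv = 0.03, floor = 0.005, seed,
                                 species_id = "isoprene",
                                 replicate_id = "r1") {
  params <- as_cascade_params(params)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  truth <- cascade_fraction(grid, params)
  obs <- with_seed(seed, {
    truth * (1 + rnorm(length(grid), 0, cv)) +
      rnorm(length(grid), 0, floor)
  })
  obs <- pmin(pmax(obs, 0), 1)
  # the constructor needs strictly increasing times; grids start at 0
  tc <- labeling_time_course(grid, obs, species_id = species_id,
                             replicate_id = replicate_id)
  attr(tc, "truth") <- truth
  tc
}

#' Simulate an isotopologue spectrum at a given enrichment
#'
#' Under positional-independence, an analyte pool at atom enrichment
#' `fraction` has binomial isotopologue probabilities
#' `Binom(n, fraction)`; natural 13C on the unlabeled carbons is layered on
#' by the convolution operator, the result scaled to `total_intensity` and
#' perturbed multiplicatively. The noiseless spectrum, corrected with
#' [correct_natural_abundance()], has enrichment exactly `fraction`.
#'
#' @param fraction Positional label probability (= atom enrichment),
#'   `[0, 1]`.
#' @param n Carbon count.
#' @param p_natural Natural 13C abundance.
#' @param total_intensity Total signal to distribute.
#' @param cv Multiplicative intensity noise CV.
#' @param seed Integer seed (mandatory).
#' @return An [isotopologue_spectrum()].
#' @export
simulate_spectrum <- function(fraction, n = 5L, p_natural = 0.0107,
                              total_intensity = 1e4, cv = 0.05, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (fraction < 0 || fraction > 1) {
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  }
  probs <- dbinom(0:n, n, fraction)
  if (p_natural > 0) {
    probs <- as.numeric(natural_abundance_matrix(n, p_natural) %*% probs)
  }
  intens <- total_intensity * probs
  if (cv > 0) {
    intens <- with_seed(seed,
                        pmax(intens * (1 + rnorm(n + 1L, 0, cv)), 0))
  }
  isotopologue_spectrum(intens, n)
}

#' Simulate a PTR-MS trace of an isoprene labeling run
#'
#' Emits the six isoprene channels (m/z 69-74) over the labeling window:
#' at each time the emission signal is distributed across isotopologues by
#' the binomial mixture at the instantaneous model fraction `f(t)` (with
#' natural abundance), a constant background is added per channel, and
#' counts are perturbed multiplicatively. Primary ion, water cluster and
#' drift pressure are constant nominal values so that
#' [normalize_ptrms()] applies.
#'
#' @param params A [cascade_params()] for the labeling kinetics.
#' @param grid Time stamps, minutes.
#' @param emission_ncps Total isoprene signal at the detector, ncps-scale
#'   counts distributed across the six channels.
#' @param background_cps Per-channel background count rate.
#' @param p_natural Natural 13C abundance.
#' @param cv Multiplicative count noise CV.
#' @param primary_cps,water_cluster_cps,drift_pressure Instrument channels.
#' @param seed Integer seed (mandatory).
#' @return A [ptrms_trace()]; the noiseless model fraction is attached as
#'   attribute `truth`.
#' @export
simulate_ptrms <- function(params, grid = seq(0, 50, length.out = 25L),
                           emission_ncps = 1e4, background_cps = 5,
                           p_natural = 0.0107, cv = 0.05,
                           primary_cps = 9.5e5, water_cluster_cps = 5e4,
                           drift_pressure = 2.2, seed) {
  params <- as_cascade_params(params)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  truth <- cascade_fraction(grid, params)
  M <- natural_abundance_matrix(5L, p_natural)
  channels <- t(vapply(truth, function(f) {
    probs <- as.numeric(M %*% dbinom(0:5, 5, f))
    emission_ncps * probs + background_cps
  }, numeric(6L)))
  if (cv > 0) {
    channels <- with_seed(seed, {
      noise <- matrix(rnorm(length(channels), 0, cv), nrow(channels))
      pmax(channels * (1 + noise), 0)
    })
  }
  colnames(channels) <- paste0("mz", 69:74)
  tr <- ptrms_trace(grid, channels, primary_cps, water_cluster_cps,
                    drift_pressure)
  attr(tr, "truth") <- truth
  tr
}

#' Simulate a pot-weight drydown series
#'
#' Exponential approach of the pot weight to its final (transpiration
#' endpoint) value, `w(d) = final + (initial - final) exp(-k d)`, optionally
#' rounded to the 1 g precision of the balance.
#'
#' @param initial,final Initial and final pot weights, g (`initial > final`).
#' @param decay_rate Drydown rate constant `k`, day^-1 (`0` = well-watered,
#'   constant weight).
#' @param days Number of days after day 0.
#' @param round_g Round weights to whole grams (default `TRUE`).
#' @param seed Integer seed (kept for interface symmetry; the trajectory is
#'   deterministic).
#' @param tree_id Label.
#' @return Tibble with columns `tree_id`, `day`, `weight_g`, plus
#'   attributes `initial` and `final`.
#' @export
simulate_pot_weights <- function(initial = 10000, final = 6000,
                                 decay_rate = 0.15, days = 20L,
                                 round_g = TRUE, seed = 1L,
                                 tree_id = "t1") {
  if (initial <= final) stop("`initial` must exceed `final`", call. = FALSE)
  if (decay_rate < 0) stop("`decay_rate` must be >= 0", call. = FALSE)
  d <- 0:days
  w <- final + (initial - final) * exp(-decay_rate * d)
  if (round_g) w <- round(w)
  out <- tibble::tibble(tree_id = tree_id, day = d, weight_g = w)
  attr(out, "initial") <- initial
  attr(out, "final") <- final
  out
}

#' Simulate a complete drought-labeling experiment
#'
#' Generates every input the pipeline consumes, with known ground truth:
#' per-tree isoprene labeling time courses, final-time isotopologue spectra
#' of DXP, MEcDP, IDP + DMADP and isoprene, a total-pool table (plastidial
#' truth inflated to whole-tissue totals by the enrichment ratios), pot
#' weights for treated and reference trees, and a tidy physiology table
#' (photosynthesis and ABA with treatment means reproducing the reported
#' percent declines and fold increases). Everything is reproducible from
#' `(config, seed)`.
#'
#' @param config A [scenario_config()].
#' @return A list of class `mep_experiment` with elements `time_courses`,
#'   `spectra`, `pools`, `pot_weights`, `pot_anchors`, `reference_weights`,
#'   `measurements` and `manifest` (the ground truth: treatment, replicate,
#'   true `J`, plateaus, plastidial pools).
#' @export
simulate_experiment <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  species <- c("dxp", "mecdp", "idp_dmadp", "isoprene")
  tc_rows <- list(); sp_rows <- list(); pool_rows <- list()
  manifest <- list()
  seed0 <- config$seed

  for (ti in seq_along(config$treatments)) {
    tr_name <- names(config$treatments)[ti]
    s <- config$treatments[[ti]]
    for (r in seq_len(config$n_replicates)) {
      rep_id <- sprintf("%s_%d", tr_name, r)
      sub_seed <- seed0 + 1000L * ti + r
      params <- cascade_params(s$pools[1L], s$pools[2L], s$pools[3L],
                               flux = s$flux,
                               plateau = s$plateaus[["isoprene"]])
      tc <- simulate_time_course(params, grid = config$time_grid,
                                 cv = config$cv_fraction,
                                 floor = config$floor_fraction,
                                 seed = sub_seed,
                                 replicate_id = rep_id)
      tc_rows[[rep_id]] <- tibble::tibble(
        treatment = tr_name, replicate_id = rep_id,
        species_id = "isoprene", time_min = tc$times, fraction = tc$fractions)

      # final-time spectra per species at that species' plateau enrichment
      plastidial <- c(dxp = s$pools[1L], mecdp = s$pools[2L],
                      idp_dmadp = s$pools[3L])
      for (si in seq_along(species)) {
        sp <- species[si]
        frac <- s$plateaus[[sp]]
        spec <- simulate_spectrum(frac, n = 5L, p_natural = config$p13c,
                                  cv = config$cv_intensity,
                                  seed = sub_seed + 10L * si)
        sp_rows[[paste(rep_id, sp)]] <- tibble::tibble(
          treatment = tr_name, replicate_id = rep_id, species_id = sp,
          mass_shift = 0:5, intensity = spec$intensities)
      }
      # whole-tissue totals: plastidial truth divided by the plastidial
      # share implied by the enrichment ratio to IDP + DMADP
      ref_enr <- s$plateaus[["idp_dmadp"]]
      for (sp in c("dxp", "mecdp", "idp_dmadp")) {
        share <- min(s$plateaus[[sp]] / ref_enr, 1)
        pool_rows[[paste(rep_id, sp)]] <- tibble::tibble(
          treatment = tr_name, replicate_id = rep_id, species_id = sp,
          total_pool_nmol_gDW = plastidial[[sp]] / share,
          final_enrichment = s$plateaus[[sp]])
      }
      manifest[[rep_id]] <- tibble::tibble(
        treatment = tr_name, replicate_id = rep_id, flux = s$flux,
        plateau_isoprene = s$plateaus[["isoprene"]],
        pool_dxp = s$pools[1L], pool_mecdp = s$pools[2L],
        pool_idpdmadp = s$pools[3L])
    }
  }

  # pot weights: treated trees dry down; reference trees stay at capacity
  pot_rows <- list(); anchor_rows <- list(); ref_rows <- list()
  for (ti in seq_along(config$treatments)) {
    tr_name <- names(config$treatments)[ti]
    decay <- if (tr_name == "control") 0 else
      config$pot_decay * (1 + 0.1 * (ti - 2))
    for (r in seq_len(config$n_replicates)) {
      rep_id <- sprintf("%s_%d", tr_name, r)
      pw <- simulate_pot_weights(config$pot_initial, config$pot_final,
                                 decay_rate = decay, days = config$pot_days,
                                 seed = seed0, tree_id = rep_id)
      pot_rows[[rep_id]] <- pw
      anchor_rows[[rep_id]] <- tibble::tibble(
        tree_id = rep_id, initial_g = config$pot_initial,
        final_g = config$pot_final)
    }
  }
  for (r in seq_len(config$n_replicates)) {
    # well-watered reference: re-irrigated to capacity every other day,
    # daily loss matched to an unstressed tree's initial transpiration
    ref_id <- sprintf("ww_%d", r)
    d <- 0:config$pot_days
    daily_loss <- (config$pot_initial - config$pot_final) *
      (1 - exp(-config$pot_decay))
    w <- config$pot_initial - daily_loss * (d %% 2L)
    ref_rows[[ref_id]] <- tibble::tibble(tree_id = ref_id, day = d,
                                         weight_g = round(w))
  }

  # tidy physiology table reproducing the reported effect sizes
  meas_means <- list(
    photosynthesis = c(control = 10, moderate = 3, severe = 0.4),
    aba = c(control = 2, moderate = 13.4, severe = 25.6))
  meas_rows <- list()
  for (vi in seq_along(meas_means)) {
    v <- names(meas_means)[vi]
    for (ti in seq_along(meas_means[[v]])) {
      tr_name <- names(meas_means[[v]])[ti]
      mu <- meas_means[[v]][[ti]]
      vals <- with_seed(seed0 + 100L * vi + ti,
                        mu * (1 + rnorm(config$n_replicates, 0, 0.08)))
      meas_rows[[paste(v, tr_name)]] <- tibble::tibble(
        variable_id = v, treatment = tr_name,
        tree_id = sprintf("%s_%d", tr_name, seq_len(config$n_replicates)),
        value = pmax(vals, 0))
    }
  }

  structure(
    list(time_courses = do.call(rbind, unname(tc_rows)),
         spectra = do.call(rbind, unname(sp_rows)),
         pools = do.call(rbind, unname(pool_rows)),
         pot_weights = do.call(rbind, unname(pot_rows)),
         pot_anchors = do.call(rbind, unname(anchor_rows)),
         reference_weights = do.call(rbind, unname(ref_rows)),
         measurements = do.call(rbind, unname(meas_rows)),
         manifest = do.call(rbind, unname(manifest)),
         config = config),
    class = "mep_experiment"
  )
}

#' @export
print.mep_experiment <- function(x, ...) {
  cat("Synthetic MEP-pathway labeling experiment\n")
  cat(sprintf("  treatments : %s\n",
              paste(names(x$config$treatments), collapse = ", ")))
  cat(sprintf("  replicates : %d per treatment\n", x$config$n_replicates))
  cat(sprintf("  time grid  : %d points over %g-%g min\n",
              length(x$config$time_grid), min(x$config$time_grid),
              max(x$config$time_grid)))
  cat(sprintf("  seed       : %d\n", x$config$seed))
  invisible(x)
}
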