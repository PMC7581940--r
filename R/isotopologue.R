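#' An isotopologue spectrum for an n-carbon analyte
#'
#' Holds the integrated signal intensities of the M+0 ... M+n isotopologues
#' of an analyte with `n` carbon atoms, in any consistent units (MRM peak
#' areas, PTR-MS ncps, ...).
#'
#' @param intensities Non-negative numeric vector of length `n + 1`
#'   (M+0 first).
#' @param carbon_count Number of carbons `n` (default inferred from the
#'   length of `intensities`).
#' @return An object of class `isotopologue_spectrum`.
#' @export
#' @examples
#' isotopologue_spectrum(c(100, 20, 5, 0, 0, 0))  # a C5 analyte
isotopologue_spectrum <- function(intensities,
                                  carbon_count = length(intensities) - 1L) {
  if (!is.numeric(intensities) || any(!is.finite(intensities))) {
    stop("`intensities` must be finite numbers", call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("`intensities` must be non-negative", call. = FALSE)
  }
  if (carbon_count < 1L || length(intensities) != carbon_count + 1L) {
    stop("`intensities` must have length carbon_count + 1", call. = FALSE)
  }
  structure(
    list(intensities = as.numeric(intensities),
         carbon_count = as.integer(carbon_count)),
    class = "isotopologue_spectrum"
  )
}

#' @export
print.isotopologue_spectrum <- function(x, ...) {
  cat(sprintf("Isotopologue spectrum, C%d analyte\n", x$carbon_count))
  print(setNames(x$intensities, paste0("M+", seq_along(x$intensities) - 1L)))
  invisible(x)
}

as_spectrum <- function(x) {
  if (inherits(x, "isotopologue_spectrum")) return(x)
  if (is.numeric(x)) return(isotopologue_spectrum(x))
  stop("cannot interpret input as an isotopologue spectrum", call. = FALSE)
}

#' Fractional 13C enrichment of an isotopologue spectrum
#'
#' The atom fraction of 13C in the analyte pool: all 13C atoms carried by
#' the isotopologues, divided by all carbon atoms,
#' \deqn{\frac{\sum_{i=0}^{n} i\, I_i}{n \sum_{i=0}^{n} I_i}.}
#' Invariant under uniform scaling of the intensities.
#'
#' @param spec An [isotopologue_spectrum()] or a numeric vector of
#'   M+0 ... M+n intensities.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' enrichment_fraction(c(1, 1, 1, 1, 1, 1))  # 0.5 for a C5 analyte
enrichment_fraction <- function(spec) {
  spec <- as_spectrum(spec)
  total <- sum(spec$intensities)
  if (total <= 0) {
    stop("all-zero spectrum: enrichment undefined", call. = FALSE)
  }
  shifts <- seq_along(spec$intensities) - 1
  sum(shifts * spec$intensities) / (spec$carbon_count * total)
}

#' Natural-abundance convolution operator
#'
#' Builds the `(n+1) x (n+1)` linear operator mapping a tracer-only
#' isotopologue distribution to the observed one when each carbon *not*
#' carrying tracer label is 13C with natural probability `p`. Column `j`
#' (0-based: `j` tracer labels) holds the binomial mass function of extra
#' mass shifts from the remaining `n - j` carbons:
#' entry `(j + k, j) = choose(n - j, k) p^k (1 - p)^(n - j - k)`.
#' The matrix is lower-triangular with columns summing to 1, so the
#' convolution preserves total intensity and is always invertible for
#' `p < 0.5`.
#'
#' @param n Number of carbon atoms.
#' @param p Natural 13C abundance; default 0.0107.
#' @return An `(n+1) x (n+1)` matrix.
#' @seealso [correct_natural_abundance()]
#' @export
natural_abundance_matrix <- function(n, p = 0.0107) {
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (p < 0 || p >= 0.5) stop("`p` must lie in [0, 0.5)", call. = FALSE)
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    k <- 0:(n - j)
    M[j + 1L + k, j + 1L] <- dbinom(k, n - j, p)
  }
  M
}

#' Correct an isotopologue spectrum for natural 13C abundance
#'
#' Removes the mass shifts contributed by naturally occurring 13C on the
#' non-tracer carbons by solving the linear system
#' `natural_abundance_matrix(n, p) %*% corrected = observed`. The system is
#' triangular and exactly invertible; small negative solution components
#' (from measurement noise) are clamped to zero with a warning and the
#' spectrum rescaled to preserve total intensity. A further warning reports
#' clamping that removes more than `clamp_report` of the total signal.
#'
#' @param spec An [isotopologue_spectrum()] or numeric intensity vector.
#' @param p Natural 13C abundance; default 0.0107.
#' @param clamp_report Fraction of total signal above which clamped negative
#'   mass triggers a loud warning. Default 0.05.
#' @return An `isotopologue_spectrum` of corrected intensities.
#' @export
#' @examples
#' M <- natural_abundance_matrix(5)
#' observed <- as.numeric(M %*% c(10, 0, 0, 0, 0, 90))
#' correct_natural_abundance(observed)
correct_natural_abundance <- function(spec, p = 0.0107, clamp_report = 0.05) {
  spec <- as_spectrum(spec)
  if (p == 0) return(spec)
  n <- spec$carbon_count
  M <- natural_abundance_matrix(n, p)
  corrected <- solve(M, spec$intensities)
  if (any(corrected < 0)) {
    removed <- -sum(corrected[corrected < 0])
    total <- sum(corrected)
    corrected[corrected < 0] <- 0
    if (sum(corrected) > 0) corrected <- corrected * total / sum(corrected)
    if (removed <= 1e-12 * max(total, 1)) {
      # numerical round-off from the triangular solve, not real signal
    } else if (removed > clamp_report * max(total, .Machine$double.eps)) {
      warning(sprintf(
        "natural-abundance correction clamped %.1f%% of total signal",
        100 * removed / total), call. = FALSE)
    } else {
      warning("small negative intensities clamped to 0 after correction",
              call. = FALSE)
    }
  }
  isotopologue_spectrum(corrected, n)
}

#' Convolve a spectrum with natural 13C abundance
#'
#' Forward operation of [correct_natural_abundance()]: predicts the observed
#' spectrum from a tracer-only spectrum. Mostly useful for simulation and
#' round-trip checks.
#'
#' @inheritParams correct_natural_abundance
#' @return An `isotopologue_spectrum`.
#' @export
convolve_natural_abundance <- function(spec, p = 0.0107) {
  spec <- as_spectrum(spec)
  if (p == 0) return(spec)
  M <- natural_abundance_matrix(spec$carbon_count, p)
  isotopologue_spectrum(as.numeric(M %*% spec$intensities),
                        spec$carbon_count)
}

#' Quantify an analyte by single-point standard addition
#'
#' Each extract is analyzed twice, once with and once without a spike of a
#' known amount of unlabeled standard; the signal increment calibrates the
#' response, giving
#' `amount = spike_amount * signal_unspiked / (signal_spiked - signal_unspiked)`.
#'
#' @param signal_unspiked Analyte signal without the spike (>= 0).
#' @param signal_spiked Analyte signal with the spike; must exceed
#'   `signal_unspiked`.
#' @param spike_amount Amount of standard added, ng (> 0).
#' @return Estimated analyte amount, ng.
#' @export
#' @examples
#' standard_addition_amount(300, 500, 25)  # 37.5 ng
standard_addition_amount <- function(signal_unspiked, signal_spiked,
                                     spike_amount) {
  if (any(spike_amount <= 0)) {
    stop("`spike_amount` must be positive", call. = FALSE)
  }
  if (any(signal_unspiked < 0)) {
    stop("signals must be non-negative", call. = FALSE)
  }
  if (any(signal_spiked <= signal_unspiked)) {
    stop("spike not recovered: spiked signal does not exceed unspiked signal",
         call. = FALSE)
  }
  spike_amount * signal_unspiked / (signal_spiked - signal_unspiked)
}

#' Quantify against an external standard curve
#'
#' Fits an ordinary least-squares line through the calibration points and
#' inverts it at the observed signal. Signals outside the calibrated
#' response range are extrapolations and are flagged with a warning and an
#' `extrapolated` attribute.
#'
#' @param signal Observed signal(s).
#' @param concentrations Calibration concentrations (>= 2 distinct values).
#' @param signals Calibration signals, same length.
#' @return Estimated concentration(s), with attribute `extrapolated`
#'   (logical, per signal).
#' @export
#' @examples
#' external_standard_quantify(50, c(0, 10), c(0, 100))  # 5
external_standard_quantify <- function(signal, concentrations, signals) {
  if (length(concentrations) != length(signals)) {
    stop("calibration vectors must have equal length", call. = FALSE)
  }
  if (length(concentrations) < 2L || length(unique(concentrations)) < 2L) {
    stop("need at least 2 distinct calibration concentrations", call. = FALSE)
  }
  fit <- lm(signals ~ concentrations)
  slope <- coef(fit)[[2L]]
  if (!is.finite(slope) || slope == 0) {
    stop("degenerate calibration: zero slope", call. = FALSE)
  }
  conc <- (signal - coef(fit)[[1L]]) / slope
  extrap <- signal < min(signals) | signal > max(signals)
  if (any(extrap)) {
    warning("signal outside the calibrated range; inverse prediction is an extrapolation",
            call. = FALSE)
  }
  attr(conc, "extrapolated") <- extrap
  conc
}

#' A PTR-MS trace of isoprene isotopologue channels
#'
#' Container for the raw count rates of protonated isoprene and its 13C
#' isotopologues (m/z 69 ... 74) together with the primary-ion signal, the
#' water cluster and the drift-tube pressure needed for normalization.
#'
#' @param times Time stamps, minutes.
#' @param channel_cps Matrix or data frame with columns `mz69` ... `mz74`,
#'   counts s^-1, one row per time stamp.
#' @param primary_ion_cps Primary-ion count rate(s), counts s^-1.
#' @param water_cluster_cps Water-cluster count rate(s), counts s^-1.
#' @param drift_pressure Drift-tube pressure(s), mbar.
#' @return An object of class `ptrms_trace`.
#' @export
ptrms_trace <- function(times, channel_cps, primary_ion_cps,
                        water_cluster_cps, drift_pressure) {
  channel_cps <- as.data.frame(channel_cps)
  need <- paste0("mz", 69:74)
  miss <- setdiff(need, names(channel_cps))
  if (length(miss)) {
    stop("missing PTR-MS channel(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  channel_cps <- channel_cps[need]
  if (nrow(channel_cps) != length(times)) {
    stop("`channel_cps` must have one row per time stamp", call. = FALSE)
  }
  if (any(as.matrix(channel_cps) < 0)) {
    stop("count rates must be non-negative", call. = FALSE)
  }
  rec <- function(x) if (length(x) == 1L) rep(x, length(times)) else x
  structure(
    list(times = as.numeric(times), channel_cps = channel_cps,
         primary_ion_cps = rec(primary_ion_cps),
         water_cluster_cps = rec(water_cluster_cps),
         drift_pressure = rec(drift_pressure)),
    class = "ptrms_trace"
  )
}

#' Map PTR-MS isoprene channels to an isotopologue spectrum
#'
#' Protonated isoprene (C5H9+) appears at m/z 69; each incorporated 13C
#' shifts it up one mass unit, so m/z 69 + k is the M+k isotopologue,
#' k = 0 ... 5. Extracts one time point of a trace (or a bare named vector
#' of channel intensities) as a C5 [isotopologue_spectrum()].
#'
#' @param trace A [ptrms_trace()], or a numeric vector of length 6 (named
#'   `mz69` ... `mz74` or in that order).
#' @param t_index Row index of the time point to extract (ignored for bare
#'   vectors).
#' @return An `isotopologue_spectrum` with `carbon_count = 5`.
#' @export
isoprene_channels_to_spectrum <- function(trace, t_index = 1L) {
  need <- paste0("mz", 69:74)
  if (inherits(trace, "ptrms_trace")) {
    if (t_index < 1L || t_index > length(trace$times)) {
      stop("`t_index` out of range", call. = FALSE)
    }
    v <- as.numeric(trace$channel_cps[t_index, need])
  } else if (is.numeric(trace) && length(trace) == 6L) {
    v <- if (!is.null(names(trace)) && all(need %in% names(trace))) {
      as.numeric(trace[need])
    } else {
      as.numeric(trace)
    }
  } else {
    stop("`trace` must be a ptrms_trace or 6 channel intensities",
         call. = FALSE)
  }
  isotopologue_spectrum(v, carbon_count = 5L)
}

#' Normalize a PTR-MS count rate
#'
#' Scales a raw count rate to normalized counts per second (ncps):
#' referenced to a conventional primary-ion signal (primary ion + water
#' cluster) of `reference_primary` counts s^-1 and to a reference drift-tube
#' pressure,
#' `ncps = cps * (reference_primary / (primary + water)) * (reference_pressure / pressure)`.
#'
#' @param cps Raw count rate(s), counts s^-1.
#' @param primary_cps Primary-ion count rate, counts s^-1.
#' @param water_cluster_cps Water-cluster count rate, counts s^-1.
#' @param drift_pressure Drift-tube pressure, mbar (> 0).
#' @param reference_primary Reference primary-ion signal; conventional
#'   1e6 counts s^-1.
#' @param reference_pressure Reference drift pressure, mbar; default 2.2.
#' @return Normalized count rate(s), ncps.
#' @export
#' @examples
#' normalize_ptrms(500, 4.5e5, 5e4, 2.2)  # 1000 ncps
normalize_ptrms <- function(cps, primary_cps, water_cluster_cps,
                            drift_pressure, reference_primary = 1e6,
                            reference_pressure = 2.2) {
  denom <- primary_cps + water_cluster_cps
  if (any(denom <= 0)) {
    stop("primary-ion + water-cluster signal must be positive", call. = FALSE)
  }
  if (any(drift_pressure <= 0) || reference_pressure <= 0) {
    stop("pressures must be positive", call. = FALSE)
  }
  cps * (reference_primary / denom) * (reference_pressure / drift_pressure)
}

#' Isoprene emission rate from normalized steady-state signal
#'
#' Converts the background-subtracted steady-state ncps signal to an
#' emission rate per gram needle dry weight using a gas-standard calibration
#' slope: `rate = (steady - background) * slope / dry_weight`. A background
#' exceeding the signal yields 0 with a warning.
#'
#' @param steady_ncps Mean normalized signal during steady state.
#' @param background_ncps Normalized signal of the empty chamber.
#' @param calibration_slope nmol per ncps per minute, from the gas
#'   calibration standard (> 0).
#' @param dry_weight Needle dry weight, g (> 0).
#' @return Emission rate, nmol g^-1 DW min^-1.
#' @export
#' @examples
#' emission_rate(1000, 200, 0.01, 0.5)  # 16
emission_rate <- function(steady_ncps, background_ncps, calibration_slope,
                          dry_weight) {
  if (any(dry_weight <= 0)) stop("`dry_weight` must be positive", call. = FALSE)
  if (any(calibration_slope <= 0)) {
    stop("`calibration_slope` must be positive", call. = FALSE)
  }
  net <- steady_ncps - background_ncps
  if (any(net < 0)) {
    warning("background exceeds steady-state signal; emission floored at 0",
            call. = FALSE)
    net <- pmax(net, 0)
  }
  net * calibration_slope / dry_weight
}
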