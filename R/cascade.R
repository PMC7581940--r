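#' Parameters of the three-pool cascade labeling model
#'
#' Bundles the quantities entering the closed-form labeling curve of a
#' linear three-pool series pathway at metabolic steady state: the plastidial
#' pool sizes of DXP (`A`), MEcDP (`B`) and IDP + DMADP (`C`), the pathway
#' flux `J` carrying label through them, and the plateau `m`, the maximal
#' fractional labeling approached at long times. A plateau below 1 reflects
#' unlabeled ("alternative") carbon sources feeding the pathway alongside
#' newly fixed 13C.
#'
#' The smaller intermediates between the measured pools (MEP, CDP-ME,
#' CDP-MEP, HMBDP) are taken as negligibly small and do not appear in the
#' model: they are too small to delay label transit measurably.
#'
#' @param pool_dxp Plastidial DXP pool size `A`, nmol g^-1 DW. Must be > 0.
#' @param pool_mecdp Plastidial MEcDP pool size `B`, nmol g^-1 DW. Must be > 0.
#' @param pool_idpdmadp Plastidial IDP + DMADP pool size `C`, nmol g^-1 DW.
#'   Must be > 0.
#' @param flux Pathway flux `J`, nmol g^-1 DW min^-1. Must be >= 0.
#' @param plateau Maximal fractional labeling `m`, dimensionless in `[0, 1]`.
#' @return An object of class `cascade_params` (a named list).
#' @seealso [cascade_fraction()] for the curve these parameters define.
#' @export
#' @examples
#' cascade_params(pool_dxp = 2, pool_mecdp = 1, pool_idpdmadp = 0.5,
#'                flux = 0.2, plateau = 0.85)
cascade_params <- function(pool_dxp, pool_mecdp, pool_idpdmadp, flux, plateau) {
  for (nm in c("pool_dxp", "pool_mecdp", "pool_idpdmadp", "flux", "plateau")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (pool_dxp <= 0 || pool_mecdp <= 0 || pool_idpdmadp <= 0) {
    stop("pool sizes A, B, C must all be positive", call. = FALSE)
  }
  if (flux < 0) stop("flux J must be non-negative", call. = FALSE)
  if (plateau < 0 || plateau > 1) {
    stop("plateau m must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(pool_dxp = pool_dxp, pool_mecdp = pool_mecdp,
         pool_idpdmadp = pool_idpdmadp, flux = flux, plateau = plateau),
    class = "cascade_params"
  )
}

#' @export
print.cascade_params <- function(x, ...) {
  cat("Three-pool cascade parameters\n")
  cat(sprintf("  A (DXP)        : %g nmol/gDW\n", x$pool_dxp))
  cat(sprintf("  B (MEcDP)      : %g nmol/gDW\n", x$pool_mecdp))
  cat(sprintf("  C (IDP+DMADP)  : %g nmol/gDW\n", x$pool_idpdmadp))
  cat(sprintf("  J (flux)       : %g nmol/gDW/min\n", x$flux))
  cat(sprintf("  m (plateau)    : %g\n", x$plateau))
  invisible(x)
}

as_cascade_params <- function(params) {
  if (inherits(params, "cascade_params")) return(params)
  if (is.numeric(params) && length(params) == 5L) {
    return(cascade_params(params[[1L]], params[[2L]], params[[3L]],
                          params[[4L]], params[[5L]]))
  }
  if (is.list(params) &&
      all(c("pool_dxp", "pool_mecdp", "pool_idpdmadp", "flux", "plateau")
          %in% names(params))) {
    return(cascade_params(params$pool_dxp, params$pool_mecdp,
                          params$pool_idpdmadp, params$flux, params$plateau))
  }
  stop("cannot interpret `params` as cascade parameters", call. = FALSE)
}

# Relative gap between the closest pair of pool sizes; the closed form has
# removable singularities where two pools coincide.
min_pool_gap <- function(A, B, C) {
  min(abs(A - B) / max(A, B),
      abs(A - C) / max(A, C),
      abs(B - C) / max(B, C))
}

#' Closed-form fractional labeling of the IDP + DMADP pool
#'
#' Evaluates the analytical step response of the three-pool series cascade:
#' after the atmosphere is switched to 13CO2 at `t = 0`, the fractional
#' labeling of the terminal IDP + DMADP pool (equal to that of emitted
#' isoprene) is
#' \deqn{f(t) = m\left[1 - \frac{A^2}{(A-B)(A-C)}e^{-Jt/A}
#'   - \frac{B^2}{(B-A)(B-C)}e^{-Jt/B}
#'   - \frac{C^2}{(C-A)(C-B)}e^{-Jt/C}\right]}
#' where `A`, `B`, `C` are the plastidial pool sizes of DXP, MEcDP and
#' IDP + DMADP, `J` the pathway flux and `m` the plateau labeling. The three
#' exponential rates are the pool turnover times `A/J`, `B/J`, `C/J`; only
#' the ratios pool/flux enter, so scaling all pools and `J` together leaves
#' the curve unchanged.
#'
#' When any two pool sizes coincide within `confluence_tol` (relative), the
#' partial-fraction coefficients suffer catastrophic cancellation; the value
#' is then delegated to the numerical integrator [cascade_fraction_ode()],
#' which is smooth through the confluence.
#'
#' @param t Time(s) since the 13CO2 switch, minutes, all >= 0. Vectorized.
#' @param params A [cascade_params()] object (or coercible).
#' @param confluence_tol Relative pool-size gap below which the ODE route is
#'   used instead of the closed form.
#' @return Numeric vector of fractional labeling values in `[0, m]`;
#'   `f(0) = 0` and `f(t) -> m` as `t -> Inf`.
#' @seealso [cascade_fraction_ode()], [fit_flux()]
#' @export
#' @examples
#' p <- cascade_params(2, 1, 0.5, flux = 0.2, plateau = 0.85)
#' cascade_fraction(c(0, 10, 50), p)
cascade_fraction <- function(t, params, confluence_tol = 1e-6) {
  params <- as_cascade_params(params)
  if (!is.numeric(t) || any(!is.finite(t) & !is.infinite(t))) {
    stop("`t` must be numeric", call. = FALSE)
  }
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  A <- params$pool_dxp; B <- params$pool_mecdp; C <- params$pool_idpdmadp
  J <- params$flux; m <- params$plateau
  if (J == 0 || m == 0) return(rep(0, length(t)))
  if (min_pool_gap(A, B, C) < confluence_tol) {
    return(cascade_fraction_ode(t, params))
  }
  cA <- A^2 / ((A - B) * (A - C))
  cB <- B^2 / ((B - A) * (B - C))
  cC <- C^2 / ((C - A) * (C - B))
  f <- m * (1 - cA * exp(-J * t / A) - cB * exp(-J * t / B) -
              cC * exp(-J * t / C))
  # guard against sub-eps cancellation at very small t
  pmin(pmax(f, 0), m)
}

#' Numerical oracle for the cascade labeling curve
#'
#' Integrates the label balance of the three-pool chain directly:
#' \deqn{A\,\dot l_A = J(m - l_A),\quad B\,\dot l_B = J(l_A - l_B),\quad
#'       C\,\dot l_C = J(l_B - l_C),\qquad l(0) = 0,}
#' with `f(t) = l_C(t)`. This is the defining initial-value problem of which
#' [cascade_fraction()] is the closed-form solution; it is exposed as an
#' independent check and as the evaluation route where pool sizes are
#' (near-)confluent and the closed form cancels catastrophically.
#'
#' @inheritParams cascade_fraction
#' @param tol Relative and absolute integration tolerance passed to
#'   [deSolve::ode()] (lsoda).
#' @return Numeric vector, fractional labeling at each `t`.
#' @export
#' @examples
#' p <- cascade_params(1, 1, 1, flux = 1, plateau = 1)
#' # Erlang-3 step response: 1 - exp(-1) * (1 + 1 + 1/2)
#' cascade_fraction_ode(1, p)
cascade_fraction_ode <- function(t, params, tol = 1e-10) {
  params <- as_cascade_params(params)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  A <- params$pool_dxp; B <- params$pool_mecdp; C <- params$pool_idpdmadp
  J <- params$flux; m <- params$plateau
  if (J == 0 || m == 0 || all(t == 0)) return(rep(0, length(t)))
  times <- sort(unique(c(0, t)))
  rhs <- function(time, y, parms) {
    list(c(J * (m - y[1L]) / A,
           J * (y[1L] - y[2L]) / B,
           J * (y[2L] - y[3L]) / C))
  }
  sol <- deSolve::ode(y = c(lA = 0, lB = 0, lC = 0), times = times,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = tol, atol = tol)
  istate <- attr(sol, "istate")[1L]
  if (is.null(istate) || istate < 0 || anyNA(sol[, "lC"])) {
    stop("ODE integration failed (istate = ", istate,
         "); parameters: A=", A, " B=", B, " C=", C, " J=", J,
         call. = FALSE)
  }
  f <- sol[match(t, times), "lC"]
  unname(pmin(pmax(f, 0), m))
}

#' Plastidial share of a total metabolite pool from final enrichments
#'
#' Whole-tissue measurements of DXP and MEcDP mix plastidial (labeled on the
#' experiment's time scale) and extra-plastidial (effectively unlabeled)
#' pools. Taking IDP + DMADP as purely plastidial, the plastidial share of
#' another pool equals the ratio of its final 13C enrichment to that of
#' IDP + DMADP, and the plastidial content is the total pool scaled by that
#' ratio.
#'
#' @param total_pool Total measured pool, nmol g^-1 DW (>= 0). Vectorized.
#' @param final_enrichment Final fractional 13C enrichment of the pool, in
#'   `[0, 1]`.
#' @param reference_enrichment Final fractional enrichment of the purely
#'   plastidial reference pool (IDP + DMADP); must be > 0.
#' @return Plastidial pool size(s), nmol g^-1 DW. Ratios above 1 (enrichment
#'   exceeding the reference, possible through measurement error) are capped
#'   at 1 with a warning.
#' @export
#' @examples
#' plastidial_pool(10, 0.75, 0.87)  # 8.62 nmol/gDW
plastidial_pool <- function(total_pool, final_enrichment, reference_enrichment) {
  if (!is.numeric(reference_enrichment) || length(reference_enrichment) != 1L) {
    stop("`reference_enrichment` must be a single number", call. = FALSE)
  }
  if (reference_enrichment == 0) {
    stop("reference pool unlabeled: reference_enrichment is 0", call. = FALSE)
  }
  if (reference_enrichment < 0 || reference_enrichment > 1) {
    stop("`reference_enrichment` must lie in (0, 1]", call. = FALSE)
  }
  if (any(total_pool < 0)) stop("`total_pool` must be >= 0", call. = FALSE)
  if (any(final_enrichment < 0 | final_enrichment > 1)) {
    stop("`final_enrichment` must lie in [0, 1]", call. = FALSE)
  }
  ratio <- final_enrichment / reference_enrichment
  if (any(ratio > 1)) {
    warning("enrichment exceeds the reference; plastidial ratio capped at 1",
            call. = FALSE)
    ratio <- pmin(ratio, 1)
  }
  total_pool * ratio
}

#' Percent change of flux relative to a control
#'
#' Reporting helper: the percent reduction of a treatment flux relative to
#' the control, `100 (J_control - J_treatment) / J_control`. Negative values
#' indicate an increase.
#'
#' @param j_control Control flux (> 0).
#' @param j_treatment Treatment flux. Vectorized.
#' @return Percent change(s).
#' @export
#' @examples
#' flux_percent_change(0.8, 0.504)  # 37
flux_percent_change <- function(j_control, j_treatment) {
  if (!is.numeric(j_control) || length(j_control) != 1L || j_control <= 0) {
    stop("`j_control` must be a single positive number", call. = FALSE)
  }
  100 * (j_control - j_treatment) / j_control
}
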