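#' A 13C labeling time course for one species and replicate
#'
#' @param times Sampling times, minutes; strictly increasing, all >= 0.
#' @param fractions Fractional 13C enrichment at each time, in `[0, 1]`.
#' @param species_id Label for the measured species (e.g. `"isoprene"`).
#' @param replicate_id Label for the biological replicate (tree).
#' @return An object of class `labeling_time_course`.
#' @export
labeling_time_course <- function(times, fractions, species_id = "isoprene",
                                 replicate_id = "r1") {
  if (length(times) != length(fractions)) {
    stop("`times` and `fractions` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be finite and >= 0", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(fractions)) || any(fractions < 0 | fractions > 1)) {
    stop("`fractions` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(times = as.numeric(times), fractions = as.numeric(fractions),
         species_id = as.character(species_id),
         replicate_id = as.character(replicate_id)),
    class = "labeling_time_course"
  )
}

as_labeling_time_course <- function(tc) {
  if (inherits(tc, "labeling_time_course")) return(tc)
  if (is.data.frame(tc)) {
    need <- c("time_min", "fraction")
    if (!all(need %in% names(tc))) {
      stop("time-course data frame needs columns `time_min` and `fraction`",
           call. = FALSE)
    }
    ord <- order(tc$time_min)
    return(labeling_time_course(
      tc$time_min[ord], tc$fraction[ord],
      species_id = if ("species_id" %in% names(tc)) tc$species_id[1L] else "isoprene",
      replicate_id = if ("replicate_id" %in% names(tc)) tc$replicate_id[1L] else "r1"
    ))
  }
  stop("cannot interpret `tc` as a labeling time course", call. = FALSE)
}

#' @export
print.labeling_time_course <- function(x, ...) {
  cat(sprintf("Labeling time course: %s / %s, %d points over %g-%g min\n",
              x$species_id, x$replicate_id, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

new_flux_fit_result <- function(flux_hat, plateau_hat, sse, n_points,
                                converged, detectable, span_warning,
                                stderr_flux = NA_real_,
                                stderr_plateau = NA_real_,
                                message = "", pools = NULL,
                                species_id = NA_character_,
                                replicate_id = NA_character_) {
  structure(
    list(flux_hat = flux_hat, plateau_hat = plateau_hat, sse = sse,
         n_points = n_points, converged = converged, detectable = detectable,
         span_warning = span_warning, stderr_flux = stderr_flux,
         stderr_plateau = stderr_plateau, message = message, pools = pools,
         species_id = species_id, replicate_id = replicate_id),
    class = "flux_fit_result"
  )
}

#' @export
print.flux_fit_result <- function(x, ...) {
  cat("Cascade flux fit\n")
  cat(sprintf("  J-hat : %.5g nmol/gDW/min (SE %.3g)\n",
              x$flux_hat, x$stderr_flux))
  cat(sprintf("  m-hat : %.5g (SE %.3g)\n", x$plateau_hat, x$stderr_plateau))
  cat(sprintf("  SSE %.4g over %d points; converged: %s; detectable: %s\n",
              x$sse, x$n_points, x$converged, x$detectable))
  if (x$span_warning) {
    cat("  warning: labeling window < 2x the slowest time constant;",
        "(m, J) weakly identified\n")
  }
  if (nzchar(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

# Deterministic, data-driven starting values: plateau from the last observed
# fraction; flux from the half-rise time scaled by the slowest pool.
fit_flux_init <- function(times, fractions, pools) {
  m0 <- min(max(fractions[length(fractions)], 1e-3), 1)
  above <- which(fractions > m0 / 2)
  t_half <- if (length(above)) times[above[1L]] else max(times)
  t_half <- max(t_half, min(diff(c(0, times))))
  c(J = max(pools) / t_half, m = m0)
}

#' Fit pathway flux and plateau to a labeling time course
#'
#' Least-squares fit of the closed-form cascade curve
#' ([cascade_fraction()]) to an observed fractional-labeling time course,
#' with the plastidial pool sizes `A`, `B`, `C` entered as known constants.
#' The flux `J` and (by default) the plateau `m` are estimated by
#' Levenberg-Marquardt minimization of the residual sum of squares
#' ([minpack.lm::nls.lm()]), with `J` bounded to `[0, Inf)` and `m` to
#' `[0, 1]`.
#'
#' A fit is reported as *not detectable* when the time course never exceeds
#' `detect_threshold` or the fitted plateau falls below it — too little 13C
#' incorporation to support a flux estimate, as happens under severe
#' drought. Independently, `span_warning` flags weakly identified fits whose
#' labeling window is shorter than twice the slowest time constant
#' `max(A, B, C) / J-hat`: such curves are still far from plateau and
#' (m, J) are nearly confounded.
#'
#' @param tc A [labeling_time_course()] or a data frame with columns
#'   `time_min` and `fraction` (at least 3 points).
#' @param pools Numeric length-3 vector `c(A, B, C)`: plastidial pool sizes
#'   of DXP, MEcDP and IDP + DMADP, nmol g^-1 DW.
#' @param init Optional named starting values `c(J = , m = )`; by default
#'   derived from the data (plateau from the last observation, flux from the
#'   half-rise time).
#' @param fit_plateau If `TRUE` (default) co-fit `m`; if `FALSE`, fix `m` at
#'   the last observed fraction and fit `J` alone.
#' @param detect_threshold Enrichment below which a curve or fitted plateau
#'   is declared not detectable. Default 0.05.
#' @param maxiter Maximum optimizer iterations.
#' @return A `flux_fit_result`: estimates `flux_hat`, `plateau_hat`, their
#'   standard errors from the least-squares covariance, `sse`, `n_points`,
#'   and the flags `converged`, `detectable`, `span_warning`.
#' @seealso [fit_flux_table()] to fit many replicates at once.
#' @export
#' @examples
#' p <- cascade_params(2, 1, 0.5, flux = 0.2, plateau = 0.85)
#' t <- seq(2, 50, length.out = 20)
#' tc <- labeling_time_course(t, cascade_fraction(t, p))
#' fit_flux(tc, pools = c(2, 1, 0.5))
fit_flux <- function(tc, pools, init = NULL, fit_plateau = TRUE,
                     detect_threshold = 0.05, maxiter = 200L) {
  tc <- as_labeling_time_course(tc)
  if (length(tc$times) < 3L) {
    stop("at least 3 time points are required for fitting", call. = FALSE)
  }
  if (!is.numeric(pools) || length(pools) != 3L || any(pools <= 0)) {
    stop("`pools` must be 3 positive pool sizes c(A, B, C)", call. = FALSE)
  }
  times <- tc$times
  y <- tc$fractions
  span <- max(times) - min(times)

  if (max(y) < detect_threshold) {
    return(new_flux_fit_result(
      flux_hat = 0, plateau_hat = max(y), sse = sum(y^2),
      n_points = length(y), converged = FALSE, detectable = FALSE,
      span_warning = TRUE,
      message = sprintf(
        "flux not detectable: enrichment never exceeds %.3g", detect_threshold),
      pools = pools, species_id = tc$species_id, replicate_id = tc$replicate_id
    ))
  }

  m_fixed <- min(max(y[length(y)], 1e-3), 1)
  start <- fit_flux_init(times, y, pools)
  if (!is.null(init)) {
    if (!is.null(init[["J"]])) start[["J"]] <- init[["J"]]
    if (fit_plateau && !is.null(init[["m"]])) start[["m"]] <- init[["m"]]
  }
  model_fractions <- function(J, m) {
    cascade_fraction(times, cascade_params(pools[1L], pools[2L], pools[3L],
                                           flux = J, plateau = m))
  }
  if (fit_plateau) {
    par0 <- c(J = unname(start[["J"]]), m = unname(start[["m"]]))
    lower <- c(J = 0, m = 0); upper <- c(J = Inf, m = 1)
    resid_fn <- function(par) model_fractions(par[["J"]], par[["m"]]) - y
  } else {
    par0 <- c(J = unname(start[["J"]]))
    lower <- c(J = 0); upper <- c(J = Inf)
    resid_fn <- function(par) model_fractions(par[["J"]], m_fixed) - y
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ftol = 1e-12, ptol = 1e-12))
  est <- coef(fit)
  J_hat <- unname(est[["J"]])
  m_hat <- if (fit_plateau) unname(est[["m"]]) else m_fixed
  sse <- sum(resid_fn(est)^2)
  converged <- fit$info %in% 1:4
  se <- tryCatch({
    s <- summary(fit)$coefficients[, "Std. Error"]
    c(J = unname(s[["J"]]),
      m = if (fit_plateau) unname(s[["m"]]) else NA_real_)
  }, error = function(e) c(J = NA_real_, m = NA_real_))

  tau_slow <- if (J_hat > 0) max(pools) / J_hat else Inf
  span_warning <- span < 2 * tau_slow
  detectable <- m_hat >= detect_threshold && max(y) >= detect_threshold
  msg <- if (!detectable) {
    sprintf("flux not detectable: fitted plateau %.3g below %.3g",
            m_hat, detect_threshold)
  } else ""

  new_flux_fit_result(
    flux_hat = J_hat, plateau_hat = m_hat, sse = sse, n_points = length(y),
    converged = converged, detectable = detectable,
    span_warning = span_warning, stderr_flux = se[["J"]],
    stderr_plateau = se[["m"]], message = msg, pools = pools,
    species_id = tc$species_id, replicate_id = tc$replicate_id
  )
}

#' Fit flux replicate-by-replicate over a time-course table
#'
#' Applies [fit_flux()] to each replicate of a long-format time-course table
#' (one tree = one fit, mirroring per-tree flux estimates averaged across
#' biological replicates).
#'
#' @param time_courses Data frame with columns `replicate_id`, `time_min`,
#'   `fraction`, optionally `species_id` (filtered to `species` if present).
#' @param pools Either a length-3 numeric `c(A, B, C)` used for every
#'   replicate, or a data frame with columns `replicate_id`,
#'   `pool_dxp`, `pool_mecdp`, `pool_idpdmadp` giving per-replicate pools.
#' @param species Species to fit when `species_id` is present
#'   (default `"isoprene"`).
#' @param ... Passed to [fit_flux()].
#' @return A tibble with one row per replicate: `replicate_id`, `J_hat`,
#'   `m_hat`, `sse`, `n_points`, `converged`, `detectable`, `span_warning`.
#' @export
fit_flux_table <- function(time_courses, pools, species = "isoprene", ...) {
  stopifnot(is.data.frame(time_courses))
  need <- c("replicate_id", "time_min", "fraction")
  miss <- setdiff(need, names(time_courses))
  if (length(miss)) {
    stop("time_courses is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("species_id" %in% names(time_courses)) {
    time_courses <- time_courses[time_courses$species_id == species, ,
                                 drop = FALSE]
  }
  if (!nrow(time_courses)) stop("no rows to fit", call. = FALSE)
  reps <- unique(time_courses$replicate_id)
  rows <- lapply(reps, function(r) {
    sub <- time_courses[time_courses$replicate_id == r, , drop = FALSE]
    pr <- if (is.data.frame(pools)) {
      p <- pools[pools$replicate_id == r, , drop = FALSE]
      if (!nrow(p)) stop("no pools for replicate ", r, call. = FALSE)
      c(p$pool_dxp[1L], p$pool_mecdp[1L], p$pool_idpdmadp[1L])
    } else {
      pools
    }
    f <- fit_flux(sub, pools = pr, ...)
    tibble::tibble(replicate_id = as.character(r), J_hat = f$flux_hat,
                   m_hat = f$plateau_hat, sse = f$sse,
                   n_points = f$n_points, converged = f$converged,
                   detectable = f$detectable, span_warning = f$span_warning)
  })
  do.call(rbind, rows)
}
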