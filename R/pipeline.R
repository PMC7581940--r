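#' Run the full labeling-to-report pipeline
#'
#' Executes the analysis chain on a simulated or supplied experiment:
#' 1. *enrich* — natural-abundance-correct the final-time isotopologue
#'    spectra and compute fractional 13C enrichments;
#' 2. *pools* — partition whole-tissue DXP and MEcDP pools into plastidial
#'    pools using the IDP + DMADP enrichment as reference;
#' 3. *fit* — fit flux `J` and plateau `m` to each tree's isoprene time
#'    course with its plastidial pools;
#' 4. *stage* — FTSW/RTR drought staging from pot weights;
#' 5. *report* — per-variable ANOVA + Tukey + compact letters + effect
#'    sizes, with the fitted fluxes of detectable trees appended as a
#'    variable.
#'
#' Outputs are deterministic given the experiment; every warning raised by
#' a stage is collected into the run log.
#'
#' @param experiment An `mep_experiment` from [simulate_experiment()], or a
#'   directory containing the CSV files written by [write_experiment()].
#' @param out_dir Optional directory; when given, result tables are written
#'   there as CSV (`enrichment.csv`, `plastidial_pools.csv`, `fits.csv`,
#'   `staging.csv`, `report.csv`, `run_log.txt`).
#' @param alpha Significance level for the report stage.
#' @param detect_threshold Passed to [fit_flux()].
#' @return A list of class `mep_pipeline_result` with tibbles `enrichment`,
#'   `plastidial_pools`, `fits`, `staging`, `report`, and `log` (character
#'   vector of stage messages and collected warnings).
#' @export
run_pipeline <- function(experiment, out_dir = NULL, alpha = 0.05,
                         detect_threshold = 0.05) {
  if (is.character(experiment)) {
    experiment <- read_experiment_dir(experiment)
  }
  stopifnot(inherits(experiment, "mep_experiment"))
  log <- character()
  warns <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warns[[length(warns) + 1L]] <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  }
  p13c <- if (!is.null(experiment$config)) experiment$config$p13c else 0.0107

  # --- enrich ---------------------------------------------------------
  sp <- experiment$spectra
  if (is.null(sp) || !nrow(sp)) stop("enrich stage: no spectra", call. = FALSE)
  keys <- unique(sp[, intersect(c("treatment", "replicate_id", "species_id"),
                                names(sp))])
  enr <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- sp$replicate_id == keys$replicate_id[i] &
      sp$species_id == keys$species_id[i]
    d <- sp[sel, , drop = FALSE]
    d <- d[order(d$mass_shift), , drop = FALSE]
    corrected <- collect(correct_natural_abundance(d$intensity, p = p13c))
    row <- keys[i, , drop = FALSE]
    row$fraction_13C <- enrichment_fraction(corrected)
    row
  }))
  log <- c(log, sprintf("enrich: %d spectra corrected (p13C = %g)",
                        nrow(enr), p13c))

  # --- plastidial pools ----------------------------------------------
  pools <- experiment$pools
  if (is.null(pools) || !nrow(pools)) {
    stop("pools stage: no pool table", call. = FALSE)
  }
  reps <- unique(pools$replicate_id)
  ppool <- do.call(rbind, lapply(reps, function(r) {
    d <- pools[pools$replicate_id == r, , drop = FALSE]
    ref <- enr$fraction_13C[enr$replicate_id == r &
                              enr$species_id == "idp_dmadp"]
    if (!length(ref)) {
      stop("pools stage: no IDP+DMADP enrichment for replicate ", r,
           call. = FALSE)
    }
    d$plastidial_nmol_gDW <- collect(vapply(seq_len(nrow(d)), function(k) {
      e <- enr$fraction_13C[enr$replicate_id == r &
                              enr$species_id == d$species_id[k]]
      e <- if (length(e)) e[1L] else d$final_enrichment[k]
      plastidial_pool(d$total_pool_nmol_gDW[k], min(e, 1), ref[1L])
    }, numeric(1)))
    d
  }))
  log <- c(log, sprintf("pools: plastidial partition for %d replicates",
                        length(reps)))

  # --- fit -----------------------------------------------------------
  tcs <- experiment$time_courses
  if (is.null(tcs) || !nrow(tcs)) {
    stop("fit stage: no time courses", call. = FALSE)
  }
  pool_wide <- do.call(rbind, lapply(reps, function(r) {
    d <- ppool[ppool$replicate_id == r, , drop = FALSE]
    gx <- function(spid) d$plastidial_nmol_gDW[d$species_id == spid][1L]
    tibble::tibble(replicate_id = r, pool_dxp = gx("dxp"),
                   pool_mecdp = gx("mecdp"), pool_idpdmadp = gx("idp_dmadp"))
  }))
  fits <- collect(fit_flux_table(tcs, pools = pool_wide,
                                 detect_threshold = detect_threshold))
  if ("treatment" %in% names(tcs)) {
    fits$treatment <- tcs$treatment[match(fits$replicate_id,
                                          tcs$replicate_id)]
  }
  n_nd <- sum(!fits$detectable)
  log <- c(log, sprintf("fit: %d replicates, %d not detectable",
                        nrow(fits), n_nd))

  # --- stage ---------------------------------------------------------
  staging <- NULL
  if (!is.null(experiment$pot_weights) && nrow(experiment$pot_weights)) {
    staging <- collect(stage_table(experiment$pot_weights,
                                   experiment$pot_anchors,
                                   experiment$reference_weights))
    log <- c(log, sprintf("stage: %d tree-days staged", nrow(staging)))
  }

  # --- report --------------------------------------------------------
  meas <- experiment$measurements
  if (!is.null(meas) && nrow(meas)) {
    flux_rows <- fits[fits$detectable & fits$converged, , drop = FALSE]
    if (!is.null(flux_rows$treatment) && nrow(flux_rows) &&
        length(unique(flux_rows$treatment)) >= 2L &&
        all(table(flux_rows$treatment) >= 2L)) {
      meas <- rbind(meas, tibble::tibble(
        variable_id = "mep_flux", treatment = flux_rows$treatment,
        tree_id = flux_rows$replicate_id, value = flux_rows$J_hat))
    }
    report <- collect(group_report(meas, alpha = alpha))
    log <- c(log, sprintf("report: %d variables",
                          length(unique(report$variable_id))))
  } else {
    report <- NULL
  }

  if (length(warns)) {
    log <- c(log, paste("warning:", unique(warns)))
  }
  res <- structure(
    list(enrichment = tibble::as_tibble(enr),
         plastidial_pools = tibble::as_tibble(ppool),
         fits = fits, staging = staging, report = report, log = log),
    class = "mep_pipeline_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(res$enrichment, file.path(out_dir, "enrichment.csv"))
    write_table(res$plastidial_pools,
                file.path(out_dir, "plastidial_pools.csv"))
    write_table(res$fits, file.path(out_dir, "fits.csv"))
    if (!is.null(res$staging)) {
      write_table(res$staging, file.path(out_dir, "staging.csv"))
    }
    if (!is.null(res$report)) {
      write_table(res$report, file.path(out_dir, "report.csv"))
    }
    writeLines(res$log, file.path(out_dir, "run_log.txt"))
  }
  res
}

#' @export
print.mep_pipeline_result <- function(x, ...) {
  cat("MEP-pathway pipeline result\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

# Rebuild an experiment bundle from a directory written by
# write_experiment(); the config (and hence p13c) is not serialized, so the
# default natural abundance applies downstream.
read_experiment_dir <- function(dir) {
  req <- function(name, schema) {
    read_table(file.path(dir, paste0(name, ".csv")), schema)
  }
  opt <- function(name, schema) {
    p <- file.path(dir, paste0(name, ".csv"))
    if (file.exists(p)) read_table(p, schema) else NULL
  }
  structure(
    list(time_courses = req("time_courses", "time_course"),
         spectra = req("spectra", "spectra_long"),
         pools = req("pools", "pools"),
         pot_weights = opt("pot_weights", "pot_weights"),
         pot_anchors = opt("pot_anchors", "pot_anchors"),
         reference_weights = opt("reference_weights", "pot_weights"),
         measurements = opt("measurements", "measurements"),
         manifest = {
           p <- file.path(dir, "manifest.csv")
           if (file.exists(p)) {
             tibble::as_tibble(read.csv(p, stringsAsFactors = FALSE))
           } else NULL
         },
         config = NULL),
    class = "mep_experiment"
  )
}
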