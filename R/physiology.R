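#' Fraction of transpirable soil water (FTSW)
#'
#' `FTSW = (daily weight - final weight) / (initial weight - final weight)`,
#' where the initial weight is the pot at capacity and the final weight the
#' pot when soil water no longer supports transpiration. Values marginally
#' outside `[0, 1]` — possible at the 1 g weighing precision — are clamped
#' with a warning.
#'
#' @param daily_weight Pot weight(s), g. Vectorized.
#' @param initial_weight Pot weight at capacity, g.
#' @param final_weight Pot weight at the transpiration endpoint, g; must be
#'   below `initial_weight`.
#' @return FTSW fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' ftsw(7000, 10000, 6000)  # 0.25
ftsw <- function(daily_weight, initial_weight, final_weight) {
  if (initial_weight <= final_weight) {
    stop("`initial_weight` must exceed `final_weight`", call. = FALSE)
  }
  f <- (daily_weight - final_weight) / (initial_weight - final_weight)
  if (any(f < 0 | f > 1)) {
    warning("FTSW outside [0, 1]; clamped (weighing precision)", call. = FALSE)
    f <- pmin(pmax(f, 0), 1)
  }
  f
}

#' Relative transpiration rate (RTR)
#'
#' `RTR = 100 * TR / ATR`: a tree's daily transpiration (daily pot weight
#' loss) relative to the average transpiration of the well-watered reference
#' group, in percent.
#'
#' @param tr Daily transpiration of the tree, g water day^-1. Small negative
#'   values (weighing noise) are floored at 0 with a warning.
#' @param atr Average daily transpiration of the well-watered reference
#'   group, g water day^-1 (> 0).
#' @return RTR in percent (>= 0).
#' @export
#' @examples
#' rtr(150, 300)  # 50, the moderate-stress sampling trigger
rtr <- function(tr, atr) {
  if (any(atr <= 0)) {
    stop("`atr` must be positive", call. = FALSE)
  }
  if (any(tr < 0)) {
    warning("negative transpiration floored at 0", call. = FALSE)
    tr <- pmax(tr, 0)
  }
  100 * tr / atr
}

.stage_levels <- c("unstressed", "moderate", "severe", "endpoint")

#' Classify drought stress stage from RTR
#'
#' Maps relative transpiration rate to the experiment's sampling stages:
#' trees are sampled as *moderate* stress when RTR has fallen to 50%, as
#' *severe* at 20%, and reach the drying *endpoint* at 10%. Triggers are
#' inclusive (a tree at exactly the trigger has reached the stage):
#' unstressed for RTR > 50, moderate for 20 < RTR <= 50, severe for
#' 10 < RTR <= 20, endpoint for RTR <= 10.
#'
#' @param rtr_percent RTR value(s), percent (>= 0).
#' @return Factor with levels `unstressed`, `moderate`, `severe`,
#'   `endpoint`.
#' @export
#' @examples
#' classify_stage(c(100, 50, 20, 10))
classify_stage <- function(rtr_percent) {
  if (any(!is.finite(rtr_percent)) || any(rtr_percent < 0)) {
    stop("`rtr_percent` must be finite and >= 0", call. = FALSE)
  }
  stage <- ifelse(rtr_percent > 50, "unstressed",
           ifelse(rtr_percent > 20, "moderate",
           ifelse(rtr_percent > 10, "severe", "endpoint")))
  factor(stage, levels = .stage_levels)
}

#' Fresh-to-dry weight conversion factor
#'
#' From paired weighings of the same tissue before and after freeze-drying.
#'
#' @param fresh_mass Fresh mass, mg (> 0).
#' @param dry_mass Dry mass, mg; must satisfy `0 < dry <= fresh`.
#' @return The dimensionless factor `dry / fresh`, class `dry_weight_factor`.
#' @export
dry_weight_factor <- function(fresh_mass, dry_mass) {
  if (fresh_mass <= 0 || dry_mass <= 0 || dry_mass > fresh_mass) {
    stop("need 0 < dry_mass <= fresh_mass", call. = FALSE)
  }
  structure(dry_mass / fresh_mass, class = "dry_weight_factor")
}

#' Convert a fresh-weight rate to a dry-weight basis
#'
#' Stressed and control needles differ in water content, so all rates are
#' reported per gram dry weight: `rate_DW = rate_FW / factor`.
#'
#' @param rate_per_fresh Rate(s) per g fresh weight.
#' @param factor A [dry_weight_factor()] or a bare number in `(0, 1]`.
#' @return Rate(s) per g dry weight.
#' @export
#' @examples
#' to_dry_weight(3.2, 0.4)  # 8
to_dry_weight <- function(rate_per_fresh, factor) {
  factor <- as.numeric(factor)
  if (length(factor) != 1L || factor <= 0 || factor > 1) {
    stop("`factor` must be a single value in (0, 1]", call. = FALSE)
  }
  rate_per_fresh / factor
}

#' Daily transpiration from a pot-weight series
#'
#' With pots bagged against soil evaporation, daily weight loss is the
#' tree's transpiration. Returns one value per day interval.
#'
#' @param weights Pot weights, g, in day order.
#' @param days Optional day indices (default `0:(length(weights)-1)`);
#'   unequal spacing is divided out to give g water day^-1.
#' @return Numeric vector of length `length(weights) - 1`.
#' @export
transpiration <- function(weights, days = seq_along(weights) - 1) {
  if (length(weights) < 2L) stop("need at least 2 weights", call. = FALSE)
  if (any(diff(days) <= 0)) stop("`days` must be increasing", call. = FALSE)
  -diff(weights) / diff(days)
}

#' Average transpiration of the well-watered reference group
#'
#' The ATR entering RTR: the mean daily transpiration across the
#' well-watered reference trees. Intervals in which a reference pot gained
#' weight (re-irrigation to capacity) carry no transpiration information
#' and are excluded. `mode = "per-day"` (default) returns one ATR per day
#' interval, linearly interpolating any day with no usable reference
#' measurement; `mode = "overall"` returns the single experiment-wide mean
#' recycled over all days.
#'
#' @param reference Data frame with columns `tree_id`, `day`, `weight_g`
#'   for the reference group.
#' @param mode `"per-day"` or `"overall"`.
#' @return Data frame with columns `day` (the end day of each interval) and
#'   `atr` (g water day^-1).
#' @export
atr_series <- function(reference, mode = c("per-day", "overall")) {
  mode <- match.arg(mode)
  need <- c("tree_id", "day", "weight_g")
  if (!all(need %in% names(reference))) {
    stop("`reference` needs columns tree_id, day, weight_g", call. = FALSE)
  }
  per_tree <- lapply(split(reference, reference$tree_id), function(d) {
    d <- d[order(d$day), , drop = FALSE]
    data.frame(day = d$day[-1L],
               tr = transpiration(d$weight_g, d$day))
  })
  all_tr <- do.call(rbind, per_tree)
  all_tr <- all_tr[all_tr$tr > 0, , drop = FALSE]  # drop re-irrigation days
  if (!nrow(all_tr)) {
    stop("reference group shows no net water loss on any day", call. = FALSE)
  }
  usable_days <- sort(unique(all_tr$day))
  usable_atr <- vapply(usable_days,
                       function(d) mean(all_tr$tr[all_tr$day == d]),
                       numeric(1))
  all_days <- sort(unique(reference$day))
  all_days <- all_days[all_days > min(all_days)]  # interval end days
  atr <- stats::approx(usable_days, usable_atr, xout = all_days,
                       rule = 2)$y
  if (length(usable_days) == 1L) atr <- rep(usable_atr, length(all_days))
  if (mode == "overall") atr[] <- mean(usable_atr)
  data.frame(day = all_days, atr = atr)
}

#' Per-tree drought staging table
#'
#' Combines daily pot weights, per-tree initial/final anchors and the
#' well-watered reference group into the staging table: FTSW, daily
#' transpiration, RTR and stress stage for every tree and day.
#'
#' @param weights Data frame `tree_id`, `day`, `weight_g` for the treated
#'   trees.
#' @param anchors Data frame `tree_id`, `initial_g`, `final_g`.
#' @param reference Data frame `tree_id`, `day`, `weight_g` for the
#'   well-watered reference group.
#' @param atr_mode Passed to [atr_series()].
#' @return Tibble with columns `tree_id`, `day`, `ftsw`, `tr`, `rtr`,
#'   `stage` (`tr`, `rtr`, `stage` are `NA` on each tree's first day).
#' @export
stage_table <- function(weights, anchors, reference,
                        atr_mode = c("per-day", "overall")) {
  atr_mode <- match.arg(atr_mode)
  for (nm in c("tree_id", "day", "weight_g")) {
    if (!nm %in% names(weights)) {
      stop("`weights` is missing column ", nm, call. = FALSE)
    }
  }
  if (!all(c("tree_id", "initial_g", "final_g") %in% names(anchors))) {
    stop("`anchors` needs columns tree_id, initial_g, final_g", call. = FALSE)
  }
  atr <- atr_series(reference, mode = atr_mode)
  rows <- lapply(split(weights, weights$tree_id), function(d) {
    d <- d[order(d$day), , drop = FALSE]
    a <- anchors[anchors$tree_id == d$tree_id[1L], , drop = FALSE]
    if (!nrow(a)) stop("no anchors for tree ", d$tree_id[1L], call. = FALSE)
    fw <- ftsw(d$weight_g, a$initial_g[1L], a$final_g[1L])
    tr_vals <- c(NA_real_, transpiration(d$weight_g, d$day))
    atr_vals <- c(NA_real_,
                  stats::approx(atr$day, atr$atr, xout = d$day[-1L],
                                rule = 2)$y)
    rtr_vals <- rep(NA_real_, nrow(d))
    ok_tr <- !is.na(tr_vals) & !is.na(atr_vals)
    rtr_vals[ok_tr] <- rtr(pmax(tr_vals[ok_tr], 0), atr_vals[ok_tr])
    stage <- rep(NA_character_, nrow(d))
    ok <- !is.na(rtr_vals)
    stage[ok] <- as.character(classify_stage(rtr_vals[ok]))
    tibble::tibble(tree_id = as.character(d$tree_id), day = d$day,
                   ftsw = fw, tr = tr_vals, rtr = rtr_vals,
                   stage = factor(stage, levels = .stage_levels))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
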