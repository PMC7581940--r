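#' One-way ANOVA of treatment groups
#'
#' Classical fixed-effects one-way analysis of variance of a response
#' across treatment groups, as used to test drought effects variable by
#' variable.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length (>= 2 groups, each with >= 2
#'   replicates).
#' @return List with `f` (F statistic), `p` (p-value), `df` (numerator,
#'   denominator degrees of freedom) and `table` (the full ANOVA table).
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'               rep(c("c", "m", "s"), each = 3))
one_way_anova <- function(values, groups) {
  groups <- check_groups(values, groups)
  if (all(vapply(split(values, groups), var, numeric(1)) == 0)) {
    stop("ANOVA undefined: zero residual variance", call. = FALSE)
  }
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  f <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  list(f = f, p = p, df = c(tab$Df[1L], tab$Df[2L]), table = tab)
}

check_groups <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  n <- table(groups)
  if (any(n < 2L)) {
    stop("each group needs >= 2 replicates for variance estimation",
         call. = FALSE)
  }
  groups
}

#' Tukey HSD pairwise comparisons
#'
#' Tukey's honestly-significant-difference post hoc test on a one-way
#' layout, controlling the family-wise error rate via the studentized range
#' distribution (the Tukey-Kramer extension handles unbalanced groups).
#'
#' @inheritParams one_way_anova
#' @param alpha Family-wise significance level; default 0.05.
#' @return Tibble with one row per group pair: `group1`, `group2`, `diff`
#'   (mean difference `group2 - group1`), `lwr`, `upr` (simultaneous
#'   confidence limits), `p_adj`, `significant`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- check_groups(values, groups)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  fit <- aov(values ~ groups)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble::tibble(
    group1 = vapply(pairs, `[[`, character(1), 2L),
    group2 = vapply(pairs, `[[`, character(1), 1L),
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"] < alpha)
  )
}

#' Compact letter display for pairwise comparisons
#'
#' Assigns letters to groups so that two groups share a letter exactly when
#' their pairwise comparison is non-significant ("different letters
#' indicate significant differences"). Uses the insert-and-absorb
#' algorithm: walk the significant pairs, splitting any letter class that
#' contains both members, then absorb redundant classes. The letter count
#' is not guaranteed minimal, but the sharing relation is exact.
#'
#' @param pairwise Either the tibble returned by [tukey_hsd()] or a
#'   symmetric logical matrix with dimnames, `TRUE` where a pair differs
#'   significantly.
#' @param group_order Optional character vector fixing the output order
#'   (letters are assigned in this order).
#' @return Tibble with columns `group` and `letters` (e.g. `"a"`, `"ab"`).
#' @export
#' @examples
#' sig <- matrix(c(FALSE, FALSE, TRUE,
#'                 FALSE, FALSE, FALSE,
#'                 TRUE, FALSE, FALSE), 3, 3,
#'               dimnames = list(c("c", "m", "s"), c("c", "m", "s")))
#' compact_letters(sig)  # a, ab, b
compact_letters <- function(pairwise, group_order = NULL) {
  sig <- as_significance_matrix(pairwise)
  groups <- rownames(sig)
  if (!is.null(group_order)) {
    if (!setequal(group_order, groups)) {
      stop("`group_order` must contain exactly the group names", call. = FALSE)
    }
    groups <- group_order
    sig <- sig[groups, groups, drop = FALSE]
  }
  k <- length(groups)
  # letter classes as logical membership vectors; start with one class
  classes <- list(rep(TRUE, k))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (!sig[i, j]) next
      for (ci in seq_along(classes)) {
        cl <- classes[[ci]]
        if (cl[i] && cl[j]) {
          # split the offending class into copies without i and without j
          a <- cl; a[i] <- FALSE
          b <- cl; b[j] <- FALSE
          classes[[ci]] <- a
          classes[[length(classes) + 1L]] <- b
        }
      }
      # absorb any class contained in (or equal to) another
      keep <- rep(TRUE, length(classes))
      for (ci in seq_along(classes)) {
        if (!keep[ci]) next
        for (cj in seq_along(classes)) {
          if (ci == cj || !keep[cj]) next
          if (all(!classes[[cj]] | classes[[ci]])) keep[cj] <- FALSE
        }
      }
      classes <- classes[keep]
    }
  }
  # stable letter order: by first member group
  first <- vapply(classes, function(cl) which(cl)[1L], integer(1))
  classes <- classes[order(first)]
  letters_out <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(classes, `[[`, logical(1), i))],
           collapse = "")
  }, character(1))
  tibble::tibble(group = groups, letters = letters_out)
}

as_significance_matrix <- function(pairwise) {
  if (is.matrix(pairwise)) {
    if (is.null(rownames(pairwise)) ||
        !identical(rownames(pairwise), colnames(pairwise))) {
      stop("significance matrix needs matching dimnames", call. = FALSE)
    }
    if (!isTRUE(all.equal(pairwise, t(pairwise)))) {
      stop("significance matrix must be symmetric", call. = FALSE)
    }
    storage.mode(pairwise) <- "logical"
    diag(pairwise) <- FALSE
    return(pairwise)
  }
  if (is.data.frame(pairwise) &&
      all(c("group1", "group2", "significant") %in% names(pairwise))) {
    groups <- sort(unique(c(pairwise$group1, pairwise$group2)))
    sig <- matrix(FALSE, length(groups), length(groups),
                  dimnames = list(groups, groups))
    for (r in seq_len(nrow(pairwise))) {
      g1 <- pairwise$group1[r]; g2 <- pairwise$group2[r]
      sig[g1, g2] <- sig[g2, g1] <- isTRUE(pairwise$significant[r])
    }
    return(sig)
  }
  stop("`pairwise` must be a tukey_hsd() result or a symmetric matrix",
       call. = FALSE)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] with the input checks used
#' throughout the package (3 <= n <= 5000, non-constant sample).
#'
#' @param values Numeric sample.
#' @return List with `w` (the W statistic) and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (var(values) == 0) {
    stop("Shapiro-Wilk undefined for a constant sample", call. = FALSE)
  }
  ht <- shapiro.test(values)
  list(w = unname(ht$statistic), p = ht$p.value)
}

#' Per-group means, errors and effect sizes versus control
#'
#' Group summary in the form the results are reported: mean, standard
#' error, percent change versus the control group
#' (`100 (mean_ctrl - mean_trt) / mean_ctrl`, positive = decrease) and fold
#' change (`mean_trt / mean_ctrl`).
#'
#' @inheritParams one_way_anova
#' @param control Name of the control group; default `"control"`.
#' @return Tibble with columns `group`, `n`, `mean`, `se`, `pct_change`,
#'   `fold_change`. Percent change is `NA` (flagged by a warning) when the
#'   control mean is 0.
#' @export
#' @examples
#' effect_summary(c(10, 10, 3, 3), c("control", "control", "d", "d"),
#'                control = "control")
effect_summary <- function(values, groups, control = "control") {
  groups <- factor(groups)
  if (!control %in% levels(groups)) {
    stop("control group '", control, "' not present", call. = FALSE)
  }
  levs <- c(control, setdiff(levels(groups), control))
  mean_ctrl <- mean(values[groups == control])
  if (mean_ctrl == 0) {
    warning("control mean is 0; percent change undefined", call. = FALSE)
  }
  rows <- lapply(levs, function(g) {
    v <- values[groups == g]
    tibble::tibble(
      group = g, n = length(v), mean = mean(v),
      se = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_,
      pct_change = if (mean_ctrl == 0) NA_real_ else
        100 * (mean_ctrl - mean(v)) / mean_ctrl,
      fold_change = if (mean_ctrl == 0) NA_real_ else mean(v) / mean_ctrl
    )
  })
  do.call(rbind, rows)
}

#' Full per-variable group report
#'
#' For each variable in a tidy measurement table, runs the one-way ANOVA,
#' Shapiro-Wilk on the residuals, Tukey HSD when the ANOVA is significant,
#' the compact letter display, and the effect summary versus control. When
#' the ANOVA is not significant all groups share the letter "a". A
#' Shapiro-Wilk rejection is reported (column `normal_resid`), not acted
#' on.
#'
#' @param data Tidy data frame with columns `variable_id`, `treatment`,
#'   `value` (and optionally `tree_id`).
#' @param alpha Significance level for ANOVA, Tukey and letters.
#' @param control Name of the control treatment.
#' @return Tibble with one row per variable and group: `variable_id`,
#'   `group`, `n`, `mean`, `se`, `pct_change`, `fold_change`, `letters`,
#'   plus per-variable `f`, `p_anova`, `normal_resid`.
#' @export
group_report <- function(data, alpha = 0.05, control = "control") {
  need <- c("variable_id", "treatment", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("`data` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(data, data$variable_id), function(d) {
    av <- one_way_anova(d$value, d$treatment)
    resid <- d$value - stats::ave(d$value, d$treatment)
    normal <- tryCatch(shapiro_wilk(resid)$p >= alpha,
                       error = function(e) NA)
    groups <- levels(factor(d$treatment))
    if (av$p < alpha) {
      tk <- tukey_hsd(d$value, d$treatment, alpha = alpha)
      cl <- compact_letters(tk, group_order = groups)
    } else {
      cl <- tibble::tibble(group = groups, letters = "a")
    }
    es <- effect_summary(d$value, d$treatment, control = control)
    es$letters <- cl$letters[match(es$group, cl$group)]
    es$variable_id <- d$variable_id[1L]
    es$f <- av$f
    es$p_anova <- av$p
    es$normal_resid <- normal
    es[, c("variable_id", "group", "n", "mean", "se", "pct_change",
           "fold_change", "letters", "f", "p_anova", "normal_resid")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
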