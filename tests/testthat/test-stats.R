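test_that("one-way ANOVA reproduces the hand-worked decomposition", {
  # groups {1,2,3},{2,3,4},{3,4,5}: SSB = 6 on 2 df, SSW = 6 on 6 df, F = 3
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  av <- one_way_anova(v, g)
  expect_equal(av$f, 3)
  expect_equal(av$df, c(2, 6))
  expect_equal(av$table$`Sum Sq`, c(6, 6))
})

test_that("ANOVA edge cases behave classically", {
  # identical group means with within-group spread: F = 0, p = 1
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  av <- one_way_anova(v, g)
  expect_equal(av$f, 0)
  expect_equal(av$p, 1)
  # no residual variance at all: undefined
  expect_error(one_way_anova(rep(1, 6), rep(c("a", "b"), each = 3)),
               "zero residual variance")
  expect_error(one_way_anova(1:5, c("a", "a", "a", "a", "b")),
               ">= 2 replicates")
})

test_that("ANOVA F is location-invariant and scale-invariant", {
  set.seed(2)
  v <- rnorm(15); g <- rep(c("a", "b", "c"), each = 5)
  f0 <- one_way_anova(v, g)$f
  expect_equal(one_way_anova(v + 100, g)$f, f0)
  expect_equal(one_way_anova(v * 7, g)$f, f0)
})

test_that("permuting labels of a null dataset preserves the F law", {
  # resampling sanity check: the permutation distribution of F under the
  # null matches the original F's quantile placement
  set.seed(12)
  v <- rnorm(15); g <- rep(c("a", "b", "c"), each = 5)
  f_obs <- one_way_anova(v, g)$f
  f_perm <- replicate(300, one_way_anova(v, sample(g))$f)
  p_perm <- mean(f_perm >= f_obs)
  p_f <- one_way_anova(v, g)$p
  expect_lt(abs(p_perm - p_f), 0.12)
})

test_that("Tukey HSD controls pairwise comparisons as expected", {
  set.seed(22)
  same <- rnorm(10)
  tk <- tukey_hsd(same, rep(c("a", "b"), each = 5))
  expect_false(tk$significant[1])
  far <- c(rnorm(5), rnorm(5, 100))  # ~100 pooled SDs apart
  tk2 <- tukey_hsd(far, rep(c("a", "b"), each = 5))
  expect_true(tk2$significant[1])
})

test_that("Tukey p-values match the hand-built studentized-range check", {
  set.seed(32)
  v <- c(rnorm(5, 0), rnorm(5, 1.2), rnorm(5, 3))
  g <- rep(c("a", "b", "c"), each = 5)
  tk <- tukey_hsd(v, g)
  # independent computation: q = |diff| / sqrt(MSE / n), balanced case
  mse <- sum(unlist(lapply(split(v, g), function(x) sum((x - mean(x))^2)))) / 12
  means <- tapply(v, g, mean)
  for (r in seq_len(nrow(tk))) {
    q <- abs(means[[tk$group2[r]]] - means[[tk$group1[r]]]) / sqrt(mse / 5)
    p_hand <- stats::ptukey(q, nmeans = 3, df = 12, lower.tail = FALSE)
    expect_equal(tk$p_adj[r], p_hand, tolerance = 1e-8)
  }
})

make_sig <- function(groups, sig_pairs) {
  m <- matrix(FALSE, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (p in sig_pairs) m[p[1], p[2]] <- m[p[2], p[1]] <- TRUE
  m
}

test_that("compact letters reproduce the canonical patterns", {
  g3 <- c("c", "m", "s")
  all_sig <- make_sig(g3, list(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(compact_letters(all_sig)$letters, c("a", "b", "c"))
  none <- make_sig(g3, list())
  expect_equal(compact_letters(none)$letters, rep("a", 3))
  chain <- make_sig(g3, list(c(1, 3)))  # 1 != 3 but 1 = 2 = 3
  expect_equal(compact_letters(chain)$letters, c("a", "ab", "b"))
})

test_that("letter sharing equals non-significance for every pattern", {
  # brute force over all significance patterns on 3 and 4 groups
  for (k in 3:4) {
    groups <- letters[seq_len(k)]
    pairs <- utils::combn(k, 2, simplify = FALSE)
    for (mask in 0:(2^length(pairs) - 1)) {
      on <- pairs[bitwAnd(bitwShiftR(mask, seq_along(pairs) - 1L), 1L) == 1L]
      sig <- make_sig(groups, on)
      cl <- compact_letters(sig)
      for (p in pairs) {
        shared <- length(intersect(strsplit(cl$letters[p[1]], "")[[1]],
                                   strsplit(cl$letters[p[2]], "")[[1]])) > 0
        expect_identical(shared, !sig[p[1], p[2]],
                         label = sprintf("k=%d mask=%d pair=%d-%d shared",
                                         k, mask, p[1], p[2]))
      }
    }
  }
})

test_that("compact letters accept tukey output and reject bad input", {
  set.seed(42)
  v <- c(rnorm(5, 0, 0.1), rnorm(5, 5, 0.1), rnorm(5, 10, 0.1))
  g <- rep(c("ctrl", "mod", "sev"), each = 5)
  cl <- compact_letters(tukey_hsd(v, g), group_order = c("ctrl", "mod", "sev"))
  expect_equal(cl$letters, c("a", "b", "c"))
  bad <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(compact_letters(bad), "symmetric")
})

test_that("Shapiro-Wilk wrapper screens degenerate samples", {
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  set.seed(52)
  normal <- shapiro_wilk(rnorm(50))
  expect_true(normal$w > 0 && normal$w <= 1)
  bimodal <- shapiro_wilk(c(rnorm(25, 0, 0.01), rnorm(25, 1, 0.01)))
  expect_lt(bimodal$p, 0.05)
})

test_that("effect summary reports the reported-style effect sizes", {
  v <- c(2, 2, 0.6, 0.6, 13.4, 13.4)
  g <- c("control", "control", "drought", "drought", "aba_up", "aba_up")
  es <- effect_summary(v, g, control = "control")
  expect_equal(es$group[1], "control")
  expect_equal(es$pct_change[es$group == "control"], 0)
  expect_equal(es$fold_change[es$group == "control"], 1)
  expect_equal(es$pct_change[es$group == "drought"], 70)
  expect_equal(es$fold_change[es$group == "aba_up"], 6.7)
  expect_error(effect_summary(v, g, control = "nope"), "not present")
  expect_warning(es0 <- effect_summary(c(0, 0, 1, 1),
                                       rep(c("control", "t"), each = 2)),
                 "undefined")
  expect_true(is.na(es0$pct_change[2]))
})

test_that("group_report combines ANOVA, letters and effects per variable", {
  set.seed(62)
  d <- rbind(
    data.frame(variable_id = "x", treatment = rep(c("control", "moderate",
                                                    "severe"), each = 5),
               tree_id = as.character(1:15),
               value = c(rnorm(5, 10, 0.5), rnorm(5, 3, 0.5),
                         rnorm(5, 0.4, 0.1))),
    data.frame(variable_id = "flat", treatment = rep(c("control", "moderate",
                                                       "severe"), each = 5),
               tree_id = as.character(1:15), value = rnorm(15, 5))
  )
  rep_out <- group_report(d, alpha = 0.05)
  x <- rep_out[rep_out$variable_id == "x", ]
  expect_lt(x$p_anova[1], 0.05)
  expect_equal(x$letters, c("a", "b", "c"))
  expect_equal(x$pct_change[x$group == "moderate"], 70, tolerance = 0.2)
  flat <- rep_out[rep_out$variable_id == "flat", ]
  expect_gt(flat$p_anova[1], 0.05)
  expect_equal(unique(flat$letters), "a")
})
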