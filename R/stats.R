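#' Mann-Whitney U test (rank-sum)
#'
#' Two-sided Mann-Whitney U with exact enumeration for small samples
#' (both groups <= `exact_max` and no ties) and the tie-corrected normal
#' approximation otherwise. The statistic reported is U for the first
#' group. When every value in both groups is identical the test is
#' degenerate and `p = 1`.
#'
#' @param a,b numeric samples (each n >= 1).
#' @param exact_max largest per-group n for which the exact distribution
#'   is used (default 20).
#' @return list: `U`, `p`, `exact` (logical), `n` (per-group sizes).
#' @export
mann_whitney_u <- function(a, b, exact_max = 20) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1)
    return(list(U = length(a) * length(b) / 2, p = 1, exact = TRUE,
                n = c(length(a), length(b))))
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && max(length(a), length(b)) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact,
       n = c(length(a), length(b)))
}

#' Welch two-sample t test (unpaired, unequal variance)
#'
#' Unpaired two-tailed Student's t test with unequal variances (Welch
#' statistic, Satterthwaite degrees of freedom). Degenerate zero-variance
#' input is handled explicitly: equal means give `p = 1`, separated means
#' give a p floored at machine epsilon.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list: `t`, `df`, `p`, `mean_diff`.
#' @export
t_test_unequal_var <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_diff = 0))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2,
                p = .Machine$double.eps, mean_diff = mean(a) - mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = max(tt$p.value, .Machine$double.eps),
       mean_diff = mean(a) - mean(b))
}

#' One-way ANOVA
#'
#' Standard fixed-effects one-way analysis of variance across k groups.
#' On two groups it is equivalent to the squared pooled-variance two-sample
#' t test (F = t^2). Identical group means give F = 0, p = 1.
#'
#' @param groups named (or unnamed) list of numeric vectors, each n >= 2,
#'   with >= 2 groups; or a data.frame with columns `group` and `value`.
#' @return list: `F`, `df` (between, within), `p`, `n` per group.
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  stopifnot(length(groups) >= 2)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("each group needs at least 2 values")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), ns))
  if (stats::var(value) == 0)
    return(list(F = 0, df = c(length(groups) - 1, sum(ns) - length(groups)),
                p = 1, n = unname(ns)))
  fit <- stats::aov(value ~ grp)
  s <- summary(fit)[[1]]
  list(F = s$`F value`[1], df = c(s$Df[1], s$Df[2]), p = s$`Pr(>F)`[1],
       n = unname(ns))
}

#' Grouped-sample test dispatcher on a tidy table
#'
#' Runs one of the three tests used for figure-style comparisons on a tidy
#' `(group, value, replicate)` table. By default the unit of analysis is
#' the per-replicate mean (one value per biological replicate per group);
#' set `unit = "cell"` to pool individual measurements instead. No
#' multiple-testing correction is applied (per-comparison reporting);
#' `stats::p.adjust(..., "BH")` can be applied downstream when several
#' comparisons are made.
#'
#' @param data data.frame with columns `group`, `value` and (for
#'   `unit = "replicate"`) `replicate`.
#' @param test `"mann_whitney"`, `"t_welch"` or `"anova"`.
#' @param unit `"replicate"` (test per-replicate means) or `"cell"`.
#' @return the underlying test's result list, plus `test` and `unit`.
#' @export
grouped_test <- function(data, test = c("mann_whitney", "t_welch", "anova"),
                         unit = c("replicate", "cell")) {
  test <- match.arg(test); unit <- match.arg(unit)
  stopifnot(all(c("group", "value") %in% names(data)))
  if (unit == "replicate") {
    stopifnot("replicate" %in% names(data))
    agg <- stats::aggregate(value ~ group + replicate, data, mean)
    groups <- split(agg$value, agg$group)
  } else {
    groups <- split(data$value, data$group)
  }
  res <- switch(test,
    mann_whitney = {
      stopifnot(length(groups) == 2)
      mann_whitney_u(groups[[1]], groups[[2]])
    },
    t_welch = {
      stopifnot(length(groups) == 2)
      t_test_unequal_var(groups[[1]], groups[[2]])
    },
    anova = one_way_anova(groups))
  c(res, list(test = test, unit = unit))
}
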