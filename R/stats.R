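#' Two-tailed paired t-test
#'
#' Classical paired t statistic on per-animal pre/post values. Degenerate
#' inputs (zero variance of the differences) are flagged rather than
#' erroring: identical arrays give statistic 0 and p = 1; a constant nonzero
#' difference gives an infinite statistic with p = 0.
#'
#' @param pre,post paired measurements, equal length >= 3.
#' @return list with `statistic`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_test <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must be paired")
  n <- length(pre)
  if (n < 3L) stop("need at least 3 pairs")
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(statistic = 0, p = 1, df = n - 1L, mean_diff = 0,
                  degenerate = TRUE))
    }
    return(list(statistic = sign(mean(d)) * Inf, p = 0, df = n - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Iterative two-sided Grubbs outlier exclusion
#'
#' Repeatedly tests the most extreme observation against the Grubbs critical
#' value at the given significance and removes it while significant.
#' Returns the indices (into the original vector) of removed values, in
#' removal order.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha significance level; default 0.05.
#' @return integer vector of flagged indices (possibly empty).
#' @export
grubbs_outliers <- function(values, alpha = 0.05) {
  if (length(values) < 3L) stop("Grubbs test needs at least 3 values")
  idx <- seq_along(values)
  x <- values
  flagged <- integer(0)
  while (length(x) >= 3L) {
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    G <- dev[i] / s
    n <- length(x)
    tcrit <- stats::qt(1 - alpha / (2 * n), df = n - 2)
    Gcrit <- ((n - 1) / sqrt(n)) *
      sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (G <= Gcrit) break
    flagged <- c(flagged, idx[i])
    x <- x[-i]
    idx <- idx[-i]
  }
  flagged
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with the chi-square approximation.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return list with `H`, `p`, `df`, `degenerate` (TRUE when every value is
#'   identical, in which case H = 0 and p = 1).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    return(list(H = 0, p = 1, df = length(groups) - 1L, degenerate = TRUE))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE)
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Fits `value ~ A * B` and reports F and p for both main effects and the
#' interaction using Type II sums of squares, which remain well defined for
#' the unbalanced cohorts that arise after outlier exclusion. Empty cells
#' are reported by name.
#'
#' @param table data.frame holding the response and both factors.
#' @param response name of the response column.
#' @param factors character vector of two factor column names, e.g.
#'   `c("sex", "timepoint")`.
#' @return data.frame with rows for each main effect and the interaction:
#'   `term`, `F`, `p`, `df`; attribute `ss_type = "II"`.
#' @export
two_way_anova <- function(table, response, factors) {
  stopifnot(is.data.frame(table), length(factors) == 2L)
  for (f in c(response, factors)) {
    if (!f %in% names(table)) stop("column '", f, "' not found")
  }
  a <- factor(table[[factors[1]]]); b <- factor(table[[factors[2]]])
  counts <- table(a, b)
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s",
                 factors[1], rownames(counts)[empty[1]],
                 factors[2], colnames(counts)[empty[2]]))
  }
  dat <- data.frame(y = table[[response]], A = a, B = b)
  fit <- stats::lm(y ~ A * B, data = dat)
  an <- car::Anova(fit, type = 2)
  terms <- c("A", "B", "A:B")
  out <- data.frame(
    term = c(factors, paste(factors, collapse = ":")),
    F = an[terms, "F value"],
    p = an[terms, "Pr(>F)"],
    df = an[terms, "Df"]
  )
  attr(out, "ss_type") <- "II"
  out
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentized-range pairwise comparisons with the Kramer correction for
#' unequal group sizes, via a one-way fit.
#'
#' @param groups named list of >= 2 numeric vectors (each length >= 2).
#' @return data.frame: `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_kramer <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(x ~ g)
  tk <- stats::TukeyHSD(fit)$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}

#' ANCOVA comparison of pre- vs post-injection slopes
#'
#' Fits `value ~ segment * minute` by least squares on an ambient series
#' split at the injection minute and returns the two segment slopes with
#' the interaction (slope difference) p value.
#'
#' @param series an [ambient_series()] (or data.frame with columns `minute`,
#'   `serotonin_nM` and an `injection_minute` attribute/column).
#' @return list with `slope_pre`, `slope_post` (nM/min), `interaction_p`,
#'   `F`, and the underlying `lm` fit.
#' @export
ancova_slopes <- function(series) {
  s <- as_ambient_df(series)
  seg <- factor(ifelse(s$minute <= s$injection_minute[1], "pre", "post"),
                levels = c("pre", "post"))
  if (min(table(seg)) < 3L) stop("need >= 3 points per segment")
  for (lv in levels(seg)) {
    if (stats::sd(s$minute[seg == lv]) == 0) {
      stop("degenerate segment: constant minute in '", lv, "'")
    }
  }
  fit <- stats::lm(serotonin_nM ~ seg * minute, data = cbind(s, seg = seg))
  cf <- stats::coef(fit)
  slope_pre <- unname(cf["minute"])
  slope_post <- unname(cf["minute"] + cf["segpost:minute"])
  # noise-free series fit exactly; the F table is then uninformative but
  # the slopes themselves remain valid, so silence only that warning
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(slope_pre = slope_pre, slope_post = slope_post,
       interaction_p = an["seg:minute", "Pr(>F)"],
       F = an["seg:minute", "F value"], fit = fit)
}

#' First minute of significant departure from the control period
#'
#' For a cohort of ambient series on a common minute grid, pools all
#' pre-injection (control-period) observations into one reference group and
#' compares every post-injection minute against it with the Tukey-Kramer
#' procedure; returns the earliest post-injection minute whose adjusted
#' p < `alpha`, or `NA` if none departs.
#'
#' @param cohort list of >= 3 [ambient_series()] on identical minute grids
#'   with identical injection minutes.
#' @param alpha significance level; default 0.05.
#' @return the minute index of first significant departure (`NA` if none),
#'   with attribute `p_by_minute` (named vector of adjusted p values).
#' @export
first_significant_departure <- function(cohort, alpha = 0.05) {
  if (!is.list(cohort) || length(cohort) < 3L) stop("need >= 3 series")
  dfs <- lapply(cohort, as_ambient_df)
  m0 <- dfs[[1]]$minute; inj <- dfs[[1]]$injection_minute[1]
  for (d in dfs) {
    if (!identical(d$minute, m0) || d$injection_minute[1] != inj) {
      stop("all series must share one minute grid and injection minute")
    }
  }
  if (!any(m0 <= inj)) stop("no control period before the injection minute")
  ctrl <- unlist(lapply(dfs, function(d) d$serotonin_nM[d$minute <= inj]))
  post_minutes <- m0[m0 > inj]
  groups <- c(list(control = ctrl),
              stats::setNames(
                lapply(post_minutes, function(m) {
                  vapply(dfs, function(d) d$serotonin_nM[d$minute == m],
                         numeric(1))
                }),
                paste0("min", post_minutes)))
  tk <- tukey_kramer(groups)
  vs_ctrl <- tk[grepl("(^control-)|(-control$)", tk$comparison), ]
  lab <- sub("-?control-?", "", vs_ctrl$comparison)
  p <- stats::setNames(vs_ctrl$p_adj, lab)
  p <- p[paste0("min", post_minutes)]
  hit <- which(p < alpha)
  out <- if (length(hit)) post_minutes[hit[1]] else NA_real_
  attr(out, "p_by_minute") <- p
  out
}

#' Normality-gated group comparison
#'
#' Routes a comparison of >= 2 independent groups through the decision rule
#' used for the cohort analyses: Shapiro-Wilk normality at 0.05 on each
#' group; if every group is consistent with normality, a one-way ANOVA
#' (two groups: Welch t-test), otherwise the Kruskal-Wallis rank test. The
#' gate decision is returned alongside the result.
#'
#' @param groups list of >= 2 numeric vectors.
#' @param alpha significance for the normality gate; default 0.05.
#' @return list with `method` ("anova", "t_test" or "kruskal_wallis"),
#'   `normal` (per-group Shapiro p values), `statistic`, `p`.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  sw <- vapply(groups, function(g) stats::shapiro.test(g)$p.value,
               numeric(1))
  if (all(sw >= alpha)) {
    if (length(groups) == 2L) {
      tt <- stats::t.test(groups[[1]], groups[[2]])
      return(list(method = "t_test", normal = sw,
                  statistic = unname(tt$statistic), p = tt$p.value))
    }
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    an <- stats::anova(stats::aov(x ~ g))
    return(list(method = "anova", normal = sw,
                statistic = an["g", "F value"], p = an["g", "Pr(>F)"]))
  }
  kw <- kruskal_wallis(groups)
  list(method = "kruskal_wallis", normal = sw, statistic = kw$H, p = kw$p)
}
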