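# Descriptive/inferential layer for cohort tables: normality-gated
# two-group comparisons and categorical tests.

#' Compare a numeric variable between two groups
#'
#' Normality of each group is assessed with the Shapiro--Wilk test at
#' `alpha`; if both groups pass, a two-sided Welch t-test is used and the
#' groups are summarised as mean +- SD, otherwise a Mann--Whitney test with
#' median (IQR) summaries.
#'
#' @param x,y numeric samples for the two groups (each n >= 3).
#' @param alpha significance level of the normality gate.
#' @param variable optional variable name carried into the result.
#' @return Object of class `group_comparison`: test name, p-value, and the
#'   gate-consistent per-group summaries.
#' @export
compare_numeric <- function(x, y, alpha = 0.05, variable = NA_character_) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop("each group needs at least 3 observations")
  # shapiro.test caps at n = 5000; a subsample decides the gate beyond that
  sw <- function(v) {
    if (length(v) > 5000) v <- v[seq(1, length(v), length.out = 5000)]
    if (stats::var(v) == 0) return(0)  # degenerate: clearly non-normal gate
    shapiro.test(v)$p.value
  }
  normal <- sw(x) > alpha && sw(y) > alpha
  if (normal) {
    ht <- t.test(x, y)  # Welch form
    summ <- data.frame(group = c("x", "y"), n = c(length(x), length(y)),
                       location = c(mean(x), mean(y)),
                       spread_lo = c(mean(x) - sd(x), mean(y) - sd(y)),
                       spread_hi = c(mean(x) + sd(x), mean(y) + sd(y)),
                       style = "mean_sd")
  } else {
    ht <- suppressWarnings(wilcox.test(x, y))
    summ <- data.frame(group = c("x", "y"), n = c(length(x), length(y)),
                       location = c(median(x), median(y)),
                       spread_lo = c(quantile(x, 0.25), quantile(y, 0.25)),
                       spread_hi = c(quantile(x, 0.75), quantile(y, 0.75)),
                       style = "median_iqr")
  }
  structure(list(variable = variable,
                 test = if (normal) "t" else "mann_whitney",
                 p_value = ht$p.value, summaries = summ),
            class = "group_comparison")
}

#' Compare categorical data between groups
#'
#' Pearson chi-square test when all expected counts are at least 5,
#' otherwise Fisher's exact test (two-sided).
#'
#' @param contingency 2 x k matrix of counts (groups in rows).
#' @param variable optional variable name.
#' @return Object of class `group_comparison`.
#' @export
compare_categorical <- function(contingency, variable = NA_character_) {
  m <- as.matrix(contingency)
  if (any(dim(m) < 2L) || sum(m) == 0) stop("need a 2 x k table of counts")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("contingency table has an empty margin")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (all(expected >= 5)) {
    ht <- suppressWarnings(chisq.test(m, correct = FALSE))
    test <- "chi_square"
  } else {
    ht <- fisher.test(m)
    test <- "fisher"
  }
  structure(list(variable = variable, test = test, p_value = ht$p.value,
                 table = m),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s test, p = %.4g\n",
              ifelse(is.na(x$variable), "comparison", x$variable),
              x$test, x$p_value))
  invisible(x)
}

#' Publication-style cohort summary table
#'
#' Builds the all-patients / CA / no-CA summary with normality-gated
#' numeric summaries, device-type counts and percentages, outcome counts
#' and the two-group p-value for every feature. With a single outcome group
#' the p-values are omitted.
#'
#' @param cohort cohort data frame.
#' @param numeric_variables numeric columns to summarise.
#' @return List of class `cohort_summary` with data frames `header`,
#'   `numeric`, `categorical` and `outcomes`.
#' @export
summarize_cohort <- function(cohort,
                             numeric_variables = c("annular_diameter",
                                                   "ibms_length", "ibms_angle",
                                                   "d3", "doi", "sizing_index",
                                                   "cpmax", "cpi")) {
  stopifnot(nrow(cohort) > 0)
  numeric_variables <- intersect(numeric_variables, names(cohort))
  n <- nrow(cohort); n1 <- sum(cohort$ca == 1); n0 <- n - n1
  two_groups <- n1 >= 3 && n0 >= 3
  header <- data.frame(
    column = c("all", "ca", "no_ca"),
    label = c(sprintf("All patients (n = %d)", n),
              sprintf("CA, N = %d (%.0f%%)", n1, 100 * n1 / n),
              sprintf("No CA, N = %d (%.0f%%)", n0, 100 * n0 / n)),
    n = c(n, n1, n0))
  num <- do.call(rbind, lapply(numeric_variables, function(nm) {
    fmt <- function(x, style) {
      if (style == "mean_sd") sprintf("%.2f ± %.2f", mean(x), sd(x))
      else sprintf("%.2f (%.2f–%.2f)", median(x),
                   quantile(x, 0.25), quantile(x, 0.75))
    }
    if (two_groups) {
      cmp <- compare_numeric(cohort[[nm]][cohort$ca == 1],
                             cohort[[nm]][cohort$ca == 0], variable = nm)
      style <- cmp$summaries$style[1]
      data.frame(variable = nm, style = style,
                 all = fmt(cohort[[nm]], style),
                 ca = fmt(cohort[[nm]][cohort$ca == 1], style),
                 no_ca = fmt(cohort[[nm]][cohort$ca == 0], style),
                 p_value = cmp$p_value)
    } else {
      data.frame(variable = nm, style = "mean_sd",
                 all = fmt(cohort[[nm]], "mean_sd"), ca = NA, no_ca = NA,
                 p_value = NA_real_)
    }
  }))
  lev <- sort(unique(cohort$device_type))
  cat_tab <- do.call(rbind, lapply(lev, function(l) {
    cnt <- function(sel) sum(cohort$device_type[sel] == l)
    data.frame(variable = "device_type", level = l,
               all_count = cnt(rep(TRUE, n)),
               all_pct = 100 * cnt(rep(TRUE, n)) / n,
               ca_count = cnt(cohort$ca == 1),
               ca_pct = if (n1) 100 * cnt(cohort$ca == 1) / n1 else NA,
               no_ca_count = cnt(cohort$ca == 0),
               no_ca_pct = if (n0) 100 * cnt(cohort$ca == 0) / n0 else NA)
  }))
  p_dev <- if (two_groups && length(lev) >= 2) {
    m <- rbind(ca = cat_tab$ca_count, no_ca = cat_tab$no_ca_count)
    colnames(m) <- lev
    compare_categorical(m, variable = "device_type")$p_value
  } else NA_real_
  attr(cat_tab, "p_value") <- p_dev
  outc <- data.frame(outcome = c("ca", "lbbb_rbbb", "ppi"),
                     count = c(n1, sum(cohort$lbbb_rbbb), sum(cohort$ppi)),
                     pct = 100 * c(n1, sum(cohort$lbbb_rbbb), sum(cohort$ppi)) / n)
  structure(list(header = header, numeric = num, categorical = cat_tab,
                 outcomes = outc),
            class = "cohort_summary")
}
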