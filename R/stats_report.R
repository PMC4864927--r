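#' Per-arm summary of a cohort metric
#'
#' Reports n, mean and sample standard deviation (n-1 denominator) of
#' one metric per treatment arm, matching the bar-plus-SD presentation
#' convention. `NA` metric values (not-computed sentinels) are dropped
#' with a message stating how many.
#'
#' @param cohort Data.frame of per-section metrics with an `arm` column.
#' @param metric Name of the metric column.
#' @return Data.frame with columns `arm`, `n`, `mean`, `sd` (`sd` is
#'   `NA` when `n < 2`).
#' @export
summarize_groups <- function(cohort, metric) {
  stopifnot(is.data.frame(cohort), "arm" %in% names(cohort))
  if (!metric %in% names(cohort)) stop("metric '", metric, "' not in cohort")
  x <- cohort[[metric]]
  drop <- sum(is.na(x))
  if (drop > 0) message(drop, " sentinel value(s) dropped for '", metric, "'")
  arms <- unique(cohort$arm)
  out <- lapply(arms, function(a) {
    v <- x[cohort$arm == a & !is.na(x)]
    if (!length(v)) stop("no valid values of '", metric, "' in arm '", a, "'")
    data.frame(arm = a, n = length(v), mean = mean(v),
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
  })
  do.call(rbind, out)
}

#' One-way ANOVA with Bonferroni post-tests
#'
#' Classical one-way ANOVA across arms followed by pairwise comparisons
#' using the pooled within-group error (so with two groups F equals the
#' squared pooled t statistic). Raw pairwise p-values are Bonferroni
#' adjusted as `min(1, m * p_raw)` with `m` the number of comparisons
#' made: all pairs (`m = k(k-1)/2`, default) or each arm against a
#' control (`m = k-1`).
#'
#' @param groups Named list of numeric vectors (metric values by arm),
#'   at least two arms with at least two values each. `NA`s are dropped.
#' @param alpha Significance level for the flags (default 0.05).
#' @param comparisons `"all_pairwise"` or `"vs_control"`.
#' @param control Control arm name for `"vs_control"` (default: first).
#' @param metric Optional metric name carried in the result.
#' @return An `anova_result` list: `metric`, `F`, `df_between`,
#'   `df_within`, `p_value`, and `pairwise` (data.frame with `arm_i`,
#'   `arm_j`, `mean_diff`, `p_raw`, `p_bonferroni`, `significant`).
#'   Degenerate data (zero within-group variance with unequal means)
#'   yields `NA` F and p.
#' @export
anova_bonferroni <- function(groups, alpha = 0.05,
                             comparisons = c("all_pairwise", "vs_control"),
                             control = NULL, metric = NA_character_) {
  comparisons <- match.arg(comparisons)
  stopifnot(is.list(groups))
  if (length(groups) < 2) stop("at least two arms are required")
  groups <- lapply(groups, function(v) v[!is.na(v)])
  ns <- lengths(groups)
  if (any(ns < 2)) stop("every arm needs at least two values")
  arms <- names(groups)
  if (is.null(arms)) stop("groups must be named by arm")

  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(arms, ns), levels = arms)
  k <- length(arms); N <- length(x)
  df_b <- k - 1L; df_w <- N - k

  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(ns * (means - mean(x))^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))

  if (ssw <= 0 && ssb <= 1e-12 * max(abs(x), 1)^2) {
    f <- 0; p <- 1; mse <- 0
  } else if (ssw <= 0) {
    warning("zero within-group variance with unequal means: F undefined")
    f <- NA_real_; p <- NA_real_; mse <- 0
  } else {
    fit <- stats::aov(x ~ g)
    tab <- stats::anova(fit)
    f <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
    mse <- tab[["Mean Sq"]][2]
  }

  if (comparisons == "all_pairwise") {
    pairs <- utils::combn(arms, 2, simplify = FALSE)
  } else {
    control <- control %||% arms[1]
    if (!control %in% arms) stop("control arm '", control, "' not found")
    pairs <- lapply(setdiff(arms, control), function(a) c(control, a))
  }
  m <- length(pairs)
  pw <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- means[[j]] - means[[i]]
    if (is.na(f) || mse <= 0) {
      praw <- if (!is.na(f) && f == 0) 1 else NA_real_
    } else {
      tstat <- diff / sqrt(mse * (1 / ns[[i]] + 1 / ns[[j]]))
      praw <- 2 * stats::pt(-abs(tstat), df_w)
    }
    data.frame(arm_i = i, arm_j = j, mean_diff = diff, p_raw = praw,
               p_bonferroni = pmin(1, m * praw),
               significant = !is.na(praw) & pmin(1, m * praw) < alpha)
  })
  structure(list(metric = metric, F = f, df_between = df_b, df_within = df_w,
                 p_value = p, pairwise = do.call(rbind, pw),
                 n_comparisons = m, alpha = alpha),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("One-way ANOVA", if (!is.na(x$metric)) paste0(" on ", x$metric), ":\n",
      sep = "")
  cat(sprintf("  F(%d, %d) = %s, p = %s\n", x$df_between, x$df_within,
              format(x$F, digits = 4), format(x$p_value, digits = 4)))
  cat("  Bonferroni post-tests (m = ", x$n_comparisons, "):\n", sep = "")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
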