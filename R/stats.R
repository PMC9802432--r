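# Comparison procedures across response-probability strata: Pearson
# chi-square for categorical outcomes; one-way ANOVA (3 strata) or pooled
# two-sample t-test (2 strata) for continuous outcomes. Each continuous test
# has a summary-statistics variant operating on (n, mean, SD) triplets so
# the published tables can be recomputed without raw data.

new_test_result <- function(method, statistic, df, p_value) {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value)),
            class = "cdst_test")
}

#' @export
print.cdst_test <- function(x, ...) {
  df <- if (length(x$df) == 2) sprintf("df = %g, %g", x$df[1], x$df[2])
        else sprintf("df = %g", x$df)
  cat(sprintf("%s: statistic = %.4f, %s, p = %.4g\n", x$method,
              x$statistic, df, x$p_value))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' No continuity correction. Emits a warning when any expected cell count is
#' below 5 (asymptotic p-values are then unreliable).
#'
#' @param x matrix of non-negative integer counts (strata in rows, outcome
#'   levels in columns), at least 2x2 with positive margins.
#' @return A `cdst_test` with statistic, degrees of freedom
#'   `(r - 1)(c - 1)` and p-value.
#' @examples
#' chi_square_test(rbind(high = c(532, 403), low = c(295, 215)))
#' @export
chi_square_test <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0) || anyNA(x)) stop("counts must be non-negative", call. = FALSE)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  rz <- which(rowSums(x) == 0); cz <- which(colSums(x) == 0)
  if (length(rz))
    stop(sprintf("row %s has zero margin", toString(rownames(x)[rz] %||% rz)),
         call. = FALSE)
  if (length(cz))
    stop(sprintf("column %s has zero margin", toString(colnames(x)[cz] %||% cz)),
         call. = FALSE)
  expected <- outer(rowSums(x), colSums(x)) / sum(x)
  if (any(expected < 5))
    warning("expected cell count below 5; asymptotic p-value may be unreliable",
            call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  new_test_result("Pearson chi-square", unname(res$statistic),
                  unname(res$parameter), unname(res$p.value))
}

#' One-way ANOVA from per-group summary statistics
#'
#' Reconstructs the F statistic from per-group (n, mean, SD):
#' between-group sum of squares from the group means about the grand mean,
#' within-group sum of squares from the SDs. Identical to observation-level
#' ANOVA when the summaries are computed from the same data.
#'
#' @param n,mean,sd numeric vectors, one entry per group (all n >= 2).
#' @return A `cdst_test` with `F`, df `(k - 1, N - k)` and p-value.
#' @examples
#' anova_oneway_summary(n = c(179, 152, 27), mean = c(46.3, 45.2, 36.9),
#'                      sd = c(16.8, 14.9, 13.6))
#' @export
anova_oneway_summary <- function(n, mean, sd) {
  k <- length(n)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(mean) != k || length(sd) != k)
    stop("n, mean, sd must have equal length", call. = FALSE)
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  N <- sum(n)
  grand <- sum(n * mean) / N
  ssb <- sum(n * (mean - grand)^2)
  ssw <- sum((n - 1) * sd^2)
  if (ssw == 0 && ssb == 0)
    return(new_test_result("one-way ANOVA (summary)", 0, c(k - 1, N - k), 1))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  new_test_result("one-way ANOVA (summary)", f, c(k - 1, N - k),
                  stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' One-way ANOVA on raw observations
#'
#' Computes per-group summaries and delegates to [anova_oneway_summary()];
#' the two routes agree exactly by construction.
#'
#' @param values numeric observations.
#' @param group grouping vector of the same length.
#' @return A `cdst_test`.
#' @export
anova_oneway <- function(values, group) {
  g <- split(values, group)
  anova_oneway_summary(vapply(g, length, 1L),
                       vapply(g, mean, 1), vapply(g, stats::sd, 1))
}

#' Two-sample t-test from per-group summary statistics
#'
#' Pooled-variance (Student) by default; set `var_equal = FALSE` for the
#' Welch/Satterthwaite form. Two-sided.
#'
#' @param n,mean,sd numeric vectors of length 2 (both n >= 2).
#' @param var_equal pool the variances (default `TRUE`).
#' @return A `cdst_test`.
#' @examples
#' t_test_summary(n = c(935, 510), mean = c(3.2, 5.0), sd = c(3.0, 3.7))
#' @export
t_test_summary <- function(n, mean, sd, var_equal = TRUE) {
  if (length(n) != 2 || length(mean) != 2 || length(sd) != 2)
    stop("exactly 2 groups required", call. = FALSE)
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (var_equal) {
    sp2 <- sum((n - 1) * sd^2) / (sum(n) - 2)
    se <- sqrt(sp2 * sum(1 / n))
    df <- sum(n) - 2
    method <- "two-sample t (pooled)"
  } else {
    v <- sd^2 / n
    se <- sqrt(sum(v))
    df <- sum(v)^2 / sum(v^2 / (n - 1))
    method <- "two-sample t (Welch)"
  }
  t <- if (se == 0) 0 else (mean[1] - mean[2]) / se
  new_test_result(method, t, df, 2 * stats::pt(-abs(t), df))
}

#' Two-sample t-test on raw observations
#'
#' @param values numeric observations.
#' @param group grouping vector with exactly 2 levels.
#' @param var_equal pool the variances (default `TRUE`).
#' @return A `cdst_test`.
#' @export
t_test_two_sample <- function(values, group, var_equal = TRUE) {
  g <- split(values, group)
  if (length(g) != 2) stop("exactly 2 groups required", call. = FALSE)
  t_test_summary(vapply(g, length, 1L), vapply(g, mean, 1),
                 vapply(g, stats::sd, 1), var_equal = var_equal)
}

#' Compare outcomes and costs across response-probability strata
#'
#' Mirrors the published table layout: for each binary outcome a Pearson
#' chi-square test across strata with per-stratum "n (%)" summaries; for
#' each continuous cost variable a one-way ANOVA (3+ strata) or pooled
#' two-sample t-test (2 strata) with per-stratum "mean (SD)" summaries.
#'
#' @param outcomes per-patient outcome rows (see [extract_cohort_events()]).
#' @param costs per-patient cost rows (see [aggregate_cohort_costs()]); may
#'   be `NULL`.
#' @param strata data frame `patient_id`, `stratum`.
#' @param stratum_levels optional ordering of strata (defaults to the order
#'   of first appearance).
#' @return Data frame of class `strata_comparison`: one row per variable
#'   with per-stratum summary strings, the test statistic and p-value.
#' @export
compare_strata <- function(outcomes, costs, strata, stratum_levels = NULL) {
  lev <- stratum_levels %||% intersect(c("high", "intermediate", "low"),
                                       unique(strata$stratum))
  if (length(lev) < 2) {
    warning("fewer than 2 strata; nothing to compare", call. = FALSE)
    return(structure(data.frame(), class = c("strata_comparison", "data.frame")))
  }
  binary_vars <- c(hospitalization = "had_hospitalization",
                   surgery = "had_surgery", ed_visit = "had_ed_visit")
  rows <- list()
  mo <- merge(outcomes, strata[, c("patient_id", "stratum")], by = "patient_id")
  mo$stratum <- factor(mo$stratum, levels = lev)
  for (v in names(binary_vars)) {
    tab <- table(mo$stratum, factor(mo[[binary_vars[[v]]]], levels = c(TRUE, FALSE)))
    res <- tryCatch(suppressWarnings(chi_square_test(unclass(tab))),
                    error = function(e) NULL)
    pct <- vapply(lev, function(s) {
      n <- sum(mo$stratum == s)
      k <- sum(mo$stratum == s & mo[[binary_vars[[v]]]])
      sprintf("%d (%.1f)", k, if (n) 100 * k / n else NA_real_)
    }, "")
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, type = "n (%)",
      t(stats::setNames(pct, lev)),
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      p_value = if (is.null(res)) NA_real_ else res$p_value,
      test = if (is.null(res)) "chi-square (not computable)" else res$method,
      stringsAsFactors = FALSE)
  }
  if (!is.null(costs)) {
    mc <- merge(costs, strata[, c("patient_id", "stratum")], by = "patient_id")
    mc$stratum <- factor(mc$stratum, levels = lev)
    for (v in c(COST_CATEGORIES, "total")) {
      g <- split(mc[[v]], mc$stratum)
      if (any(vapply(g, length, 1L) < 2)) {
        warning(sprintf("stratum with < 2 patients; '%s' skipped", v),
                call. = FALSE)
        next
      }
      res <- if (length(lev) == 2) t_test_two_sample(mc[[v]], mc$stratum)
             else anova_oneway(mc[[v]], mc$stratum)
      ms <- vapply(lev, function(s)
        sprintf("%.1f (%.1f)", mean(g[[s]]), stats::sd(g[[s]])), "")
      rows[[length(rows) + 1]] <- data.frame(
        variable = paste0("cost_", v), type = "mean (SD)",
        t(stats::setNames(ms, lev)),
        statistic = res$statistic, p_value = res$p_value, test = res$method,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("strata_comparison", "data.frame")
  out
}

#' @export
print.strata_comparison <- function(x, ...) {
  if (!nrow(x)) { cat("<strata_comparison> (empty)\n"); return(invisible(x)) }
  y <- as.data.frame(x)
  y$p_value <- formatC(y$p_value, format = "f", digits = 4)
  y$statistic <- formatC(y$statistic, format = "f", digits = 3)
  print(y, row.names = FALSE)
  invisible(x)
}
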