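# independent brute-force Pearson statistic for cross-checking
chisq_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(stat = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

test_that("chi-square matches a direct formula evaluation", {
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rpois(6, 40) + 5, 2, 3)
    r <- suppressWarnings(chi_square_test(m))
    o <- chisq_oracle(m)
    expect_equal(r$statistic, o$stat, tolerance = 1e-12)
    expect_equal(r$p_value, o$p, tolerance = 1e-12)
    expect_equal(r$df, 2)
  }
})

test_that("chi-square is invariant under row and column permutation", {
  m <- matrix(c(41, 138, 52, 100, 19, 8), 3, 2, byrow = TRUE)
  r <- chi_square_test(m)
  expect_equal(chi_square_test(m[c(3, 1, 2), ])$statistic, r$statistic)
  expect_equal(chi_square_test(m[, 2:1])$statistic, r$statistic)
})

test_that("identical row proportions give statistic 0 and p = 1", {
  r <- chi_square_test(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("degenerate margins and small expected counts are flagged", {
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)),
               "zero margin")
  expect_warning(chi_square_test(matrix(c(1, 2, 2, 1), 2, 2)), "below 5")
})

test_that("summary ANOVA agrees with observation-level aov to 1e-9", {
  set.seed(5)
  for (i in 1:10) {
    g <- rep(c("a", "b", "c"), times = c(12, 9, 15))
    y <- rnorm(length(g), mean = c(a = 0, b = 0.5, c = 1)[g])
    r <- anova_oneway(y, g)
    a <- summary(stats::aov(y ~ g))[[1]]
    expect_equal(r$statistic, a[["F value"]][1], tolerance = 1e-9)
    expect_equal(r$p_value, a[["Pr(>F)"]][1], tolerance = 1e-9)
    # summary route from the same data is identical
    gs <- split(y, g)
    rs <- anova_oneway_summary(lengths(gs), sapply(gs, mean), sapply(gs, sd))
    expect_equal(rs$p_value, r$p_value, tolerance = 1e-12)
  }
})

test_that("identical groups give F = 0 and p = 1", {
  r <- anova_oneway_summary(c(10, 10, 10), c(5, 5, 5), c(2, 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(anova_oneway_summary(c(10, 1), c(1, 2), c(1, 1)), "n >= 2")
})

test_that("pooled t matches t.test and t^2 equals the two-group ANOVA F", {
  set.seed(9)
  y <- rnorm(40); g <- rep(c("a", "b"), 20)
  r <- t_test_two_sample(y, g)
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  expect_equal(r$statistic, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-9)
  f <- anova_oneway(y, g)
  expect_equal(r$statistic^2, f$statistic, tolerance = 1e-9)
  expect_equal(r$p_value, f$p_value, tolerance = 1e-9)
  # Welch variant matches t.test default
  rw <- t_test_two_sample(y, g, var_equal = FALSE)
  tw <- stats::t.test(y ~ g)
  expect_equal(rw$statistic, unname(tw$statistic), tolerance = 1e-9)
  expect_equal(rw$p_value, tw$p.value, tolerance = 1e-9)
})

test_that("identical summaries give t = 0, p = 1; group count is enforced", {
  r <- t_test_summary(c(20, 20), c(3, 3), c(1, 1))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(t_test_summary(c(10, 10, 10), c(1, 2, 3), c(1, 1, 1)),
               "exactly 2")
  expect_error(t_test_two_sample(rnorm(9), rep(c("a", "b", "c"), 3)),
               "exactly 2")
})

test_that("strata comparison mirrors the published table layout", {
  set.seed(12)
  n <- 60
  out <- data.frame(patient_id = sprintf("P%02d", 1:n),
                    had_hospitalization = runif(n) < 0.3,
                    had_surgery = runif(n) < 0.2,
                    had_ed_visit = runif(n) < 0.25,
                    n_hospitalizations = 0L, n_surgeries = 0L, n_ed_visits = 0L,
                    followup_days = 365L)
  costs <- data.frame(patient_id = out$patient_id,
                      hospitalization = rlnorm(n, 8, 1), surgery = rlnorm(n, 6, 1),
                      ed_visit = rlnorm(n, 5, 1), office_visit = rlnorm(n, 5, .5),
                      endoscopy_scan = rlnorm(n, 6, .5), lab_test = rlnorm(n, 4, .5))
  costs$total <- rowSums(costs[, -1])
  strata <- data.frame(patient_id = out$patient_id,
                       stratum = rep(c("high", "intermediate", "low"), 20))
  cmp <- suppressWarnings(compare_strata(out, costs, strata))
  expect_s3_class(cmp, "strata_comparison")
  expect_true(all(c("hospitalization", "cost_total") %in% cmp$variable))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1, na.rm = TRUE))
  expect_true(all(cmp$test[cmp$type == "mean (SD)"] == "one-way ANOVA (summary)"))
  # two strata switch the continuous test to the pooled t
  two <- strata; two$stratum <- rep(c("high", "low"), 30)
  cmp2 <- suppressWarnings(compare_strata(out, costs, two))
  expect_true(all(cmp2$test[cmp2$type == "mean (SD)"] == "two-sample t (pooled)"))
})

test_that("a single-stratum input yields an empty comparison with a warning", {
  out <- data.frame(patient_id = c("A", "B"), had_hospitalization = c(TRUE, FALSE),
                    had_surgery = FALSE, had_ed_visit = FALSE,
                    n_hospitalizations = 0L, n_surgeries = 0L, n_ed_visits = 0L,
                    followup_days = 365L)
  strata <- data.frame(patient_id = c("A", "B"), stratum = "high")
  expect_warning(cmp <- compare_strata(out, NULL, strata), "fewer than 2")
  expect_equal(nrow(cmp), 0)
})
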