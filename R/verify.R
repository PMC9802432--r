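# Recompute every derivable number of the published summary tables from the
# printed counts and (n, mean, SD) triplets bundled under inst/extdata, and
# compare with the printed values.
#
# Comparison rules:
#  - percentages: recomputed 100*count/total must round (half away from
#    zero) to the printed 1-decimal value;
#  - chi-square p-values (integer-count inputs, hence exact): recomputed p
#    must round to the printed precision, or fall below a printed "<" bound;
#  - ANOVA / t-test p-values: the printed means and SDs are rounded to one
#    decimal, so the check passes when the printed p is attainable for some
#    configuration of the true summaries inside their +/-0.05 rounding
#    intervals (evaluated at all corner combinations).

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "cdsthru")
  if (!nzchar(path)) stop(sprintf("fixture %s not installed", name), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("printed" %in% names(df)) df$printed <- as.character(df$printed)
  df
}

#' The bundled published summary tables
#'
#' @return List of data frames: `counts` (baseline "n (%)" cells with their
#'   stratum totals), `means` ((n, mean, SD) triplets for age, disease
#'   duration and the annualized cost categories) and `pvalues` (the printed
#'   p-value column, as printed, including "<" bounds). Each row carries its
#'   dataset (`optum_5var`, `optum_3var`, `truven_3var`), variable and
#'   stratum labels.
#' @export
published_tables <- function() {
  list(counts = read_fixture("published_counts.csv"),
       means = read_fixture("published_means.csv"),
       pvalues = read_fixture("published_pvalues.csv"))
}

parse_printed_p <- function(s) {
  s <- trimws(s)
  if (startsWith(s, "<"))
    return(list(bound = as.numeric(sub("<", "0", s)), value = NA_real_,
                digits = NA_integer_))
  list(bound = NA_real_, value = as.numeric(paste0("0", s)),
       digits = nchar(sub("^\\.", "", sub("^0?\\.", ".", s))))
}

p_matches <- function(computed, printed, range = NULL) {
  pp <- parse_printed_p(printed)
  if (!is.na(pp$bound)) return(computed < pp$bound)
  if (abs(round_half_up(computed, pp$digits) - pp$value) < 1e-9) return(TRUE)
  if (is.null(range)) return(FALSE)
  half <- 0.5 * 10^-pp$digits  # printed p itself is rounded
  pp$value >= range[1] - half && pp$value <= range[2] + half
}

# p-value range over all corners of the +/-delta rounding boxes of the
# summary means and SDs (n are exact)
corner_range <- function(n, mean, sd, test_fun, delta = 0.05) {
  k <- length(mean)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 2 * k)))
  ps <- apply(signs, 1, function(s)
    test_fun(n, mean + delta * s[seq_len(k)],
             pmax(0, sd + delta * s[k + seq_len(k)]))$p_value)
  range(ps)
}

#' Recompute the published tables and compare with the printed values
#'
#' Every derivable printed number is recomputed from the bundled printed
#' counts and summary statistics: the "n (%)" percentages, the Pearson
#' chi-square p-values from the counts, the one-way ANOVA (three-stratum)
#' and pooled two-sample t-test (two-stratum) p-values from the (n, mean,
#' SD) triplets, and the low-vs-high total-cost ratio. One row is emitted
#' per check; failures are reported, never raised.
#'
#' @return Data frame of class `cdst_verification` with columns `check`,
#'   `type`, `computed`, `printed`, `pass` and `note`.
#' @examples
#' v <- verify_published()
#' table(v$type, v$pass)
#' @export
verify_published <- function() {
  fx <- published_tables()
  rows <- list()
  add <- function(check, type, computed, printed, pass, note = "")
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, type = type, computed = computed, printed = printed,
      pass = pass, note = note, stringsAsFactors = FALSE)

  # percentage cells
  for (i in seq_len(nrow(fx$counts))) {
    r <- fx$counts[i, ]
    pct <- round_half_up(100 * r$count / r$total, 1)
    add(sprintf("%s:%s:%s:%s:pct", r$dataset, r$variable, r$level, r$stratum),
        "percentage", pct, sprintf("%.1f", r$printed_pct),
        abs(pct - r$printed_pct) < 1e-9)
  }

  # chi-square tests from counts
  combos <- unique(fx$counts[c("dataset", "variable")])
  for (i in seq_len(nrow(combos))) {
    ds <- combos$dataset[i]; v <- combos$variable[i]
    sub <- fx$counts[fx$counts$dataset == ds & fx$counts$variable == v, ]
    strata <- unique(sub$stratum)
    levels <- unique(sub$level)
    m <- matrix(0, length(strata), length(levels) + (length(levels) == 1),
                dimnames = list(strata, NULL))
    for (s in strata) {
      ss <- sub[sub$stratum == s, ]
      if (length(levels) == 1) m[s, ] <- c(ss$count, ss$total[1] - ss$count)
      else m[s, ] <- ss$count[match(levels, ss$level)]
    }
    p <- suppressWarnings(chi_square_test(m))$p_value
    printed <- fx$pvalues$printed[fx$pvalues$dataset == ds &
                                    fx$pvalues$variable == v]
    add(sprintf("%s:%s:chisq", ds, v), "chi_square", p, printed,
        p_matches(p, printed))
  }

  # ANOVA / t-tests from summary triplets
  combos <- unique(fx$means[c("dataset", "variable")])
  for (i in seq_len(nrow(combos))) {
    ds <- combos$dataset[i]; v <- combos$variable[i]
    sub <- fx$means[fx$means$dataset == ds & fx$means$variable == v, ]
    three <- nrow(sub) >= 3
    fun <- if (three) anova_oneway_summary
           else function(n, mean, sd) t_test_summary(n, mean, sd)
    p <- fun(sub$n, sub$mean, sub$sd)$p_value
    rng <- corner_range(sub$n, sub$mean, sub$sd, fun)
    if (!three) {
      # the published analysis does not state pooled vs unequal variances;
      # accept the rounding range of either form
      welch <- function(n, mean, sd) t_test_summary(n, mean, sd, var_equal = FALSE)
      rng <- range(rng, corner_range(sub$n, sub$mean, sub$sd, welch))
    }
    printed <- fx$pvalues$printed[fx$pvalues$dataset == ds &
                                    fx$pvalues$variable == v]
    add(sprintf("%s:%s:%s", ds, v, if (three) "anova" else "ttest"),
        if (three) "anova" else "t_test", p, printed,
        p_matches(p, printed, rng),
        if (!p_matches(p, printed) && p_matches(p, printed, rng))
          "within summary-rounding range" else "")
  }

  # low-vs-high total-cost ratio (printed as "2.5 times lower")
  ct <- fx$means[fx$means$dataset == "optum_5var" &
                   fx$means$variable == "cost_total", ]
  ratio <- round_half_up(ct$mean[ct$stratum == "low"] /
                           ct$mean[ct$stratum == "high"], 1)
  add("optum_5var:cost_total:ratio_low_high", "ratio", ratio, "2.5",
      abs(ratio - 2.5) < 1e-9)

  out <- do.call(rbind, rows)
  class(out) <- c("cdst_verification", "data.frame")
  out
}

#' @export
print.cdst_verification <- function(x, ...) {
  cat(sprintf("<cdst_verification> %d checks, %d pass, %d fail\n",
              nrow(x), sum(x$pass), sum(!x$pass)))
  if (any(!x$pass)) {
    cat("failing checks:\n")
    print(as.data.frame(x[!x$pass, c("check", "computed", "printed")]),
          row.names = FALSE)
  }
  invisible(x)
}
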