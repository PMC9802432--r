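# Cost conversion to 2017 USD and per-patient, per-category annualization.
#
# Annualization rule: if the interval from treatment initiation to the end
# of continuous insurance eligibility exceeds 12 months, the actual
# expenditure is kept; otherwise it is scaled as
# total / (days_between + 1) * 365.25. ">12 months" is tested as
# days_between + 1 > 365.25, consistent with the formula's own denominator.

COST_CATEGORIES <- c("hospitalization", "surgery", "ed_visit", "office_visit",
                     "endoscopy_scan", "lab_test")

#' Consumer-price-index conversion table to 2017 USD
#'
#' @param factors named numeric vector mapping service year to the
#'   multiplicative conversion factor into 2017 USD. 2017 must map to 1.
#'   The default is an identity table (factor 1 for 2013--2019); supply the
#'   CPI-derived factors for real analyses.
#' @return A named numeric vector of class `cpi_table`.
#' @examples
#' cpi_table(c("2015" = 1.033, "2016" = 1.021, "2017" = 1))
#' @export
cpi_table <- function(factors = NULL) {
  if (is.null(factors))
    factors <- stats::setNames(rep(1, 7), as.character(2013:2019))
  if (is.null(names(factors)) || any(!nzchar(names(factors))))
    stop_config("factors", "must be named by year")
  if (any(factors <= 0)) stop_config("factors", "factors must be > 0")
  if (!"2017" %in% names(factors)) factors["2017"] <- 1
  if (abs(factors[["2017"]] - 1) > 1e-12)
    stop_config("factors", "2017 must map to 1.0")
  structure(factors, class = "cpi_table")
}

#' Convert an amount to 2017 USD
#'
#' @param amount paid amount(s) in nominal USD; must be non-negative.
#' @param service_year year(s) of service.
#' @param cpi a [cpi_table()].
#' @return Amount(s) in 2017 USD.
#' @export
to_2017_usd <- function(amount, service_year, cpi = cpi_table()) {
  if (any(amount < 0)) stop("amount must be non-negative", call. = FALSE)
  yr <- as.character(service_year)
  unknown <- setdiff(unique(yr), names(cpi))
  if (length(unknown))
    stop(sprintf("no CPI conversion factor for year %s", unknown[1]),
         call. = FALSE)
  amount * unname(unclass(cpi)[yr])
}

#' Annualize a 12-month expenditure
#'
#' Returns the expenditure unchanged when the eligibility interval exceeds
#' 12 months, otherwise `total / (days_between + 1) * 365.25` where
#' `days_between = eligibility_end - index_date`.
#'
#' @param total expenditure in 2017 USD.
#' @param index_date treatment initiation date.
#' @param eligibility_end end of continuous insurance eligibility.
#' @return Annualized expenditure in 2017 USD per year.
#' @examples
#' annualize_cost(500, as.Date("2017-01-01"), as.Date("2017-06-30"))
#' # 500 / 181 * 365.25 = 1009.0
#' @export
annualize_cost <- function(total, index_date, eligibility_end) {
  if (eligibility_end < index_date)
    stop("eligibility end precedes index date", call. = FALSE)
  days <- as.numeric(eligibility_end - index_date)
  if (days + 1 > 365.25) return(total)
  total / (days + 1) * 365.25
}

#' Aggregate a patient's annualized per-category costs
#'
#' Every in-window claim is assigned to at most one category by
#' [classify_claims()] (precedence surgery > hospitalization > ED >
#' endoscopy/scan > office visit > laboratory; ED claims reclassified to
#' hospitalization/surgery contribute their cost there). Per-category sums
#' are converted to 2017 USD and annualized; the total is the sum of the
#' categories.
#'
#' @param claims the patient's claims.
#' @param index_date the patient's index date.
#' @param eligibility_end end of the continuous enrollment span containing
#'   the index date (see [extract_events()]).
#' @param config an [outcomes_config()].
#' @param cpi a [cpi_table()].
#' @return One-row data frame: one column per category (2017 USD/year),
#'   `total`, `eligibility_days`, and `annualized` (whether scaling was
#'   applied).
#' @export
aggregate_costs <- function(claims, index_date, eligibility_end,
                            config = outcomes_config(), cpi = cpi_table()) {
  cc <- classify_claims(claims, index_date, config)
  cc <- cc[!is.na(cc$category), , drop = FALSE]
  sums <- stats::setNames(numeric(length(COST_CATEGORIES)), COST_CATEGORIES)
  if (nrow(cc)) {
    usd <- to_2017_usd(cc$paid_amount, cc$service_year, cpi)
    agg <- tapply(usd, cc$category, sum)
    sums[names(agg)] <- agg
  }
  ann <- vapply(sums, annualize_cost, numeric(1),
                index_date = index_date, eligibility_end = eligibility_end)
  days <- as.numeric(eligibility_end - index_date)
  out <- as.data.frame(as.list(ann), stringsAsFactors = FALSE)
  out$patient_id <- claims$patient_id[1] %||% NA_character_
  out$total <- sum(ann)
  out$eligibility_days <- as.integer(days)
  out$annualized <- days + 1 <= 365.25
  out[, c("patient_id", COST_CATEGORIES, "total", "eligibility_days",
          "annualized")]
}

#' Aggregate annualized costs for a whole cohort
#'
#' @param dataset a `claims_dataset`.
#' @param outcomes per-patient outcome rows from [extract_cohort_events()]
#'   (supplies index dates and eligibility ends).
#' @param config an [outcomes_config()].
#' @param cpi a [cpi_table()].
#' @return Data frame with one [aggregate_costs()] row per patient.
#' @export
aggregate_cohort_costs <- function(dataset, outcomes,
                                   config = outcomes_config(),
                                   cpi = cpi_table()) {
  claims_by <- split(dataset$claims, dataset$claims$patient_id)
  empty_claims <- dataset$claims[0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(outcomes)), function(i) {
    id <- outcomes$patient_id[i]
    r <- aggregate_costs(claims_by[[id]] %||% empty_claims,
                         outcomes$index_date[i], outcomes$eligibility_end[i],
                         config, cpi)
    r$patient_id <- id
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- aggregate_costs(empty_claims, Sys.Date(), Sys.Date() + 400,
                           config, cpi)[0, , drop = FALSE]
  out
}

#' Per-stratum cost summary (mean and SD per category)
#'
#' @param costs per-patient cost rows from [aggregate_cohort_costs()].
#' @param strata data frame `patient_id`, `stratum`.
#' @return Data frame: stratum, category, n, mean, sd.
#' @export
cost_summary <- function(costs, strata) {
  m <- merge(costs, strata[, c("patient_id", "stratum")], by = "patient_id")
  cats <- c(COST_CATEGORIES, "total")
  grid <- expand.grid(stratum = unique(strata$stratum), category = cats,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- m[m$stratum == grid$stratum[i], grid$category[i]]
    data.frame(stratum = grid$stratum[i], category = grid$category[i],
               n = length(x), mean = mean(x), sd = stats::sd(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
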