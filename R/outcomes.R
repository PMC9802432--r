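# 12-month post-index outcome extraction: hospitalization, surgery and ED
# visits, with the ED reclassification rule (an ED visit followed within the
# linkage window by a hospitalization or surgery is counted as that event,
# surgery taking precedence) shared between event counting and cost
# assignment.

#' Outcome-extraction configuration
#'
#' @param window_days length of the post-index outcome window (claims in
#'   `[index, index + window_days)` are considered).
#' @param ed_linkage_days an ED claim on day d is reclassified if a
#'   hospitalization or surgery claim occurs in `[d, d + ed_linkage_days]`
#'   (default 1: same day or next day).
#' @param code_sets named code lists, see [default_code_sets()].
#' @return A list of class `outcomes_config`.
#' @export
outcomes_config <- function(window_days = 365, ed_linkage_days = 1,
                            code_sets = default_code_sets()) {
  validate_code_sets(code_sets)
  check_pos(window_days, "window_days")
  if (ed_linkage_days < 0) stop_config("ed_linkage_days", "must be >= 0")
  structure(list(window_days = window_days, ed_linkage_days = ed_linkage_days,
                 code_sets = code_sets),
            class = "outcomes_config")
}

# classify every in-window claim into a cost/event category.
# Precedence when a claim matches several code sets:
# surgery > hospitalization > ed_visit > endoscopy_scan > office_visit >
# lab_test; unmatched claims get NA. ED claims linked to a subsequent
# hospitalization/surgery are reclassified (surgery preferred) and flagged.
classify_claims <- function(claims, index_date, config) {
  cs <- config$code_sets
  w <- claims[claims$service_date >= index_date &
                claims$service_date < index_date + config$window_days, ,
              drop = FALSE]
  if (!nrow(w))
    return(cbind(w, data.frame(category = character(0),
                               reclassified = logical(0))))
  is_surg <- w$code_type == "procedure" & w$code %in% cs$surgery_px
  is_hosp <- w$code_type == "diagnosis" & w$code %in% cs$cd_dx &
    w$setting == "inpatient"
  is_ed <- w$code_type == "revenue" & w$code %in% cs$ed_rev
  is_endo <- w$code_type == "procedure" & w$code %in% cs$endoscopy_px
  is_office <- w$code_type == "procedure" & w$code %in% cs$office_cpt
  is_lab <- w$code_type == "revenue" & w$code %in% cs$lab_rev

  category <- rep(NA_character_, nrow(w))
  category[is_lab] <- "lab_test"
  category[is_office] <- "office_visit"
  category[is_endo] <- "endoscopy_scan"
  category[is_ed] <- "ed_visit"
  category[is_hosp] <- "hospitalization"
  category[is_surg] <- "surgery"

  reclassified <- rep(FALSE, nrow(w))
  ed_idx <- which(category == "ed_visit")
  if (length(ed_idx)) {
    hosp_dates <- w$service_date[which(category == "hospitalization")]
    surg_dates <- w$service_date[which(category == "surgery")]
    for (i in ed_idx) {
      d <- w$service_date[i]
      in_link <- function(dates) any(dates >= d & dates <= d + config$ed_linkage_days)
      if (in_link(surg_dates)) {
        category[i] <- "surgery"; reclassified[i] <- TRUE
      } else if (in_link(hosp_dates)) {
        category[i] <- "hospitalization"; reclassified[i] <- TRUE
      }
    }
  }
  w$category <- category
  w$reclassified <- reclassified
  w
}

# collapse claim dates into episodes: dates <= 1 day apart belong to the
# same episode (claims are line items; overlapping inpatient lines must not
# be double counted)
count_episodes <- function(dates) {
  dates <- dates[!is.na(dates)]
  if (!length(dates)) return(0L)
  d <- sort(unique(dates))
  if (length(d) == 1) return(1L)
  sum(c(TRUE, diff(d) > 1))
}

#' Extract 12-month outcomes for one patient
#'
#' @param claims the patient's claims.
#' @param enrollment the patient's (merged) enrollment spans.
#' @param index_date the patient's index date.
#' @param config an [outcomes_config()].
#' @return One-row data frame: event flags and counts for hospitalization,
#'   surgery and ED visits, the number of reclassified ED claims, and
#'   `followup_days` (days of enrollment inside the outcome window).
#' @examples
#' cl <- data.frame(patient_id = "A",
#'                  service_date = as.Date("2016-01-11"),
#'                  code_type = "revenue", code = "0450", setting = "ED",
#'                  paid_amount = 800, service_year = 2016)
#' en <- data.frame(patient_id = "A", start_date = as.Date("2015-01-01"),
#'                  end_date = as.Date("2017-12-31"))
#' extract_events(cl, en, as.Date("2016-01-01"), outcomes_config())
#' @export
extract_events <- function(claims, enrollment, index_date, config = outcomes_config()) {
  if (is.null(enrollment) || !nrow(enrollment))
    stop("patient absent from enrollment table", call. = FALSE)
  spans <- merge_spans(enrollment, 0)
  cover <- spans[spans$start_date <= index_date & spans$end_date >= index_date, ,
                 drop = FALSE]
  if (!nrow(cover))
    stop("index date outside all enrollment spans", call. = FALSE)
  elig_end <- max(cover$end_date)

  in_enroll <- rep(FALSE, nrow(claims))
  for (j in seq_len(nrow(spans)))
    in_enroll <- in_enroll | (claims$service_date >= spans$start_date[j] &
                                claims$service_date <= spans$end_date[j])
  if (any(!in_enroll)) {
    warning(sprintf("%d claim(s) outside enrollment ignored", sum(!in_enroll)),
            call. = FALSE)
    claims <- claims[in_enroll, , drop = FALSE]
  }

  cc <- classify_claims(claims, index_date, config)
  n_hosp <- count_episodes(cc$service_date[cc$category %in% "hospitalization"])
  n_surg <- count_episodes(cc$service_date[cc$category %in% "surgery"])
  n_ed <- count_episodes(cc$service_date[cc$category %in% "ed_visit"])
  followup <- min(as.integer(elig_end - index_date) + 1L, config$window_days)

  data.frame(patient_id = claims$patient_id[1] %||% NA_character_,
             index_date = index_date,
             had_hospitalization = n_hosp >= 1, had_surgery = n_surg >= 1,
             had_ed_visit = n_ed >= 1,
             n_hospitalizations = n_hosp, n_surgeries = n_surg,
             n_ed_visits = n_ed,
             n_reclassified_ed = sum(cc$reclassified),
             followup_days = followup,
             eligibility_end = elig_end,
             stringsAsFactors = FALSE)
}

#' Extract outcomes for a whole cohort
#'
#' @param dataset a `claims_dataset`.
#' @param cohort a `cdst_cohort` (or its `features` data frame with
#'   `patient_id` and `index_date`).
#' @param config an [outcomes_config()].
#' @return Data frame with one [extract_events()] row per cohort patient.
#' @export
extract_cohort_events <- function(dataset, cohort, config = outcomes_config()) {
  features <- if (inherits(cohort, "cdst_cohort")) cohort$features else cohort
  claims_by <- split(dataset$claims, dataset$claims$patient_id)
  enroll_by <- split(dataset$enrollment, dataset$enrollment$patient_id)
  empty_claims <- dataset$claims[0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(features)), function(i) {
    id <- features$patient_id[i]
    r <- extract_events(claims_by[[id]] %||% empty_claims, enroll_by[[id]],
                        features$index_date[i], config)
    r$patient_id <- id
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- extract_events(
    empty_claims,
    data.frame(patient_id = "x", start_date = as.Date("2000-01-01"),
               end_date = as.Date("2000-01-02")),
    as.Date("2000-01-01"), config)[0, , drop = FALSE]
  out
}

#' Per-stratum event proportions and incidence rates
#'
#' @param outcomes outcome rows from [extract_cohort_events()].
#' @param strata data frame `patient_id`, `stratum` (e.g. the `scores`
#'   element of [score_cohort()], or a simulation truth table).
#' @return Data frame with one row per stratum and event type: numerator
#'   (patients with at least one event), denominator, proportion (%), and
#'   incidence rate per person-year of follow-up. Strata with no patients
#'   yield `NA` proportions.
#' @export
event_proportions <- function(outcomes, strata) {
  m <- merge(outcomes, strata[, c("patient_id", "stratum")], by = "patient_id")
  if (nrow(m) < nrow(outcomes))
    warning("some outcome rows have no stratum and were dropped", call. = FALSE)
  events <- c(hospitalization = "had_hospitalization", surgery = "had_surgery",
              ed_visit = "had_ed_visit")
  counts <- c(hospitalization = "n_hospitalizations", surgery = "n_surgeries",
              ed_visit = "n_ed_visits")
  out <- expand.grid(stratum = unique(strata$stratum), event = names(events),
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    g <- m[m$stratum == out$stratum[i], , drop = FALSE]
    n <- nrow(g)
    num <- sum(g[[events[[out$event[i]]]]])
    py <- sum(g$followup_days) / 365.25
    data.frame(stratum = out$stratum[i], event = out$event[i],
               n_events = num, n_patients = n,
               proportion_pct = if (n) round_half_up(100 * num / n, 1) else NA_real_,
               incidence_per_py = if (py > 0)
                 sum(g[[counts[[out$event[i]]]]]) / py else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
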