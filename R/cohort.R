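# Cohort construction: index-date determination, eligibility screening and
# baseline-feature derivation from a claims dataset.

#' Cohort-construction configuration
#'
#' Encodes the eligibility rules: adults (>= `min_age_years` at index) with
#' two separate Crohn's disease diagnoses at least `dx_separation_days`
#' apart, both after `dx_floor` and before the index date, and one
#' continuous enrollment span covering at least `pre_enroll_days` before and
#' `post_enroll_days` after the index date. "6 months" of continuous
#' enrollment is implemented as 183 days. Baseline laboratory values are the
#' most recent result within `baseline_lab_lookback_days` before index.
#'
#' @param index_drug codes whose first claim in `index_window` defines the
#'   index date (default vedolizumab; pass the anti-TNF list for the
#'   comparator cohort).
#' @param index_window pair of dates bounding eligible index dates.
#' @param min_age_years minimum age at index (years).
#' @param dx_separation_days minimum days between the two qualifying CD
#'   diagnoses (inclusive: exactly 30 days apart qualifies).
#' @param dx_floor earliest admissible date for the first qualifying
#'   diagnosis.
#' @param pre_enroll_days,post_enroll_days continuous-enrollment requirement
#'   around the index date, in days.
#' @param baseline_lab_lookback_days lookback window for baseline albumin
#'   and CRP.
#' @param enrollment_gap_days spans separated by at most this many days are
#'   merged when assessing continuity (0 = strictly continuous).
#' @param code_sets named code lists, see [default_code_sets()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(index_drug = default_code_sets()$vedolizumab,
                          index_window = c("2014-05-01", "2018-03-31"),
                          min_age_years = 18,
                          dx_separation_days = 30,
                          dx_floor = "2000-01-01",
                          pre_enroll_days = 183,
                          post_enroll_days = 183,
                          baseline_lab_lookback_days = 90,
                          enrollment_gap_days = 0,
                          code_sets = default_code_sets()) {
  validate_code_sets(code_sets)
  if (!length(index_drug)) stop_config("index_drug", "code set must be non-empty")
  for (f in c("min_age_years", "dx_separation_days", "pre_enroll_days",
              "post_enroll_days", "baseline_lab_lookback_days"))
    check_pos(get(f), f)
  if (enrollment_gap_days < 0) stop_config("enrollment_gap_days", "must be >= 0")
  structure(list(index_drug = index_drug, index_window = as_date(index_window),
                 min_age_years = min_age_years,
                 dx_separation_days = dx_separation_days,
                 dx_floor = as_date(dx_floor),
                 pre_enroll_days = pre_enroll_days,
                 post_enroll_days = post_enroll_days,
                 baseline_lab_lookback_days = baseline_lab_lookback_days,
                 enrollment_gap_days = enrollment_gap_days,
                 code_sets = code_sets),
            class = "cohort_config")
}

#' Determine a patient's index date
#'
#' The index date is the earliest claim for an index-drug code falling
#' inside the index window.
#'
#' @param claims the patient's claims (data frame with `service_date`,
#'   `code`).
#' @param config a [cohort_config()].
#' @return A `Date`, or `NA` if the patient has no qualifying claim.
#' @export
find_index_date <- function(claims, config) {
  d <- claims$service_date[claims$code %in% config$index_drug &
                             claims$service_date >= config$index_window[1] &
                             claims$service_date <= config$index_window[2]]
  if (!length(d)) return(as.Date(NA))
  min(d)
}

# merge enrollment spans whose gap is <= gap_days; returns ordered spans
merge_spans <- function(enrollment, gap_days = 0) {
  if (!nrow(enrollment)) return(enrollment)
  en <- enrollment[order(enrollment$start_date), , drop = FALSE]
  start <- en$start_date[1]; end <- en$end_date[1]
  out_s <- out_e <- list()
  k <- 0L
  for (i in seq_len(nrow(en))[-1]) {
    if (as.integer(en$start_date[i] - end) <= gap_days + 1L) {
      end <- max(end, en$end_date[i])
    } else {
      k <- k + 1L; out_s[[k]] <- start; out_e[[k]] <- end
      start <- en$start_date[i]; end <- en$end_date[i]
    }
  }
  k <- k + 1L; out_s[[k]] <- start; out_e[[k]] <- end
  data.frame(patient_id = en$patient_id[1],
             start_date = do.call(c, out_s), end_date = do.call(c, out_e))
}

#' Check a patient's eligibility at a candidate index date
#'
#' Eligibility requires (a) age at index of at least `min_age_years`; (b)
#' two CD-diagnosis claims before the index date, at least
#' `dx_separation_days` apart, the earlier one on or after `dx_floor`; and
#' (c) one continuous enrollment span covering the full pre/post window
#' around the index date.
#'
#' @param claims the patient's claims.
#' @param enrollment the patient's enrollment spans.
#' @param birth_year the patient's birth year.
#' @param index_date candidate index date.
#' @param config a [cohort_config()].
#' @return List with `eligible` (logical) and `failed` (character vector of
#'   failed criteria among `"age"`, `"dx_separation"`, `"pre_enrollment"`,
#'   `"post_enrollment"`).
#' @export
check_eligibility <- function(claims, enrollment, birth_year, index_date,
                              config) {
  if (is.na(index_date)) stop("index_date must be defined", call. = FALSE)
  if (!nrow(enrollment))
    stop("patient absent from enrollment table", call. = FALSE)
  failed <- character()

  age <- as.integer(format(index_date, "%Y")) - birth_year
  if (age < config$min_age_years) failed <- c(failed, "age")

  cs <- config$code_sets
  dx <- sort(unique(claims$service_date[claims$code_type == "diagnosis" &
                                          claims$code %in% cs$cd_dx &
                                          claims$service_date < index_date &
                                          claims$service_date >= config$dx_floor]))
  ok_dx <- length(dx) >= 2 &&
    as.integer(dx[length(dx)] - dx[1]) >= config$dx_separation_days
  if (!ok_dx) failed <- c(failed, "dx_separation")

  spans <- merge_spans(enrollment, config$enrollment_gap_days)
  pre_ok <- any(spans$start_date <= index_date - config$pre_enroll_days &
                  spans$end_date >= index_date)
  post_ok <- any(spans$start_date <= index_date &
                   spans$end_date >= index_date + config$post_enroll_days)
  both_ok <- any(spans$start_date <= index_date - config$pre_enroll_days &
                   spans$end_date >= index_date + config$post_enroll_days)
  if (!pre_ok) failed <- c(failed, "pre_enrollment")
  if (!post_ok || (pre_ok && !both_ok)) failed <- c(failed, "post_enrollment")

  list(eligible = length(failed) == 0, failed = failed)
}

#' Derive baseline features for one eligible patient
#'
#' Risk-factor flags (`prior_bowel_surgery`, `prior_fistulizing_disease`,
#' `prior_anti_tnf_exposure`) use the full claims history strictly before
#' the index date; `prior_year_*` flags use the 365 days before index;
#' baseline labs are the most recent result within the lookback window
#' (same-day duplicates averaged); concomitant medications are any claim in
#' the 365 days from index; disease duration runs from the earliest CD
#' diagnosis.
#'
#' @param claims,labs,birth_year,sex the patient's data.
#' @param index_date the patient's index date.
#' @param config a [cohort_config()].
#' @return One-row data frame of baseline features.
#' @export
derive_baseline_features <- function(claims, labs, birth_year, sex, index_date,
                                     config) {
  cs <- config$code_sets
  pre <- claims[claims$service_date < index_date, , drop = FALSE]
  year_pre <- pre[pre$service_date >= index_date - 365, , drop = FALSE]
  post_year <- claims[claims$service_date >= index_date &
                        claims$service_date < index_date + 365, , drop = FALSE]

  has <- function(df, codes, type = NULL) {
    m <- df$code %in% codes
    if (!is.null(type)) m <- m & df$code_type == type
    any(m)
  }
  tnf_agents <- unique(pre$code[pre$code %in% cs$anti_tnf])

  lab_at <- function(analyte) {
    lb <- labs[labs$analyte == analyte &
                 labs$collection_date < index_date &
                 labs$collection_date >= index_date - config$baseline_lab_lookback_days, ,
               drop = FALSE]
    if (!nrow(lb)) return(NA_real_)
    last <- max(lb$collection_date)
    mean(lb$value[lb$collection_date == last])  # same-day duplicates: mean
  }

  cd_dates <- pre$service_date[pre$code_type == "diagnosis" & pre$code %in% cs$cd_dx]
  inpatient_cd <- year_pre$code %in% cs$cd_dx &
    year_pre$code_type == "diagnosis" & year_pre$setting == "inpatient"

  data.frame(
    patient_id = claims$patient_id[1] %||% NA_character_,
    index_date = index_date,
    age_at_index = as.integer(format(index_date, "%Y")) - birth_year,
    sex = sex,
    prior_bowel_surgery = has(pre, cs$surgery_px, "procedure"),
    prior_fistulizing_disease = has(pre, cs$fistula_dx, "diagnosis"),
    prior_anti_tnf_exposure = length(tnf_agents) >= 1,
    n_anti_tnf_agents = length(tnf_agents),
    baseline_albumin = lab_at("albumin"),
    baseline_crp = lab_at("crp"),
    prior_year_hospitalization = any(inpatient_cd),
    prior_year_surgery = has(year_pre, cs$surgery_px, "procedure"),
    prior_year_fistula = has(year_pre, cs$fistula_dx, "diagnosis"),
    prior_year_stricture = has(year_pre, cs$stricture_dx, "diagnosis"),
    concomitant_imm = has(post_year, cs$immunomodulator, "drug"),
    concomitant_cs = has(post_year, cs$corticosteroid, "drug"),
    disease_duration_years =
      if (length(cd_dates)) as.numeric(index_date - min(cd_dates)) / 365.25
      else NA_real_,
    stringsAsFactors = FALSE)
}

#' Build the eligible cohort from a claims dataset
#'
#' Applies, in order: index-drug claim present in the window; age; diagnosis
#' separation; pre-index enrollment; post-index enrollment. Each patient is
#' counted against the first criterion they fail.
#'
#' @param dataset a `claims_dataset`.
#' @param config a [cohort_config()].
#' @return List of class `cdst_cohort`: `features` (one row of baseline
#'   features per eligible patient) and `attrition` (data frame of
#'   exclusion counts per criterion, in application order).
#' @examples
#' sim <- simulate_claims(claims_sim_config(n_patients = 30, seed = 1))
#' coh <- build_cohort(sim$dataset, cohort_config())
#' coh$attrition
#' @export
build_cohort <- function(dataset, config = cohort_config()) {
  stopifnot(inherits(dataset, "claims_dataset"))
  pts <- dataset$patients
  crit <- c("no_index_claim", "age", "dx_separation", "pre_enrollment",
            "post_enrollment")
  counts <- stats::setNames(integer(length(crit)), crit)
  rows <- vector("list", nrow(pts))

  claims_by <- split(dataset$claims, dataset$claims$patient_id)
  labs_by <- split(dataset$labs, dataset$labs$patient_id)
  enroll_by <- split(dataset$enrollment, dataset$enrollment$patient_id)
  empty_labs <- dataset$labs[0, , drop = FALSE]
  empty_claims <- dataset$claims[0, , drop = FALSE]

  for (i in seq_len(nrow(pts))) {
    id <- pts$patient_id[i]
    cl <- claims_by[[id]] %||% empty_claims
    idx <- find_index_date(cl, config)
    if (is.na(idx)) {
      counts["no_index_claim"] <- counts["no_index_claim"] + 1L
      next
    }
    en <- enroll_by[[id]]
    if (is.null(en))
      stop(sprintf("patient %s absent from enrollment table", id), call. = FALSE)
    el <- check_eligibility(cl, en, pts$birth_year[i], idx, config)
    if (!el$eligible) {
      first <- el$failed[1]
      counts[first] <- counts[first] + 1L
      next
    }
    rows[[i]] <- derive_baseline_features(cl, labs_by[[id]] %||% empty_labs,
                                          pts$birth_year[i], pts$sex[i], idx,
                                          config)
    rows[[i]]$patient_id <- id
  }
  features <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(features))
    features <- derive_empty_features()
  structure(list(features = features,
                 attrition = data.frame(criterion = crit,
                                        excluded = as.integer(counts),
                                        stringsAsFactors = FALSE),
                 config = config),
            class = "cdst_cohort")
}

derive_empty_features <- function() {
  data.frame(patient_id = character(), index_date = as.Date(character()),
             age_at_index = integer(), sex = character(),
             prior_bowel_surgery = logical(), prior_fistulizing_disease = logical(),
             prior_anti_tnf_exposure = logical(), n_anti_tnf_agents = integer(),
             baseline_albumin = numeric(), baseline_crp = numeric(),
             prior_year_hospitalization = logical(), prior_year_surgery = logical(),
             prior_year_fistula = logical(), prior_year_stricture = logical(),
             concomitant_imm = logical(), concomitant_cs = logical(),
             disease_duration_years = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.cdst_cohort <- function(x, ...) {
  cat(sprintf("<cdst_cohort> %d eligible patients\n", nrow(x$features)))
  excl <- x$attrition[x$attrition$excluded > 0, ]
  if (nrow(excl))
    cat("  excluded:",
        paste(sprintf("%s:%d", excl$criterion, excl$excluded), collapse = ", "),
        "\n")
  invisible(x)
}
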