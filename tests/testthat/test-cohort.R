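cfg <- cohort_config()

test_that("index date is the earliest index-drug claim inside the window", {
  cl <- rbind(claim_row("P1", "2015-06-01", "drug", "VEDO", "outpatient"),
              claim_row("P1", "2015-03-01", "drug", "VEDO", "outpatient"))
  expect_equal(find_index_date(cl, cfg), as.Date("2015-03-01"))
  # claim the day before the window opens does not qualify
  expect_true(is.na(find_index_date(
    claim_row("P1", "2014-04-30", "drug", "VEDO", "outpatient"), cfg)))
  expect_true(is.na(find_index_date(
    claim_row("P1", "2015-03-01", "diagnosis", "DX_CD", "outpatient"), cfg)))
})

test_that("diagnosis separation is inclusive at exactly 30 days", {
  en <- data.frame(patient_id = "P1", start_date = as.Date("2013-01-01"),
                   end_date = as.Date("2019-12-31"))
  idx <- as.Date("2016-01-01")
  dx <- function(gap) rbind(
    claim_row("P1", "2014-01-01", "diagnosis", "DX_CD", "outpatient"),
    claim_row("P1", as.character(as.Date("2014-01-01") + gap), "diagnosis",
              "DX_CD", "outpatient"))
  expect_true(check_eligibility(dx(30), en, 1975L, idx, cfg)$eligible)
  r29 <- check_eligibility(dx(29), en, 1975L, idx, cfg)
  expect_false(r29$eligible)
  expect_equal(r29$failed, "dx_separation")
})

test_that("short post-index enrollment and minor age are flagged by criterion", {
  cl <- rbind(claim_row("P1", "2014-01-01", "diagnosis", "DX_CD", "outpatient"),
              claim_row("P1", "2014-06-01", "diagnosis", "DX_CD", "outpatient"))
  idx <- as.Date("2016-01-01")
  en_short <- data.frame(patient_id = "P1", start_date = as.Date("2013-01-01"),
                         end_date = idx + 100)
  r <- check_eligibility(cl, en_short, 1975L, idx, cfg)
  expect_false(r$eligible)
  expect_equal(r$failed, "post_enrollment")
  en <- data.frame(patient_id = "P1", start_date = as.Date("2013-01-01"),
                   end_date = as.Date("2019-12-31"))
  r <- check_eligibility(cl, en, 2000L, idx, cfg)
  expect_equal(r$failed, "age")
  expect_error(check_eligibility(cl, en[0, ], 1975L, idx, cfg), "enrollment")
})

test_that("baseline features: lifetime flags, latest labs, prior-year windows", {
  idx <- as.Date("2016-01-01")
  cl <- rbind(
    claim_row("P1", "2013-01-01", "procedure", "PX_SURG", "inpatient"),  # 3y pre
    claim_row("P1", "2010-05-01", "diagnosis", "DX_CD", "outpatient"),
    claim_row("P1", "2015-09-01", "diagnosis", "DX_CD", "inpatient"),    # prior-year hosp
    claim_row("P1", "2015-06-01", "drug", "TNF_ADA", "pharmacy"),
    claim_row("P1", "2014-06-01", "drug", "TNF_IFX", "pharmacy"),
    claim_row("P1", "2016-03-01", "drug", "DRUG_CS", "pharmacy"))        # concomitant
  labs <- rbind(lab_row("P1", "2015-11-01", "albumin", 30),
                lab_row("P1", "2015-12-10", "albumin", 42))
  f <- derive_baseline_features(cl, labs, 1980L, "F", idx, cfg)
  expect_true(f$prior_bowel_surgery)
  expect_false(f$prior_fistulizing_disease)
  expect_true(f$prior_anti_tnf_exposure)
  expect_equal(f$n_anti_tnf_agents, 2)
  expect_equal(f$baseline_albumin, 42)          # most recent wins
  expect_true(is.na(f$baseline_crp))            # no CRP in lookback
  expect_true(f$prior_year_hospitalization)
  expect_false(f$prior_year_surgery)            # surgery older than a year
  expect_true(f$concomitant_cs)
  expect_false(f$concomitant_imm)
  expect_equal(f$disease_duration_years,
               as.numeric(idx - as.Date("2010-05-01")) / 365.25)
})

test_that("same-day duplicate labs are averaged, never an error", {
  idx <- as.Date("2016-01-01")
  labs <- rbind(lab_row("P1", "2015-12-10", "crp", 2),
                lab_row("P1", "2015-12-10", "crp", 4))
  f <- derive_baseline_features(claim_row("P1", "2015-01-01", "diagnosis",
                                          "DX_CD", "outpatient"),
                                labs, 1980L, "F", idx, cfg)
  expect_equal(f$baseline_crp, 3)
})

test_that("cohort build applies criteria in order and logs attrition", {
  ds <- eligible_patient("P1")
  # P2: under 18 at index
  p2 <- eligible_patient("P2")
  p2$patients$birth_year <- 2000L
  # P3: diagnoses 29 days apart only
  p3 <- eligible_patient("P3")
  p3$claims$service_date[p3$claims$code == "DX_CD"] <-
    as.Date(c("2014-01-10", "2014-02-08"))
  all <- mk_dataset(rbind(ds$patients, p2$patients, p3$patients),
                    rbind(ds$enrollment, p2$enrollment, p3$enrollment),
                    rbind(ds$claims, p2$claims, p3$claims))
  coh <- build_cohort(all, cfg)
  expect_equal(coh$features$patient_id, "P1")
  att <- setNames(coh$attrition$excluded, coh$attrition$criterion)
  expect_equal(att[["age"]], 1L)
  expect_equal(att[["dx_separation"]], 1L)
})

test_that("empty dataset gives empty cohort and zero attrition", {
  coh <- build_cohort(simulate_claims(claims_sim_config(n_patients = 0))$dataset, cfg)
  expect_equal(nrow(coh$features), 0)
  expect_true(all(coh$attrition$excluded == 0))
})

test_that("eligibility is monotone and the build is row-order independent", {
  ds <- eligible_patient("P1")
  coh1 <- build_cohort(ds, cfg)
  expect_equal(nrow(coh1$features), 1)
  # adding CD diagnoses or extending enrollment never removes eligibility
  more <- ds
  more$claims <- rbind(more$claims,
                       claim_row("P1", "2015-05-05", "diagnosis", "DX_CD",
                                 "outpatient"))
  more$enrollment$end_date <- more$enrollment$end_date + 500
  expect_equal(nrow(build_cohort(more, cfg)$features), 1)
  # shuffling claim rows changes nothing
  set.seed(1)
  shuf <- ds
  shuf$claims <- shuf$claims[sample(nrow(shuf$claims)), ]
  coh2 <- build_cohort(shuf, cfg)
  rownames(coh1$features) <- rownames(coh2$features) <- NULL
  expect_equal(coh2$features, coh1$features)
})
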