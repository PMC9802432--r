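ocfg <- outcomes_config()
en1 <- data.frame(patient_id = "P1", start_date = as.Date("2015-01-01"),
                  end_date = as.Date("2017-12-31"))
idx <- as.Date("2016-01-01")

test_that("an ED claim adjacent to a hospitalization is counted as hospitalization", {
  cl <- rbind(claim_row("P1", "2016-01-11", "revenue", "0450", "ED", 800),
              claim_row("P1", "2016-01-11", "diagnosis", "DX_CD", "inpatient", 9000))
  r <- extract_events(cl, en1, idx, ocfg)
  expect_equal(r$n_hospitalizations, 1)
  expect_equal(r$n_ed_visits, 0)
  expect_equal(r$n_reclassified_ed, 1)
  # next-day hospitalization also captures the ED claim
  cl2 <- rbind(claim_row("P1", "2016-01-11", "revenue", "0450", "ED", 800),
               claim_row("P1", "2016-01-12", "diagnosis", "DX_CD", "inpatient", 9000))
  expect_equal(extract_events(cl2, en1, idx, ocfg)$n_ed_visits, 0)
})

test_that("surgery takes precedence over hospitalization for reclassified ED claims", {
  cl <- rbind(claim_row("P1", "2016-01-11", "revenue", "0450", "ED", 800),
              claim_row("P1", "2016-01-12", "diagnosis", "DX_CD", "inpatient", 9000),
              claim_row("P1", "2016-01-12", "procedure", "PX_SURG", "inpatient", 15000))
  cc <- classify_claims(cl, idx, ocfg)
  expect_equal(cc$category[cc$code == "0450"], "surgery")
})

test_that("a lone ED claim is an ED visit; no claims give zero counts", {
  r <- extract_events(claim_row("P1", "2016-01-11", "revenue", "0450", "ED", 800),
                      en1, idx, ocfg)
  expect_equal(r$n_ed_visits, 1)
  expect_true(r$had_ed_visit)
  r0 <- extract_events(claim_row("P1", "2015-06-01", "diagnosis", "DX_CD",
                                 "outpatient")[0, ], en1, idx, ocfg)
  expect_equal(r0$n_hospitalizations + r0$n_surgeries + r0$n_ed_visits, 0)
})

test_that("same-stay inpatient line items are merged into one episode", {
  cl <- rbind(claim_row("P1", "2016-02-01", "diagnosis", "DX_CD", "inpatient", 5000),
              claim_row("P1", "2016-02-01", "diagnosis", "DX_CD", "inpatient", 2000),
              claim_row("P1", "2016-02-02", "diagnosis", "DX_CD", "inpatient", 1000),
              claim_row("P1", "2016-05-01", "diagnosis", "DX_CD", "inpatient", 4000))
  r <- extract_events(cl, en1, idx, ocfg)
  expect_equal(r$n_hospitalizations, 2)
})

test_that("events outside the 12-month window or enrollment are not counted", {
  cl <- rbind(claim_row("P1", "2017-01-02", "diagnosis", "DX_CD", "inpatient", 5000),
              claim_row("P1", "2014-06-01", "revenue", "0450", "ED", 800))
  expect_warning(r <- extract_events(cl, en1, idx, ocfg), "outside enrollment")
  expect_equal(r$n_hospitalizations, 0)
  expect_equal(r$n_ed_visits, 0)
})

test_that("reclassification conserves ED claims", {
  set.seed(7)
  for (i in 1:25) {
    n_ed <- sample(0:3, 1)
    days <- sample(5:360, n_ed + 2)
    cl <- rbind(
      if (n_ed) do.call(rbind, lapply(seq_len(n_ed), function(j)
        claim_row("P1", as.character(idx + days[j]), "revenue", "0450", "ED", 500))),
      claim_row("P1", as.character(idx + days[n_ed + 1]), "diagnosis", "DX_CD",
                "inpatient", 4000),
      claim_row("P1", as.character(idx + days[n_ed + 2]), "procedure", "PX_SURG",
                "inpatient", 8000))
    cc <- classify_claims(cl, idx, ocfg)
    n_before <- n_ed
    n_after <- sum(cc$category == "ed_visit")
    expect_equal(n_before, n_after + sum(cc$reclassified))
  }
})

test_that("event proportions and incidence rates follow the definitions", {
  out <- data.frame(patient_id = c("A", "B", "C"),
                    had_hospitalization = c(TRUE, FALSE, TRUE),
                    had_surgery = FALSE, had_ed_visit = FALSE,
                    n_hospitalizations = c(2L, 0L, 1L), n_surgeries = 0L,
                    n_ed_visits = 0L, followup_days = 365L)
  strata <- data.frame(patient_id = c("A", "B", "C"),
                       stratum = c("high", "high", "low"))
  p <- event_proportions(out, strata)
  h <- p[p$stratum == "high" & p$event == "hospitalization", ]
  expect_equal(h$proportion_pct, 50.0)
  expect_equal(h$incidence_per_py, 2 / (2 * 365 / 365.25))
  l <- p[p$stratum == "low" & p$event == "hospitalization", ]
  expect_equal(l$proportion_pct, 100.0)
  # single patient, 2 events, full year: rate ~2 per person-year
  expect_equal(l$incidence_per_py, 1 / (365 / 365.25))
})

test_that("proportions recompute printed percentage conventions", {
  out <- data.frame(patient_id = sprintf("P%03d", 1:179),
                    had_hospitalization = c(rep(TRUE, 41), rep(FALSE, 138)),
                    had_surgery = FALSE, had_ed_visit = FALSE,
                    n_hospitalizations = c(rep(1L, 41), rep(0L, 138)),
                    n_surgeries = 0L, n_ed_visits = 0L, followup_days = 365L)
  strata <- data.frame(patient_id = out$patient_id, stratum = "high")
  p <- event_proportions(out, strata)
  expect_equal(p$proportion_pct[p$event == "hospitalization"], 22.9)
})

test_that("an empty stratum yields missing proportions", {
  out <- data.frame(patient_id = "A", had_hospitalization = TRUE,
                    had_surgery = FALSE, had_ed_visit = FALSE,
                    n_hospitalizations = 1L, n_surgeries = 0L, n_ed_visits = 0L,
                    followup_days = 365L)
  strata <- data.frame(patient_id = c("A", "Z"), stratum = c("high", "low"))
  p <- suppressWarnings(event_proportions(out, strata))
  expect_true(is.na(p$proportion_pct[p$stratum == "low" &
                                       p$event == "hospitalization"]))
})
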