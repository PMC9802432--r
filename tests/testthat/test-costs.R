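ocfg <- outcomes_config()
idx <- as.Date("2017-01-01")

test_that("CPI conversion multiplies by the year factor and validates input", {
  cpi <- cpi_table(c("2015" = 1.05, "2016" = 1.02, "2017" = 1))
  expect_equal(to_2017_usd(100, 2017, cpi), 100)
  expect_equal(to_2017_usd(100, 2015, cpi), 105)
  expect_error(to_2017_usd(-1, 2017, cpi), "non-negative")
  expect_error(to_2017_usd(100, 1999, cpi), "1999")
  expect_error(cpi_table(c("2017" = 1.1)), "2017")
  expect_error(cpi_table(c("2016" = -1, "2017" = 1)), "> 0")
})

test_that("annualization follows the printed formula and its 12-month cutoff", {
  # >12-month eligibility: actual expenditure unchanged
  expect_equal(annualize_cost(5000, idx, idx + 400), 5000)
  # 180 days between, +1 = 181 in the denominator
  expect_equal(annualize_cost(500, idx, as.Date("2017-06-30")),
               500 / 181 * 365.25)
  expect_equal(round(annualize_cost(500, idx, as.Date("2017-06-30")), 1), 1009.0)
  expect_equal(annualize_cost(0, idx, idx + 10), 0)
  expect_error(annualize_cost(100, idx, idx - 1), "precedes")
  # boundary: days_between + 1 > 365.25 switches scaling off
  expect_equal(annualize_cost(1000, idx, idx + 365), 1000)          # 366 days
  expect_equal(annualize_cost(1000, idx, idx + 364), 1000 / 365 * 365.25)
})

test_that("annualization is homogeneous of degree one", {
  for (k in c(0, 0.5, 2, 10)) {
    expect_equal(annualize_cost(k * 123.4, idx, idx + 100),
                 k * annualize_cost(123.4, idx, idx + 100))
  }
})

test_that("category assignment partitions claim costs with no double counting", {
  cl <- rbind(
    claim_row("P1", "2017-02-01", "diagnosis", "DX_CD", "inpatient", 10000),
    claim_row("P1", "2017-03-01", "procedure", "PX_SURG", "inpatient", 4000),
    claim_row("P1", "2017-04-01", "revenue", "0450", "ED", 1000),
    claim_row("P1", "2017-05-01", "procedure", "99213", "outpatient", 300),
    claim_row("P1", "2017-06-01", "procedure", "PX_ENDO", "outpatient", 150),
    claim_row("P1", "2017-07-01", "revenue", "0301", "outpatient", 50),
    claim_row("P1", "2017-08-01", "drug", "VEDO", "outpatient", 5500))  # uncategorized
  r <- aggregate_costs(cl, idx, idx + 400, ocfg)
  expect_equal(r$hospitalization, 10000)
  expect_equal(r$surgery, 4000)
  expect_equal(r$ed_visit, 1000)
  expect_equal(r$office_visit, 300)
  expect_equal(r$endoscopy_scan, 150)
  expect_equal(r$lab_test, 50)
  expect_equal(r$total, 15500)
  expect_equal(r$total,
               sum(unlist(r[c("hospitalization", "surgery", "ed_visit",
                              "office_visit", "endoscopy_scan", "lab_test")])))
  expect_false(r$annualized)
})

test_that("reclassified ED claims contribute their cost to the linked category", {
  cl <- rbind(claim_row("P1", "2017-02-01", "revenue", "0450", "ED", 1000),
              claim_row("P1", "2017-02-01", "diagnosis", "DX_CD", "inpatient", 9000))
  r <- aggregate_costs(cl, idx, idx + 400, ocfg)
  expect_equal(r$hospitalization, 10000)
  expect_equal(r$ed_visit, 0)
})

test_that("single hospitalization claim with full-year eligibility passes through", {
  cl <- claim_row("P1", "2017-02-01", "diagnosis", "DX_CD", "inpatient", 10000)
  r <- aggregate_costs(cl, idx, idx + 400, ocfg)
  expect_equal(r$hospitalization, 10000)
  expect_equal(r$total, 10000)
})

test_that("short eligibility annualizes every category by the same factor", {
  cl <- rbind(claim_row("P1", "2017-01-10", "diagnosis", "DX_CD", "inpatient", 1000),
              claim_row("P1", "2017-01-20", "revenue", "0301", "outpatient", 100))
  end <- idx + 182  # 183-day interval
  r <- aggregate_costs(cl, idx, end, ocfg)
  f <- 365.25 / 183
  expect_equal(r$hospitalization, 1000 * f)
  expect_equal(r$lab_test, 100 * f)
  expect_equal(r$total, 1100 * f)
  expect_true(r$annualized)
})

test_that("a patient with no claims has all-zero costs", {
  r <- aggregate_costs(claim_row("P1", "2017-02-01", "diagnosis", "DX_CD",
                                 "inpatient")[0, ], idx, idx + 400, ocfg)
  expect_equal(r$total, 0)
  expect_equal(r$hospitalization, 0)
})
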