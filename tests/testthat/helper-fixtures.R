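# In-code fixtures: small hand-built claims datasets and feature rows.

claim_row <- function(id, date, code_type, code, setting, paid = 100) {
  data.frame(patient_id = id, service_date = as.Date(date),
             code_type = code_type, code = code, setting = setting,
             paid_amount = paid,
             service_year = as.integer(format(as.Date(date), "%Y")),
             stringsAsFactors = FALSE)
}

mk_dataset <- function(patients, enrollment, claims, labs = NULL) {
  if (is.null(labs))
    labs <- data.frame(patient_id = character(),
                       collection_date = as.Date(character()),
                       analyte = character(), value = numeric(),
                       unit = character(), stringsAsFactors = FALSE)
  structure(list(patients = patients, enrollment = enrollment,
                 claims = claims, labs = labs),
            class = "claims_dataset")
}

lab_row <- function(id, date, analyte, value) {
  data.frame(patient_id = id, collection_date = as.Date(date),
             analyte = analyte, value = value,
             unit = if (analyte == "albumin") "g/L" else "mg/L",
             stringsAsFactors = FALSE)
}

# one baseline-feature row with explicit risk factors and labs
feat <- function(surgery = FALSE, fistula = FALSE, antitnf = FALSE,
                 albumin = 40, crp = 1, id = "P1") {
  data.frame(patient_id = id, prior_bowel_surgery = surgery,
             prior_fistulizing_disease = fistula,
             prior_anti_tnf_exposure = antitnf,
             baseline_albumin = albumin, baseline_crp = crp,
             stringsAsFactors = FALSE)
}

# a minimal eligible single-patient history: index 2016-01-01, enrollment
# 2013-01-01..2019-12-31, two CD diagnoses in 2014
eligible_patient <- function(id = "P1", extra_claims = NULL) {
  claims <- rbind(
    claim_row(id, "2014-01-10", "diagnosis", "DX_CD", "outpatient"),
    claim_row(id, "2014-04-01", "diagnosis", "DX_CD", "outpatient"),
    claim_row(id, "2016-01-01", "drug", "VEDO", "outpatient", 5500))
  if (!is.null(extra_claims)) claims <- rbind(claims, extra_claims)
  mk_dataset(
    patients = data.frame(patient_id = id, birth_year = 1980L, sex = "F",
                          stringsAsFactors = FALSE),
    enrollment = data.frame(patient_id = id,
                            start_date = as.Date("2013-01-01"),
                            end_date = as.Date("2019-12-31")),
    claims = claims)
}
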