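# Synthetic longitudinal claims generator.
#
# Emits the four joinable tables the pipeline consumes (patients, enrollment,
# claims, labs) plus a separate latent-stratum truth table that downstream
# stages never see. A latent response-probability stratum drives the
# pre-index risk-factor history, baseline labs, 12-month event draws and
# per-claim costs, so planted event probabilities and cost means can be
# recovered by the outcomes/costs modules.

STRATA3 <- c("high", "intermediate", "low")

#' Configuration for the synthetic claims generator
#'
#' Defaults reproduce the structure of the vedolizumab study cohort this
#' package analyses: the stratum mix matches the 179/152/27
#' high/intermediate/low split of the 358-patient reference cohort, the
#' per-stratum risk-factor and prior-year event prevalences match the
#' published baseline table, and the planted 12-month hospitalization and
#' surgery probabilities match the published outcome proportions
#' (19.0%/48.1% hospitalization and 8.4%/44.4% surgery for high vs low).
#' Per-claim costs are drawn log-normal per service category: claims costs
#' are strongly right-skewed (published SDs exceed means).
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer seed; identical `(config, seed)` give byte-identical
#'   datasets.
#' @param index_window two dates; vedolizumab initiation dates are drawn
#'   uniformly inside it.
#' @param stratum_mix proportions over the latent `high`, `intermediate`,
#'   `low` strata (must sum to 1).
#' @param event_probs list with per-stratum 12-month probabilities of
#'   `hospitalization`, `surgery` and `ed_visit` (each length 3, stratum
#'   order high/intermediate/low).
#' @param cost_params list of `c(meanlog, sdlog)` log-normal parameters per
#'   cost category (2017 USD).
#' @param lab_params albumin mean (g/L) per stratum, common albumin SD, CRP
#'   band probabilities per stratum over `<3`, `3--10`, `>10` mg/L, and the
#'   probability that baseline labs are missing.
#' @param feature_probs per-stratum probabilities of prior bowel surgery,
#'   prior fistulizing disease and prior anti-TNF exposure, plus the
#'   conditional probability of a second anti-TNF agent given exposure.
#' @param prior_year_probs per-stratum probabilities of prior-year
#'   hospitalization, fistula and stricture claims and of concomitant
#'   immunomodulator / corticosteroid treatment.
#' @param demo_params per-stratum age mean, common age SD, minimum age and
#'   per-stratum probability of female sex.
#' @param visit_rates expected 12-month counts of office visits,
#'   endoscopies/scans and laboratory tests (Poisson).
#' @param enrollment_slack uniform day ranges for pre-index enrollment
#'   length, post-index length without dropout (>= 365), and post-index
#'   length under dropout (< 365).
#' @param dropout_prob probability that post-index enrollment ends before
#'   365 days.
#' @param ed_link_frac fraction of hospitalization events that additionally
#'   carry a same-day ED revenue-coded claim, exercising the ED
#'   reclassification rule.
#' @return A validated list of class `claims_sim_config`.
#' @seealso [simulate_claims()]
#' @export
claims_sim_config <- function(n_patients = 358,
                              seed = 1L,
                              index_window = c("2014-05-01", "2018-03-31"),
                              stratum_mix = c(high = 179, intermediate = 152, low = 27) / 358,
                              event_probs = list(
                                hospitalization = c(0.190, 0.300, 0.481),
                                surgery         = c(0.084, 0.190, 0.444),
                                ed_visit        = c(0.160, 0.230, 0.330)),
                              cost_params = list(
                                hospitalization = c(meanlog = log(20000), sdlog = 1.0),
                                surgery         = c(meanlog = log(12000), sdlog = 0.8),
                                ed_visit        = c(meanlog = log(2500),  sdlog = 1.0),
                                office_visit    = c(meanlog = log(150),   sdlog = 0.5),
                                endoscopy_scan  = c(meanlog = log(1800),  sdlog = 0.7),
                                lab_test        = c(meanlog = log(120),   sdlog = 0.6)),
                              lab_params = list(
                                albumin_mean = c(42, 37, 31),
                                albumin_sd   = 4,
                                crp_band_probs = rbind(
                                  high         = c(0.70, 0.25, 0.05),
                                  intermediate = c(0.45, 0.35, 0.20),
                                  low          = c(0.20, 0.35, 0.45)),
                                missing_prob = 0.05),
                              feature_probs = list(
                                prior_surgery  = c(0.045, 0.191, 0.519),
                                prior_fistula  = c(0.084, 0.388, 0.778),
                                prior_anti_tnf = c(0.598, 0.908, 1.000),
                                second_agent   = c(0.346, 0.420, 0.556)),
                              prior_year_probs = list(
                                hospitalization = c(0.229, 0.342, 0.704),
                                fistula         = c(0.056, 0.263, 0.593),
                                stricture       = c(0.005, 0.013, 0.010),
                                concomitant_imm = c(0.268, 0.243, 0.407),
                                concomitant_cs  = c(0.492, 0.605, 0.630)),
                              demo_params = list(
                                age_mean = c(46, 45, 37), age_sd = 15,
                                min_age = 18,
                                female_prob = c(0.542, 0.632, 0.741)),
                              visit_rates = c(office_visit = 5, endoscopy_scan = 1.2,
                                              lab_test = 6),
                              enrollment_slack = list(pre = c(400, 1500),
                                                      post = c(365, 1200),
                                                      dropout_post = c(183, 364)),
                              dropout_prob = 0.10,
                              ed_link_frac = 0.5) {
  cfg <- list(n_patients = n_patients, seed = as.integer(seed),
              index_window = as_date(index_window), stratum_mix = stratum_mix,
              event_probs = event_probs, cost_params = cost_params,
              lab_params = lab_params, feature_probs = feature_probs,
              prior_year_probs = prior_year_probs, demo_params = demo_params,
              visit_rates = visit_rates, enrollment_slack = enrollment_slack,
              dropout_prob = dropout_prob, ed_link_frac = ed_link_frac)
  class(cfg) <- "claims_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 0 || cfg$n_patients != floor(cfg$n_patients))
    stop_config("n_patients", "must be a single non-negative integer")
  if (length(cfg$index_window) != 2 || anyNA(cfg$index_window) ||
      cfg$index_window[1] > cfg$index_window[2])
    stop_config("index_window", "must be an ordered pair of dates")
  if (length(cfg$stratum_mix) != 3) stop_config("stratum_mix", "needs 3 proportions")
  check_prob(cfg$stratum_mix, "stratum_mix")
  if (abs(sum(cfg$stratum_mix) - 1) > 1e-9)
    stop_config("stratum_mix", "must sum to 1")
  for (nm in c("hospitalization", "surgery", "ed_visit"))
    check_prob(cfg$event_probs[[nm]], paste0("event_probs$", nm))
  for (nm in names(cfg$cost_params))
    check_pos(cfg$cost_params[[nm]][2], paste0("cost_params$", nm, "[sdlog]"))
  check_pos(cfg$lab_params$albumin_sd, "lab_params$albumin_sd")
  check_prob(cfg$lab_params$crp_band_probs, "lab_params$crp_band_probs")
  if (any(abs(rowSums(cfg$lab_params$crp_band_probs) - 1) > 1e-9))
    stop_config("lab_params$crp_band_probs", "rows must sum to 1")
  check_prob(cfg$lab_params$missing_prob, "lab_params$missing_prob")
  for (nm in names(cfg$feature_probs))
    check_prob(cfg$feature_probs[[nm]], paste0("feature_probs$", nm))
  for (nm in names(cfg$prior_year_probs))
    check_prob(cfg$prior_year_probs[[nm]], paste0("prior_year_probs$", nm))
  check_prob(cfg$dropout_prob, "dropout_prob")
  check_prob(cfg$ed_link_frac, "ed_link_frac")
  check_pos(cfg$visit_rates, "visit_rates", strict = FALSE)
  es <- cfg$enrollment_slack
  if (es$pre[1] < 190) stop_config("enrollment_slack$pre", "minimum must be >= 190 days")
  if (es$post[1] < 365) stop_config("enrollment_slack$post", "minimum must be >= 365 days")
  if (es$dropout_post[1] < 1 || es$dropout_post[2] > 364)
    stop_config("enrollment_slack$dropout_post", "must lie in [1, 364] days")
  cfg
}

# uniform integer draw in [lo, hi], vectorised over lo/hi
runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

new_claims_dataset <- function(patients, enrollment, claims, labs) {
  structure(list(patients = patients, enrollment = enrollment,
                 claims = claims, labs = labs),
            class = "claims_dataset")
}

empty_claims_dataset <- function() {
  new_claims_dataset(
    patients = data.frame(patient_id = character(), birth_year = integer(),
                          sex = character(), stringsAsFactors = FALSE),
    enrollment = data.frame(patient_id = character(),
                            start_date = as.Date(character()),
                            end_date = as.Date(character())),
    claims = data.frame(patient_id = character(),
                        service_date = as.Date(character()),
                        code_type = character(), code = character(),
                        setting = character(), paid_amount = numeric(),
                        service_year = integer(), stringsAsFactors = FALSE),
    labs = data.frame(patient_id = character(),
                      collection_date = as.Date(character()),
                      analyte = character(), value = numeric(),
                      unit = character(), stringsAsFactors = FALSE))
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  cat(sprintf("  patients:   %d\n", nrow(x$patients)))
  cat(sprintf("  enrollment: %d spans\n", nrow(x$enrollment)))
  cat(sprintf("  claims:     %d rows\n", nrow(x$claims)))
  cat(sprintf("  labs:       %d results\n", nrow(x$labs)))
  invisible(x)
}

claim_block <- function(patient_id, service_date, code_type, code, setting,
                        paid_amount) {
  data.frame(patient_id = patient_id, service_date = service_date,
             code_type = code_type, code = code, setting = setting,
             paid_amount = paid_amount, stringsAsFactors = FALSE)
}

#' Simulate a synthetic claims dataset
#'
#' Draws a latent response-probability stratum per patient and generates a
#' complete, internally consistent claims history: a vedolizumab initiation
#' claim inside the index window, two qualifying Crohn's disease diagnosis
#' claims more than 30 days apart before it, stratum-dependent pre-index
#' risk-factor claims (bowel surgery, fistulizing disease, anti-TNF agents),
#' baseline albumin/CRP results shortly before initiation, and 12-month
#' post-index hospitalization, surgery and ED events with log-normal costs.
#' A configurable fraction of hospitalization events carries a same-day ED
#' revenue claim so the ED-reclassification rule is exercised.
#'
#' @param config a [claims_sim_config()].
#' @return A list of class `claims_simulation` with elements `dataset` (a
#'   `claims_dataset`), `truth` (data frame `patient_id`, `stratum` — the
#'   latent stratum, kept outside the dataset so downstream stages cannot
#'   see it) and `config`.
#' @examples
#' sim <- simulate_claims(claims_sim_config(n_patients = 20, seed = 7))
#' sim$dataset
#' table(sim$truth$stratum)
#' @export
simulate_claims <- function(config = claims_sim_config()) {
  config <- validate_sim_config(config)
  n <- config$n_patients
  if (n == 0) {
    return(structure(list(dataset = empty_claims_dataset(),
                          truth = data.frame(patient_id = character(),
                                             stratum = character(),
                                             stringsAsFactors = FALSE),
                          config = config),
                     class = "claims_simulation"))
  }
  with_seed(config$seed, simulate_claims_impl(config, n))
}

simulate_claims_impl <- function(config, n) {
  codes <- default_code_sets()
  pid <- sprintf("P%05d", seq_len(n))
  si <- sample.int(3, n, replace = TRUE, prob = config$stratum_mix)
  stratum <- STRATA3[si]

  win <- config$index_window
  index_date <- win[1] + runif_int(n, 0, as.integer(win[2] - win[1]))
  es <- config$enrollment_slack
  pre_days <- runif_int(n, es$pre[1], es$pre[2])
  dropout <- stats::runif(n) < config$dropout_prob
  post_days <- ifelse(dropout,
                      runif_int(n, es$dropout_post[1], es$dropout_post[2]),
                      runif_int(n, es$post[1], es$post[2]))
  start_date <- index_date - pre_days
  end_date <- index_date + post_days

  dm <- config$demo_params
  age <- pmax(dm$min_age, round(stats::rnorm(n, dm$age_mean[si], dm$age_sd)))
  birth_year <- as.integer(format(index_date, "%Y")) - age
  sex <- ifelse(stats::runif(n) < dm$female_prob[si], "F", "M")

  fp <- config$feature_probs
  prior_surgery <- stats::runif(n) < fp$prior_surgery[si]
  prior_fistula <- stats::runif(n) < fp$prior_fistula[si]
  tnf_exposed <- stats::runif(n) < fp$prior_anti_tnf[si]
  two_agents <- tnf_exposed & (stats::runif(n) < fp$second_agent[si])

  py <- config$prior_year_probs
  py_hosp <- stats::runif(n) < py$hospitalization[si]
  # prior-year fistula is a subset of lifetime fistulizing disease
  p_cond <- pmin(1, py$fistula / pmax(fp$prior_fistula, 1e-12))
  py_fist <- prior_fistula & (stats::runif(n) < p_cond[si])
  py_stric <- stats::runif(n) < py$stricture[si]
  con_imm <- stats::runif(n) < py$concomitant_imm[si]
  con_cs <- stats::runif(n) < py$concomitant_cs[si]

  lp <- config$lab_params
  lab_missing <- stats::runif(n) < lp$missing_prob
  albumin <- round(stats::rnorm(n, lp$albumin_mean[si], lp$albumin_sd), 1)
  cb <- lp$crp_band_probs
  u <- stats::runif(n)
  band <- 1L + (u > cb[si, 1]) + (u > cb[si, 1] + cb[si, 2])
  crp <- round(c(stats::runif(n, 0.2, 2.9), stats::runif(n, 3.0, 10.0),
                 stats::runif(n, 10.1, 40.0))[(band - 1L) * n + seq_len(n)], 2)

  ep <- config$event_probs
  ev_hosp <- stats::runif(n) < ep$hospitalization[si]
  ev_surg <- stats::runif(n) < ep$surgery[si]
  ev_ed <- stats::runif(n) < ep$ed_visit[si]
  # event days: window split in thirds so standalone events never fall inside
  # another event's ED-linkage window
  W <- pmin(364L, post_days)
  seg <- W %/% 3L
  day_hosp <- runif_int(n, 3L, seg - 3L)
  day_surg <- runif_int(n, seg + 3L, 2L * seg - 3L)
  day_ed <- runif_int(n, 2L * seg + 3L, W - 3L)
  linked_ed <- ev_hosp & (stats::runif(n) < config$ed_link_frac)

  cp <- config$cost_params
  rcost <- function(k, m) stats::rlnorm(k, cp[[m]][1], cp[[m]][2])

  blocks <- list()
  add <- function(b) blocks[[length(blocks) + 1L]] <<- b

  # index + maintenance vedolizumab claims
  add(claim_block(pid, index_date, "drug", codes$vedolizumab[1], "outpatient",
                  round(stats::rlnorm(n, log(5500), 0.1), 2)))
  for (off in c(14L, 42L, 98L, 154L, 210L, 266L, 322L)) {
    keep <- post_days >= off
    if (any(keep))
      add(claim_block(pid[keep], index_date[keep] + off, "drug",
                      codes$vedolizumab[1], "outpatient",
                      round(stats::rlnorm(sum(keep), log(5500), 0.1), 2)))
  }

  # qualifying CD diagnoses (>= 30 days apart, both before index)
  d2_off <- runif_int(n, 31L, 90L)
  d1_off <- d2_off + runif_int(n, 30L, 99L)
  add(claim_block(pid, index_date - d1_off, "diagnosis", codes$cd_dx[1],
                  "outpatient", round(stats::runif(n, 80, 300), 2)))
  add(claim_block(pid, index_date - d2_off, "diagnosis", codes$cd_dx[1],
                  "outpatient", round(stats::runif(n, 80, 300), 2)))

  emit <- function(mask, offset, code_type, code, setting, paid) {
    if (any(mask))
      add(claim_block(pid[mask], index_date[mask] + offset[mask], code_type,
                      code, setting, round(paid[mask], 2)))
  }

  # pre-index risk-factor history
  surg_off <- -runif_int(n, 40L, pre_days - 10L)
  emit(prior_surgery, surg_off, "procedure", codes$surgery_px[1], "inpatient",
       rcost(n, "surgery")[seq_len(n)])
  fist_off <- ifelse(py_fist, -runif_int(n, 30L, 180L),
                     -runif_int(n, 370L, pre_days - 10L))
  emit(prior_fistula, fist_off, "diagnosis", codes$fistula_dx[1], "outpatient",
       stats::runif(n, 100, 400))
  tnf1 <- sample(codes$anti_tnf, n, replace = TRUE)
  shift <- runif_int(n, 1L, length(codes$anti_tnf) - 1L)
  tnf2 <- codes$anti_tnf[((match(tnf1, codes$anti_tnf) - 1L + shift) %%
                            length(codes$anti_tnf)) + 1L]
  tnf_off1 <- -runif_int(n, 40L, pre_days - 10L)
  tnf_off2 <- -runif_int(n, 40L, pre_days - 10L)
  if (any(tnf_exposed))
    add(claim_block(pid[tnf_exposed], index_date[tnf_exposed] + tnf_off1[tnf_exposed],
                    "drug", tnf1[tnf_exposed], "pharmacy",
                    round(stats::runif(sum(tnf_exposed), 2000, 5000), 2)))
  if (any(two_agents))
    add(claim_block(pid[two_agents], index_date[two_agents] + tnf_off2[two_agents],
                    "drug", tnf2[two_agents], "pharmacy",
                    round(stats::runif(sum(two_agents), 2000, 5000), 2)))

  # prior-year events (inpatient CD claim; stricture/fistula diagnoses)
  emit(py_hosp, -runif_int(n, 30L, 180L), "diagnosis", codes$cd_dx[1],
       "inpatient", rcost(n, "hospitalization")[seq_len(n)])
  emit(py_stric, -runif_int(n, 30L, 180L), "diagnosis", codes$stricture_dx[1],
       "outpatient", stats::runif(n, 100, 400))

  # concomitant medication claims in the post-index year
  emit(con_imm, runif_int(n, 10L, 170L), "drug", codes$immunomodulator[1],
       "pharmacy", stats::runif(n, 50, 400))
  emit(con_cs, runif_int(n, 5L, 120L), "drug", codes$corticosteroid[1],
       "pharmacy", stats::runif(n, 10, 80))

  # post-index events
  emit(ev_hosp, day_hosp, "diagnosis", codes$cd_dx[1], "inpatient",
       rcost(n, "hospitalization"))
  emit(linked_ed, day_hosp, "revenue", codes$ed_rev[1], "ED",
       rcost(n, "ed_visit"))
  emit(ev_surg, day_surg, "procedure", codes$surgery_px[1], "inpatient",
       rcost(n, "surgery"))
  emit(ev_ed, day_ed, "revenue", codes$ed_rev[1], "ED", rcost(n, "ed_visit"))

  # routine utilization: office visits, endoscopies/scans, laboratory tests
  routine <- function(rate, code_type, code_pool, setting, cost_cat) {
    k <- stats::rpois(n, rate * W / 365)
    if (sum(k) == 0) return(invisible())
    who <- rep.int(seq_len(n), k)
    add(claim_block(pid[who],
                    index_date[who] + runif_int(length(who), 1L, W[who] - 1L),
                    code_type, sample(code_pool, length(who), replace = TRUE),
                    setting, round(rcost(length(who), cost_cat), 2)))
  }
  routine(config$visit_rates[["office_visit"]], "procedure", codes$office_cpt,
          "outpatient", "office_visit")
  routine(config$visit_rates[["endoscopy_scan"]], "procedure",
          codes$endoscopy_px, "outpatient", "endoscopy_scan")
  routine(config$visit_rates[["lab_test"]], "revenue", codes$lab_rev,
          "outpatient", "lab_test")

  claims <- do.call(rbind, blocks)
  claims$paid_amount <- round(claims$paid_amount, 2)
  claims <- claims[order(claims$patient_id, claims$service_date, claims$code), ]
  rownames(claims) <- NULL
  claims$service_year <- as.integer(format(claims$service_date, "%Y"))

  lab_off <- runif_int(n, 5L, 60L)
  keep <- !lab_missing
  labs <- data.frame(
    patient_id = rep(pid[keep], 2L),
    collection_date = rep(index_date[keep] - lab_off[keep], 2L),
    analyte = rep(c("albumin", "crp"), each = sum(keep)),
    value = c(albumin[keep], crp[keep]),
    unit = rep(c("g/L", "mg/L"), each = sum(keep)),
    stringsAsFactors = FALSE)
  labs <- labs[order(labs$patient_id, labs$analyte), ]
  rownames(labs) <- NULL

  dataset <- new_claims_dataset(
    patients = data.frame(patient_id = pid, birth_year = birth_year, sex = sex,
                          stringsAsFactors = FALSE),
    enrollment = data.frame(patient_id = pid, start_date = start_date,
                            end_date = end_date, stringsAsFactors = FALSE),
    claims = claims, labs = labs)
  structure(list(dataset = dataset,
                 truth = data.frame(patient_id = pid, stratum = stratum,
                                    stringsAsFactors = FALSE),
                 config = config),
            class = "claims_simulation")
}

#' @export
print.claims_simulation <- function(x, ...) {
  cat(sprintf("<claims_simulation> n = %d, seed = %d\n",
              x$config$n_patients, x$config$seed))
  print(x$dataset)
  invisible(x)
}

#' Validate the internal consistency of a claims dataset
#'
#' Checks referential integrity (every patient referenced in claims, labs and
#' enrollment exists in the patient table), enrollment ordering, that every
#' claim falls inside one of its patient's enrollment spans, non-negative
#' paid amounts, and laboratory units (albumin g/L, CRP mg/L).
#'
#' @param dataset a `claims_dataset`.
#' @return `dataset`, invisibly; errors describe the first violated rule.
#' @export
validate_claims_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "claims_dataset"))
  p <- dataset$patients$patient_id
  for (tab in c("enrollment", "claims", "labs")) {
    bad <- setdiff(dataset[[tab]]$patient_id, p)
    if (length(bad))
      stop(sprintf("table '%s' references unknown patient_id: %s", tab, bad[1]),
           call. = FALSE)
  }
  en <- dataset$enrollment
  if (any(en$start_date > en$end_date))
    stop("enrollment has start_date after end_date", call. = FALSE)
  cl <- dataset$claims
  if (nrow(cl)) {
    if (any(cl$paid_amount < 0)) stop("negative paid_amount", call. = FALSE)
    key <- paste(cl$patient_id, cl$service_date)
    covered <- logical(nrow(cl))
    idx <- split(seq_len(nrow(cl)), cl$patient_id)
    spans <- split(en, en$patient_id)
    for (id in names(idx)) {
      s <- spans[[id]]
      d <- cl$service_date[idx[[id]]]
      ok <- rep(FALSE, length(d))
      for (j in seq_len(nrow(s)))
        ok <- ok | (d >= s$start_date[j] & d <= s$end_date[j])
      covered[idx[[id]]] <- ok
    }
    if (!all(covered))
      stop(sprintf("claim outside enrollment for patient %s",
                   cl$patient_id[which(!covered)[1]]), call. = FALSE)
  }
  lb <- dataset$labs
  if (nrow(lb)) {
    if (any(lb$analyte == "albumin" & lb$unit != "g/L"))
      stop("albumin results must be in g/L", call. = FALSE)
    if (any(lb$analyte == "crp" & lb$unit != "mg/L"))
      stop("CRP results must be in mg/L", call. = FALSE)
  }
  invisible(dataset)
}
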