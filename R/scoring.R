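# The vedolizumab clinical decision support tool (CDST).
#
# Five-variable score: +2 points for no prior bowel surgery, +2 for no prior
# fistulizing disease, +3 for no prior anti-TNF exposure, +0.4 points per
# g/L of albumin, and a piecewise CRP penalty (0 below 3 mg/L, -0.5 in
# [3, 10] mg/L, -3 above 10 mg/L). Strata: high > 19 points, intermediate
# > 13 to <= 19, low <= 13. The modified three-variable score keeps only
# the clinical points; high > 3, low <= 3.

#' CDST point values and stratum cutoffs
#'
#' @param no_prior_surgery_pts,no_prior_fistula_pts,no_prior_antitnf_pts
#'   points awarded when the corresponding risk factor is absent.
#' @param albumin_pts_per_gL points per g/L of baseline serum albumin.
#' @param crp_mid_penalty penalty for CRP in the closed band
#'   \[`crp_band_low`, `crp_band_high`\] mg/L.
#' @param crp_high_penalty penalty for CRP above `crp_band_high` mg/L.
#' @param crp_band_low,crp_band_high CRP band edges (mg/L); 10.0 belongs to
#'   the middle band ("> 10" defines the high penalty), 3.0 to the middle
#'   band as well.
#' @param cut_high_5var,cut_low_5var five-variable cutoffs: high when score
#'   strictly exceeds `cut_high_5var`, low when score is at most
#'   `cut_low_5var`.
#' @param cut_3var three-variable cutoff: high when score strictly exceeds
#'   it.
#' @return A list of class `cdst_weights`.
#' @export
cdst_weights <- function(no_prior_surgery_pts = 2,
                         no_prior_fistula_pts = 2,
                         no_prior_antitnf_pts = 3,
                         albumin_pts_per_gL = 0.4,
                         crp_mid_penalty = -0.5,
                         crp_high_penalty = -3,
                         crp_band_low = 3.0,
                         crp_band_high = 10.0,
                         cut_high_5var = 19,
                         cut_low_5var = 13,
                         cut_3var = 3) {
  w <- list(no_prior_surgery_pts = no_prior_surgery_pts,
            no_prior_fistula_pts = no_prior_fistula_pts,
            no_prior_antitnf_pts = no_prior_antitnf_pts,
            albumin_pts_per_gL = albumin_pts_per_gL,
            crp_mid_penalty = crp_mid_penalty,
            crp_high_penalty = crp_high_penalty,
            crp_band_low = crp_band_low, crp_band_high = crp_band_high,
            cut_high_5var = cut_high_5var, cut_low_5var = cut_low_5var,
            cut_3var = cut_3var)
  if (w$cut_high_5var <= w$cut_low_5var)
    stop_config("cut_high_5var", "must exceed cut_low_5var")
  for (f in c("no_prior_surgery_pts", "no_prior_fistula_pts",
              "no_prior_antitnf_pts", "albumin_pts_per_gL"))
    check_pos(w[[f]], f)
  if (w$crp_band_low >= w$crp_band_high)
    stop_config("crp_band_low", "must be below crp_band_high")
  structure(w, class = "cdst_weights")
}

crp_penalty <- function(crp, weights) {
  ifelse(crp > weights$crp_band_high, weights$crp_high_penalty,
         ifelse(crp >= weights$crp_band_low, weights$crp_mid_penalty, 0))
}

clinical_points <- function(features, weights) {
  (!features$prior_bowel_surgery) * weights$no_prior_surgery_pts +
    (!features$prior_fistulizing_disease) * weights$no_prior_fistula_pts +
    (!features$prior_anti_tnf_exposure) * weights$no_prior_antitnf_pts
}

stratum_5var <- function(score, weights) {
  ifelse(score > weights$cut_high_5var, "high",
         ifelse(score > weights$cut_low_5var, "intermediate", "low"))
}

#' Five-variable CDST score
#'
#' Requires baseline albumin and CRP; patients with either missing are
#' flagged `inputs_complete = FALSE`, receive no score, and are excluded
#' from five-variable analyses (the analysis is restricted to patients with
#' available laboratory data).
#'
#' @param features one or more rows of baseline features (see
#'   [derive_baseline_features()]).
#' @param weights a [cdst_weights()].
#' @return Data frame with `patient_id`, `variant`, `score`, `stratum`
#'   (`high`/`intermediate`/`low`) and `inputs_complete`.
#' @examples
#' f <- data.frame(patient_id = "A", prior_bowel_surgery = FALSE,
#'                 prior_fistulizing_disease = FALSE,
#'                 prior_anti_tnf_exposure = FALSE,
#'                 baseline_albumin = 40, baseline_crp = 2)
#' score_5var(f)  # 2 + 2 + 3 + 16 + 0 = 23 -> high
#' @export
score_5var <- function(features, weights = cdst_weights()) {
  complete <- !is.na(features$baseline_albumin) & !is.na(features$baseline_crp)
  score <- clinical_points(features, weights) +
    weights$albumin_pts_per_gL * features$baseline_albumin +
    crp_penalty(features$baseline_crp, weights)
  score[!complete] <- NA_real_
  data.frame(patient_id = features$patient_id,
             variant = rep("five_var", length(score)),
             score = score,
             stratum = ifelse(complete, stratum_5var(score, weights), NA_character_),
             inputs_complete = complete, stringsAsFactors = FALSE)
}

#' Three-variable CDST score
#'
#' Clinical points only (no laboratory data needed): possible scores are
#' 0, 2, 3, 4, 5 and 7. High probability of response when the score strictly
#' exceeds 3, low otherwise.
#'
#' @inheritParams score_5var
#' @return Data frame with `patient_id`, `variant`, `score`, `stratum`
#'   (`high`/`low`) and `inputs_complete` (always `TRUE`).
#' @export
score_3var <- function(features, weights = cdst_weights()) {
  score <- clinical_points(features, weights)
  data.frame(patient_id = features$patient_id,
             variant = rep("three_var", length(score)),
             score = score,
             stratum = ifelse(score > weights$cut_3var, "high", "low"),
             inputs_complete = rep(TRUE, length(score)),
             stringsAsFactors = FALSE)
}

#' Score a cohort under one CDST variant
#'
#' @param cohort a `cdst_cohort` or its `features` data frame.
#' @param variant `"five_var"` or `"three_var"`.
#' @param weights a [cdst_weights()].
#' @return List of class `cdst_scores`: `scores` (scored patients only),
#'   `n_missing_labs` (patients excluded for missing labs; always 0 for
#'   `three_var`) and `variant`.
#' @export
score_cohort <- function(cohort, variant = c("five_var", "three_var"),
                         weights = cdst_weights()) {
  variant <- match.arg(variant)
  features <- if (inherits(cohort, "cdst_cohort")) cohort$features else cohort
  res <- if (variant == "five_var") score_5var(features, weights)
         else score_3var(features, weights)
  n_missing <- sum(!res$inputs_complete)
  structure(list(scores = res[res$inputs_complete, , drop = FALSE],
                 n_missing_labs = n_missing, variant = variant),
            class = "cdst_scores")
}

#' @export
print.cdst_scores <- function(x, ...) {
  cat(sprintf("<cdst_scores> variant = %s, %d scored", x$variant,
              nrow(x$scores)))
  if (x$n_missing_labs)
    cat(sprintf(" (%d excluded: missing labs)", x$n_missing_labs))
  cat("\n")
  if (nrow(x$scores)) print(table(stratum = x$scores$stratum))
  invisible(x)
}
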