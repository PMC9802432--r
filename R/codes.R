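#' Default claim code sets
#'
#' Named lists of codes used to recognise diagnoses, procedures, revenue
#' centres and drugs in a claims table. The revenue-centre and CPT ranges are
#' the standard ones for this analysis (emergency department revenue codes
#' 0450--0459 and 0981; established-patient office visits CPT 99211--99215;
#' laboratory revenue codes 0300--0319). Diagnosis, surgery, endoscopy and
#' drug vocabularies default to the compact synthetic vocabulary emitted by
#' [simulate_claims()] (`DX_CD`, `PX_SURG`, ...); replace them with real
#' ICD/CPT/NDC lists when running on real extracts.
#'
#' @return A named list of character vectors with elements `cd_dx`,
#'   `fistula_dx`, `stricture_dx`, `surgery_px`, `endoscopy_px`,
#'   `office_cpt`, `lab_rev`, `ed_rev`, `vedolizumab`, `anti_tnf`,
#'   `immunomodulator`, `corticosteroid`.
#' @examples
#' default_code_sets()$ed_rev
#' @export
default_code_sets <- function() {
  list(
    cd_dx          = "DX_CD",
    fistula_dx     = "DX_FIST",
    stricture_dx   = "DX_STRIC",
    surgery_px     = "PX_SURG",
    endoscopy_px   = c("PX_ENDO", "PX_SCAN"),
    office_cpt     = sprintf("992%02d", 11:15),
    lab_rev        = sprintf("03%02d", 0:19),
    ed_rev         = c(sprintf("045%d", 0:9), "0981"),
    vedolizumab    = "VEDO",
    anti_tnf       = c("TNF_IFX", "TNF_ADA", "TNF_CZP", "TNF_GOL"),
    immunomodulator = "DRUG_IMM",
    corticosteroid = "DRUG_CS"
  )
}

validate_code_sets <- function(code_sets) {
  required <- names(default_code_sets())
  missing <- setdiff(required, names(code_sets))
  if (length(missing))
    stop_config("code_sets", paste("missing code set(s):", paste(missing, collapse = ", ")))
  for (nm in required)
    if (!length(code_sets[[nm]]))
      stop_config(paste0("code_sets$", nm), "code set must be non-empty")
  invisible(code_sets)
}
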