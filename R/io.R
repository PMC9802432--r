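# Delimited-text serialization of claims datasets.
#
# One CSV per table (patients.csv, enrollment.csv, claims.csv, labs.csv),
# ISO-8601 dates, UTF-8. A simulation's latent-stratum table is written to
# truth.csv alongside when requested, but read_claims_dataset() never loads
# it: the analysis stages must not see the latent stratum.

DATASET_SCHEMA <- list(
  patients = c("patient_id", "birth_year", "sex"),
  enrollment = c("patient_id", "start_date", "end_date"),
  claims = c("patient_id", "service_date", "code_type", "code", "setting",
             "paid_amount", "service_year"),
  labs = c("patient_id", "collection_date", "analyte", "value", "unit"))

DATE_COLS <- c(start_date = "enrollment", end_date = "enrollment",
               service_date = "claims", collection_date = "labs")

#' Write a claims dataset to a directory of CSV files
#'
#' @param dataset a `claims_dataset` (or a `claims_simulation`, whose truth
#'   table is then written to `truth.csv` as well).
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @seealso [read_claims_dataset()]
#' @export
write_claims_dataset <- function(dataset, dir) {
  truth <- NULL
  if (inherits(dataset, "claims_simulation")) {
    truth <- dataset$truth
    dataset <- dataset$dataset
  }
  stopifnot(inherits(dataset, "claims_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tab in names(DATASET_SCHEMA)) {
    df <- dataset[[tab]]
    for (col in names(df)) if (inherits(df[[col]], "Date"))
      df[[col]] <- format(df[[col]], "%Y-%m-%d")
    utils::write.csv(df, file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.null(truth))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(dir)
}

read_table_checked <- function(path, required, table) {
  if (!file.exists(path))
    stop(sprintf("missing dataset file: %s", path), call. = FALSE)
  cc <- c(patient_id = "character")
  if (table == "claims")  # keep leading zeros of revenue/CPT codes
    cc <- c(cc, code = "character")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = cc,
                        fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("file '%s': missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")), call. = FALSE)
  for (col in names(DATE_COLS)[DATE_COLS == table]) {
    parsed <- as.Date(df[[col]], format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop(sprintf("file '%s', line %d, column '%s': unparseable date '%s'",
                   basename(path), bad[1] + 1L, col, df[[col]][bad[1]]),
           call. = FALSE)
    df[[col]] <- parsed
  }
  df[required]
}

#' Read a claims dataset from a directory of CSV files
#'
#' Expects the file layout produced by [write_claims_dataset()]. Column
#' presence and ISO-8601 date parsing are checked; errors name the file,
#' line and column.
#'
#' @param dir directory containing `patients.csv`, `enrollment.csv`,
#'   `claims.csv`, `labs.csv`.
#' @param validate also run [validate_claims_dataset()] on the result.
#' @return A `claims_dataset`.
#' @export
read_claims_dataset <- function(dir, validate = TRUE) {
  tabs <- lapply(names(DATASET_SCHEMA), function(tab)
    read_table_checked(file.path(dir, paste0(tab, ".csv")),
                       DATASET_SCHEMA[[tab]], tab))
  names(tabs) <- names(DATASET_SCHEMA)
  ds <- new_claims_dataset(tabs$patients, tabs$enrollment, tabs$claims, tabs$labs)
  if (validate) validate_claims_dataset(ds)
  ds
}
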