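# End-to-end orchestration: simulate (or ingest) claims -> build cohort ->
# score (5-variable and 3-variable CDSTs) -> extract 12-month outcomes ->
# aggregate annualized costs -> compare strata -> write report artifacts.

#' Run the full claims-to-report pipeline
#'
#' Deterministic given `(sim_config, seed)`. When `out_dir` is given, every
#' intermediate artifact is written (cohort CSV, attrition log JSON, per
#' patient scores/outcomes/costs CSVs, per-variant comparison CSVs, and a
#' markdown report mirroring the baseline, utilization and cost tables).
#'
#' @param dataset a `claims_dataset`; when `NULL`, one is simulated from
#'   `sim_config`.
#' @param sim_config a [claims_sim_config()], used only when `dataset` is
#'   `NULL`.
#' @param cohort_cfg a [cohort_config()].
#' @param outcomes_cfg an [outcomes_config()].
#' @param cpi a [cpi_table()].
#' @param weights a [cdst_weights()].
#' @param variants CDST variants to run (`"five_var"`, `"three_var"`).
#' @param out_dir optional output directory for artifacts.
#' @return List of class `cdst_pipeline`: `cohort`, per-variant `scores`,
#'   `outcomes`, `costs`, per-variant `proportions` and `comparison`
#'   tables, and (when simulated) the simulation object.
#' @examples
#' \donttest{
#' res <- run_cdst_pipeline(sim_config = claims_sim_config(n_patients = 100))
#' res$comparison$three_var
#' }
#' @export
run_cdst_pipeline <- function(dataset = NULL,
                              sim_config = claims_sim_config(),
                              cohort_cfg = cohort_config(),
                              outcomes_cfg = outcomes_config(),
                              cpi = cpi_table(),
                              weights = cdst_weights(),
                              variants = c("five_var", "three_var"),
                              out_dir = NULL) {
  variants <- match.arg(variants, several.ok = TRUE)
  sim <- NULL
  if (is.null(dataset)) {
    sim <- simulate_claims(sim_config)
    dataset <- sim$dataset
  }
  cohort <- build_cohort(dataset, cohort_cfg)
  outcomes <- extract_cohort_events(dataset, cohort, outcomes_cfg)
  costs <- aggregate_cohort_costs(dataset, outcomes, outcomes_cfg, cpi)

  scores <- proportions <- comparison <- list()
  for (v in variants) {
    sc <- score_cohort(cohort, v, weights)
    scores[[v]] <- sc
    if (!nrow(sc$scores)) {
      warning(sprintf("variant %s: zero scorable patients", v), call. = FALSE)
      proportions[[v]] <- NULL
      comparison[[v]] <- NULL
      next
    }
    proportions[[v]] <- event_proportions(outcomes, sc$scores)
    comparison[[v]] <- suppressWarnings(
      compare_strata(outcomes, costs, sc$scores))
  }

  res <- structure(list(cohort = cohort, scores = scores, outcomes = outcomes,
                        costs = costs, proportions = proportions,
                        comparison = comparison, simulation = sim),
                   class = "cdst_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

#' @export
print.cdst_pipeline <- function(x, ...) {
  cat("<cdst_pipeline>\n")
  print(x$cohort)
  for (v in names(x$scores)) print(x$scores[[v]])
  invisible(x)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(res$cohort$features, "cohort.csv")
  jsonlite::write_json(
    stats::setNames(as.list(res$cohort$attrition$excluded),
                    res$cohort$attrition$criterion),
    file.path(out_dir, "attrition.json"), auto_unbox = TRUE)
  wcsv(res$outcomes, "outcomes.csv")
  wcsv(res$costs, "costs.csv")
  for (v in names(res$scores)) {
    wcsv(res$scores[[v]]$scores, sprintf("scores_%s.csv", v))
    if (!is.null(res$proportions[[v]]))
      wcsv(res$proportions[[v]], sprintf("proportions_%s.csv", v))
    if (!is.null(res$comparison[[v]]))
      wcsv(as.data.frame(res$comparison[[v]]), sprintf("comparison_%s.csv", v))
  }
  writeLines(render_report(res), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

md_table <- function(df) {
  if (is.null(df) || !nrow(df)) return("(empty)")
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, format = "g", digits = 4))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, body)
}

render_report <- function(res) {
  out <- c("# CDST healthcare-resource-utilization report", "",
           sprintf("Eligible cohort: %d patients", nrow(res$cohort$features)),
           "", "## Attrition", "", md_table(res$cohort$attrition))
  for (v in names(res$scores)) {
    sc <- res$scores[[v]]
    out <- c(out, "", sprintf("## CDST variant: %s", v), "",
             sprintf("Scored patients: %d (excluded for missing labs: %d)",
                     nrow(sc$scores), sc$n_missing_labs))
    if (nrow(sc$scores)) {
      tab <- table(sc$scores$stratum)
      out <- c(out, "",
               paste("Strata:", paste(sprintf("%s = %d", names(tab), tab),
                                      collapse = ", ")))
    }
    if (!is.null(res$proportions[[v]]))
      out <- c(out, "", "### 12-month event proportions", "",
               md_table(res$proportions[[v]]))
    if (!is.null(res$comparison[[v]]))
      out <- c(out, "", "### Strata comparison (events and annualized costs)",
               "", md_table(as.data.frame(res$comparison[[v]])))
  }
  out
}
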