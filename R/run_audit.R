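#' Run the full emetic-risk and prophylaxis audit
#'
#' End-to-end pipeline: cohort construction, regimen assembly and risk
#' classification, prophylaxis attribution, and all output tables. Inputs
#' may be file paths or already-read tibbles. The run is deterministic given
#' its inputs.
#'
#' @param registry,claims,procedures File paths or tibbles (see
#'   [read_inputs]). `procedures` may be `NULL`.
#' @param config An [audit_config()].
#' @param out_dir Optional directory; when given, one delimited file per
#'   table is written along with `flow_log.json` and `run_manifest.json`.
#' @return List of class `cinv_audit` with the cohort, course events,
#'   assignments, profiles, a `tables` list
#'   (`characteristics`, `risk_distribution`, `top_regimens`, `prophylaxis`,
#'   `per_cancer_risk`, `per_cancer_prophylaxis`), the flow log, rule
#'   versions and the config.
#' @export
run_audit <- function(registry, claims, procedures = NULL,
                      config = audit_config(), out_dir = NULL) {
  if (is.character(registry)) registry <- read_registry(registry)
  if (is.character(claims)) claims <- read_claims(claims)
  if (is.character(procedures)) procedures <- read_procedures(procedures)

  rules <- load_guideline_table(config$guideline)
  built <- build_cohort(registry, claims, procedures, config)
  empty <- nrow(built$cohort) == 0
  assignments <- if (empty) {
    tibble::tibble(patient_id = character(), cancer_type = character(),
                   route_group = character(), regimen = character(),
                   guideline = character(), category = character(),
                   fired_rule = character())
  } else classify_cohort(built, rules, config)
  profiles <- if (empty) {
    tibble::tibble(patient_id = character(), has_nk1 = logical(),
                   has_serotonin = logical(), has_steroid = logical(),
                   category = character(), nk1_unpartnered = logical())
  } else attribute_prophylaxis(built, claims, rules, config)

  tables <- list(
    characteristics = if (empty) tibble::tibble() else
      characteristics_table(built$cohort),
    risk_distribution = risk_distribution_table(assignments),
    top_regimens = if (empty) tibble::tibble() else top_regimens(assignments),
    prophylaxis = if (empty) tibble::tibble() else
      prophylaxis_table(profiles, assignments, method = config$ci_method,
                        alpha = config$alpha),
    per_cancer_risk = if (empty) tibble::tibble() else
      per_cancer_distribution(assignments),
    per_cancer_prophylaxis = if (empty) tibble::tibble() else
      prophylaxis_per_cancer(profiles, assignments, risk_filter = "high")
  )

  out <- structure(list(
    cohort = built$cohort, course_events = built$course_events,
    exclusions = built$exclusions, flow_log = built$flow_log,
    assignments = assignments, profiles = profiles, tables = tables,
    rules_version = rules$version, config = config
  ), class = "cinv_audit")

  if (!is.null(out_dir)) write_audit_outputs(out, out_dir)
  out
}

#' Write audit outputs to a directory
#'
#' One CSV per table, a machine-readable `flow_log.json`, and a
#' `run_manifest.json` echoing the configuration and rule-table version.
#'
#' @param audit A `cinv_audit` from [run_audit()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_audit_outputs <- function(audit, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(characteristics = "table2_characteristics.csv",
             risk_distribution = "table3_risk_distribution.csv",
             top_regimens = "table4_top_regimens.csv",
             prophylaxis = "table5_prophylaxis.csv",
             per_cancer_risk = "fig1_per_cancer.csv",
             per_cancer_prophylaxis = "fig2_prophylaxis_per_cancer.csv")
  for (nm in names(files)) {
    readr::write_csv(audit$tables[[nm]], file.path(out_dir, files[[nm]]))
  }
  jsonlite::write_json(audit$flow_log, file.path(out_dir, "flow_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cinvaudit")),
    rules_version = audit$rules_version,
    config = unclass(audit$config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.cinv_audit <- function(x, ...) {
  cat("<cinv_audit>\n")
  cat(sprintf("  cohort: %d patients retained of %d registry rows (%d excluded)\n",
              x$flow_log$n_final, x$flow_log$n_input,
              x$flow_log$n_excluded_unique))
  rd <- x$tables$risk_distribution
  tot <- rd[rd$route_group == "total" & is.na(rd$regimen), , drop = FALSE]
  if (nrow(tot) > 0) {
    cat("  emetic risk (overall %): ",
        paste(sprintf("%s %.1f", tot$category,
                      round_half_up(tot$percent, 1)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Paths to the packaged 30-patient demonstration fixture
#'
#' A small, human-readable linked dataset covering every exclusion reason, a
#' day-8 cisplatin escalation case, an oral-only patient, the 30-day oral
#' lookback boundary, and an NK1-antagonist-without-partner profile. This is
#' a synthetic dataset constructed for demonstrations and golden-file tests.
#'
#' @return Named list with `registry`, `claims` and `procedures` file paths.
#' @export
#' @examples
#' audit <- run_audit(demo_fixture()$registry, demo_fixture()$claims,
#'                    demo_fixture()$procedures)
demo_fixture <- function() {
  dir <- system.file("extdata", "fixture30", package = "cinvaudit",
                     mustWork = TRUE)
  list(registry = file.path(dir, "registry.csv"),
       claims = file.path(dir, "claims.csv"),
       procedures = file.path(dir, "procedures.csv"))
}
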