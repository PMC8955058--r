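#' Audit configuration
#'
#' Collects the tunable parameters of the pipeline in one object. Defaults
#' reproduce the study conditions: an 8-day inclusive first-course window, a
#' 21-day post-chemotherapy transplant exclusion window, a 30-day oral
#' antiemetic lookback, JSCO as the headline guideline, and a 1.48 m2
#' population-average body surface area.
#'
#' @param diagnosis_year Calendar year of diagnosis to include (`NULL` keeps
#'   all registry rows).
#' @param window_days Length of the first-course window in calendar days,
#'   inclusive of the start day.
#' @param hsct_days Days after a course chemotherapy administration within
#'   which a stem-cell transplant excludes the patient.
#' @param hsct_symmetric If `TRUE`, a transplant within `hsct_days` before
#'   chemotherapy also excludes.
#' @param oral_lookback_days Days before course start within which an oral
#'   antiemetic prescription counts as prophylactic.
#' @param guideline Guideline id for headline classification.
#' @param bsa_m2 Assumed body surface area, m2.
#' @param missing_dose How to resolve dose-tiered drugs with missing dose:
#'   `"fallback"` or `"unknown"`.
#' @param escalation_categories Single-agent categories that trigger the
#'   late-administration prophylaxis attribution rule (default: high only).
#' @param ci_method `"clopper_pearson"` (default) or `"wilson"`.
#' @param alpha Two-sided confidence level complement (0.05 = 95% CI).
#' @param adjuvant_heuristic If `TRUE` and the registry lacks an
#'   `adjuvant_flag`, flag courses starting 0-180 days after resection.
#' @return A list of class `cinv_config`.
#' @export
audit_config <- function(diagnosis_year = NULL, window_days = 8,
                         hsct_days = 21, hsct_symmetric = FALSE,
                         oral_lookback_days = 30, guideline = "JSCO",
                         bsa_m2 = 1.48,
                         missing_dose = c("fallback", "unknown"),
                         escalation_categories = "high",
                         ci_method = c("clopper_pearson", "wilson"),
                         alpha = 0.05, adjuvant_heuristic = FALSE) {
  stopifnot(window_days >= 1, hsct_days >= 0, oral_lookback_days >= 0,
            alpha > 0, alpha < 1)
  structure(list(
    diagnosis_year = diagnosis_year, window_days = window_days,
    hsct_days = hsct_days, hsct_symmetric = hsct_symmetric,
    oral_lookback_days = oral_lookback_days,
    guideline = match.arg(guideline, guideline_ids()),
    bsa_m2 = bsa_m2, missing_dose = match.arg(missing_dose),
    escalation_categories = escalation_categories,
    ci_method = match.arg(ci_method), alpha = alpha,
    adjuvant_heuristic = adjuvant_heuristic
  ), class = "cinv_config")
}

exclusion_reasons <- function() {
  c("interferon_alpha", "same_day_surgery_or_drainage", "arterial_route",
    "hsct_within_3_weeks", "under_20", "no_chemo")
}

procedure_kinds <- function() {
  c("surgery", "thoracic_drainage", "abdominal_drainage",
    "pericardial_drainage", "hsct")
}

#' Read the three pipeline input tables
#'
#' Delimited-text readers for the registry, drug-claims and procedures
#' schemas. Dates must be ISO-8601 (`YYYY-MM-DD`).
#'
#' @param path Path to a CSV file.
#' @return A tibble with typed columns.
#' @name read_inputs
NULL

#' @rdname read_inputs
#' @export
read_registry <- function(path) {
  reg <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           sex = readr::col_character(),
                           age_at_dx = readr::col_double(),
                           cancer_type = readr::col_character(),
                           dx_date = readr::col_date(),
                           clinical_stage = readr::col_character(),
                           pathological_stage = readr::col_character(),
                           resection_date = readr::col_date(),
                           .default = readr::col_guess()
                         ))
  if (!"adjuvant_flag" %in% names(reg)) reg$adjuvant_flag <- NA
  reg$adjuvant_flag <- as.logical(reg$adjuvant_flag)
  reg
}

#' @rdname read_inputs
#' @export
read_claims <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    date = readr::col_date(),
                    drug_id = readr::col_character(),
                    drug_class = readr::col_character(),
                    route = readr::col_character(),
                    dose_mg = readr::col_double()
                  ))
}

#' @rdname read_inputs
#' @export
read_procedures <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    date = readr::col_date(),
                    kind = readr::col_character()
                  ))
}

#' Identify a patient's first chemotherapy course
#'
#' The first course starts at the earliest chemotherapy administration on or
#' after diagnosis and spans `window_days` inclusive calendar days (day 1 =
#' start, day 8 = start + 7 under the default). All chemotherapy events in
#' that window belong to one combination regimen; later courses are ignored.
#'
#' @param chemo_events Tibble of one patient's chemotherapy drug events
#'   (columns `date`, `drug_id`, `route`, `dose_mg`).
#' @param dx_date Diagnosis date.
#' @param window_days Window length in days, inclusive of the start day.
#' @return A list of class `course_window` with `start_date`, `end_date` and
#'   `events` (events inside the window), or `NULL` (with attribute handling
#'   upstream) when the patient has no qualifying chemotherapy event.
#' @export
identify_first_course <- function(chemo_events, dx_date, window_days = 8) {
  ev <- chemo_events[!is.na(chemo_events$date) & chemo_events$date >= dx_date, ,
                     drop = FALSE]
  if (nrow(ev) == 0) return(NULL)
  start <- min(ev$date)
  end <- start + (window_days - 1L)
  structure(list(start_date = start, end_date = end,
                 events = ev[ev$date <= end, , drop = FALSE]),
            class = "course_window")
}

#' Apply the cohort exclusion rules to one patient
#'
#' Evaluates every exclusion against the first-course window: interferon-alpha
#' in the course; surgery or thoracic/abdominal/pericardial drainage on the
#' same day as a course administration (the drug may have been applied
#' topically); any arterial-route course drug; a haematopoietic stem cell
#' transplant within `hsct_days` after a course administration; and age under
#' 20 at diagnosis.
#'
#' @param record One registry row (list or one-row data frame).
#' @param course A `course_window` from [identify_first_course()], or `NULL`
#'   when the patient never received chemotherapy.
#' @param procedures Tibble of the patient's procedure events.
#' @param config An [audit_config()].
#' @return List with `excluded` (logical) and `reasons` (character vector).
#' @export
apply_exclusions <- function(record, course, procedures = NULL,
                             config = audit_config()) {
  reasons <- character()
  age <- record$age_at_dx
  if (!is.na(age) && age < 20) reasons <- c(reasons, "under_20")
  if (is.null(course)) {
    reasons <- c(reasons, "no_chemo")
  } else {
    ev <- course$events
    if (any(ev$drug_id == "interferon-alpha")) {
      reasons <- c(reasons, "interferon_alpha")
    }
    if (any(ev$route == "arterial")) reasons <- c(reasons, "arterial_route")
    if (!is.null(procedures) && nrow(procedures) > 0) {
      drain <- procedures[procedures$kind %in% setdiff(procedure_kinds(), "hsct"), ,
                          drop = FALSE]
      if (nrow(drain) > 0 && any(drain$date %in% ev$date)) {
        reasons <- c(reasons, "same_day_surgery_or_drainage")
      }
      hsct <- procedures[procedures$kind == "hsct", , drop = FALSE]
      if (nrow(hsct) > 0) {
        gaps <- outer(as.integer(hsct$date), as.integer(ev$date), "-")
        hit <- gaps >= 0 & gaps <= config$hsct_days
        if (config$hsct_symmetric) hit <- hit | (abs(gaps) <= config$hsct_days)
        if (any(hit)) reasons <- c(reasons, "hsct_within_3_weeks")
      }
    }
  }
  list(excluded = length(reasons) > 0, reasons = reasons)
}

#' Assign the route group of a course
#'
#' A course containing any intravenous drug belongs to the intravenous group;
#' courses of exclusively oral drugs form the oral group. (Mixed IV/oral
#' regimens such as S-1 plus cisplatin are driven emetogenically by their IV
#' component.)
#'
#' @param course A `course_window`, or a tibble of course events with a
#'   `route` column.
#' @return `"intravenous_group"` or `"oral_group"`.
#' @export
assign_route_group <- function(course) {
  ev <- if (inherits(course, "course_window")) course$events else course
  if (NROW(ev) == 0) stop("empty course window", call. = FALSE)
  if (any(ev$route == "IV")) "intravenous_group" else "oral_group"
}

#' Combine clinical and pathological stage
#'
#' The pathological stage is used for resected patients when available;
#' otherwise the clinical stage; `"unknown"` when neither is available.
#' Vectorised.
#'
#' @param clinical_stage,pathological_stage Stage values in
#'   `c("0","I","II","III","IV","unknown")`; `NA` is treated as unknown.
#' @param resection_date Resection date or `NA` (any non-`NA` value counts as
#'   resected).
#' @return Character vector of combined stages.
#' @export
combine_stage <- function(clinical_stage, pathological_stage, resection_date) {
  cs <- ifelse(is.na(clinical_stage), "unknown", clinical_stage)
  ps <- ifelse(is.na(pathological_stage), "unknown", pathological_stage)
  assert_in(c(cs, ps), stage_levels(), "stage")
  resected <- !is.na(resection_date)
  ifelse(resected & ps != "unknown", ps, cs)
}

#' Build the analyzable first-course cohort
#'
#' Applies the full patient-selection sequence to the three input tables:
#' restrict to the configured diagnosis year, find each patient's first
#' chemotherapy course, apply every exclusion, and derive route group and
#' combined stage. Selection counts at every step are recorded in a flow log.
#'
#' @param registry Registry tibble (see [read_registry()]).
#' @param claims Drug claims tibble with canonical `drug_id` and `drug_class`
#'   (see [read_claims()] and [canonicalize_claims()]).
#' @param procedures Procedures tibble, or `NULL`.
#' @param config An [audit_config()].
#' @return List of class `cinv_cohort` with:
#'   \describe{
#'     \item{cohort}{one row per retained patient: demographics, cancer type,
#'       combined stage, course start date, route group, adjuvant flag}
#'     \item{course_events}{chemotherapy events inside each retained
#'       patient's course window}
#'     \item{exclusions}{patient-level exclusion reasons (one row per patient
#'       x reason)}
#'     \item{flow_log}{named list of selection counts}
#'   }
#' @export
build_cohort <- function(registry, claims, procedures = NULL,
                         config = audit_config()) {
  if (anyDuplicated(registry$patient_id)) {
    stop("duplicate patient_id in registry", call. = FALSE)
  }
  assert_in(registry$cancer_type, cancer_types(), "cancer_type")
  if (is.null(procedures)) {
    procedures <- tibble::tibble(patient_id = character(),
                                 date = as.Date(character()),
                                 kind = character())
  }
  assert_in(procedures$kind, procedure_kinds(), "procedure kind")

  if (!is.null(config$diagnosis_year)) {
    registry <- registry[format(registry$dx_date, "%Y") %in%
                           as.character(config$diagnosis_year), , drop = FALSE]
  }
  orphan <- !claims$patient_id %in% registry$patient_id
  if (any(orphan)) {
    warning(sprintf("%d claim rows reference patient ids absent from the registry and were dropped",
                    sum(orphan)), call. = FALSE)
    claims <- claims[!orphan, , drop = FALSE]
  }
  procedures <- procedures[procedures$patient_id %in% registry$patient_id, ,
                           drop = FALSE]

  chemo <- claims |>
    dplyr::filter(.data$drug_class == "chemotherapy") |>
    dplyr::inner_join(dplyr::select(registry, "patient_id", "dx_date"),
                      by = "patient_id") |>
    dplyr::filter(.data$date >= .data$dx_date)

  starts <- if (nrow(chemo) == 0) {
    tibble::tibble(patient_id = character(), start_date = as.Date(character()))
  } else {
    dplyr::summarise(chemo, start_date = min(.data$date), .by = "patient_id")
  }

  course_events <- chemo |>
    dplyr::inner_join(starts, by = "patient_id") |>
    dplyr::filter(.data$date <= .data$start_date + (config$window_days - 1L)) |>
    dplyr::select("patient_id", "date", "drug_id", "route", "dose_mg",
                  "start_date")

  # exclusion reasons, patient level
  excl <- list()
  excl$under_20 <- registry$patient_id[!is.na(registry$age_at_dx) &
                                         registry$age_at_dx < 20]
  excl$no_chemo <- setdiff(registry$patient_id, starts$patient_id)
  excl$interferon_alpha <- unique(
    course_events$patient_id[course_events$drug_id == "interferon-alpha"])
  excl$arterial_route <- unique(
    course_events$patient_id[course_events$route == "arterial"])

  drain <- procedures[procedures$kind != "hsct", , drop = FALSE]
  excl$same_day_surgery_or_drainage <- course_events |>
    dplyr::semi_join(drain, by = c("patient_id", "date")) |>
    dplyr::pull("patient_id") |>
    unique()

  hsct <- procedures[procedures$kind == "hsct", , drop = FALSE]
  hsct_hits <- course_events |>
    dplyr::inner_join(dplyr::select(hsct, "patient_id", hsct_date = "date"),
                      by = "patient_id", relationship = "many-to-many") |>
    dplyr::mutate(gap = as.integer(.data$hsct_date - .data$date)) |>
    dplyr::filter(if (config$hsct_symmetric) abs(.data$gap) <= config$hsct_days
                  else .data$gap >= 0 & .data$gap <= config$hsct_days)
  excl$hsct_within_3_weeks <- unique(hsct_hits$patient_id)

  exclusions <- dplyr::bind_rows(lapply(names(excl), function(r) {
    tibble::tibble(patient_id = excl[[r]], reason = r)
  })) |>
    dplyr::arrange(.data$patient_id, .data$reason)
  excluded_ids <- unique(exclusions$patient_id)

  retained <- registry |>
    dplyr::filter(!.data$patient_id %in% excluded_ids,
                  .data$patient_id %in% starts$patient_id)
  course_events <- course_events |>
    dplyr::semi_join(retained, by = "patient_id")

  route_groups <- course_events |>
    dplyr::summarise(route_group = ifelse(any(.data$route == "IV"),
                                          "intravenous_group", "oral_group"),
                     .by = "patient_id")

  cohort <- retained |>
    dplyr::left_join(starts, by = "patient_id") |>
    dplyr::left_join(route_groups, by = "patient_id") |>
    dplyr::mutate(
      stage = combine_stage(.data$clinical_stage, .data$pathological_stage,
                            .data$resection_date),
      adjuvant = if (config$adjuvant_heuristic) {
        ifelse(is.na(.data$adjuvant_flag),
               !is.na(.data$resection_date) &
                 .data$start_date >= .data$resection_date &
                 .data$start_date <= .data$resection_date + 180L,
               .data$adjuvant_flag)
      } else .data$adjuvant_flag
    ) |>
    dplyr::select("patient_id", "sex", "age_at_dx", "cancer_type", "dx_date",
                  "stage", "start_date", "route_group", "adjuvant")

  reason_counts <- vapply(excl, length, integer(1))
  flow_log <- list(
    n_input = nrow(registry),
    n_chemo_recipients = nrow(starts),
    exclusions = as.list(reason_counts),
    n_excluded_unique = length(excluded_ids),
    n_final = nrow(cohort)
  )

  structure(list(cohort = cohort, course_events = course_events,
                 exclusions = exclusions, flow_log = flow_log),
            class = "cinv_cohort")
}
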