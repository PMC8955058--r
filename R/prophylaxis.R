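#' Collect prophylactically attributed antiemetic classes for one patient
#'
#' An antiemetic claim counts as prophylactic when (a) it is dated on the
#' course start date (any route); (b) a course component whose single-agent
#' category is in `config$escalation_categories` (high, by default) is
#' administered after the start date and the claim shares that
#' administration's date - the pattern of regimens such as S-1 with cisplatin
#' added on day 8; or (c) it is an oral prescription dated within
#' `config$oral_lookback_days` before the start (inclusive of day
#' start - 30 under the default).
#'
#' @param course A `course_window` (or tibble of the patient's course
#'   chemotherapy events with `date`, `drug_id`, `route`, `dose_mg`).
#' @param antiemetic_events Tibble of the patient's antiemetic claims
#'   (`date`, `drug_class` in NK1/serotonin_antagonist/steroid, `route`).
#' @param rules A `cinv_rules` object for the escalation check.
#' @param config An [audit_config()].
#' @return Character vector: the subset of antiemetic classes attributed.
#' @export
collect_prophylactic_events <- function(course, antiemetic_events,
                                        rules = load_guideline_table("JSCO"),
                                        config = audit_config()) {
  ev <- if (inherits(course, "course_window")) course$events else course
  if (NROW(ev) == 0) stop("empty course window", call. = FALSE)
  start <- min(ev$date)
  ae <- antiemetic_events[antiemetic_events$drug_class %in% antiemetic_classes(), ,
                          drop = FALSE]
  if (NROW(ae) == 0) return(character())

  late <- ev[ev$date > start, , drop = FALSE]
  esc_dates <- as.Date(character())
  if (nrow(late) > 0) {
    cats <- suppressWarnings(
      classify_agents_df(late, rules, bsa_m2 = config$bsa_m2,
                         missing_dose = config$missing_dose, quiet = TRUE))
    esc_dates <- unique(late$date[cats %in% config$escalation_categories])
  }

  counted <- ae$date == start |
    ae$date %in% esc_dates |
    (ae$route == "PO" &
       ae$date >= start - config$oral_lookback_days & ae$date < start)
  sort(unique(ae$drug_class[counted]))
}

#' Collapse attributed antiemetic classes into a prophylaxis category
#'
#' The five mutually exclusive, exhaustive categories: the three-drug
#' combination (NK1 antagonist + serotonin antagonist + steroid, any systemic
#' corticosteroid counting as the steroid component), serotonin antagonist
#' plus dexamethasone, serotonin antagonist alone, dexamethasone alone, or
#' none. An NK1 antagonist without both partners matches no printed category;
#' such profiles fall through to the category determined by the
#' serotonin/steroid pair and are flagged via [attribute_prophylaxis()]'s
#' `nk1_unpartnered` audit column.
#'
#' @param classes_present Character vector, subset of
#'   `c("NK1", "serotonin_antagonist", "steroid")` (vector of one patient's
#'   classes).
#' @return One of [prophylaxis_levels()].
#' @export
#' @examples
#' categorize_prophylaxis(c("NK1", "serotonin_antagonist", "steroid"))
#' categorize_prophylaxis(character())
categorize_prophylaxis <- function(classes_present) {
  stopifnot(all(classes_present %in% antiemetic_classes()))
  nk1 <- "NK1" %in% classes_present
  ser <- "serotonin_antagonist" %in% classes_present
  ste <- "steroid" %in% classes_present
  if (nk1 && ser && ste) "triple"
  else if (ser && ste) "serotonin_plus_dex"
  else if (ser) "serotonin_only"
  else if (ste) "dex_only"
  else "none_of_above"
}

#' Attribute prophylactic antiemetics across a cohort
#'
#' Vectorised pipeline step applying the attribution windows of
#' [collect_prophylactic_events()] and the category collapse of
#' [categorize_prophylaxis()] to every retained patient.
#'
#' @param built A `cinv_cohort` from [build_cohort()].
#' @param claims Full claims tibble (antiemetic rows are selected by
#'   `drug_class`).
#' @param rules A `cinv_rules` object.
#' @param config An [audit_config()].
#' @return Tibble with one row per cohort patient: `patient_id`, logical
#'   `has_nk1`/`has_serotonin`/`has_steroid`, `category`, and
#'   `nk1_unpartnered` (NK1 present without the full three-drug set).
#' @export
attribute_prophylaxis <- function(built, claims,
                                  rules = load_guideline_table("JSCO"),
                                  config = audit_config()) {
  cohort <- built$cohort
  course <- built$course_events
  starts <- dplyr::select(cohort, "patient_id", "start_date")

  ae <- claims |>
    dplyr::filter(.data$drug_class %in% antiemetic_classes()) |>
    dplyr::inner_join(starts, by = "patient_id")

  late <- course |>
    dplyr::filter(.data$date > .data$start_date)
  esc <- tibble::tibble(patient_id = character(), date = as.Date(character()))
  if (nrow(late) > 0) {
    late$comp_category <- suppressWarnings(
      classify_agents_df(late, rules, bsa_m2 = config$bsa_m2,
                         missing_dose = config$missing_dose, quiet = TRUE))
    esc <- late |>
      dplyr::filter(.data$comp_category %in% config$escalation_categories) |>
      dplyr::distinct(.data$patient_id, .data$date)
  }

  counted <- ae |>
    dplyr::left_join(dplyr::mutate(esc, esc_hit = TRUE),
                     by = c("patient_id", "date")) |>
    dplyr::filter(
      .data$date == .data$start_date |
        !is.na(.data$esc_hit) |
        (.data$route == "PO" &
           .data$date >= .data$start_date - config$oral_lookback_days &
           .data$date < .data$start_date)
    )

  flags <- counted |>
    dplyr::summarise(
      has_nk1 = any(.data$drug_class == "NK1"),
      has_serotonin = any(.data$drug_class == "serotonin_antagonist"),
      has_steroid = any(.data$drug_class == "steroid"),
      .by = "patient_id"
    )

  cohort |>
    dplyr::select("patient_id") |>
    dplyr::left_join(flags, by = "patient_id") |>
    dplyr::mutate(
      dplyr::across(c("has_nk1", "has_serotonin", "has_steroid"),
                    ~ !is.na(.x) & .x),
      category = dplyr::case_when(
        has_nk1 & has_serotonin & has_steroid ~ "triple",
        has_serotonin & has_steroid ~ "serotonin_plus_dex",
        has_serotonin ~ "serotonin_only",
        has_steroid ~ "dex_only",
        TRUE ~ "none_of_above"
      ),
      nk1_unpartnered = .data$has_nk1 & .data$category != "triple"
    )
}
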