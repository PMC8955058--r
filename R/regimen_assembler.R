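#' Collapse a course window into one regimen episode
#'
#' All chemotherapy administered in the first-course window is treated as one
#' combination regimen: one component per distinct (drug, route), carrying
#' the maximum dose observed in the window (conservative for dose-tiered
#' drugs).
#'
#' @param course A `course_window` from [identify_first_course()], or a
#'   tibble of course events.
#' @param cancer_type The patient's cancer type.
#' @return A list of class `regimen_episode` with `components` (tibble of
#'   `drug_id`, `route`, `dose_mg`) and `cancer_type`.
#' @export
assemble_regimen <- function(course, cancer_type = NA_character_) {
  ev <- if (inherits(course, "course_window")) course$events else course
  if (NROW(ev) == 0) stop("empty course window", call. = FALSE)
  components <- ev |>
    dplyr::summarise(
      dose_mg = if (all(is.na(.data$dose_mg))) NA_real_ else
        max(.data$dose_mg, na.rm = TRUE),
      .by = c("drug_id", "route")
    ) |>
    dplyr::arrange(.data$drug_id, .data$route)
  structure(list(components = components, cancer_type = cancer_type),
            class = "regimen_episode")
}

#' Match a named combination rule against an episode
#'
#' A combination rule fires when every one of its component drugs is present
#' in the episode (extra drugs are allowed, so rituximab plus CHOP still
#' fires the anthracycline + cyclophosphamide override) and its cancer
#' context, when set, matches. Rules are tried in specificity order: more
#' components first, context-restricted before unrestricted, then
#' lexicographic name.
#'
#' @param episode A `regimen_episode` from [assemble_regimen()].
#' @param rules A `cinv_rules` object.
#' @return The matching rule as a one-row tibble, or `NULL`.
#' @export
match_combination_rule <- function(episode, rules) {
  combos <- rules$combinations
  if (NROW(combos) == 0) return(NULL)
  comp <- episode$components
  for (i in seq_len(nrow(combos))) {
    want <- combos$components[[i]]
    pool <- if (!is.na(combos$route[i])) {
      comp$drug_id[comp$route == combos$route[i]]
    } else comp$drug_id
    if (!all(want %in% pool)) next
    ctx <- combos$cancer_context[i]
    if (!is.na(ctx) && !identical(ctx, episode$cancer_type)) next
    return(combos[i, ])
  }
  NULL
}

#' Classify a regimen episode's emetic risk
#'
#' A firing combination override determines the category as a unit;
#' otherwise the regimen takes the maximum single-agent category over its
#' components (components classifying as unknown are ignored for the
#' maximum; a regimen of only unknown components is unknown).
#'
#' @param episode A `regimen_episode`.
#' @param rules A `cinv_rules` object (or guideline id).
#' @param bsa_m2 Assumed body surface area, m2.
#' @param missing_dose See [classify_single_agent()].
#' @return List with `category`, `fired_rule` (rule name,
#'   `"max-of-components"` or `"unknown"`), and `guideline`.
#' @export
#' @examples
#' ep <- assemble_regimen(
#'   tibble::tibble(drug_id = c("s1", "cisplatin"), route = c("PO", "IV"),
#'                  dose_mg = c(100, 89)), "gastric")
#' classify_regimen(ep, load_guideline_table("JSCO"))
classify_regimen <- function(episode, rules = load_guideline_table("JSCO"),
                             bsa_m2 = 1.48,
                             missing_dose = c("fallback", "unknown")) {
  if (!inherits(rules, "cinv_rules")) rules <- load_guideline_table(rules)
  hit <- match_combination_rule(episode, rules)
  if (!is.null(hit)) {
    return(list(category = hit$category, fired_rule = hit$name,
                guideline = rules$guideline))
  }
  cats <- classify_agents_df(episode$components, rules, bsa_m2 = bsa_m2,
                             missing_dose = missing_dose)
  ranks <- risk_rank(cats)
  if (all(is.na(ranks))) {
    list(category = "unknown", fired_rule = "unknown",
         guideline = rules$guideline)
  } else {
    list(category = risk_levels()[5 - max(ranks, na.rm = TRUE)],
         fired_rule = "max-of-components", guideline = rules$guideline)
  }
}

#' Classify every cohort member's first-course regimen
#'
#' Vectorised pipeline step: assembles one regimen episode per retained
#' patient and assigns its emetic-risk category under the configured
#' guideline.
#'
#' @param built A `cinv_cohort` from [build_cohort()].
#' @param rules A `cinv_rules` object (defaults to the configured guideline).
#' @param config An [audit_config()].
#' @return Tibble of risk assignments: `patient_id`, `cancer_type`,
#'   `route_group`, `regimen` (sorted `+`-joined component label, or the
#'   fired combination-rule name), `guideline`, `category`, `fired_rule`.
#' @export
classify_cohort <- function(built, rules = NULL, config = audit_config()) {
  if (is.null(rules)) rules <- load_guideline_table(config$guideline)
  cohort <- built$cohort
  components <- built$course_events |>
    dplyr::summarise(
      dose_mg = if (all(is.na(.data$dose_mg))) NA_real_ else
        max(.data$dose_mg, na.rm = TRUE),
      .by = c("patient_id", "drug_id", "route")
    ) |>
    dplyr::left_join(dplyr::select(cohort, "patient_id", "cancer_type"),
                     by = "patient_id")

  # combination overrides, in specificity order; first match per patient wins
  combos <- rules$combinations
  fired <- tibble::tibble(patient_id = character(), fired_rule = character(),
                          category = character())
  if (NROW(combos) > 0) {
    for (i in seq_len(nrow(combos))) {
      want <- combos$components[[i]]
      pool <- components
      if (!is.na(combos$route[i])) {
        pool <- pool[pool$route == combos$route[i], , drop = FALSE]
      }
      if (!is.na(combos$cancer_context[i])) {
        pool <- pool[pool$cancer_type %in% combos$cancer_context[i], ,
                     drop = FALSE]
      }
      hits <- pool |>
        dplyr::filter(.data$drug_id %in% want) |>
        dplyr::summarise(n_hit = dplyr::n_distinct(.data$drug_id),
                         .by = "patient_id") |>
        dplyr::filter(.data$n_hit == length(want),
                      !.data$patient_id %in% fired$patient_id)
      if (nrow(hits) > 0) {
        fired <- dplyr::bind_rows(fired, tibble::tibble(
          patient_id = hits$patient_id, fired_rule = combos$name[i],
          category = combos$category[i]))
      }
    }
  }

  # component-wise max for the rest
  rest <- components |>
    dplyr::filter(!.data$patient_id %in% fired$patient_id)
  rest$comp_category <- classify_agents_df(rest, rules, bsa_m2 = config$bsa_m2,
                                           missing_dose = config$missing_dose)
  max_assign <- rest |>
    dplyr::mutate(rank = risk_rank(.data$comp_category)) |>
    dplyr::summarise(
      category = if (all(is.na(.data$rank))) "unknown" else
        risk_levels()[5 - max(.data$rank, na.rm = TRUE)],
      .by = "patient_id"
    ) |>
    dplyr::mutate(fired_rule = ifelse(.data$category == "unknown", "unknown",
                                      "max-of-components"))

  labels <- components |>
    dplyr::arrange(.data$patient_id, .data$drug_id, .data$route) |>
    dplyr::summarise(regimen = paste(unique(.data$drug_id), collapse = "+"),
                     .by = "patient_id")

  dplyr::bind_rows(fired, max_assign) |>
    dplyr::left_join(labels, by = "patient_id") |>
    dplyr::mutate(regimen = ifelse(.data$fired_rule %in%
                                     c("max-of-components", "unknown"),
                                   .data$regimen, .data$fired_rule)) |>
    dplyr::left_join(dplyr::select(cohort, "patient_id", "cancer_type",
                                   "route_group"), by = "patient_id") |>
    dplyr::mutate(guideline = rules$guideline) |>
    dplyr::select("patient_id", "cancer_type", "route_group", "regimen",
                  "guideline", "category", "fired_rule") |>
    dplyr::arrange(.data$patient_id)
}
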