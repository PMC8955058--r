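#' Load a packaged guideline rule table
#'
#' Reads the versioned rule files that map single agents (with dose-per-BSA
#' tiers) and named drug combinations to emetic-risk categories under one
#' guideline system. Single-agent tiers are resolved against the dose divided
#' by an assumed body surface area (see [dose_per_bsa()]); combination rules
#' assign a category to a whole regimen and take precedence over
#' component-wise classification.
#'
#' Rule files are plain CSV shipped under `inst/extdata/rules/`; users may
#' point `agents_file`/`combinations_file` at extended copies. Combination
#' overrides are defined for the JSCO system (the system the tiered dose
#' rules and named-regimen overrides were written for); the other systems
#' load with an empty combination set.
#'
#' @param guideline One of `"JSCO"`, `"ASCO"`, `"NCCN"`, `"MASCC"`.
#' @param agents_file,combinations_file Optional paths overriding the
#'   packaged rule files.
#' @return A list of class `cinv_rules` with elements `guideline`, `agents`
#'   (tibble of single-agent rows), `combinations` (tibble of combination
#'   rules with a `components` list-column), and `version`.
#' @export
#' @examples
#' rules <- load_guideline_table("JSCO")
#' head(rules$agents)
load_guideline_table <- function(guideline = c("JSCO", "ASCO", "NCCN", "MASCC"),
                                 agents_file = NULL, combinations_file = NULL) {
  guideline <- match.arg(guideline)
  if (is.null(agents_file)) {
    agents_file <- system.file("extdata", "rules",
                               paste0(tolower(guideline), "_agents.csv"),
                               package = "cinvaudit", mustWork = TRUE)
  }
  version <- read_rules_version(agents_file)
  agents <- readr::read_csv(agents_file, comment = "#", show_col_types = FALSE,
                            col_types = readr::cols(
                              drug_id = readr::col_character(),
                              route = readr::col_character(),
                              tier_bound = readr::col_double(),
                              bound_unit = readr::col_character(),
                              bound_op = readr::col_character(),
                              category = readr::col_character(),
                              default_category = readr::col_character(),
                              fallback_category = readr::col_character()
                            ))
  validate_agent_rules(agents, agents_file)

  combinations <- empty_combination_rules()
  if (guideline == "JSCO" || !is.null(combinations_file)) {
    if (is.null(combinations_file)) {
      combinations_file <- system.file("extdata", "rules",
                                       "jsco_combinations.csv",
                                       package = "cinvaudit", mustWork = TRUE)
    }
    combinations <- readr::read_csv(combinations_file, comment = "#",
                                    show_col_types = FALSE,
                                    col_types = readr::cols(.default = readr::col_character()))
    validate_combination_rules(combinations, combinations_file)
    combinations <- combinations |>
      dplyr::mutate(
        components = strsplit(.data$components, "|", fixed = TRUE),
        n_components = lengths(.data$components),
        has_context = !is.na(.data$cancer_context)
      ) |>
      # specificity order: more components first, context-restricted before
      # unrestricted, then lexicographic name as the deterministic tie-break
      dplyr::arrange(dplyr::desc(.data$n_components),
                     dplyr::desc(.data$has_context), .data$name)
  }

  structure(list(guideline = guideline, agents = agents,
                 combinations = combinations, version = version),
            class = "cinv_rules")
}

empty_combination_rules <- function() {
  tibble::tibble(name = character(), components = list(),
                 route = character(), cancer_context = character(),
                 category = character(), n_components = integer(),
                 has_context = logical())
}

read_rules_version <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^# *rules_version:", first)) {
    sub("^# *rules_version: *([^ ]+).*$", "\\1", first)
  } else {
    NA_character_
  }
}

validate_agent_rules <- function(agents, file) {
  needed <- c("drug_id", "route", "tier_bound", "bound_unit", "bound_op",
              "category", "default_category", "fallback_category")
  missing <- setdiff(needed, names(agents))
  if (length(missing) > 0) {
    stop(sprintf("rule file %s: missing column(s) %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad_cat <- which(!(agents$category %in% risk_levels()) |
                     !(agents$default_category %in% risk_levels()))
  if (length(bad_cat) > 0) {
    stop(sprintf("rule file %s: row %d, column category: invalid category",
                 file, bad_cat[1] + 1L), call. = FALSE)
  }
  bad_op <- which(!is.na(agents$bound_op) & !agents$bound_op %in% c("gt", "ge"))
  if (length(bad_op) > 0) {
    stop(sprintf("rule file %s: row %d, column bound_op: expected gt or ge",
                 file, bad_op[1] + 1L), call. = FALSE)
  }
  # a drug/route pair must have one default and strictly increasing tiers
  chk <- split(agents, paste(agents$drug_id, agents$route))
  for (g in chk) {
    if (length(unique(g$default_category)) != 1) {
      stop(sprintf("rule file %s: drug %s/%s has conflicting default_category",
                   file, g$drug_id[1], g$route[1]), call. = FALSE)
    }
    tiers <- sort(g$tier_bound[!is.na(g$tier_bound)])
    if (anyDuplicated(tiers) || is.unsorted(tiers, strictly = TRUE)) {
      stop(sprintf("rule file %s: drug %s/%s tiers not strictly increasing",
                   file, g$drug_id[1], g$route[1]), call. = FALSE)
    }
  }
  invisible(agents)
}

validate_combination_rules <- function(rules, file) {
  needed <- c("name", "components", "route", "cancer_context", "category")
  missing <- setdiff(needed, names(rules))
  if (length(missing) > 0) {
    stop(sprintf("rule file %s: missing column(s) %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!rules$category %in% risk_levels())
  if (length(bad) > 0) {
    stop(sprintf("rule file %s: row %d, column category: invalid category",
                 file, bad[1] + 1L), call. = FALSE)
  }
  invisible(rules)
}

#' Load the drug canonicalization dictionary
#'
#' Maps raw claim drug names (including regimen-sheet abbreviations such as
#' CDDP, L-OHP, 5-FU) to canonical drug identifiers and a drug class
#' (`chemotherapy`, `NK1`, `serotonin_antagonist`, `steroid`, `other`).
#'
#' @param path Optional path to a custom dictionary CSV with columns
#'   `raw_name`, `drug_id`, `drug_class`.
#' @return Tibble with columns `raw_name`, `drug_id`, `drug_class`.
#' @export
load_drug_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rules", "drug_dictionary.csv",
                        package = "cinvaudit", mustWork = TRUE)
  }
  dict <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  assert_in(dict$drug_class,
            c("chemotherapy", antiemetic_classes(), "other"), "drug_class")
  dict
}

#' Canonicalize raw claim drug names
#'
#' Replaces `drug_id` in a claims table by its canonical form and fills
#' `drug_class` from the dictionary. Unrecognised names are kept as-is with
#' class `other` and a warning.
#'
#' @param claims Claims tibble with at least a `drug_id` column.
#' @param dictionary Dictionary as returned by [load_drug_dictionary()].
#' @return The claims tibble with canonical `drug_id` and `drug_class`.
#' @export
canonicalize_claims <- function(claims, dictionary = load_drug_dictionary()) {
  idx <- match(claims$drug_id, dictionary$raw_name)
  unknown <- is.na(idx)
  if (any(unknown)) {
    warning(sprintf("%d claim rows with unrecognised drug names kept as class 'other' (e.g. %s)",
                    sum(unknown), claims$drug_id[which(unknown)[1]]), call. = FALSE)
  }
  claims$drug_class <- ifelse(unknown, "other", dictionary$drug_class[idx])
  claims$drug_id <- ifelse(unknown, claims$drug_id, dictionary$drug_id[idx])
  claims
}

#' Convert an absolute dose to dose per body surface area
#'
#' Claims record absolute milligram doses; guideline dose tiers are written
#' per square metre of body surface area (BSA). Patient-level BSA is absent
#' from claims, so a population-average BSA of 1.48 m2 (average Japanese
#' adult) is assumed by default.
#'
#' @param dose_mg Administered dose in mg (vectorised, must be >= 0).
#' @param bsa_m2 Assumed body surface area in m2 (> 0).
#' @return Dose in mg/m2.
#' @export
#' @examples
#' dose_per_bsa(2220) # 1500 mg/m2
dose_per_bsa <- function(dose_mg, bsa_m2 = 1.48) {
  if (!is.numeric(bsa_m2) || length(bsa_m2) != 1 || is.na(bsa_m2) || bsa_m2 <= 0) {
    stop("bsa_m2 must be a single positive number", call. = FALSE)
  }
  if (any(dose_mg < 0, na.rm = TRUE)) {
    stop("dose_mg must be non-negative", call. = FALSE)
  }
  dose_mg / bsa_m2
}

# Vectorised single-agent classification over a data frame of
# (drug_id, route, dose_mg). Returns a character vector of categories.
# Tier semantics: start from the drug/route default, then apply tiers in
# increasing bound order; a tier fires when dose (mg/m2, or raw mg for
# absolute-mg bounds) is > / >= its bound. Missing dose on a tiered drug
# resolves to the documented fallback tier (or "unknown" under
# missing_dose = "unknown") with a warning.
classify_agents_df <- function(df, rules, bsa_m2 = 1.48,
                               missing_dose = c("fallback", "unknown"),
                               auc = NULL, quiet = FALSE) {
  missing_dose <- match.arg(missing_dose)
  agents <- rules$agents
  defaults <- dplyr::distinct(agents, .data$drug_id, .data$route,
                              .data$default_category, .data$fallback_category)
  n <- nrow(df)
  key <- paste(df$drug_id, df$route)
  dkey <- paste(defaults$drug_id, defaults$route)
  idx <- match(key, dkey)
  out <- ifelse(is.na(idx), "unknown", defaults$default_category[idx])

  tiers <- agents[!is.na(agents$tier_bound), , drop = FALSE]
  if (nrow(tiers) > 0) {
    tiers <- tiers[order(tiers$tier_bound), , drop = FALSE]
    tkey <- paste(tiers$drug_id, tiers$route)
    tiered <- key %in% tkey
    miss <- tiered & is.na(df$dose_mg)
    if (any(miss)) {
      if (missing_dose == "fallback") {
        fb <- defaults$fallback_category[idx[miss]]
        out[miss] <- ifelse(is.na(fb), "unknown", fb)
        if (!quiet) {
          warning(sprintf("%d dose-tiered administration(s) with missing dose resolved to the fallback tier",
                          sum(miss)), call. = FALSE)
        }
      } else {
        out[miss] <- "unknown"
      }
    }
    hit <- tiered & !is.na(df$dose_mg)
    if (any(hit)) {
      for (j in seq_len(nrow(tiers))) {
        sel <- hit & key == tkey[j]
        if (!any(sel)) next
        basis <- if (tiers$bound_unit[j] == "mg") df$dose_mg[sel] else
          dose_per_bsa(df$dose_mg[sel], bsa_m2)
        ok <- if (tiers$bound_op[j] == "gt") basis > tiers$tier_bound[j] else
          basis >= tiers$tier_bound[j]
        out[sel][ok] <- tiers$category[j]
      }
    }
  }

  # NCCN grades carboplatin by AUC, which mg doses cannot recover; an
  # explicit AUC resolves the tier, otherwise moderate with a warning.
  if (rules$guideline == "NCCN") {
    carbo <- df$drug_id == "carboplatin"
    if (any(carbo)) {
      aucv <- if (is.null(auc)) rep(NA_real_, n) else rep_len(auc, n)
      out[carbo & !is.na(aucv) & aucv >= 4] <- "high"
      out[carbo & !is.na(aucv) & aucv < 4] <- "moderate"
      if (any(carbo & is.na(aucv)) && !quiet) {
        warning("carboplatin without AUC under NCCN resolved to moderate",
                call. = FALSE)
      }
    }
  }
  out
}

#' Classify a single chemotherapy agent
#'
#' Resolves one drug administration to an emetic-risk category under a
#' guideline system. Dose-tiered drugs (cyclophosphamide, methotrexate,
#' cytarabine, and the NCCN anthracycline thresholds) are resolved via the
#' dose per assumed body surface area; dose-independent drugs via their
#' table category. Drugs absent from the rule table return `"unknown"`.
#'
#' @param drug_id Canonical drug name.
#' @param dose_mg Administered dose in mg, or `NA` when not recorded.
#' @param route `"IV"`, `"PO"` or `"arterial"`.
#' @param guideline Guideline id or a `cinv_rules` object from
#'   [load_guideline_table()].
#' @param bsa_m2 Assumed body surface area, m2.
#' @param auc Optional carboplatin AUC (used by the NCCN rule only).
#' @param missing_dose `"fallback"` (default: resolve a tiered drug with
#'   missing dose to its documented fallback tier, with a warning) or
#'   `"unknown"`.
#' @return One of [risk_levels()].
#' @export
#' @examples
#' classify_single_agent("cisplatin", 80, "IV")
#' classify_single_agent("methotrexate", 59.2, "IV") # 40 mg/m2 -> low
classify_single_agent <- function(drug_id, dose_mg = NA_real_, route = "IV",
                                  guideline = "JSCO", bsa_m2 = 1.48,
                                  auc = NULL,
                                  missing_dose = c("fallback", "unknown")) {
  rules <- if (inherits(guideline, "cinv_rules")) guideline else
    load_guideline_table(guideline)
  df <- tibble::tibble(drug_id = drug_id, route = route,
                       dose_mg = as.numeric(dose_mg))
  classify_agents_df(df, rules, bsa_m2 = bsa_m2,
                     missing_dose = missing_dose, auc = auc)
}

#' Compare a drug's emetic-risk category across guideline systems
#'
#' @inheritParams classify_single_agent
#' @param rules_list Optional pre-loaded named list of `cinv_rules` (one per
#'   guideline), to avoid re-reading the packaged files in a loop.
#' @return Named character vector with one category per guideline.
#' @export
#' @examples
#' compare_guidelines("cetuximab")
compare_guidelines <- function(drug_id, dose_mg = NA_real_, route = "IV",
                               bsa_m2 = 1.48, auc = NULL, rules_list = NULL,
                               missing_dose = c("fallback", "unknown")) {
  missing_dose <- match.arg(missing_dose)
  if (is.null(rules_list)) {
    rules_list <- lapply(setNames(nm = guideline_ids()), load_guideline_table)
  }
  vapply(guideline_ids(), function(g) {
    suppressWarnings(
      classify_single_agent(drug_id, dose_mg, route, rules_list[[g]],
                            bsa_m2 = bsa_m2, auc = auc,
                            missing_dose = missing_dose)
    )
  }, character(1))
}
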