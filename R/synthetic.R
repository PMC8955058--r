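daily8 <- "0;1;2;3;4;5;6;7"

#' Synthetic regimen catalogue
#'
#' One row per regimen component: the named regimens used by the synthetic
#' generator, their cancer type, intended risk cell, within-cell prescription
#' share, and the component drugs with route, dose (mg) and administration-day
#' offsets (0 = course start). `attr_offset` marks the day offset on which
#' prophylaxis is attributable (7 for regimens whose high-risk component is
#' added on day 8, 0 otherwise). Rows with `drug_class = "steroid"` are
#' supportive steroids that are part of the regimen itself (CHOP's
#' prednisolone) and are emitted as steroid-class claims, not chemotherapy.
#'
#' @return Tibble of regimen components.
#' @export
regimen_catalog <- function() {
  tibble::tribble(
    ~regimen, ~cancer_type, ~risk, ~share, ~drug_id, ~drug_class, ~route, ~dose_mg, ~days, ~attr_offset,
    "CDDP+PEM", "non_small_cell_lung", "high", 0.353, "cisplatin", "chemotherapy", "IV", 118, "0", 0,
    "CDDP+PEM", "non_small_cell_lung", "high", 0.353, "pemetrexed", "chemotherapy", "IV", 740, "0", 0,
    "NP", "non_small_cell_lung", "high", 0.356, "cisplatin", "chemotherapy", "IV", 118, "0", 0,
    "NP", "non_small_cell_lung", "high", 0.356, "vinorelbine", "chemotherapy", "IV", 37, "0;7", 0,
    "TC-lung", "non_small_cell_lung", "moderate", 0.488, "carboplatin", "chemotherapy", "IV", 600, "0", 0,
    "TC-lung", "non_small_cell_lung", "moderate", 0.488, "paclitaxel", "chemotherapy", "IV", 296, "0", 0,
    "UFT-lung", "non_small_cell_lung", "low", 0.530, "uft", "chemotherapy", "PO", 400, daily8, 0,
    "Pemetrexed", "non_small_cell_lung", "low", 0.386, "pemetrexed", "chemotherapy", "IV", 740, "0", 0,
    "Gefitinib", "non_small_cell_lung", "minimal", 0.496, "gefitinib", "chemotherapy", "PO", 250, daily8, 0,
    "Erlotinib", "non_small_cell_lung", "minimal", 0.304, "erlotinib", "chemotherapy", "PO", 150, daily8, 0,
    "FOLFOXIRI", "colorectal", "high", 1.000, "fluorouracil", "chemotherapy", "IV", 4800, "0", 0,
    "FOLFOXIRI", "colorectal", "high", 1.000, "levofolinate", "chemotherapy", "IV", 296, "0", 0,
    "FOLFOXIRI", "colorectal", "high", 1.000, "oxaliplatin", "chemotherapy", "IV", 126, "0", 0,
    "FOLFOXIRI", "colorectal", "high", 1.000, "irinotecan", "chemotherapy", "IV", 245, "0", 0,
    "CAPOX", "colorectal", "moderate", 0.587, "capecitabine", "chemotherapy", "PO", 3000, daily8, 0,
    "CAPOX", "colorectal", "moderate", 0.587, "oxaliplatin", "chemotherapy", "IV", 190, "0", 0,
    "FOLFOX", "colorectal", "moderate", 0.221, "fluorouracil", "chemotherapy", "IV", 3500, "0;1", 0,
    "FOLFOX", "colorectal", "moderate", 0.221, "levofolinate", "chemotherapy", "IV", 296, "0", 0,
    "FOLFOX", "colorectal", "moderate", 0.221, "oxaliplatin", "chemotherapy", "IV", 126, "0", 0,
    "Capecitabine", "colorectal", "low", 0.385, "capecitabine", "chemotherapy", "PO", 3600, daily8, 0,
    "UFT+LV", "colorectal", "low", 0.365, "uft", "chemotherapy", "PO", 400, daily8, 0,
    "UFT+LV", "colorectal", "low", 0.365, "folinate", "chemotherapy", "PO", 75, daily8, 0,
    "Panitumumab", "colorectal", "minimal", 0.179, "panitumumab", "chemotherapy", "IV", 888, "0", 0,
    "Regorafenib", "colorectal", "minimal", 0.149, "regorafenib", "chemotherapy", "PO", 160, daily8, 0,
    "FEC", "breast", "high", 0.431, "fluorouracil", "chemotherapy", "IV", 740, "0", 0,
    "FEC", "breast", "high", 0.431, "epirubicin", "chemotherapy", "IV", 148, "0", 0,
    "FEC", "breast", "high", 0.431, "cyclophosphamide", "chemotherapy", "IV", 740, "0", 0,
    "EC", "breast", "high", 0.319, "epirubicin", "chemotherapy", "IV", 133, "0", 0,
    "EC", "breast", "high", 0.319, "cyclophosphamide", "chemotherapy", "IV", 888, "0", 0,
    "AC", "breast", "high", 0.246, "doxorubicin", "chemotherapy", "IV", 89, "0", 0,
    "AC", "breast", "high", 0.246, "cyclophosphamide", "chemotherapy", "IV", 888, "0", 0,
    "TC-breast", "breast", "moderate", 0.858, "docetaxel", "chemotherapy", "IV", 111, "0", 0,
    "TC-breast", "breast", "moderate", 0.858, "cyclophosphamide", "chemotherapy", "IV", 888, "0", 0,
    "PTX", "breast", "low", 0.350, "paclitaxel", "chemotherapy", "IV", 133, "0;7", 0,
    "Trastuzumab+PTX", "breast", "low", 0.170, "trastuzumab", "chemotherapy", "IV", 518, "0", 0,
    "Trastuzumab+PTX", "breast", "low", 0.170, "paclitaxel", "chemotherapy", "IV", 133, "0;7", 0,
    "DTX", "breast", "low", 0.129, "docetaxel", "chemotherapy", "IV", 111, "0", 0,
    "Trastuzumab", "breast", "minimal", 0.747, "trastuzumab", "chemotherapy", "IV", 518, "0", 0,
    "S-1+CDDP", "gastric", "high", 0.644, "s1", "chemotherapy", "PO", 120, daily8, 7,
    "S-1+CDDP", "gastric", "high", 0.644, "cisplatin", "chemotherapy", "IV", 89, "7", 7,
    "Cape+CDDP", "gastric", "high", 0.177, "capecitabine", "chemotherapy", "PO", 2500, daily8, 0,
    "Cape+CDDP", "gastric", "high", 0.177, "cisplatin", "chemotherapy", "IV", 118, "0", 0,
    "SOX", "gastric", "moderate", 0.684, "s1", "chemotherapy", "PO", 120, daily8, 0,
    "SOX", "gastric", "moderate", 0.684, "oxaliplatin", "chemotherapy", "IV", 148, "0", 0,
    "S-1-gastric", "gastric", "low", 0.887, "s1", "chemotherapy", "PO", 120, daily8, 0,
    "Nivolumab", "gastric", "minimal", 0.039, "nivolumab", "chemotherapy", "IV", 240, "0", 0,
    "Ramucirumab", "gastric", "minimal", 0.036, "ramucirumab", "chemotherapy", "IV", 444, "0", 0,
    "CHOP", "malignant_lymphoma", "high", 0.841, "cyclophosphamide", "chemotherapy", "IV", 1110, "0", 0,
    "CHOP", "malignant_lymphoma", "high", 0.841, "doxorubicin", "chemotherapy", "IV", 74, "0", 0,
    "CHOP", "malignant_lymphoma", "high", 0.841, "vincristine", "chemotherapy", "IV", 2, "0", 0,
    "CHOP", "malignant_lymphoma", "high", 0.841, "rituximab", "chemotherapy", "IV", 550, "0", 0,
    "CHOP", "malignant_lymphoma", "high", 0.841, "prednisolone", "steroid", "PO", 100, "0;1;2;3;4", 0,
    "CPM-lt1500", "malignant_lymphoma", "moderate", 0.651, "cyclophosphamide", "chemotherapy", "IV", 740, "0", 0,
    "Rituximab", "malignant_lymphoma", "minimal", 1.000, "rituximab", "chemotherapy", "IV", 550, "0", 0,
    "FOLFIRINOX", "pancreatic", "high", 1.000, "oxaliplatin", "chemotherapy", "IV", 126, "0", 0,
    "FOLFIRINOX", "pancreatic", "high", 1.000, "irinotecan", "chemotherapy", "IV", 266, "0", 0,
    "FOLFIRINOX", "pancreatic", "high", 1.000, "fluorouracil", "chemotherapy", "IV", 3552, "0", 0,
    "FOLFIRINOX", "pancreatic", "high", 1.000, "levofolinate", "chemotherapy", "IV", 296, "0", 0,
    "GEM+nab-PTX", "pancreatic", "moderate", 0.913, "gemcitabine", "chemotherapy", "IV", 1480, "0;7", 0,
    "GEM+nab-PTX", "pancreatic", "moderate", 0.913, "nab-paclitaxel", "chemotherapy", "IV", 185, "0;7", 0,
    "GS", "pancreatic", "moderate", 0.087, "gemcitabine", "chemotherapy", "IV", 1480, "0;7", 0,
    "GS", "pancreatic", "moderate", 0.087, "s1", "chemotherapy", "PO", 120, daily8, 0,
    "S-1-panc", "pancreatic", "low", 0.696, "s1", "chemotherapy", "PO", 120, daily8, 0,
    "GEM", "pancreatic", "low", 0.292, "gemcitabine", "chemotherapy", "IV", 1480, "0;7", 0,
    "FP", "oesophageal", "high", 0.775, "fluorouracil", "chemotherapy", "IV", 1184, "0;1;2;3;4", 0,
    "FP", "oesophageal", "high", 0.775, "cisplatin", "chemotherapy", "IV", 104, "0", 0,
    "DCF", "oesophageal", "high", 0.176, "docetaxel", "chemotherapy", "IV", 89, "0", 0,
    "DCF", "oesophageal", "high", 0.176, "cisplatin", "chemotherapy", "IV", 104, "0", 0,
    "DCF", "oesophageal", "high", 0.176, "fluorouracil", "chemotherapy", "IV", 1110, "0;1;2;3;4", 0,
    "Nedaplatin+5-FU", "oesophageal", "moderate", 0.638, "nedaplatin", "chemotherapy", "IV", 133, "0", 0,
    "Nedaplatin+5-FU", "oesophageal", "moderate", 0.638, "fluorouracil", "chemotherapy", "IV", 1184, "0;1;2", 0,
    "DTX-oeso", "oesophageal", "low", 0.124, "docetaxel", "chemotherapy", "IV", 104, "0", 0,
    "PE", "small_cell_lung", "high", 0.690, "cisplatin", "chemotherapy", "IV", 118, "0", 0,
    "PE", "small_cell_lung", "high", 0.690, "etoposide", "chemotherapy", "IV", 148, "0;1;2", 0,
    "PI", "small_cell_lung", "high", 0.303, "cisplatin", "chemotherapy", "IV", 89, "0", 0,
    "PI", "small_cell_lung", "high", 0.303, "irinotecan", "chemotherapy", "IV", 89, "0;7", 0,
    "CBDCA+etoposide", "small_cell_lung", "moderate", 0.888, "carboplatin", "chemotherapy", "IV", 625, "0", 0,
    "CBDCA+etoposide", "small_cell_lung", "moderate", 0.888, "etoposide", "chemotherapy", "IV", 148, "0;1;2", 0,
    "CBDCA+CPT11", "small_cell_lung", "moderate", 0.058, "carboplatin", "chemotherapy", "IV", 625, "0", 0,
    "CBDCA+CPT11", "small_cell_lung", "moderate", 0.058, "irinotecan", "chemotherapy", "IV", 74, "0;7", 0,
    "CPT11", "small_cell_lung", "low", 0.413, "irinotecan", "chemotherapy", "IV", 148, "0;7", 0,
    "CDDP-other", "other", "high", 1.000, "cisplatin", "chemotherapy", "IV", 118, "0", 0,
    "CBDCA-other", "other", "moderate", 1.000, "carboplatin", "chemotherapy", "IV", 600, "0", 0,
    "PTX-other", "other", "low", 0.500, "paclitaxel", "chemotherapy", "IV", 148, "0;7", 0,
    "GEM-other", "other", "low", 0.500, "gemcitabine", "chemotherapy", "IV", 1480, "0;7", 0,
    "Sorafenib", "other", "minimal", 0.600, "sorafenib", "chemotherapy", "PO", 800, daily8, 0,
    "Cetuximab-other", "other", "minimal", 0.400, "cetuximab", "chemotherapy", "IV", 592, "0", 0
  )
}

#' Default synthetic-study configuration
#'
#' Study-condition defaults for the synthetic linked registry + claims
#' generator: the cancer-type mixture and per-cancer risk-cell splits follow
#' the published cohort composition; within-cell regimen shares come from the
#' regimen catalogue (renormalised within each cell); prophylaxis mixing
#' probabilities per route group and risk category follow the published
#' prescription-rate columns (renormalised from one-decimal percentages).
#'
#' @param n_patients Number of patients to simulate.
#' @param timing_noise Probability that a patient's antiemetic claims are
#'   displaced outside every attribution window.
#' @param oral_lookback_frac Probability that a patient's prophylaxis is
#'   issued as oral prescriptions in the 30 days before the course start
#'   rather than on the attribution date.
#' @param exclusion_rates Named list of per-reason probabilities for
#'   exclusion-triggering noise (at most one reason is injected per patient).
#' @return A list of class `cinv_sim_config`.
#' @export
default_config <- function(n_patients = 2000, timing_noise = 0,
                           oral_lookback_frac = 0.3,
                           exclusion_rates = list(
                             interferon_alpha = 0.002,
                             same_day_surgery_or_drainage = 0.004,
                             arterial_route = 0.002,
                             hsct_within_3_weeks = 0.002,
                             under_20 = 0.002,
                             no_chemo = 0.002
                           )) {
  cancer_mix <- c(non_small_cell_lung = 0.141, colorectal = 0.129,
                  breast = 0.099, gastric = 0.093, malignant_lymphoma = 0.080,
                  pancreatic = 0.064, oesophageal = 0.043,
                  small_cell_lung = 0.025, other = 0.326)
  risk_mix <- tibble::tribble(
    ~cancer_type, ~high, ~moderate, ~low, ~minimal,
    "non_small_cell_lung", 0.250, 0.300, 0.250, 0.200,
    "colorectal",          0.020, 0.404, 0.552, 0.024,
    "breast",              0.538, 0.250, 0.150, 0.062,
    "gastric",             0.150, 0.160, 0.602, 0.088,
    "malignant_lymphoma",  0.602, 0.300, 0.000, 0.098,
    "pancreatic",          0.030, 0.442, 0.528, 0.000,
    "oesophageal",         0.803, 0.130, 0.067, 0.000,
    "small_cell_lung",     0.350, 0.599, 0.051, 0.000,
    "other",               0.150, 0.300, 0.400, 0.150
  ) |>
    tidyr::pivot_longer(-"cancer_type", names_to = "risk",
                        values_to = "risk_prob")
  # Table-5-shaped mixing probabilities (IV and oral columns per risk
  # category), renormalised from printed one-decimal percentages
  prophylaxis_probs <- tibble::tribble(
    ~route_group, ~risk, ~triple, ~serotonin_plus_dex, ~serotonin_only, ~dex_only, ~none_of_above,
    "intravenous_group", "high",     70.7, 24.7,  1.8,  0.5,  1.2,
    "oral_group",        "high",      4.6, 34.9, 10.5, 16.4, 32.9,
    "intravenous_group", "moderate", 24.0, 59.1,  3.7,  2.7,  8.6,
    "oral_group",        "moderate",  0.0, 10.6, 13.7, 10.6, 64.6,
    "intravenous_group", "low",       2.1, 31.6,  4.7, 46.9, 13.3,
    "oral_group",        "low",       0.4,  0.8,  0.6,  3.6, 93.8,
    "intravenous_group", "minimal",   0.2,  5.0,  0.9, 30.0, 63.1,
    "oral_group",        "minimal",   0.0,  0.1,  0.2,  2.6, 96.8
  ) |>
    tidyr::pivot_longer(-c("route_group", "risk"), names_to = "category",
                        values_to = "prob") |>
    dplyr::mutate(prob = .data$prob / sum(.data$prob),
                  .by = c("route_group", "risk"))
  structure(list(
    n_patients = n_patients, diagnosis_year = 2016,
    cancer_mix = cancer_mix, risk_mix = risk_mix,
    catalog = regimen_catalog(), prophylaxis_probs = prophylaxis_probs,
    oral_lookback_frac = oral_lookback_frac, timing_noise = timing_noise,
    exclusion_rates = exclusion_rates,
    age_mean = 65.9, age_sd = 12.0, male_frac = 0.547, resected_frac = 0.5,
    stage_probs = c("0" = 0.021, I = 0.143, II = 0.182, III = 0.246,
                    IV = 0.313, unknown = 0.095)
  ), class = "cinv_sim_config")
}

#' Validate a synthetic-study configuration
#'
#' @param config A `cinv_sim_config`.
#' @return `config`, invisibly; errors describe the first violated invariant.
#' @export
validate_sim_config <- function(config) {
  stopifnot(is.numeric(config$n_patients), config$n_patients > 0)
  if (abs(sum(config$cancer_mix) - 1) > 1e-9) {
    stop("cancer_mix must sum to 1", call. = FALSE)
  }
  active <- names(config$cancer_mix)[config$cancer_mix > 0]
  rm_active <- config$risk_mix[config$risk_mix$cancer_type %in% active, ]
  rm_sums <- tapply(rm_active$risk_prob, rm_active$cancer_type, sum)
  if (any(abs(rm_sums - 1) > 1e-9)) {
    stop("risk_mix rows must sum to 1 for every cancer type with mixture mass",
         call. = FALSE)
  }
  pp_sums <- config$prophylaxis_probs |>
    dplyr::summarise(s = sum(.data$prob), .by = c("route_group", "risk"))
  if (any(abs(pp_sums$s - 1) > 1e-9)) {
    stop("prophylaxis_probs must sum to 1 within route group x risk",
         call. = FALSE)
  }
  rates <- unlist(config$exclusion_rates)
  if (any(rates < 0 | rates > 1) || sum(rates) > 1) {
    stop("exclusion_rates must be probabilities with sum <= 1", call. = FALSE)
  }
  stopifnot(config$timing_noise >= 0, config$timing_noise <= 1,
            config$oral_lookback_frac >= 0, config$oral_lookback_frac <= 1)
  shares <- dplyr::distinct(config$catalog, .data$regimen, .data$cancer_type,
                            .data$risk, .data$share)
  pos <- rm_active[rm_active$risk_prob > 0, ]
  missing_cell <- dplyr::anti_join(pos, shares, by = c("cancer_type", "risk"))
  if (nrow(missing_cell) > 0) {
    stop(sprintf("risk_mix assigns probability to a cell with no regimen: %s/%s",
                 missing_cell$cancer_type[1], missing_cell$risk[1]),
         call. = FALSE)
  }
  invisible(config)
}

# regimen-level attributes derived from the catalogue
regimen_attrs <- function(catalog) {
  purrr::map_dfr(split(catalog, catalog$regimen), function(g) {
    ao <- g$attr_offset[1]
    tibble::tibble(
      regimen = g$regimen[1], cancer_type = g$cancer_type[1],
      risk = g$risk[1], share = g$share[1], attr_offset = ao,
      route_group = if (any(g$route == "IV" & g$drug_class == "chemotherapy"))
        "intravenous_group" else "oral_group",
      support_on_attr = any(g$drug_class == "steroid" &
                              vapply(strsplit(g$days, ";", fixed = TRUE),
                                     function(d) as.character(ao) %in% d,
                                     logical(1)))
    )
  })
}

#' Generate a synthetic linked registry + claims dataset
#'
#' Draws each patient's cancer type, risk cell and regimen, emits the
#' regimen's drug administrations at its day offsets inside the 8-day course
#' window, places antiemetic claims according to a sampled prophylaxis
#' category (on the attribution date, or as oral prescriptions in the 30-day
#' lookback, or displaced outside every window for the `timing_noise`
#' fraction), and injects exclusion-triggering noise. Ground truth is
#' consistent with the emitted claims by construction: a regimen's own
#' supportive steroid on the attribution date (CHOP's prednisolone) is part
#' of the recorded true prophylaxis category.
#'
#' @param config A `cinv_sim_config` from [default_config()].
#' @param seed Integer seed; the same (config, seed) pair reproduces the
#'   dataset exactly.
#' @return List of class `cinv_sim` with `registry`, `claims`, `procedures`,
#'   `truth` and `config`.
#' @export
generate_dataset <- function(config = default_config(), seed = 1L) {
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  n <- config$n_patients
  ids <- sprintf("SYN%06d", seq_len(n))
  attrs <- regimen_attrs(config$catalog)
  reg_probs <- attrs |>
    dplyr::inner_join(config$risk_mix, by = c("cancer_type", "risk")) |>
    dplyr::mutate(p = .data$share / sum(.data$share) * .data$risk_prob,
                  .by = c("cancer_type", "risk")) |>
    dplyr::filter(.data$p > 0)

  cancer <- sample(names(config$cancer_mix), n, replace = TRUE,
                   prob = config$cancer_mix)
  regimen <- character(n)
  for (ct in unique(cancer)) {
    rows <- reg_probs[reg_probs$cancer_type == ct, ]
    idx <- which(cancer == ct)
    regimen[idx] <- sample(rows$regimen, length(idx), replace = TRUE,
                           prob = rows$p)
  }
  ri <- match(regimen, attrs$regimen)
  risk <- attrs$risk[ri]
  route_group <- attrs$route_group[ri]
  attr_offset <- attrs$attr_offset[ri]
  support_on_attr <- attrs$support_on_attr[ri]

  sex <- ifelse(runif(n) < config$male_frac, "male", "female")
  age <- round(pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 20), 94))
  clinical_stage <- sample(names(config$stage_probs), n, replace = TRUE,
                           prob = config$stage_probs)
  resected <- runif(n) < config$resected_frac
  pathological_stage <- ifelse(resected, clinical_stage, "unknown")
  dx_date <- as.Date(sprintf("%d-01-01", config$diagnosis_year)) +
    sample(0:334, n, replace = TRUE)
  start_date <- dx_date + sample(5:45, n, replace = TRUE)
  resection_date <- dplyr::if_else(
    resected, pmax(start_date - sample(14:60, n, replace = TRUE), dx_date + 1L),
    as.Date(NA))

  registry <- tibble::tibble(
    patient_id = ids, sex = sex, age_at_dx = age, cancer_type = cancer,
    dx_date = dx_date, clinical_stage = clinical_stage,
    pathological_stage = pathological_stage,
    resection_date = resection_date, adjuvant_flag = resected
  )

  patients <- tibble::tibble(patient_id = ids, regimen = regimen,
                             start_date = start_date)
  chemo_claims <- patients |>
    dplyr::inner_join(config$catalog, by = "regimen",
                      relationship = "many-to-many") |>
    tidyr::separate_rows("days", sep = ";") |>
    dplyr::mutate(date = .data$start_date + as.integer(.data$days)) |>
    dplyr::select("patient_id", "date", "drug_id", "drug_class", "route",
                  "dose_mg")

  # prophylaxis category, sampled per (route group, risk) stratum
  pp <- config$prophylaxis_probs
  proph_sampled <- character(n)
  strat <- paste(route_group, risk)
  for (s in unique(strat)) {
    parts <- strsplit(s, " ")[[1]]
    rows <- pp[pp$route_group == parts[1] & pp$risk == parts[2], ]
    idx <- which(strat == s)
    proph_sampled[idx] <- sample(rows$category, length(idx), replace = TRUE,
                                 prob = rows$prob)
  }

  lookback <- runif(n) < config$oral_lookback_frac & attr_offset == 0
  displaced <- runif(n) < config$timing_noise
  lb_days <- sample(1:30, n, replace = TRUE)

  class_map <- list(
    triple = antiemetic_classes(),
    serotonin_plus_dex = c("serotonin_antagonist", "steroid"),
    serotonin_only = "serotonin_antagonist",
    dex_only = "steroid",
    none_of_above = character()
  )
  ae_drug <- c(NK1 = "aprepitant", serotonin_antagonist = "granisetron",
               steroid = "dexamethasone")
  ae_dose <- c(NK1 = 125, serotonin_antagonist = 3, steroid = 9.9)

  ae_list <- tibble::tibble(
    patient_id = ids, start_date = start_date, attr_offset = attr_offset,
    route_group = route_group, category = proph_sampled,
    lookback = lookback, displaced = displaced, lb_days = lb_days
  ) |>
    dplyr::mutate(drug_class = class_map[.data$category]) |>
    tidyr::unnest_longer("drug_class") |>
    dplyr::mutate(
      drug_id = ae_drug[.data$drug_class],
      dose_mg = ae_dose[.data$drug_class],
      route = dplyr::case_when(
        lookback ~ "PO",
        drug_class == "NK1" ~ "PO",
        route_group == "oral_group" ~ "PO",
        TRUE ~ "IV"
      ),
      date = dplyr::case_when(
        displaced ~ start_date + 12L,
        lookback ~ start_date - lb_days,
        TRUE ~ start_date + attr_offset
      )
    ) |>
    dplyr::select("patient_id", "date", "drug_id", "drug_class", "route",
                  "dose_mg")

  claims <- dplyr::bind_rows(chemo_claims, ae_list) |>
    dplyr::arrange(.data$patient_id, .data$date, .data$drug_id)

  procedures <- tibble::tibble(
    patient_id = ids[resected], date = resection_date[resected],
    kind = "surgery"
  )

  # realized true prophylaxis: displaced claims leave only the regimen's own
  # supportive steroid in an attribution window
  classes_eff <- purrr::pmap(
    list(proph_sampled, displaced, support_on_attr),
    function(cat, disp, sup) {
      cl <- if (disp) character() else class_map[[cat]]
      if (sup) union(cl, "steroid") else cl
    })
  proph_true <- vapply(classes_eff, categorize_prophylaxis, character(1))

  truth <- tibble::tibble(
    patient_id = ids, cancer_type = cancer, regimen = regimen, risk = risk,
    route_group = route_group, prophylaxis_sampled = proph_sampled,
    prophylaxis = proph_true, start_date = start_date,
    displaced = displaced, excluded = FALSE,
    exclusion_reason = NA_character_
  )

  dataset <- structure(list(registry = registry, claims = claims,
                            procedures = procedures, truth = truth,
                            config = config), class = "cinv_sim")
  inject_exclusion_noise(dataset, config$exclusion_rates, seed = NULL)
}

#' Inject exclusion-triggering noise into a synthetic dataset
#'
#' Marks a random subset of patients with one exclusion-triggering construct
#' each: an interferon-alpha course line, a same-day surgery procedure, an
#' arterial-route administration, a stem-cell transplant 14 days after the
#' course start, an under-20 age, or removal of all claims (never treated).
#' Ground truth is updated accordingly.
#'
#' @param dataset A `cinv_sim` from [generate_dataset()].
#' @param rates Named list of per-reason probabilities (see
#'   [default_config()]); their sum is the total injection probability.
#' @param seed Integer seed, or `NULL` to continue the current random stream.
#' @return The modified `cinv_sim`.
#' @export
inject_exclusion_noise <- function(dataset, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rates <- unlist(rates)
  stopifnot(all(rates >= 0), all(rates <= 1), sum(rates) <= 1)
  if (length(rates) == 0 || sum(rates) == 0) return(dataset)
  truth <- dataset$truth
  n <- nrow(truth)
  # one draw per patient; cumulative bins give at most one reason each
  u <- runif(n)
  edges <- cumsum(rates)
  reason <- rep(NA_character_, n)
  lower <- c(0, head(edges, -1))
  for (j in seq_along(rates)) {
    reason[u >= lower[j] & u < edges[j]] <- names(rates)[j]
  }

  pick <- function(r) truth$patient_id[!is.na(reason) & reason == r]
  start_of <- function(id) truth$start_date[match(id, truth$patient_id)]

  reg <- dataset$registry
  claims <- dataset$claims
  procs <- dataset$procedures

  ids_u20 <- pick("under_20")
  reg$age_at_dx[reg$patient_id %in% ids_u20] <- 19

  ids_ifn <- pick("interferon_alpha")
  if (length(ids_ifn) > 0) {
    claims <- dplyr::bind_rows(claims, tibble::tibble(
      patient_id = ids_ifn, date = start_of(ids_ifn),
      drug_id = "interferon-alpha", drug_class = "chemotherapy",
      route = "IV", dose_mg = 600))
  }

  ids_art <- pick("arterial_route")
  if (length(ids_art) > 0) {
    claims <- dplyr::bind_rows(claims, tibble::tibble(
      patient_id = ids_art, date = start_of(ids_art),
      drug_id = "cisplatin", drug_class = "chemotherapy",
      route = "arterial", dose_mg = 59))
  }

  ids_srg <- pick("same_day_surgery_or_drainage")
  if (length(ids_srg) > 0) {
    procs <- dplyr::bind_rows(procs, tibble::tibble(
      patient_id = ids_srg, date = start_of(ids_srg), kind = "surgery"))
  }

  ids_hsct <- pick("hsct_within_3_weeks")
  if (length(ids_hsct) > 0) {
    procs <- dplyr::bind_rows(procs, tibble::tibble(
      patient_id = ids_hsct, date = start_of(ids_hsct) + 14L, kind = "hsct"))
  }

  ids_nochemo <- pick("no_chemo")
  claims <- claims[!claims$patient_id %in% ids_nochemo, , drop = FALSE]

  truth$excluded <- !is.na(reason)
  truth$exclusion_reason <- reason
  dataset$registry <- reg
  dataset$claims <- claims
  dataset$procedures <- procs
  dataset$truth <- truth
  dataset
}

#' Analytically implied marginals of a synthetic configuration
#'
#' The population frequencies the pipeline should recover from a dataset
#' generated under `config` (before exclusion injection): risk-category and
#' route-group shares, and realized prophylaxis-category shares. The
#' prophylaxis marginals account for regimens whose own supportive steroid
#' lands on the attribution date (the sampled category `none_of_above` is
#' then realized as `dex_only`, `serotonin_only` as `serotonin_plus_dex`)
#' and for `timing_noise` displacement.
#'
#' @param config A `cinv_sim_config`.
#' @return List with `regimens` (per-regimen probability table), `risk`,
#'   `route_group` and `prophylaxis` (named probability vectors), and
#'   `prophylaxis_by_stratum` (tibble per route group x risk).
#' @export
implied_marginals <- function(config = default_config()) {
  attrs <- regimen_attrs(config$catalog)
  regs <- attrs |>
    dplyr::inner_join(config$risk_mix, by = c("cancer_type", "risk")) |>
    dplyr::mutate(share_norm = .data$share / sum(.data$share),
                  .by = c("cancer_type", "risk")) |>
    dplyr::mutate(p = config$cancer_mix[.data$cancer_type] *
                    .data$risk_prob * .data$share_norm) |>
    dplyr::filter(.data$p > 0)

  risk <- tapply(regs$p, regs$risk, sum)
  route <- tapply(regs$p, regs$route_group, sum)

  tn <- config$timing_noise
  long <- regs |>
    dplyr::inner_join(config$prophylaxis_probs,
                      by = c("route_group", "risk"),
                      relationship = "many-to-many") |>
    dplyr::mutate(
      realized = dplyr::case_when(
        support_on_attr & category == "none_of_above" ~ "dex_only",
        support_on_attr & category == "serotonin_only" ~ "serotonin_plus_dex",
        TRUE ~ category
      ),
      displaced_to = ifelse(.data$support_on_attr, "dex_only",
                            "none_of_above"),
      w_realized = .data$p * .data$prob * (1 - tn),
      w_displaced = .data$p * .data$prob * tn
    )
  proph_tab <- dplyr::bind_rows(
    dplyr::summarise(long, w = sum(.data$w_realized),
                     .by = c("route_group", "risk", "realized")),
    dplyr::summarise(long, w = sum(.data$w_displaced),
                     .by = c("route_group", "risk", "displaced_to")) |>
      dplyr::rename(realized = "displaced_to")
  ) |>
    dplyr::summarise(w = sum(.data$w),
                     .by = c("route_group", "risk", "realized"))
  proph <- tapply(proph_tab$w, proph_tab$realized, sum) / sum(proph_tab$w)
  by_stratum <- proph_tab |>
    dplyr::mutate(prob = .data$w / sum(.data$w), .by = c("route_group", "risk")) |>
    dplyr::rename(prophylaxis = "realized") |>
    dplyr::select(-"w")

  list(regimens = regs,
       risk = as.numeric(risk) |> setNames(names(risk)),
       route_group = as.numeric(route) |> setNames(names(route)),
       prophylaxis = as.numeric(proph) |> setNames(names(proph)),
       prophylaxis_by_stratum = by_stratum)
}

#' Write a synthetic dataset to disk
#'
#' Emits `registry.csv`, `claims.csv`, `procedures.csv` (the exact schemas
#' consumed by [build_cohort()]), `ground_truth.csv`, and the configuration
#' as `config.yaml`.
#'
#' @param dataset A `cinv_sim`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$registry, file.path(dir, "registry.csv"))
  readr::write_csv(dataset$claims, file.path(dir, "claims.csv"))
  readr::write_csv(dataset$procedures, file.path(dir, "procedures.csv"))
  readr::write_csv(dataset$truth, file.path(dir, "ground_truth.csv"))
  cfg <- dataset$config
  cfg$catalog <- NULL   # the catalogue is code-defined; keep the YAML compact
  cfg$risk_mix <- as.data.frame(cfg$risk_mix)
  cfg$prophylaxis_probs <- as.data.frame(cfg$prophylaxis_probs)
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.data.frame(x)) as.list(x) else x), file.path(dir, "config.yaml"))
  invisible(dir)
}
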