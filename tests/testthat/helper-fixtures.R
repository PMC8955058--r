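# shared rule objects (reading the packaged CSVs once per test run)
jsco_rules <- load_guideline_table("JSCO")
all_rules <- lapply(stats::setNames(nm = guideline_ids()), load_guideline_table)

reg_row <- function(id, cancer = "other", age = 60, sex = "male",
                    dx = as.Date("2016-02-01"), cs = "III", ps = "unknown",
                    resection = as.Date(NA), adjuvant = NA) {
  tibble::tibble(patient_id = id, sex = sex, age_at_dx = age,
                 cancer_type = cancer, dx_date = dx, clinical_stage = cs,
                 pathological_stage = ps, resection_date = resection,
                 adjuvant_flag = adjuvant)
}

claim_row <- function(id, date, drug, class = "chemotherapy", route = "IV",
                      dose = 100) {
  tibble::tibble(patient_id = id, date = as.Date(date), drug_id = drug,
                 drug_class = class, route = route, dose_mg = dose)
}

proc_row <- function(id, date, kind) {
  tibble::tibble(patient_id = id, date = as.Date(date), kind = kind)
}

episode <- function(drugs, routes = "IV", doses = NA_real_,
                    cancer = "other") {
  assemble_regimen(tibble::tibble(drug_id = drugs,
                                  route = rep_len(routes, length(drugs)),
                                  dose_mg = rep_len(doses, length(drugs))),
                   cancer)
}

# independent Clopper-Pearson oracle: invert the binomial CDF numerically
cp_oracle <- function(k, n, alpha = 0.05) {
  lo <- if (k == 0) 0 else
    stats::uniroot(function(p) stats::pbinom(k - 1, n, p) - (1 - alpha / 2),
                   c(0, 1), tol = 1e-14)$root
  hi <- if (k == n) 1 else
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha / 2,
                   c(0, 1), tol = 1e-14)$root
  c(lo, hi)
}
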