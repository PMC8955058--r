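test_that("dose_per_bsa converts absolute mg to mg/m2 under the assumed BSA", {
  expect_equal(dose_per_bsa(2220, 1.48), 1500)
  expect_equal(dose_per_bsa(370, 1.48), 250)
  expect_equal(dose_per_bsa(0, 1.48), 0)
  expect_equal(dose_per_bsa(c(148, 74)), c(100, 50))
  expect_error(dose_per_bsa(-1), "non-negative")
  expect_error(dose_per_bsa(100, 0), "positive")
})

test_that("rule tables load with a version stamp and full drug coverage", {
  expect_s3_class(jsco_rules$agents, "tbl_df")
  expect_equal(jsco_rules$version, "2016.1")
  # every drug of the packaged tables appears once per route
  expect_false(any(duplicated(
    jsco_rules$agents[is.na(jsco_rules$agents$tier_bound),
                      c("drug_id", "route")])))
  # the named combination overrides are present
  expect_setequal(
    jsco_rules$combinations$name,
    c("FOLFOXIRI", "FOLFIRINOX", "GS", "GEM-nabPTX", "ICE", "AC", "EC",
      "oral-etoposide", "nimustine-ml", "ranimustine-ml"))
  # non-JSCO systems carry no combination overrides
  expect_equal(nrow(all_rules$ASCO$combinations), 0)
})

test_that("malformed rule files produce schema errors naming the file", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug_id,route,category", "cisplatin,IV,high"), f)
  suppressWarnings(
    expect_error(load_guideline_table("JSCO", agents_file = f),
                 "missing column"))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug_id,route,tier_bound,bound_unit,bound_op,category,default_category,fallback_category",
               "cisplatin,IV,,,,severe,severe,"), f2)
  expect_error(load_guideline_table("JSCO", agents_file = f2),
               "invalid category")
})

test_that("single agents classify per the packaged JSCO table", {
  expect_equal(classify_single_agent("cisplatin", 80, "IV", jsco_rules), "high")
  expect_equal(classify_single_agent("carboplatin", NA, "IV", jsco_rules),
               "moderate")
  expect_equal(classify_single_agent("methotrexate", 59.2, "IV", jsco_rules),
               "low") # 40 mg/m2
  expect_equal(classify_single_agent("cyclophosphamide", 2960, "IV", jsco_rules),
               "high") # 2000 mg/m2
  expect_equal(classify_single_agent("never-seen-drug", NA, "IV", jsco_rules),
               "unknown")
  # methotrexate is dose-tiered IV but flat minimal as an oral drug
  expect_equal(classify_single_agent("methotrexate", NA, "PO", jsco_rules),
               "minimal")
})

test_that("missing dose on a tiered drug falls back to the middle tier with a warning", {
  expect_warning(
    cat <- classify_single_agent("cyclophosphamide", NA, "IV", jsco_rules),
    "fallback")
  expect_equal(cat, "moderate")
  expect_warning(
    mtx <- classify_single_agent("methotrexate", NA, "IV", jsco_rules))
  expect_equal(mtx, "moderate")
  expect_equal(
    classify_single_agent("methotrexate", NA, "IV", jsco_rules,
                          missing_dose = "unknown"), "unknown")
})

test_that("dose-tier boundaries follow the stated inequalities exactly", {
  bsa <- 1.48
  mtx <- function(mg_m2) classify_single_agent("methotrexate", mg_m2 * bsa,
                                               "IV", jsco_rules, bsa_m2 = bsa)
  expect_equal(mtx(49.9), "low")
  expect_equal(mtx(50), "moderate")    # closed middle interval
  expect_equal(mtx(250), "moderate")   # exactly 250 is not >250
  expect_equal(mtx(250.1), "high")
  cpa <- function(mg_m2) classify_single_agent("cyclophosphamide", mg_m2 * bsa,
                                               "IV", jsco_rules, bsa_m2 = bsa)
  expect_equal(cpa(1500), "moderate")  # >1500 strictly
  expect_equal(cpa(1500.1), "high")
  ara <- function(mg_m2) classify_single_agent("cytarabine", mg_m2 * bsa,
                                               "IV", jsco_rules, bsa_m2 = bsa)
  expect_equal(ara(200), "low")        # >200 strictly
  expect_equal(ara(200.1), "moderate")
})

test_that("tiered categories are monotone non-decreasing in dose", {
  for (drug in c("methotrexate", "cyclophosphamide", "cytarabine")) {
    doses <- seq(0, 4000, by = 25)
    cats <- vapply(doses, function(d)
      classify_single_agent(drug, d, "IV", jsco_rules), character(1))
    ranks <- c(high = 4, moderate = 3, low = 2, minimal = 1)[cats]
    expect_true(all(diff(ranks) >= 0), info = drug)
  }
})

test_that("classification is deterministic and total over the packaged table", {
  ag <- jsco_rules$agents
  df <- tibble::tibble(drug_id = ag$drug_id, route = ag$route, dose_mg = 200)
  a <- cinvaudit:::classify_agents_df(df, jsco_rules)
  b <- cinvaudit:::classify_agents_df(df, jsco_rules)
  expect_identical(a, b)
  expect_true(all(a %in% risk_levels()))
})

test_that("NCCN resolves carboplatin by AUC and anthracyclines by absolute mg", {
  nccn <- all_rules$NCCN
  expect_equal(classify_single_agent("carboplatin", 600, "IV", nccn, auc = 5),
               "high")
  expect_equal(classify_single_agent("carboplatin", 600, "IV", nccn, auc = 3.9),
               "moderate")
  expect_warning(
    noauc <- classify_single_agent("carboplatin", 600, "IV", nccn),
    "AUC")
  expect_equal(noauc, "moderate")
  # doxorubicin >=60 mg and epirubicin >90 mg are absolute-mg thresholds
  expect_equal(classify_single_agent("doxorubicin", 60, "IV", nccn), "high")
  expect_equal(classify_single_agent("doxorubicin", 59, "IV", nccn), "moderate")
  expect_equal(classify_single_agent("epirubicin", 90, "IV", nccn), "moderate")
  expect_equal(classify_single_agent("epirubicin", 91, "IV", nccn), "high")
})

test_that("compare_guidelines reports one category per system", {
  expect_equal(
    compare_guidelines("cetuximab", rules_list = all_rules),
    c(JSCO = "minimal", ASCO = "low", NCCN = "minimal", MASCC = "low"))
  # 444 mg at 1.48 m2 = 300 mg/m2: above the 200 threshold, below 1000
  expect_equal(
    compare_guidelines("cytarabine", 444, rules_list = all_rules),
    c(JSCO = "moderate", ASCO = "low", NCCN = "moderate", MASCC = "low"))
  expect_equal(
    unname(compare_guidelines("cisplatin", 80, rules_list = all_rules)),
    rep("high", 4))
})

test_that("the canonicalization dictionary maps abbreviations and classes", {
  dict <- load_drug_dictionary()
  cl <- claim_row("X", "2016-01-01", c("CDDP", "5-FU", "PSL", "granisetron"))
  expect_warning(out <- canonicalize_claims(
    dplyr::bind_rows(cl, claim_row("X", "2016-01-01", "mystery-drug")), dict),
    "unrecognised")
  expect_equal(out$drug_id[1:4],
               c("cisplatin", "fluorouracil", "prednisolone", "granisetron"))
  expect_equal(out$drug_class,
               c("chemotherapy", "chemotherapy", "steroid",
                 "serotonin_antagonist", "other"))
})
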