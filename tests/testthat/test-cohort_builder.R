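test_that("the first course spans 8 inclusive calendar days from the first event", {
  ev <- claim_row("A", as.Date("2016-03-01") + c(0, 7, 29), "cisplatin")
  cw <- identify_first_course(ev, as.Date("2016-02-01"))
  expect_equal(cw$start_date, as.Date("2016-03-01"))
  expect_equal(cw$end_date, as.Date("2016-03-08"))
  expect_equal(nrow(cw$events), 2) # day 1 and day 8 in; day 30 out

  cw2 <- identify_first_course(claim_row("A", "2016-03-01", "cisplatin"),
                               as.Date("2016-02-01"))
  expect_equal(nrow(cw2$events), 1)

  # day 9 is the first day outside the window
  ev3 <- claim_row("A", as.Date("2016-03-01") + c(0, 8), "cisplatin")
  cw3 <- identify_first_course(ev3, as.Date("2016-02-01"))
  expect_equal(nrow(cw3$events), 1)

  # pre-diagnosis events never start a course
  ev4 <- claim_row("A", as.Date(c("2016-01-15", "2016-03-01")), "cisplatin")
  cw4 <- identify_first_course(ev4, as.Date("2016-02-01"))
  expect_equal(cw4$start_date, as.Date("2016-03-01"))
  expect_null(identify_first_course(ev4[1, ], as.Date("2016-02-01")))
})

test_that("each exclusion rule fires on its own trigger and not otherwise", {
  rec <- reg_row("A")
  course <- identify_first_course(claim_row("A", "2016-03-01", "cisplatin"),
                                  rec$dx_date)
  clean <- apply_exclusions(rec, course)
  expect_false(clean$excluded)
  expect_length(clean$reasons, 0)

  ifn <- identify_first_course(
    claim_row("A", "2016-03-01", c("cisplatin", "interferon-alpha")),
    rec$dx_date)
  expect_equal(apply_exclusions(rec, ifn)$reasons, "interferon_alpha")

  art <- identify_first_course(
    claim_row("A", "2016-03-01", "cisplatin", route = "arterial"), rec$dx_date)
  expect_equal(apply_exclusions(rec, art)$reasons, "arterial_route")

  same_day <- apply_exclusions(rec, course,
                               proc_row("A", "2016-03-01", "abdominal_drainage"))
  expect_equal(same_day$reasons, "same_day_surgery_or_drainage")
  prior_day <- apply_exclusions(rec, course,
                                proc_row("A", "2016-02-28", "surgery"))
  expect_false(prior_day$excluded)

  # transplant within 21 days after chemotherapy, inclusive boundary
  expect_equal(
    apply_exclusions(rec, course, proc_row("A", "2016-03-21", "hsct"))$reasons,
    "hsct_within_3_weeks")
  expect_equal(
    apply_exclusions(rec, course, proc_row("A", "2016-03-22", "hsct"))$reasons,
    "hsct_within_3_weeks") # start+21
  expect_false(
    apply_exclusions(rec, course, proc_row("A", "2016-03-23", "hsct"))$excluded)

  expect_equal(apply_exclusions(reg_row("A", age = 19), course)$reasons,
               "under_20")
  expect_equal(apply_exclusions(rec, NULL)$reasons, "no_chemo")
})

test_that("route group is intravenous when any course drug is IV", {
  mixed <- tibble::tibble(drug_id = c("s1", "cisplatin"),
                          route = c("PO", "IV"), dose_mg = c(100, 89))
  expect_equal(assign_route_group(mixed), "intravenous_group")
  expect_equal(assign_route_group(mixed[1, ]), "oral_group")
  expect_equal(assign_route_group(mixed[2, ]), "intravenous_group")
  expect_error(assign_route_group(mixed[0, ]), "empty")
})

test_that("combined stage prefers the pathological stage of resected patients", {
  expect_equal(combine_stage("III", "II", as.Date("2016-01-01")), "II")
  expect_equal(combine_stage("IV", "unknown", as.Date(NA)), "IV")
  expect_equal(combine_stage("IV", "II", as.Date(NA)), "IV") # not resected
  expect_equal(combine_stage("unknown", "unknown", as.Date(NA)), "unknown")
  expect_equal(combine_stage(NA, NA, as.Date(NA)), "unknown")
  expect_error(combine_stage("X", "II", as.Date(NA)), "invalid stage")
})

make_ten_patient_inputs <- function() {
  registry <- dplyr::bind_rows(lapply(sprintf("T%02d", 1:10), reg_row))
  registry$age_at_dx[3] <- 18
  claims <- dplyr::bind_rows(
    lapply(sprintf("T%02d", 1:10), function(id)
      claim_row(id, "2016-03-01", "cisplatin", dose = 118)))
  claims <- dplyr::bind_rows(
    claims, claim_row("T01", "2016-03-02", "interferon-alpha"))
  procedures <- proc_row("T02", "2016-03-01", "surgery")
  list(registry = registry, claims = claims, procedures = procedures)
}

test_that("build_cohort applies every exclusion and keeps the flow log conserved", {
  inp <- make_ten_patient_inputs()
  built <- build_cohort(inp$registry, inp$claims, inp$procedures)
  expect_equal(built$flow_log$n_final, 7)
  expect_equal(built$flow_log$n_excluded_unique, 3)
  expect_setequal(built$exclusions$reason,
                  c("interferon_alpha", "same_day_surgery_or_drainage",
                    "under_20"))
  # conservation: input N = retained + unique excluded
  expect_equal(built$flow_log$n_input,
               built$flow_log$n_final + built$flow_log$n_excluded_unique)
  # every retained course has chemotherapy and no arterial route
  expect_true(all(table(built$course_events$patient_id) >= 1))
  expect_false(any(built$course_events$route == "arterial"))
})

test_that("cohort construction is independent of input row order", {
  inp <- make_ten_patient_inputs()
  a <- build_cohort(inp$registry, inp$claims, inp$procedures)
  set.seed(42)
  b <- build_cohort(inp$registry[sample(nrow(inp$registry)), ],
                    inp$claims[sample(nrow(inp$claims)), ],
                    inp$procedures)
  expect_equal(a$cohort[order(a$cohort$patient_id), ],
               b$cohort[order(b$cohort$patient_id), ])
})

test_that("only the first of multiple courses contributes", {
  registry <- reg_row("A")
  claims <- dplyr::bind_rows(
    claim_row("A", "2016-03-01", "cisplatin", dose = 118),
    claim_row("A", "2016-04-30", "carboplatin", dose = 600))
  built <- build_cohort(registry, claims)
  expect_equal(nrow(built$course_events), 1)
  expect_equal(built$course_events$drug_id, "cisplatin")
})

test_that("input validation catches duplicates, orphans and empty claims", {
  registry <- dplyr::bind_rows(reg_row("A"), reg_row("A"))
  expect_error(build_cohort(registry, claim_row("A", "2016-03-01", "cisplatin")),
               "duplicate patient_id")
  expect_warning(
    built <- build_cohort(reg_row("A"),
                          dplyr::bind_rows(
                            claim_row("A", "2016-03-01", "cisplatin"),
                            claim_row("GHOST", "2016-03-01", "cisplatin"))),
    "absent from the registry")
  expect_equal(built$flow_log$n_final, 1)

  empty <- build_cohort(reg_row("A"), claim_row("A", "2016-03-01", "x")[0, ])
  expect_equal(empty$flow_log$n_final, 0)
  expect_equal(empty$flow_log$exclusions$no_chemo, 1)
})

test_that("the diagnosis-year filter is honoured", {
  registry <- dplyr::bind_rows(
    reg_row("A", dx = as.Date("2016-02-01")),
    reg_row("B", dx = as.Date("2017-02-01")))
  claims <- dplyr::bind_rows(
    claim_row("A", "2016-03-01", "cisplatin"),
    claim_row("B", "2017-03-01", "cisplatin"))
  expect_warning(
    built <- build_cohort(registry, claims,
                          config = audit_config(diagnosis_year = 2016)),
    "absent from the registry") # B's claims drop with B
  expect_equal(built$cohort$patient_id, "A")
  expect_equal(built$flow_log$n_input, 1)
})
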