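test_that("proportions carry exact intervals and survive boundaries", {
  est <- proportion_with_ci(46458, 172133)
  expect_equal(round_half_up(est$percent, 1), 27.0)

  zero <- proportion_with_ci(0, 10)
  expect_equal(zero$percent, 0)
  expect_equal(zero$ci_low, 0)
  full <- proportion_with_ci(10, 10)
  expect_equal(full$ci_high, 100)

  t5 <- proportion_with_ci(32738, 46306)
  expect_equal(format_estimate(t5), "70.7 (70.3-71.1)")

  expect_error(proportion_with_ci(1, 0), "denominator")
  expect_error(proportion_with_ci(5, 4))
})

test_that("Clopper-Pearson endpoints agree with binom.test", {
  for (kn in list(c(3, 10), c(0, 25), c(25, 25), c(350, 500))) {
    est <- proportion_with_ci(kn[1], kn[2])
    bt <- stats::binom.test(kn[1], kn[2])$conf.int
    expect_equal(c(est$ci_low, est$ci_high) / 100, as.numeric(bt),
                 tolerance = 1e-12)
  }
})

test_that("Wilson intervals are valid and ordered around the point estimate", {
  est <- proportion_with_ci(c(0, 7, 350, 500), 500, method = "wilson")
  expect_true(all(est$ci_low >= 0 & est$ci_high <= 100))
  expect_true(all(est$ci_low <= est$percent & est$percent <= est$ci_high))
  # Wilson is narrower than the conservative exact interval away from 0/n
  cp <- proportion_with_ci(350, 500)
  wi <- proportion_with_ci(350, 500, method = "wilson")
  expect_lt(wi$ci_high - wi$ci_low, cp$ci_high - cp$ci_low)
})

test_that("risk distribution percentages are computed on the stated denominators", {
  two <- tibble::tibble(patient_id = c("a", "b"), cancer_type = "other",
                        route_group = "intravenous_group",
                        regimen = c("cisplatin", "paclitaxel"),
                        guideline = "JSCO", category = c("high", "low"),
                        fired_rule = "max-of-components")
  tab <- risk_distribution_table(two)
  tot <- tab[tab$route_group == "total" & is.na(tab$regimen), ]
  expect_equal(sort(tot$percent), c(50, 50))

  expect_equal(nrow(risk_distribution_table(two[0, ])), 0)

  # percentage rows sum to 100 within every stratum
  fx <- demo_fixture()
  audit <- run_audit(fx$registry, fx$claims, fx$procedures)
  rd <- audit$tables$risk_distribution
  sums <- tapply(rd$percent[is.na(rd$regimen)], rd$route_group[is.na(rd$regimen)],
                 sum)
  expect_true(all(abs(sums - 100) < 0.2))
  pc <- audit$tables$per_cancer_risk
  sums2 <- tapply(pc$percent, pc$cancer_type, sum)
  expect_true(all(abs(sums2 - 100) < 0.2))
})

test_that("the prophylaxis table partitions each stratum with intervals", {
  asg <- tibble::tibble(patient_id = sprintf("p%d", 1:4),
                        cancer_type = "breast",
                        route_group = "intravenous_group", regimen = "AC",
                        guideline = "JSCO", category = "high",
                        fired_rule = "AC")
  prof <- tibble::tibble(patient_id = sprintf("p%d", 1:4),
                         category = c("triple", "triple", "triple",
                                      "none_of_above"))
  tab <- prophylaxis_table(prof, asg)
  iv <- tab[tab$route_group == "intravenous_group", ]
  expect_equal(sum(iv$numerator), 4)
  expect_equal(iv$percent[iv$prophylaxis == "triple"], 75)
  expect_equal(iv$percent[iv$prophylaxis == "none_of_above"], 25)
  expect_equal(sum(iv$percent), 100)
  expect_true(all(iv$ci_low <= iv$percent & iv$percent <= iv$ci_high))

  all_triple <- prophylaxis_table(
    dplyr::mutate(prof, category = "triple"), asg)
  expect_equal(
    all_triple$percent[all_triple$route_group == "total" &
                         all_triple$prophylaxis == "triple"], 100)
})

test_that("top regimens rank within cells and break ties lexicographically", {
  asg <- tibble::tibble(
    patient_id = sprintf("p%d", 1:5), cancer_type = "gastric",
    route_group = "intravenous_group",
    regimen = c("SOX", "SOX", "zeta", "alpha", "alpha"),
    guideline = "JSCO",
    category = c("moderate", "moderate", "low", "low", "moderate"),
    fired_rule = "max-of-components")
  top <- top_regimens(asg, k = 1)
  expect_equal(top$regimen[top$category == "moderate"], "SOX")
  expect_equal(top$percent[top$category == "moderate"], 100 * 2 / 3)
  single <- top_regimens(asg[3, ], k = 3)
  expect_equal(single$percent, 100)
  # two regimens tied at n = 1 within low: lexicographic winner
  expect_equal(top$regimen[top$category == "low"], "alpha")
})

test_that("the expected vomiting frequency mixes coverage and efficacy", {
  expect_equal(expected_vomiting_frequency(0.9, 0.3, 0.9), 0.36)
  expect_equal(expected_vomiting_frequency(1, 0.3, 0.9), 0.3)
  expect_equal(expected_vomiting_frequency(0, 0.3, 0.9), 0.9)
  expect_error(expected_vomiting_frequency(1.2, 0.3, 0.9), "proportions")
  expect_error(expected_vomiting_frequency(0.9, -0.1, 0.9), "proportions")
})

test_that("run_audit is deterministic and writes the full output bundle", {
  fx <- demo_fixture()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  a <- run_audit(fx$registry, fx$claims, fx$procedures, out_dir = out1)
  b <- run_audit(fx$registry, fx$claims, fx$procedures, out_dir = out2)
  expect_equal(a$assignments, b$assignments)
  files <- c("table2_characteristics.csv", "table3_risk_distribution.csv",
             "table4_top_regimens.csv", "table5_prophylaxis.csv",
             "fig1_per_cancer.csv", "fig2_prophylaxis_per_cancer.csv",
             "flow_log.json", "run_manifest.json")
  for (f in files) {
    expect_true(file.exists(file.path(out1, f)), info = f)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
  # empty inputs give empty outputs and a zero flow log
  empty <- run_audit(reg_row("Z")[0, ],
                     claim_row("Z", "2016-01-01", "x")[0, ])
  expect_equal(empty$flow_log$n_input, 0)
  expect_equal(nrow(empty$tables$risk_distribution), 0)
})

test_that("the characteristics table summarises by route group", {
  fx <- demo_fixture()
  audit <- run_audit(fx$registry, fx$claims, fx$procedures)
  ch <- audit$tables$characteristics
  tot_n <- unique(ch$denominator[ch$route_group == "total"])
  expect_equal(tot_n, nrow(audit$cohort))
  ct <- ch[ch$variable == "cancer_type" & ch$route_group == "total", ]
  expect_equal(sum(ct$value), 100, tolerance = 1e-9)
  expect_true(all(c("sex", "age", "stage", "adjuvant") %in% ch$variable))
})
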