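#' Binomial proportion with confidence interval
#'
#' Exact (Clopper-Pearson) intervals by default, computed from beta
#' quantiles; Wilson score intervals optionally. Values are returned on the
#' percent scale at full precision - rounding half-up to one decimal is a
#' presentation concern (see [format_estimate()]).
#'
#' @param k Numerator count(s), `0 <= k <= n`.
#' @param n Denominator count(s), `> 0`.
#' @param method `"clopper_pearson"` or `"wilson"`.
#' @param alpha Two-sided significance level (0.05 gives a 95% CI).
#' @return Tibble with `numerator`, `denominator`, `percent`, `ci_low`,
#'   `ci_high` (percent scale), `method`.
#' @export
#' @examples
#' proportion_with_ci(32738, 46306)
proportion_with_ci <- function(k, n, method = c("clopper_pearson", "wilson"),
                               alpha = 0.05) {
  method <- match.arg(method)
  if (any(n == 0)) stop("undefined proportion: denominator is zero", call. = FALSE)
  stopifnot(all(k >= 0), all(k <= n), alpha > 0, alpha < 1)
  p <- k / n
  if (method == "clopper_pearson") {
    lo <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
    hi <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- ifelse(k == 0, 0, pmax(0, centre - half))
    hi <- ifelse(k == n, 1, pmin(1, centre + half))
  }
  tibble::tibble(numerator = k, denominator = n, percent = 100 * p,
                 ci_low = 100 * lo, ci_high = 100 * hi, method = method)
}

#' Format a proportion estimate for display
#'
#' @param est A row (or rows) from [proportion_with_ci()].
#' @param digits Decimal places (half-up rounding).
#' @return Character, e.g. `"70.7 (70.3-71.1)"`.
#' @export
format_estimate <- function(est, digits = 1) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
          round_half_up(est$percent, digits),
          round_half_up(est$ci_low, digits),
          round_half_up(est$ci_high, digits))
}

# route_group rows plus a pooled "total" stratum
with_total <- function(df) {
  dplyr::bind_rows(df, dplyr::mutate(df, route_group = "total"))
}

#' Distribution of emetic risk by route group
#'
#' Counts and percentages per risk category within each route group and
#' overall (denominators include the unknown category), with per-regimen
#' drill-down rows whose percentages use the risk-category count as
#' denominator.
#'
#' @param assignments Risk assignments from [classify_cohort()].
#' @return Tibble with `route_group`, `category`, `regimen` (`NA` on the
#'   category summary rows), `n`, `denominator`, `percent`.
#' @export
risk_distribution_table <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(tibble::tibble(route_group = character(), category = character(),
                          regimen = character(), n = integer(),
                          denominator = integer(), percent = double()))
  }
  a <- with_total(assignments)
  cat_rows <- a |>
    dplyr::summarise(n = dplyr::n(), .by = c("route_group", "category")) |>
    dplyr::mutate(denominator = sum(.data$n), .by = "route_group",
                  regimen = NA_character_)
  reg_rows <- a |>
    dplyr::summarise(n = dplyr::n(),
                     .by = c("route_group", "category", "regimen")) |>
    dplyr::mutate(denominator = sum(.data$n), .by = c("route_group", "category"))
  dplyr::bind_rows(cat_rows, reg_rows) |>
    dplyr::mutate(percent = 100 * .data$n / .data$denominator,
                  category = factor(.data$category, risk_levels())) |>
    dplyr::arrange(.data$route_group, .data$category, !is.na(.data$regimen),
                   dplyr::desc(.data$n), .data$regimen) |>
    dplyr::mutate(category = as.character(.data$category))
}

#' Prophylaxis category table with confidence intervals
#'
#' The five antiemetic-prophylaxis categories per risk category and route
#' group (and pooled total), each as a binomial proportion with its
#' confidence interval on the risk-stratum denominator.
#'
#' @param profiles Prophylaxis profiles from [attribute_prophylaxis()].
#' @param assignments Risk assignments from [classify_cohort()].
#' @param method,alpha Passed to [proportion_with_ci()].
#' @return Tibble: `route_group`, `risk_category`, `prophylaxis`,
#'   `numerator`, `denominator`, `percent`, `ci_low`, `ci_high`, `method`.
#' @export
prophylaxis_table <- function(profiles, assignments,
                              method = c("clopper_pearson", "wilson"),
                              alpha = 0.05) {
  method <- match.arg(method)
  joined <- assignments |>
    dplyr::inner_join(dplyr::select(profiles, "patient_id",
                                    prophylaxis = "category"),
                      by = "patient_id") |>
    with_total()
  counts <- joined |>
    dplyr::summarise(numerator = dplyr::n(),
                     .by = c("route_group", "category", "prophylaxis")) |>
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("route_group"), !!rlang::sym("category")),
      prophylaxis = prophylaxis_levels(),
      fill = list(numerator = 0L)
    ) |>
    dplyr::mutate(denominator = sum(.data$numerator),
                  .by = c("route_group", "category"))
  est <- proportion_with_ci(counts$numerator, counts$denominator,
                            method = method, alpha = alpha)
  counts |>
    dplyr::rename(risk_category = "category") |>
    dplyr::mutate(percent = est$percent, ci_low = est$ci_low,
                  ci_high = est$ci_high, method = method,
                  risk_category = factor(.data$risk_category, risk_levels()),
                  prophylaxis = factor(.data$prophylaxis, prophylaxis_levels())) |>
    dplyr::arrange(.data$route_group, .data$risk_category, .data$prophylaxis) |>
    dplyr::mutate(dplyr::across(c("risk_category", "prophylaxis"), as.character))
}

#' Risk-category distribution by cancer type
#'
#' @param assignments Risk assignments from [classify_cohort()] (carrying
#'   `cancer_type`).
#' @return Tibble: `cancer_type`, `category`, `n`, `denominator`, `percent`
#'   (percent within cancer type).
#' @export
per_cancer_distribution <- function(assignments) {
  assignments |>
    dplyr::summarise(n = dplyr::n(), .by = c("cancer_type", "category")) |>
    dplyr::mutate(denominator = sum(.data$n), .by = "cancer_type") |>
    dplyr::mutate(percent = 100 * .data$n / .data$denominator,
                  category = factor(.data$category, risk_levels())) |>
    dplyr::arrange(.data$cancer_type, .data$category) |>
    dplyr::mutate(category = as.character(.data$category))
}

#' Prophylaxis category distribution by cancer type
#'
#' @inheritParams prophylaxis_table
#' @param risk_filter Optional risk category to restrict to (e.g. `"high"`,
#'   the stratum of primary clinical interest).
#' @return Tibble: `cancer_type`, `prophylaxis`, `n`, `denominator`,
#'   `percent`.
#' @export
prophylaxis_per_cancer <- function(profiles, assignments, risk_filter = NULL) {
  joined <- assignments |>
    dplyr::inner_join(dplyr::select(profiles, "patient_id",
                                    prophylaxis = "category"),
                      by = "patient_id")
  if (!is.null(risk_filter)) {
    joined <- dplyr::filter(joined, .data$category %in% risk_filter)
  }
  joined |>
    dplyr::summarise(n = dplyr::n(), .by = c("cancer_type", "prophylaxis")) |>
    dplyr::mutate(denominator = sum(.data$n), .by = "cancer_type") |>
    dplyr::mutate(percent = 100 * .data$n / .data$denominator,
                  prophylaxis = factor(.data$prophylaxis, prophylaxis_levels())) |>
    dplyr::arrange(.data$cancer_type, .data$prophylaxis) |>
    dplyr::mutate(prophylaxis = as.character(.data$prophylaxis))
}

#' Most frequent regimens per cancer type and risk category
#'
#' @param assignments Risk assignments from [classify_cohort()].
#' @param k Number of regimens to keep per (cancer type, risk) cell.
#' @return Tibble: `cancer_type`, `category`, `regimen`, `n`, `denominator`,
#'   `percent` (share of the cell). Ties are broken lexicographically.
#' @export
top_regimens <- function(assignments, k = 3) {
  assignments |>
    dplyr::summarise(n = dplyr::n(),
                     .by = c("cancer_type", "category", "regimen")) |>
    dplyr::mutate(denominator = sum(.data$n), .by = c("cancer_type", "category")) |>
    dplyr::arrange(.data$cancer_type, factor(.data$category, risk_levels()),
                   dplyr::desc(.data$n), .data$regimen) |>
    dplyr::slice_head(n = k, by = c("cancer_type", "category")) |>
    dplyr::mutate(percent = 100 * .data$n / .data$denominator)
}

#' Cohort characteristics table
#'
#' Demographic and clinical summary by route group and overall: sex, age,
#' cancer type, combined stage, adjuvant flag.
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @return Tibble: `route_group`, `variable`, `level`, `n`, `denominator`,
#'   `value` (percent, or the mean/sd for age).
#' @export
characteristics_table <- function(cohort) {
  a <- with_total(cohort)
  pct_block <- function(df, var) {
    df |>
      dplyr::summarise(n = dplyr::n(), .by = c("route_group", dplyr::all_of(var))) |>
      dplyr::mutate(denominator = sum(.data$n), .by = "route_group") |>
      dplyr::mutate(variable = var, level = as.character(.data[[var]]),
                    value = 100 * .data$n / .data$denominator) |>
      dplyr::select("route_group", "variable", "level", "n", "denominator",
                    "value")
  }
  male <- a |>
    dplyr::summarise(n = sum(.data$sex == "male"), denominator = dplyr::n(),
                     .by = "route_group") |>
    dplyr::mutate(variable = "sex", level = "male",
                  value = 100 * .data$n / .data$denominator)
  age <- a |>
    dplyr::summarise(n = dplyr::n(), denominator = dplyr::n(),
                     mean_age = mean(.data$age_at_dx),
                     sd_age = stats::sd(.data$age_at_dx), .by = "route_group") |>
    tidyr::pivot_longer(c("mean_age", "sd_age"), names_to = "level",
                        values_to = "value") |>
    dplyr::mutate(variable = "age") |>
    dplyr::select("route_group", "variable", "level", "n", "denominator",
                  "value")
  adjuvant <- a |>
    dplyr::summarise(n = sum(.data$adjuvant %in% TRUE),
                     denominator = dplyr::n(), .by = "route_group") |>
    dplyr::mutate(variable = "adjuvant", level = "TRUE",
                  value = 100 * .data$n / .data$denominator)
  dplyr::bind_rows(male, age, pct_block(a, "cancer_type"),
                   pct_block(a, "stage"), adjuvant) |>
    dplyr::arrange(.data$route_group)
}

#' Expected population vomiting frequency under partial prophylaxis coverage
#'
#' Mixes the vomiting frequency with and without antiemetic prophylaxis by
#' the prophylaxis coverage: `p * p_vomit_with + (1 - p) * p_vomit_without`.
#' With roughly 90% coverage of high-emetic-risk chemotherapy, a 30%
#' frequency under prophylaxis and 90% without, the population frequency is
#' about 0.36.
#'
#' @param p_prophylaxis Proportion of patients receiving prophylaxis, in
#'   `[0, 1]`.
#' @param p_vomit_with Vomiting frequency with prophylaxis, in `[0, 1]`.
#' @param p_vomit_without Vomiting frequency without prophylaxis, in `[0, 1]`.
#' @return Expected vomiting proportion in `[0, 1]`.
#' @export
#' @examples
#' expected_vomiting_frequency(0.9, 0.3, 0.9)
expected_vomiting_frequency <- function(p_prophylaxis, p_vomit_with,
                                        p_vomit_without) {
  args <- c(p_prophylaxis, p_vomit_with, p_vomit_without)
  if (any(!is.finite(args)) || any(args < 0) || any(args > 1)) {
    stop("all arguments must be proportions in [0, 1]", call. = FALSE)
  }
  p_prophylaxis * p_vomit_with + (1 - p_prophylaxis) * p_vomit_without
}
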