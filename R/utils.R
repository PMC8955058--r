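#' @importFrom rlang %||% .data
#' @importFrom stats qbeta rnorm runif setNames
#' @importFrom utils head
NULL

#' Emetic risk categories
#'
#' The ordered emetic-risk vocabulary used throughout the package. `high`,
#' `moderate`, `low` and `minimal` form a total order (high strongest);
#' `unknown` sits outside the order and never wins a maximum.
#'
#' @return Character vector of the five category labels, strongest first.
#' @export
#' @examples
#' risk_levels()
risk_levels <- function() {
  c("high", "moderate", "low", "minimal", "unknown")
}

# rank used for max-of-components aggregation; unknown -> NA so it never wins
risk_rank <- function(category) {
  unname(c(high = 4, moderate = 3, low = 2, minimal = 1, unknown = NA_real_)[category])
}

#' Guideline systems
#'
#' @return Character vector of supported guideline identifiers. `JSCO` is the
#'   default used for all headline tabulations.
#' @export
guideline_ids <- function() {
  c("JSCO", "ASCO", "NCCN", "MASCC")
}

#' Cancer-type vocabulary
#'
#' @return Character vector of the cancer-type levels used in registry records.
#' @export
cancer_types <- function() {
  c("non_small_cell_lung", "colorectal", "breast", "gastric",
    "malignant_lymphoma", "pancreatic", "oesophageal", "small_cell_lung",
    "other")
}

stage_levels <- function() c("0", "I", "II", "III", "IV", "unknown")

prophylaxis_levels <- function() {
  c("triple", "serotonin_plus_dex", "serotonin_only", "dex_only",
    "none_of_above")
}

antiemetic_classes <- function() c("NK1", "serotonin_antagonist", "steroid")

# Round half away from zero, the presentation convention for printed
# percentages (base round() is banker's rounding).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_in <- function(x, levels, what) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad) > 0) {
    stop(sprintf("invalid %s: %s (expected one of %s)", what,
                 paste(bad, collapse = ", "), paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
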