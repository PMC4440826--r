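#' Serum marker panel
#'
#' The six routine serum analytes used throughout the package, in the fixed
#' order expected by the six-marker classifier: lactate dehydrogenase (LDH,
#' u/l), C-reactive protein (CRP, mg/l), sodium (Na+, mmol/l), chloride
#' (Cl-, mmol/l), carcino-embryonic antigen (CEA, ng/ml) and neuron-specific
#' enolase (NSE, ng/ml).
#'
#' @return Character vector of the six marker column names.
#' @export
marker_names <- function() c("ldh", "crp", "na", "cl", "cea", "nse")

#' Normal critical intervals of the serum markers
#'
#' Laboratory reference ranges for the six markers, in marker units.
#'
#' @return A tibble with columns `marker`, `lower`, `upper`, `unit`.
#' @export
#' @examples
#' reference_ranges()
reference_ranges <- function() {
  tibble::tibble(
    marker = marker_names(),
    lower  = c(99, 0, 136, 96, 0, 0),
    upper  = c(245, 3, 146, 108, 3.4, 17),
    unit   = c("u/l", "mg/l", "mmol/l", "mmol/l", "ng/ml", "ng/ml")
  )
}

# Group-wise marker summaries (median and observed range) the generator is
# calibrated to. Sodium and chloride are modelled as truncated normal (tight,
# physiologically regulated); the enzyme/antigen markers as truncated
# log-normal (right-skewed ranges).
default_marker_params <- function() {
  g <- function(group, marker, median, lower, upper, family) {
    tibble::tibble(group = group, marker = marker, median = median,
                   lower = lower, upper = upper, family = family,
                   spread = NA_real_)
  }
  dplyr::bind_rows(
    g("CONTROL", "ldh", 146,    55,   397,    "lognormal"),
    g("CONTROL", "crp", 1.36,   0.04, 18.2,   "lognormal"),
    g("CONTROL", "na",  142.47, 127,  146.83, "normal"),
    g("CONTROL", "cl",  105,    98,   111,    "normal"),
    g("CONTROL", "cea", 2.07,   0.2,  14.66,  "lognormal"),
    g("CONTROL", "nse", 12.44,  6.76, 38.19,  "lognormal"),
    g("SCLC",    "ldh", 180,    3,    801,    "lognormal"),
    g("SCLC",    "crp", 6.18,   0.04, 117.96, "lognormal"),
    g("SCLC",    "na",  140,    101.4, 146.1, "normal"),
    g("SCLC",    "cl",  102,    78,   137.8,  "normal"),
    g("SCLC",    "cea", 4.29,   0.08, 181,    "lognormal"),
    g("SCLC",    "nse", 24.27,  1.07, 370,    "lognormal"),
    g("NSCLC",   "ldh", 159.98, 10,   540,    "lognormal"),
    g("NSCLC",   "crp", 19.55,  0,    145,    "lognormal"),
    g("NSCLC",   "na",  141.57, 134,  146,    "normal"),
    g("NSCLC",   "cl",  102.60, 1,    110,    "normal"),
    g("NSCLC",   "cea", 52.66,  0,    781,    "lognormal"),
    g("NSCLC",   "nse", 13.34,  1,    40,     "lognormal")
  )
}

# Demographic marginals per group: sex, age (truncated normal, integer years),
# smoking status, and disease stage proportions.
default_demographics <- function() {
  list(
    CONTROL = list(p_male = 86 / 155, age_mean = 56.23, age_sd = 8.72,
                   age_range = c(29, 81), p_smoker = 86 / 155,
                   stages = NULL),
    SCLC    = list(p_male = 94 / 145, age_mean = 57.92, age_sd = 9.46,
                   age_range = c(33, 78), p_smoker = 92 / 145,
                   stages = c(LIMITED = 74 / 145, EXTENSIVE = 71 / 145)),
    NSCLC   = list(p_male = 69 / 130, age_mean = 57.75, age_sd = 10.69,
                   age_range = c(21, 80), p_smoker = 72 / 130,
                   stages = c(I = 0.5, II = 0.5))
  )
}

#' Specify a synthetic cohort
#'
#' Describes group sizes, per-group marker distributions (a truncated
#' log-normal or normal family calibrated so the truncated median matches a
#' target, within a hard lower/upper range), the sodium-chloride rank
#' correlation (induced through a Gaussian copula), and demographic
#' marginals. The defaults reproduce the study conditions this package
#' models: 145 SCLC patients, 130 NSCLC patients and 155 non-cancer controls
#' with the published group-wise medians and ranges and a Na-Cl Spearman
#' correlation of 0.705.
#'
#' @param n_sclc,n_nsclc,n_control Non-negative group sizes.
#' @param markers Tibble of per-group marker distribution parameters with
#'   columns `group`, `marker`, `median`, `lower`, `upper`, `family`
#'   (`"lognormal"` or `"normal"`) and optional `spread` (sdlog or sd; when
#'   `NA` it is derived so the untruncated 0.5th-99.5th percentile span
#'   matches `lower`-`upper`).
#' @param na_cl_rank_corr Target Spearman correlation between sodium and
#'   chloride, in \[-1, 1\].
#' @param demographics Named list of per-group demographic marginals; see
#'   `gepdx:::default_demographics()` for the expected shape.
#' @param seed Default integer seed used by [generate_cohort()].
#'
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_sclc = 5, n_nsclc = 0, n_control = 5)
#' generate_cohort(spec, seed = 1)
cohort_spec <- function(n_sclc = 145, n_nsclc = 130, n_control = 155,
                        markers = default_marker_params(),
                        na_cl_rank_corr = 0.705,
                        demographics = default_demographics(),
                        seed = 1L) {
  for (nm in c("n_sclc", "n_nsclc", "n_control")) {
    n <- get(nm)
    if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 ||
        n != round(n)) {
      param_error(sprintf("`%s` must be a single non-negative count.", nm))
    }
  }
  assert_scalar_number(na_cl_rank_corr, "na_cl_rank_corr")
  if (abs(na_cl_rank_corr) > 1) {
    param_error("`na_cl_rank_corr` must lie in [-1, 1].")
  }
  req <- c("group", "marker", "median", "lower", "upper", "family", "spread")
  if (!all(req %in% names(markers))) {
    param_error("`markers` must have columns group, marker, median, lower, upper, family, spread.")
  }
  if (any(markers$lower >= markers$upper)) {
    param_error("Inverted truncation bounds: `lower` must be < `upper` for every marker.")
  }
  if (any(markers$median <= markers$lower | markers$median >= markers$upper)) {
    param_error("Marker medians must lie strictly inside their truncation bounds.")
  }
  if (any(!is.na(markers$spread) & markers$spread <= 0)) {
    param_error("Non-positive `spread` in marker parameters.")
  }
  structure(
    list(n_sclc = as.integer(n_sclc), n_nsclc = as.integer(n_nsclc),
         n_control = as.integer(n_control), markers = markers,
         na_cl_rank_corr = na_cl_rank_corr, demographics = demographics,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_sclc, " SCLC / ", x$n_nsclc, " NSCLC / ",
      x$n_control, " controls; Na-Cl rank corr ", x$na_cl_rank_corr,
      "\n", sep = "")
  invisible(x)
}
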