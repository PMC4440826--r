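# Distribution span of the untruncated family chosen so its 0.5th-99.5th
# percentile interval matches the configured range; the location parameter is
# then solved so the *truncated* median hits the target exactly.
z995 <- function() qnorm(0.995)

derive_spread <- function(family, med, lower, upper) {
  if (family == "lognormal") {
    if (lower > 0) log(upper / lower) / (2 * z995()) else
      log(upper / med) / z995()
  } else {
    (upper - lower) / (2 * z995())
  }
}

solve_location <- function(family, med, lower, upper, spread) {
  # The truncated median is strictly increasing in the location parameter,
  # running from `lower` to `upper`. The objective saturates numerically in
  # the far tails (CDF underflow), so the root is bracketed on a grid
  # around the target median, where evaluation is reliable, before
  # refining with uniroot.
  target <- function(loc) {
    q_truncated(0.5, family, loc, spread, lower, upper) - med
  }
  centre <- if (family == "lognormal") log(med) else med
  grid <- centre + spread * seq(-8, 8, by = 0.25)
  vals <- vapply(grid, target, numeric(1))
  ok <- is.finite(vals)
  grid <- grid[ok]; vals <- vals[ok]
  cross <- which(vals[-1] > 0 & vals[-length(vals)] <= 0)
  if (length(cross) == 0) {
    # pathological configuration: best-effort location
    return(grid[which.min(abs(vals))])
  }
  i <- cross[1]
  uniroot(target, interval = c(grid[i], grid[i + 1]), tol = 1e-10)$root
}

# Inverse-CDF sampling restricted to [F(lower), F(upper)]; `u` uniform (0,1).
q_truncated <- function(u, family, loc, spread, lower, upper) {
  if (family == "lognormal") {
    plo <- plnorm(lower, loc, spread); phi <- plnorm(upper, loc, spread)
    qlnorm(plo + u * (phi - plo), loc, spread)
  } else {
    plo <- pnorm(lower, loc, spread); phi <- pnorm(upper, loc, spread)
    qnorm(plo + u * (phi - plo), loc, spread)
  }
}

# Gaussian-copula correlation reproducing a target Spearman correlation.
copula_rho <- function(rho_s) 2 * sin(pi * rho_s / 6)

generate_group <- function(group, n, spec, seed) {
  pars <- dplyr::filter(spec$markers, .data$group == !!group)
  if (nrow(pars) == 0 && n > 0) {
    param_error(sprintf("No marker parameters configured for group %s.", group))
  }
  set.seed(seed)
  pars <- dplyr::mutate(
    pars,
    spread = ifelse(is.na(.data$spread),
                    mapply(derive_spread, .data$family, .data$median,
                           .data$lower, .data$upper),
                    .data$spread),
    loc = mapply(solve_location, .data$family, .data$median,
                 .data$lower, .data$upper, .data$spread)
  )
  row_of <- function(m) pars[pars$marker == m, , drop = FALSE]

  # Na and Cl share a Gaussian copula at the configured rank correlation;
  # the other four markers are drawn independently.
  rho <- copula_rho(spec$na_cl_rank_corr)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  u_na <- pnorm(z1); u_cl <- pnorm(z2)

  draw <- function(m, u = runif(n)) {
    r <- row_of(m)
    q_truncated(u, r$family, r$loc, r$spread, r$lower, r$upper)
  }
  markers <- tibble::tibble(
    ldh = draw("ldh"), crp = draw("crp"),
    na = draw("na", u_na), cl = draw("cl", u_cl),
    cea = draw("cea"), nse = draw("nse")
  )

  demo <- spec$demographics[[group]]
  if (is.null(demo)) {
    param_error(sprintf("No demographics configured for group %s.", group))
  }
  sex <- ifelse(runif(n) < demo$p_male, "M", "F")
  age_u <- runif(n)
  plo <- pnorm(demo$age_range[1], demo$age_mean, demo$age_sd)
  phi <- pnorm(demo$age_range[2], demo$age_mean, demo$age_sd)
  age <- as.integer(round(qnorm(plo + age_u * (phi - plo),
                                demo$age_mean, demo$age_sd)))
  smoker <- runif(n) < demo$p_smoker
  stage <- if (is.null(demo$stages)) rep(NA_character_, n) else
    sample(names(demo$stages), n, replace = TRUE, prob = demo$stages)

  tibble::tibble(
    subject_id = sprintf("%s-%05d", tolower(group), seq_len(n)),
    group = group, stage = stage, sex = sex, age = age, smoker = smoker
  ) |>
    dplyr::bind_cols(markers)
}

#' Generate a synthetic serum-marker cohort
#'
#' Draws a cohort of subjects whose group sizes, per-group marker medians and
#' ranges, sodium-chloride rank correlation, and demographic marginals follow
#' a [cohort_spec()]. Each marker is sampled from its configured truncated
#' distribution by inverse-CDF sampling; sodium and chloride are coupled
#' through a Gaussian copula. One RNG substream is used per group, derived
#' from the single seed, so a fixed seed reproduces the cohort exactly.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to the seed stored in `spec`.
#'
#' @return A tibble with one row per subject and columns `subject_id`,
#'   `group`, `stage`, `sex`, `age`, `smoker`, `ldh`, `crp`, `na`, `cl`,
#'   `cea`, `nse`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_sclc = 3, n_nsclc = 0,
#'                                       n_control = 3), seed = 42)
#' summarize_cohort(cohort)
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  if (!inherits(spec, "cohort_spec")) {
    param_error("`spec` must be a cohort_spec object.")
  }
  groups <- list(SCLC = spec$n_sclc, NSCLC = spec$n_nsclc,
                 CONTROL = spec$n_control)
  out <- purrr::imap(groups, function(n, g) {
    if (n == 0) return(NULL)
    generate_group(g, n, spec, derive_seed(seed, match(g, names(groups))))
  })
  dplyr::bind_rows(out)
}

#' Summarize a cohort by group and marker
#'
#' Per-group, per-marker sample median (average-of-middle-two convention) and
#' observed range, the layout in which serum panels are conventionally
#' reported. Empty groups simply contribute no rows.
#'
#' @param data A cohort data frame as produced by [generate_cohort()] or
#'   [read_cohort()].
#' @return A tibble with columns `group`, `marker`, `n`, `median`, `min`,
#'   `max`.
#' @export
summarize_cohort <- function(data) {
  check_cohort(data)
  data |>
    tidyr::pivot_longer(dplyr::all_of(marker_names()),
                        names_to = "marker", values_to = "value") |>
    dplyr::group_by(.data$group, .data$marker) |>
    dplyr::summarise(n = dplyr::n(),
                     median = median(.data$value),
                     min = min(.data$value),
                     max = max(.data$value),
                     .groups = "drop") |>
    dplyr::mutate(marker = factor(.data$marker, levels = marker_names())) |>
    dplyr::arrange(.data$group, .data$marker) |>
    dplyr::mutate(marker = as.character(.data$marker))
}

#' Marker distributions by group
#'
#' Log-scaled boxplots of every marker by cohort group, a quick visual check
#' of the group separation the classifiers exploit.
#'
#' @param data A cohort data frame.
#' @return A ggplot object.
#' @export
plot_marker_distributions <- function(data) {
  check_cohort(data)
  long <- tidyr::pivot_longer(data, dplyr::all_of(marker_names()),
                              names_to = "marker", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::facet_wrap(~marker, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "serum level (log scale)")
}
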