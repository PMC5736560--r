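#' Censored (Tobit) linear regression on log concentrations
#'
#' Fits log(concentration) = alpha0 + alpha1 * x + e, e ~ Normal(0, sigma^2),
#' by maximum likelihood where rows flagged `below_lloq` contribute the
#' normal CDF at their recorded bound (left-censoring) and all other rows
#' (including above-ULOQ extrapolated values) contribute the normal density.
#' Estimation is delegated to [survival::survreg()] with a Gaussian error
#' and left-censored response; standard errors come from the
#' observed-information Hessian and the p-value is a two-sided Wald test of
#' alpha1 = 0.
#'
#' @param data A tibble with one row per observation.
#' @param covariate Name of the covariate column in `data`.
#' @param value Name of the concentration column (pg/mL); censored rows must
#'   carry the effective LLOQ bound in this column.
#' @param status Name of the status column (`"below_lloq"` marks censoring).
#' @param unit Human-readable unit label for reporting (e.g. "per year").
#' @return An object of class `tobit_fit` with elements `covariate`, `unit`,
#'   `alpha0`, `alpha1`, `sigma_resid`, `se_alpha1`, `p_value`,
#'   `pct_change_per_unit`, `n_obs`, `n_censored`, `loglik`.
#' @examples
#' d <- tibble::tibble(age = 1:8,
#'                     value = exp(1 + 0.2 * age + c(0.1, -0.1, 0, 0.2,
#'                                                   -0.2, 0.1, 0, -0.1)),
#'                     status = "observed")
#' fit_tobit(d, "age", unit = "per year")
#' @export
fit_tobit <- function(data, covariate, value = "value", status = "status",
                      unit = covariate) {
  x <- data[[covariate]]
  y <- log(data[[value]])
  cens <- data[[status]] == "below_lloq"
  if (!length(x)) stop("empty data", call. = FALSE)
  if (all(cens)) stop("all observations are censored", call. = FALSE)
  if (sum(!cens) < 3) {
    stop("need at least 3 non-censored observations", call. = FALSE)
  }
  if (length(unique(x)) < 2) {
    stop("covariate '", covariate, "' is constant", call. = FALSE)
  }
  sv <- survival::survreg(
    survival::Surv(y, event = !cens, type = "left") ~ x,
    dist = "gaussian"
  )
  co <- stats::coef(sv)
  se1 <- sqrt(stats::vcov(sv)["x", "x"])
  z <- co[["x"]] / se1
  structure(list(
    covariate = covariate, unit = unit,
    alpha0 = co[["(Intercept)"]], alpha1 = co[["x"]],
    sigma_resid = sv$scale, se_alpha1 = se1,
    p_value = 2 * stats::pnorm(-abs(z)),
    pct_change_per_unit = 100 * (exp(co[["x"]]) - 1),
    n_obs = length(y), n_censored = sum(cens),
    loglik = as.numeric(stats::logLik(sv)),
    survreg = sv
  ), class = "tobit_fit")
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat("<tobit_fit> log concentration ~", x$covariate,
      sprintf("(%s)\n", x$unit))
  cat(sprintf("  alpha0 %.4f  alpha1 %.4f (SE %.4f, p = %.3g)\n",
              x$alpha0, x$alpha1, x$se_alpha1, x$p_value))
  cat(sprintf("  %% change per unit: %+.1f%%  sigma %.3f  n = %d (%d censored)\n",
              x$pct_change_per_unit, x$sigma_resid, x$n_obs, x$n_censored))
  invisible(x)
}

covariate_units <- c(age = "per year", weight_z = "per SD",
                     sex = "girls vs boys", vitd = "per 10 nmol/L")

#' Screen covariates against every cytokine x condition
#'
#' Runs a univariate censored regression of log concentration on each
#' covariate for every cytokine x condition. Cells where more than 50% of
#' observations are below the LLOQ are skipped (no regression is attempted;
#' `skipped = TRUE`). Covariates are rescaled to reporting units: age per
#' year, weight-for-age z-score per SD, sex as a girls-vs-boys indicator,
#' vitamin D per 10 nmol/L. Significance is a two-sided Wald p < 0.05 with
#' no multiplicity correction.
#'
#' @param observations Observation tibble (`subject_id`, `cytokine`,
#'   `condition`, `value`, `status`).
#' @param subjects Subject tibble (`subject_id`, `age`, `sex`, `weight_z`,
#'   `vitd`).
#' @param covariates Subset of `c("age", "weight_z", "sex", "vitd")`.
#' @return A tibble with one row per cytokine x condition x covariate:
#'   estimates, `pct_change_per_unit`, `p_value`, `direction`
#'   (`"increase"`/`"decrease"`), `significant`, and `skipped`.
#' @export
screen_covariates <- function(observations, subjects,
                              covariates = c("age", "weight_z", "sex",
                                             "vitd")) {
  unknown <- setdiff(covariates, names(covariate_units))
  if (length(unknown)) {
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dat <- observations |>
    dplyr::inner_join(subjects, by = "subject_id") |>
    dplyr::mutate(sex_num = as.numeric(.data$sex == "girl"),
                  vitd_10 = .data$vitd / 10)
  xcol <- c(age = "age", weight_z = "weight_z", sex = "sex_num",
            vitd = "vitd_10")
  dat |>
    dplyr::group_by(.data$cytokine, .data$condition) |>
    dplyr::group_modify(function(g, key) {
      frac_cens <- mean(g$status == "below_lloq")
      purrr::map_dfr(covariates, function(cv) {
        base <- tibble::tibble(
          covariate = cv, unit = unname(covariate_units[cv]),
          frac_below_lloq = frac_cens
        )
        if (frac_cens > 0.5) {
          return(dplyr::mutate(base, skipped = TRUE, alpha1 = NA_real_,
                               se_alpha1 = NA_real_, p_value = NA_real_,
                               pct_change_per_unit = NA_real_,
                               direction = NA_character_,
                               significant = FALSE,
                               n_obs = nrow(g),
                               n_censored = sum(g$status == "below_lloq")))
        }
        f <- fit_tobit(dplyr::mutate(g, .x = g[[xcol[cv]]]), ".x",
                       unit = covariate_units[cv])
        dplyr::mutate(base, skipped = FALSE, alpha1 = f$alpha1,
                      se_alpha1 = f$se_alpha1, p_value = f$p_value,
                      pct_change_per_unit = f$pct_change_per_unit,
                      direction = ifelse(f$alpha1 >= 0, "increase",
                                         "decrease"),
                      significant = f$p_value < 0.05,
                      n_obs = f$n_obs, n_censored = f$n_censored)
      })
    }) |>
    dplyr::ungroup()
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall rank correlation, used for associations between
#' subject-level covariates (e.g. age with vitamin D).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return tau-b in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("all-tied input: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "kendall")
}

format_conc <- function(v) {
  vapply(v, function(x) {
    if (x >= 100) format(round(x), trim = TRUE, scientific = FALSE)
    else format(signif(x, 3), trim = TRUE, scientific = FALSE)
  }, character(1))
}

#' Censoring-aware summary of concentrations
#'
#' Per cytokine x condition: counts and percentages below the LLOQ and above
#' the ULOQ, and median/min/max/quartiles computed with below-LLOQ rows tied
#' at the effective bound (type-7 quantiles; a display convention, not an
#' imputation). Each quantile also gets a display label: a quantile that
#' falls at or below the effective LLOQ in the presence of censored rows is
#' shown as the token `"<LLOQ>"` (e.g. `"<3.2"`), never as a number; by this
#' rule the median is the token whenever more than half the rows are
#' censored.
#'
#' @param observations Observation tibble.
#' @param limits Per-condition limits tibble (see [default_assay_limits()]).
#' @return A tibble with numeric columns (`median`, `min`, `max`, `p25`,
#'   `p75`) and display columns (`median_label`, ...).
#' @export
summarize_concentrations <- function(observations,
                                     limits = default_assay_limits()) {
  observations |>
    dplyr::left_join(limits[c("condition", "lloq_eff")], by = "condition") |>
    dplyr::group_by(.data$cytokine, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_below_lloq = sum(.data$status == "below_lloq"),
      n_above_uloq = sum(.data$status == "above_uloq_extrapolated"),
      pct_below_lloq = round_half_away(100 * .data$n_below_lloq / .data$n),
      pct_above_uloq = round_half_away(100 * .data$n_above_uloq / .data$n),
      median = unname(stats::quantile(.data$value, 0.5, type = 7)),
      min = min(.data$value),
      max = max(.data$value),
      p25 = unname(stats::quantile(.data$value, 0.25, type = 7)),
      p75 = unname(stats::quantile(.data$value, 0.75, type = 7)),
      lloq_eff = .data$lloq_eff[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(
      c("median", "min", "max", "p25", "p75"),
      ~ ifelse(.x <= .data$lloq_eff & .data$n_below_lloq > 0,
               paste0("<", format_conc(.data$lloq_eff)), format_conc(.x)),
      .names = "{.col}_label"
    )) |>
    dplyr::select(-"lloq_eff")
}

#' Grouped medians of log concentrations by a lifestyle covariate
#'
#' Numeric stand-in for visual screening of categorical covariates (smoke
#' exposure, diet, pets): per cytokine x condition x group level, the median
#' concentration and the below-LLOQ fraction.
#'
#' @param observations Observation tibble.
#' @param subjects Subject tibble containing the grouping column.
#' @param group Name of the grouping column in `subjects`.
#' @return A tibble of grouped summaries.
#' @export
summarize_by_group <- function(observations, subjects, group) {
  if (!group %in% names(subjects)) {
    stop("no column '", group, "' in subjects", call. = FALSE)
  }
  observations |>
    dplyr::inner_join(subjects[c("subject_id", group)], by = "subject_id") |>
    dplyr::group_by(.data$cytokine, .data$condition, .data[[group]]) |>
    dplyr::summarise(n = dplyr::n(),
                     median = stats::median(.data$value),
                     frac_below_lloq = mean(.data$status == "below_lloq"),
                     .groups = "drop")
}
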