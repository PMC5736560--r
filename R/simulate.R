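#' Cohort distribution settings
#'
#' Defaults emulate the study population: n = 271 children aged 0.1--12.8
#' years (median ~5.3, IQR ~3.5--7.9), 74% boys, body-weight-for-age z-score
#' ~ Normal(0.25, 1.11), 25-OH-vitamin-D3 with median ~54 nmol/L and
#' IQR ~40--69 truncated to 11--142 nmol/L, and a weak negative rank
#' correlation between age and vitamin D (Kendall tau -0.13, vitamin D
#' supplementation being concentrated in infancy). Age and vitamin D use
#' truncated lognormal marginals whose (meanlog, sdlog) were calibrated so
#' the *truncated* quartiles match the targets above; the dependence is a
#' Gaussian copula with rho = sin(pi tau / 2).
#'
#' @param n_subjects Cohort size.
#' @param age_range,age_meanlog,age_sdlog Truncated lognormal age marginal.
#' @param boy_prob Probability of sex "boy".
#' @param weight_z_mean,weight_z_sd Normal weight-for-age z-score marginal.
#' @param vitd_range,vitd_meanlog,vitd_sdlog Truncated lognormal vitamin D
#'   marginal (nmol/L).
#' @param tau_age_vitd Target Kendall rank correlation between age and
#'   vitamin D.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 271,
                          age_range = c(0.1, 12.8),
                          age_meanlog = 1.80524, age_sdlog = 0.70168,
                          boy_prob = 0.74,
                          weight_z_mean = 0.25, weight_z_sd = 1.11,
                          vitd_range = c(11, 142),
                          vitd_meanlog = 3.97557, vitd_sdlog = 0.40848,
                          tau_age_vitd = -0.13) {
  stopifnot(n_subjects >= 1, age_range[1] < age_range[2],
            vitd_range[1] < vitd_range[2],
            boy_prob >= 0, boy_prob <= 1,
            abs(tau_age_vitd) < 1)
  structure(as.list(environment()), class = "cohort_config")
}

# inverse CDF of a lognormal truncated to [lo, hi], evaluated at uniform u
qlnorm_trunc <- function(u, meanlog, sdlog, lo, hi) {
  flo <- stats::plnorm(lo, meanlog, sdlog)
  fhi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(flo + u * (fhi - flo), meanlog, sdlog)
}

#' Simulate a synthetic cohort of children
#'
#' Draws a reproducible cohort of subjects with age, sex, weight-for-age
#' z-score and vitamin D, plus inert lifestyle columns (second-hand smoke
#' exposure, fruit/vegetable intake, pets) that carry no outcome effect.
#'
#' @param n Number of subjects (default from `config`).
#' @param seed Integer seed; the same `(n, seed, config)` always yields an
#'   identical cohort.
#' @param config A [cohort_config()].
#' @return A tibble with columns `subject_id`, `age`, `sex`, `weight_z`,
#'   `vitd`, `smoke_exposure`, `fruit_veg`, `pets`.
#' @examples
#' cohort <- simulate_cohort(n = 50, seed = 1)
#' range(cohort$age)
#' @export
simulate_cohort <- function(n = config$n_subjects, seed = NULL,
                            config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  draw <- function() {
    rho <- sin(pi * config$tau_age_vitd / 2)
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = qlnorm_trunc(stats::pnorm(z1), config$age_meanlog,
                         config$age_sdlog, config$age_range[1],
                         config$age_range[2]),
      sex = ifelse(stats::runif(n) < config$boy_prob, "boy", "girl"),
      weight_z = stats::rnorm(n, config$weight_z_mean, config$weight_z_sd),
      vitd = qlnorm_trunc(stats::pnorm(z2), config$vitd_meanlog,
                          config$vitd_sdlog, config$vitd_range[1],
                          config$vitd_range[2]),
      smoke_exposure = sample(c("none", "one_member", "both_parents"), n,
                              replace = TRUE, prob = c(0.64, 0.25, 0.11)),
      fruit_veg = sample(c("0-1", "2-4", "5+"), n, replace = TRUE,
                         prob = c(0.24, 0.69, 0.07)),
      pets = sample(c("no", "yes"), n, replace = TRUE, prob = c(0.6, 0.4))
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Default cytokine x condition simulation panel
#'
#' One row per cytokine x stimulation condition with the exponential (M2)
#' age-model parameterisation used for simulation: median in infancy
#' (`beta0`, pg/mL), median at 12 years (`value_12y`), the implied log-rate
#' `beta1 = ln(value_12y / beta0) / 12`, between-subject variability as a
#' lognormal CV percent (`iiv_cv`) with its log-SD `omega`, and the residual
#' log-SD `sigma` (default 0.2 for every entry, consistent with reported
#' residual variability of roughly 9--25% CV).
#'
#' Unstimulated IL-2, IL-4, IL-6 and IL-10 sit mostly below the 3.2 pg/mL
#' LLOQ and have no quantifiable age model; they are simulated flat from a
#' sub-LLOQ median of 2 pg/mL with a representative IIV CV of 200% and are
#' flagged `quantifiable = FALSE` so heavily censored conditions are
#' represented in synthetic datasets.
#'
#' @param sigma Residual log-SD applied to all entries.
#' @return A tibble with columns `cytokine`, `condition`, `model_id`,
#'   `beta0`, `value_12y`, `beta1`, `iiv_cv`, `omega`, `sigma`,
#'   `quantifiable`.
#' @export
default_panel <- function(sigma = 0.2) {
  rows <- dplyr::tribble(
    ~cytokine, ~condition, ~beta0, ~value_12y, ~iiv_cv, ~quantifiable,
    "IL1ra", "nil",          97,     40,    244, TRUE,
    "IL2",   "nil",           2,      2,    200, FALSE,
    "IL4",   "nil",           2,      2,    200, FALSE,
    "IL6",   "nil",           2,      2,    200, FALSE,
    "IL10",  "nil",           2,      2,    200, FALSE,
    "IFNg",  "nil",           5.4,    5.4,  248, TRUE,
    "IP10",  "nil",        1071,   1071,    101, TRUE,
    "TNFa",  "nil",          19.5,    7.5,   73, TRUE,
    "IL1ra", "SEB",        1666,    801,    123, TRUE,
    "IL2",   "SEB",       46834,  19301,     42, TRUE,
    "IL4",   "SEB",         458,   1614,    111, TRUE,
    "IL6",   "SEB",        2847,   2847,    114, TRUE,
    "IL10",  "SEB",        2190,   4243,     76, TRUE,
    "IFNg",  "SEB",       19200,  38503,    104, TRUE,
    "IP10",  "SEB",      190133, 190133,     62, TRUE,
    "TNFa",  "SEB",        4740,  10859,     66, TRUE,
    "IL1ra", "PHA",         505,    505,    175, TRUE,
    "IL2",   "PHA",         225,    225,    217, TRUE,
    "IL4",   "PHA",         358,   1829,    201, TRUE,
    "IL6",   "PHA",        1263,   1263,    260, TRUE,
    "IL10",  "PHA",         146,    844,    130, TRUE,
    "IFNg",  "PHA",         413,   1340,    135, TRUE,
    "IP10",  "PHA",       97973,  97973,    111, TRUE,
    "TNFa",  "PHA",         352,    930,    157, TRUE,
    "IL1ra", "C_albicans",   372,    372,    327, TRUE,
    "IL2",   "C_albicans",    65,    392,    641, TRUE,
    "IL4",   "C_albicans",    15,     49,    437, TRUE,
    "IL6",   "C_albicans",    22,    130,   1412, TRUE,
    "IL10",  "C_albicans",    15,     15,    206, TRUE,
    "IFNg",  "C_albicans",    22,     83,    132, TRUE,
    "IP10",  "C_albicans",  5601,  11235,    266, TRUE,
    "TNFa",  "C_albicans",    26,     57,    169, TRUE
  )
  rows |>
    dplyr::mutate(model_id = "M2_exponential",
                  beta1 = log(.data$value_12y / .data$beta0) / 12,
                  omega = cv_to_omega(.data$iiv_cv),
                  sigma = sigma, .after = "condition") |>
    dplyr::relocate("model_id", .after = "condition")
}

#' Read / write a simulation panel as YAML
#'
#' @param panel A panel tibble as returned by [default_panel()].
#' @param path File path.
#' @return `read_panel()` returns the panel tibble; `write_panel()` returns
#'   `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  yaml::write_yaml(purrr::transpose(as.list(panel) |> purrr::map(as.vector)),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  rows <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

panel_model <- function(entry) {
  struct_model(entry$model_id, beta0 = entry$beta0, beta1 = entry$beta1,
               beta_asym = entry[["beta_asym"]], t50 = entry[["t50"]])
}

#' Simulate latent cytokine concentrations for a cohort
#'
#' For subject i under panel entry j, the latent (pre-censoring) value is
#' \deqn{y_{ij} = m_j(age_i) \, e^{\eta_{ij}} \, e^{\varepsilon_{ij}},}
#' with subject-level effect eta ~ Normal(0, omega_j^2) and residual
#' epsilon ~ Normal(0, sigma_j^2). By default eta is drawn independently per
#' panel entry (matching per-condition variability estimates); with
#' `eta_mode = "shared"` one standard-normal deviate per subject x cytokine
#' is scaled by each condition's omega, inducing positive dependence of a
#' subject's responses across stimulation conditions.
#'
#' @param subjects Cohort tibble from [simulate_cohort()].
#' @param panel Panel tibble (see [default_panel()]).
#' @param seed Integer seed.
#' @param eta_mode `"independent"` (default) or `"shared"`.
#' @return A tibble of observations with columns `subject_id`, `cytokine`,
#'   `condition`, `value`, `true_value`, `status` (all `"observed"`).
#' @export
simulate_concentrations <- function(subjects, panel, seed = NULL,
                                    eta_mode = c("independent", "shared")) {
  eta_mode <- match.arg(eta_mode)
  needed <- c("cytokine", "condition", "model_id", "beta0", "beta1",
              "omega", "sigma")
  if (!all(needed %in% names(panel))) {
    stop("panel is missing columns: ",
         paste(setdiff(needed, names(panel)), collapse = ", "), call. = FALSE)
  }
  draw <- function() {
    n <- nrow(subjects)
    shared_z <- if (eta_mode == "shared") {
      z <- lapply(unique(panel$cytokine), function(ck) stats::rnorm(n))
      names(z) <- unique(panel$cytokine)
      z
    }
    purrr::pmap(panel, function(...) {
      entry <- list(...)
      m <- median_at_age(panel_model(entry), subjects$age)
      z <- if (eta_mode == "shared") shared_z[[entry$cytokine]] else
        stats::rnorm(n)
      eta <- entry$omega * z
      eps <- stats::rnorm(n, 0, entry$sigma)
      tibble::tibble(
        subject_id = subjects$subject_id,
        cytokine = entry$cytokine,
        condition = entry$condition,
        true_value = m * exp(eta + eps)
      )
    }) |>
      dplyr::bind_rows() |>
      dplyr::mutate(value = .data$true_value, status = "observed",
                    .after = "condition")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Apply quantification limits to simulated observations
#'
#' Values below the condition's effective LLOQ are flagged `below_lloq` and
#' recorded *at the bound* (the bound is what the censored likelihoods use;
#' the measurement itself is unknown). Values above the effective ULOQ are
#' flagged `above_uloq_extrapolated` and kept as-is, mirroring extrapolation
#' from the calibration curve; everything else is `observed`.
#'
#' @param observations Observation tibble (needs `condition`, `value`).
#' @param limits Per-condition limits tibble, see [default_assay_limits()].
#' @return The observation tibble with updated `value` and `status`.
#' @export
apply_quantification_limits <- function(observations,
                                        limits = default_assay_limits()) {
  if (any(observations$value < 0)) {
    stop("negative concentrations are invalid", call. = FALSE)
  }
  missing <- setdiff(unique(observations$condition), limits$condition)
  if (length(missing)) {
    stop("no assay limits for condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  observations |>
    dplyr::left_join(limits[c("condition", "lloq_eff", "uloq_eff")],
                     by = "condition") |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$value < .data$lloq_eff ~ "below_lloq",
        .data$value > .data$uloq_eff ~ "above_uloq_extrapolated",
        TRUE ~ "observed"
      ),
      value = ifelse(.data$status == "below_lloq", .data$lloq_eff,
                     .data$value)
    ) |>
    dplyr::select(-"lloq_eff", -"uloq_eff")
}

#' Write / read the long-format dataset
#'
#' The interchange format is two CSVs: `subjects.csv` with columns
#' `subject_id, age_years, sex, weight_z, vitd_nmol_l` (plus any extra
#' covariate columns) and `observations.csv` with
#' `subject_id, cytokine, condition, value_pg_ml, status`.
#'
#' @param subjects,observations Tibbles as produced by the simulators.
#' @param dir Output directory (created if needed).
#' @return `write_dataset()`: invisibly, the two file paths. Readers return
#'   tibbles with the internal column names (`age`, `vitd`, `value`).
#' @export
write_dataset <- function(subjects, observations, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sub_out <- dplyr::rename(subjects, age_years = "age", vitd_nmol_l = "vitd")
  obs_out <- observations |>
    dplyr::select("subject_id", "cytokine", "condition",
                  value_pg_ml = "value", "status")
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             observations = file.path(dir, "observations.csv"))
  readr::write_csv(sub_out, paths[["subjects"]])
  readr::write_csv(obs_out, paths[["observations"]])
  invisible(paths)
}

#' @rdname write_dataset
#' @param path Path to a CSV written by `write_dataset()`.
#' @export
read_subjects <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::rename(age = "age_years", vitd = "vitd_nmol_l")
}

#' @rdname write_dataset
#' @export
read_observations <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::rename(value = "value_pg_ml")
}
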