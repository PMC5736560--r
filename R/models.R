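#' Structural age models for median cytokine concentration
#'
#' A structural model maps age (years) to the median concentration (pg/mL)
#' of a cytokine under one stimulation condition. Four shapes are supported,
#' all parameterised so that the median at age 0 equals `beta0` (the
#' "expected value in infancy"):
#'
#' * `M1_linear`: \eqn{m(a) = \beta_0 (1 + \beta_1 a)}
#' * `M2_exponential`: \eqn{m(a) = \beta_0 e^{\beta_1 a}} (the reference model)
#' * `M3_asymptote`: \eqn{m(a) = \beta_{asym} + (\beta_0 - \beta_{asym}) e^{-\beta_1 a}}
#' * `M4_logistic`: \eqn{m(a) = \beta_0 + (\beta_{asym} - \beta_0)
#'     \frac{L(a) - L(0)}{1 - L(0)}} with \eqn{L(a) = 1/(1 + e^{-\beta_1 (a - t_{50})})},
#'   i.e. a logistic transition rescaled to start exactly at `beta0`.
#'
#' `M0_constant` (\eqn{m(a) = \beta_0}) is additionally accepted as the
#' age-free null model used when quantifying variance explained by age.
#'
#' @param model_id One of `"M0_constant"`, `"M1_linear"`, `"M2_exponential"`,
#'   `"M3_asymptote"`, `"M4_logistic"` (short aliases `"M0"`..`"M4"` accepted).
#' @param beta0 Median concentration (pg/mL) at age 0; must be positive.
#' @param beta1 Age coefficient (per year): slope for M1, log-rate for M2,
#'   decay rate (> 0) for M3, steepness (> 0) for M4.
#' @param beta_asym Asymptotic concentration (pg/mL), M3/M4 only.
#' @param t50 Inflection age (years), M4 only.
#' @return An object of class `struct_model`.
#' @examples
#' m <- struct_model("M2", beta0 = 4740, beta1 = log(10859 / 4740) / 12)
#' median_at_age(m, c(0, 6, 12))
#' @export
struct_model <- function(model_id, beta0, beta1 = 0, beta_asym = NULL,
                         t50 = NULL) {
  model_id <- normalize_model_id(model_id)
  pars <- c(beta0 = beta0, beta1 = beta1,
            beta_asym = if (!is.null(beta_asym)) beta_asym,
            t50 = if (!is.null(t50)) t50)
  if (any(!is.finite(pars))) {
    stop("all structural model parameters must be finite", call. = FALSE)
  }
  if (beta0 <= 0) stop("beta0 must be > 0", call. = FALSE)
  if (model_id %in% c("M3_asymptote", "M4_logistic")) {
    if (is.null(beta_asym) || beta_asym <= 0) {
      stop(model_id, " requires beta_asym > 0", call. = FALSE)
    }
    if (beta1 < 0) stop(model_id, " requires beta1 >= 0", call. = FALSE)
  }
  if (model_id == "M4_logistic" && (is.null(t50) || t50 <= 0)) {
    stop("M4_logistic requires t50 > 0", call. = FALSE)
  }
  m <- structure(
    list(model_id = model_id, beta0 = beta0, beta1 = beta1,
         beta_asym = beta_asym, t50 = t50),
    class = "struct_model"
  )
  if (model_id == "M1_linear" && (1 + beta1 * 13) <= 0) {
    stop("M1_linear median is not positive on ages [0, 13]", call. = FALSE)
  }
  m
}

normalize_model_id <- function(model_id) {
  full <- c(M0 = "M0_constant", M1 = "M1_linear", M2 = "M2_exponential",
            M3 = "M3_asymptote", M4 = "M4_logistic")
  if (model_id %in% full) return(unname(model_id))
  if (model_id %in% names(full)) return(unname(full[model_id]))
  stop("unknown model_id: ", model_id, call. = FALSE)
}

#' @export
print.struct_model <- function(x, ...) {
  cat("<struct_model>", x$model_id, "\n")
  cat("  beta0:", format(x$beta0), "pg/mL at age 0\n")
  cat("  beta1:", format(x$beta1), "per year\n")
  if (!is.null(x$beta_asym)) cat("  beta_asym:", format(x$beta_asym), "pg/mL\n")
  if (!is.null(x$t50)) cat("  t50:", format(x$t50), "years\n")
  invisible(x)
}

#' Median concentration at a given age
#'
#' Evaluates the structural model's median function \eqn{m(age)}.
#'
#' @param model A [struct_model()].
#' @param age Age(s) in years, non-negative.
#' @return Median concentration(s) in pg/mL, same length as `age`.
#' @export
median_at_age <- function(model, age) {
  stopifnot(inherits(model, "struct_model"))
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  b0 <- model$beta0
  b1 <- model$beta1
  switch(model$model_id,
    M0_constant = rep(b0, length(age)),
    M1_linear = b0 * (1 + b1 * age),
    M2_exponential = b0 * exp(b1 * age),
    M3_asymptote = model$beta_asym + (b0 - model$beta_asym) * exp(-b1 * age),
    M4_logistic = {
      L <- stats::plogis(b1 * (age - model$t50))
      L0 <- stats::plogis(b1 * (0 - model$t50))
      b0 + (model$beta_asym - b0) * (L - L0) / (1 - L0)
    }
  )
}

#' Between- and within-subject variability on the log scale
#'
#' @param omega Between-subject standard deviation of the subject-level
#'   random effect on the natural-log scale (dimensionless); >= 0.
#' @param sigma Residual (within-subject / assay) standard deviation on the
#'   natural-log scale; > 0.
#' @return An object of class `variability_model`.
#' @export
variability_model <- function(omega, sigma) {
  if (!is.finite(omega) || omega < 0) stop("omega must be >= 0", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(list(omega = omega, sigma = sigma), class = "variability_model")
}

#' Assay quantification limits
#'
#' Calibration limits of the immunoassay; effective limits are calibration
#' limits multiplied by the dilution factor of the condition (stimulated
#' samples run at 1:10 dilution have a 10x wider effective range).
#'
#' @param lloq Lower limit of quantification of the calibration curve, pg/mL.
#' @param uloq Upper limit of quantification of the calibration curve, pg/mL.
#' @param dilution Dilution factor (1 = undiluted).
#' @return An object of class `assay_limits` with `lloq_eff`/`uloq_eff`.
#' @export
assay_limits <- function(lloq = 3.2, uloq = 10000, dilution = 1) {
  if (!(lloq > 0 && lloq < uloq)) stop("need 0 < lloq < uloq", call. = FALSE)
  if (dilution <= 0) stop("dilution must be > 0", call. = FALSE)
  structure(
    list(lloq = lloq, uloq = uloq, dilution = dilution,
         lloq_eff = lloq * dilution, uloq_eff = uloq * dilution),
    class = "assay_limits"
  )
}

#' Default per-condition assay limits
#'
#' Calibration range 3.2--10,000 pg/mL; SEB- and PHA-stimulated samples are
#' measured at 1:10 dilution, giving an effective range of 32--100,000 pg/mL.
#'
#' @return A tibble with one row per condition (`condition`, `lloq`, `uloq`,
#'   `dilution`, `lloq_eff`, `uloq_eff`).
#' @export
default_assay_limits <- function() {
  tibble::tibble(
    condition = c("nil", "SEB", "PHA", "C_albicans"),
    lloq = 3.2, uloq = 10000,
    dilution = c(1, 10, 10, 1)
  ) |>
    dplyr::mutate(lloq_eff = .data$lloq * .data$dilution,
                  uloq_eff = .data$uloq * .data$dilution)
}

#' Percent change between two concentrations
#'
#' Signed integer percent change from `v0` to `v1`, rounded half away from
#' zero (so 62.5% prints as 63, -62.5% as -63), matching the convention used
#' for "change over 12 years" summaries.
#'
#' @param v0 Reference concentration(s), > 0.
#' @param v1 Comparison concentration(s).
#' @return Integer percent change(s).
#' @examples
#' percent_change(4740, 10859)  # +129
#' percent_change(19.5, 7.5)    # -62
#' @export
percent_change <- function(v0, v1) {
  if (any(v0 <= 0)) stop("v0 must be > 0", call. = FALSE)
  x <- 100 * (v1 / v0 - 1)
  round_half_away(x)
}

round_half_away <- function(x) {
  # round() rounds half to even; percent summaries use half away from zero
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Lognormal coefficient of variation from a log-scale SD
#'
#' Exact lognormal CV, \eqn{100\sqrt{e^{\omega^2} - 1}}, in percent. Used to
#' report between-subject (IIV) and residual (RUV) variability. The exact
#' transform matters because observed IIV CVs range into the hundreds of
#' percent, far outside the small-omega regime where CV is approximately
#' 100 omega.
#'
#' @param omega Log-scale standard deviation, >= 0.
#' @return CV in percent.
#' @seealso [cv_to_omega()] for the inverse.
#' @export
iiv_cv_percent <- function(omega) {
  if (any(!is.finite(omega)) || any(omega < 0)) {
    stop("omega must be >= 0", call. = FALSE)
  }
  100 * sqrt(exp(omega^2) - 1)
}

#' Log-scale SD from a lognormal CV percent
#'
#' Inverse of [iiv_cv_percent()]: \eqn{\omega = \sqrt{\ln(1 + (CV/100)^2)}}.
#'
#' @param cv_percent CV in percent, >= 0.
#' @return Log-scale SD.
#' @export
cv_to_omega <- function(cv_percent) {
  if (any(cv_percent < 0)) stop("cv_percent must be >= 0", call. = FALSE)
  sqrt(log(1 + (cv_percent / 100)^2))
}

#' Probability of a measurement falling below the effective LLOQ
#'
#' Under the lognormal model, log concentration at a given age is
#' Normal(log m(age), omega^2 + sigma^2), so the below-LLOQ probability is
#' \eqn{\Phi\big((\ln LLOQ_{eff} - \ln m(age)) / \sqrt{\omega^2 + \sigma^2}\big)}.
#'
#' @param model A [struct_model()].
#' @param variability A [variability_model()].
#' @param age Age(s) in years.
#' @param limits An [assay_limits()] object.
#' @return Probability(ies) in `[0, 1]`.
#' @export
below_lloq_probability <- function(model, variability, age, limits) {
  stopifnot(inherits(variability, "variability_model"),
            inherits(limits, "assay_limits"))
  m <- median_at_age(model, age)
  s <- sqrt(variability$omega^2 + variability$sigma^2)
  stats::pnorm((log(limits$lloq_eff) - log(m)) / s)
}

#' Serialize / deserialize a model descriptor
#'
#' A fitted (or hypothesised) model is exchanged as a flat JSON descriptor
#' `{model_id, beta0, beta1, beta_asym, t50, omega, sigma}`.
#'
#' @param model A [struct_model()].
#' @param variability A [variability_model()] or `NULL`.
#' @return `model_to_json()`: a JSON string. `model_from_json()`: a list with
#'   elements `model` and `variability`.
#' @export
model_to_json <- function(model, variability = NULL) {
  stopifnot(inherits(model, "struct_model"))
  x <- list(model_id = model$model_id, beta0 = model$beta0,
            beta1 = model$beta1, beta_asym = model$beta_asym, t50 = model$t50)
  if (!is.null(variability)) {
    x$omega <- variability$omega
    x$sigma <- variability$sigma
  }
  jsonlite::toJSON(x[!vapply(x, is.null, logical(1))],
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname model_to_json
#' @param json A JSON string as produced by `model_to_json()`.
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  model <- struct_model(x$model_id, x$beta0, x$beta1,
                        beta_asym = x$beta_asym, t50 = x$t50)
  variability <- if (!is.null(x$omega) && !is.null(x$sigma)) {
    variability_model(x$omega, x$sigma)
  }
  list(model = model, variability = variability)
}
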