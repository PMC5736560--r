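#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a censored regression fit
#'
#' @param x A [fit_tobit()] result.
#' @param ... Ignored.
#' @return One row per model term with estimate, SE, statistic and p-value.
#' @export
tidy.tobit_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$covariate),
    estimate = c(x$alpha0, x$alpha1),
    std.error = c(NA_real_, x$se_alpha1),
    statistic = c(NA_real_, x$alpha1 / x$se_alpha1),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @rdname tidy.tobit_fit
#' @export
glance.tobit_fit <- function(x, ...) {
  tibble::tibble(
    sigma = x$sigma_resid, logLik = x$loglik,
    pct_change_per_unit = x$pct_change_per_unit,
    nobs = x$n_obs, n_censored = x$n_censored
  )
}

#' Tidy a censored mixed-effects fit
#'
#' @param x A [fit_mixed()] result.
#' @param ... Ignored.
#' @return One row per estimated parameter with estimate and SE (NA when
#'   the Hessian was not positive definite).
#' @export
tidy.mixed_fit <- function(x, ...) {
  nat <- model_to_natural(x$model)
  est <- c(nat, if (!x$omega_fixed) c(omega = x$omega),
           if (!x$sigma_fixed) c(sigma = x$sigma))
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(x$se[names(est)])
  )
}

#' @rdname tidy.mixed_fit
#' @export
glance.mixed_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model$model_id, logLik = x$loglik, AIC = x$aic,
    k = x$k, nobs = x$n_obs, n_subjects = x$n_subjects,
    n_censored = x$n_censored, converged = x$converged,
    value_infancy = x$value_infancy, value_12y = x$value_12y,
    change_12y = x$change_12y, iiv_cv = x$iiv_cv, ruv_cv = x$ruv_cv
  )
}
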