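#' Prepare per-subject data for mixed-model fitting
#'
#' Filters one cytokine x condition, joins ages, and returns the columns the
#' censored marginal likelihood needs: `subject_id`, `age`, `log_value`
#' (natural log of the measured value, or of the effective LLOQ bound for
#' censored rows) and `censored`. The condition's effective limits are
#' attached as attributes `lloq_eff` / `uloq_eff`.
#'
#' @param observations Observation tibble.
#' @param subjects Subject tibble with `subject_id` and `age`.
#' @param cytokine,condition The panel entry to extract.
#' @param limits Per-condition limits tibble.
#' @return A tibble, one row per observation.
#' @export
prepare_mixed_data <- function(observations, subjects, cytokine, condition,
                               limits = default_assay_limits()) {
  lim <- limits[limits$condition == condition, ]
  if (nrow(lim) != 1) stop("no limits for condition ", condition,
                           call. = FALSE)
  d <- observations |>
    dplyr::filter(.data$cytokine == !!cytokine,
                  .data$condition == !!condition) |>
    dplyr::inner_join(subjects[c("subject_id", "age")], by = "subject_id") |>
    dplyr::transmute(.data$subject_id, .data$age,
                     log_value = log(.data$value),
                     censored = .data$status == "below_lloq")
  if (!nrow(d)) stop("no observations for ", cytokine, " x ", condition,
                     call. = FALSE)
  attr(d, "lloq_eff") <- lim$lloq_eff
  attr(d, "uloq_eff") <- lim$uloq_eff
  d
}

# Gauss-Hermite nodes, cached per order
gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) gh_cache[[key]] <- pracma::gaussHermite(n)
  gh_cache[[key]]
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Conditional log-likelihood contributions given random effect eta:
# observed rows -> normal log density, censored rows -> normal log CDF at
# the recorded bound.
cond_loglik <- function(log_value, mu, censored, eta, sigma) {
  out <- numeric(length(mu))
  z <- (log_value - mu - eta) / sigma
  out[!censored] <- stats::dnorm(z[!censored], log = TRUE) - log(sigma)
  out[censored] <- stats::pnorm(z[censored], log.p = TRUE)
  out
}

# Index structure reused across likelihood evaluations within one fit
prepare_ll_index <- function(data) {
  data <- data[order(data$subject_id), ]
  sid <- data$subject_id
  n_per <- table(sid)[unique(sid)]
  single_ids <- names(n_per)[n_per == 1]
  multi_ids <- names(n_per)[n_per > 1]
  list(
    data = data,
    single = which(sid %in% single_ids),
    multi = lapply(multi_ids, function(id) which(sid == id))
  )
}

marginal_loglik_prepared <- function(idx, model, omega, sigma,
                                     quad_nodes = 21) {
  d <- idx$data
  mu <- log(median_at_age(model, d$age))
  if (any(!is.finite(mu))) return(-Inf)
  ll <- 0
  # Single-observation subjects: the integral over eta is available in
  # closed form (log value is marginally Normal(mu, omega^2 + sigma^2)).
  if (length(idx$single)) {
    i <- idx$single
    s_tot <- sqrt(omega^2 + sigma^2)
    z <- (d$log_value[i] - mu[i]) / s_tot
    cen <- d$censored[i]
    ll <- ll + sum(stats::dnorm(z[!cen], log = TRUE) - log(s_tot)) +
      sum(stats::pnorm(z[cen], log.p = TRUE))
  }
  if (length(idx$multi)) {
    if (omega < 1e-10) {
      for (i in idx$multi) {
        ll <- ll + sum(cond_loglik(d$log_value[i], mu[i], d$censored[i],
                                   0, sigma))
      }
    } else {
      gh <- gh_rule(quad_nodes)
      for (i in idx$multi) {
        ll <- ll + agq_subject(d$log_value[i], mu[i], d$censored[i],
                               omega, sigma, gh)
      }
    }
  }
  ll
}

# Adaptive Gauss-Hermite for one subject: center and scale the rule at the
# mode and curvature of the integrand log f(eta) = sum cond_loglik + prior.
agq_subject <- function(log_value, mu, censored, omega, sigma, gh) {
  g <- function(eta) {
    sum(cond_loglik(log_value, mu, censored, eta, sigma)) +
      stats::dnorm(eta, 0, omega, log = TRUE)
  }
  r <- range(c(0, log_value - mu))
  lo <- r[1] - 6 * omega - 3 * sigma
  hi <- r[2] + 6 * omega + 3 * sigma
  opt <- stats::optimize(function(e) g(e), c(lo, hi), maximum = TRUE,
                         tol = 1e-9)
  mode <- opt$maximum
  h <- 1e-4 * (1 + abs(mode))
  d2 <- (g(mode + h) - 2 * opt$objective + g(mode - h)) / h^2
  s <- if (is.finite(d2) && d2 < 0) 1 / sqrt(-d2) else omega
  eta_k <- mode + sqrt(2) * s * gh$x
  lg <- vapply(eta_k, g, numeric(1))
  log(sqrt(2) * s) + logsumexp(log(gh$w) + gh$x^2 + lg)
}

#' Marginal log-likelihood of a censored lognormal mixed model
#'
#' Per subject i, integrates the conditional likelihood over the subject
#' effect eta ~ Normal(0, omega^2):
#' \deqn{\ell_i = \ln \int \prod_j \ell(y_{ij} \mid \eta)\,
#'   \phi(\eta; 0, \omega^2)\, d\eta,}
#' where observed (and above-ULOQ extrapolated) rows contribute the normal
#' density of the log value around \eqn{\ln m(age) + \eta} with SD sigma,
#' and below-LLOQ rows contribute \eqn{\Phi((\ln LLOQ_{eff} - \ln m(age) -
#' \eta)/\sigma)}. Integration is exact (closed form) for subjects with a
#' single observation and adaptive Gauss-Hermite quadrature (default 21
#' nodes, centred and scaled at the mode of the integrand) otherwise.
#'
#' @param model A [struct_model()].
#' @param variability A [variability_model()].
#' @param data A tibble from [prepare_mixed_data()] (columns `subject_id`,
#'   `age`, `log_value`, `censored`).
#' @param quad_nodes Number of quadrature nodes.
#' @return The scalar marginal log-likelihood.
#' @export
marginal_loglik <- function(model, variability, data, quad_nodes = 21) {
  stopifnot(inherits(variability, "variability_model"))
  if (!nrow(data)) stop("empty data", call. = FALSE)
  marginal_loglik_prepared(prepare_ll_index(data), model,
                           variability$omega, variability$sigma, quad_nodes)
}

# --- internal parameterisation (unconstrained scale) per structural model ---

model_par_info <- function(model_id) {
  model_id <- normalize_model_id(model_id)
  switch(model_id,
    M0_constant = list(names = "lb0"),
    M1_linear = list(names = c("lb0", "tb1")),
    M2_exponential = list(names = c("lb0", "b1")),
    M3_asymptote = list(names = c("lb0", "lba", "lb1")),
    M4_logistic = list(names = c("lb0", "lba", "lb1", "lt50"))
  )
}

theta_to_model <- function(model_id, th) {
  switch(model_id,
    M0_constant = struct_model("M0", exp(th[1]), 0),
    # M1 slope mapped via (exp(t) - 1)/13 so the median stays positive on
    # ages [0, 13]
    M1_linear = struct_model("M1", exp(th[1]), (exp(th[2]) - 1) / 13),
    M2_exponential = struct_model("M2", exp(th[1]), th[2]),
    M3_asymptote = struct_model("M3", exp(th[1]), exp(th[3]),
                                beta_asym = exp(th[2])),
    M4_logistic = struct_model("M4", exp(th[1]), exp(th[3]),
                               beta_asym = exp(th[2]), t50 = exp(th[4]))
  )
}

model_to_natural <- function(model) {
  switch(model$model_id,
    M0_constant = c(beta0 = model$beta0),
    M1_linear = ,
    M2_exponential = c(beta0 = model$beta0, beta1 = model$beta1),
    M3_asymptote = c(beta0 = model$beta0, beta1 = model$beta1,
                     beta_asym = model$beta_asym),
    M4_logistic = c(beta0 = model$beta0, beta1 = model$beta1,
                    beta_asym = model$beta_asym, t50 = model$t50)
  )
}

natural_to_model <- function(model_id, p) {
  struct_model(model_id, p[["beta0"]],
               if ("beta1" %in% names(p)) p[["beta1"]] else 0,
               beta_asym = if ("beta_asym" %in% names(p)) p[["beta_asym"]],
               t50 = if ("t50" %in% names(p)) p[["t50"]])
}

default_start_theta <- function(model_id, data) {
  unc <- !data$censored
  if (sum(unc) >= 3 && length(unique(data$age[unc])) > 1) {
    lmfit <- stats::lm(data$log_value[unc] ~ data$age[unc])
    a <- stats::coef(lmfit)[[1]]
    b <- stats::coef(lmfit)[[2]]
    sd_res <- stats::sd(stats::resid(lmfit))
  } else {
    a <- mean(data$log_value)
    b <- 0
    sd_res <- max(stats::sd(data$log_value), 0.3)
  }
  th <- switch(model_id,
    M0_constant = c(a + 6 * b),
    M1_linear = c(a, log(max(1 + 13 * b, 0.05))),
    M2_exponential = c(a, b),
    M3_asymptote = c(a, a + 12 * b, log(0.2)),
    M4_logistic = c(a, a + 12 * b, log(0.5), log(6))
  )
  list(theta = th, sd_res = max(sd_res, 0.05, na.rm = TRUE))
}

#' Fit a censored nonlinear mixed-effects age model
#'
#' Maximises the marginal likelihood of [marginal_loglik()] over the
#' structural parameters, the between-subject SD omega and (optionally) the
#' residual SD sigma, with variance parameters estimated on the log scale.
#' Starting values are taken from an uncensored log-linear regression and
#' perturbed into `starts` multi-start replicates (Nelder-Mead each,
#' best-likelihood selection); the fit is deterministic given
#' `(data, starts, seed)`. Standard errors come from a finite-difference
#' Hessian of the marginal log-likelihood at the optimum (flagged
#' unavailable when not positive definite).
#'
#' When every subject contributes a single observation, only the total
#' log-variance omega^2 + sigma^2 is identified; `sigma` therefore defaults
#' to a fixed assay value of 0.2 (log-SD, ~20% CV) and only omega is
#' estimated. Pass `sigma = "estimate"` for data with replicate
#' observations per subject (e.g. the shared-eta pooled mode).
#'
#' @param data A tibble from [prepare_mixed_data()].
#' @param model_id Structural model (`"M1"`..`"M4"`, `"M0"` for the age-free
#'   null; long names accepted).
#' @param omega `"estimate"` (default) or a fixed non-negative value.
#' @param sigma A fixed positive value (default 0.2) or `"estimate"`.
#' @param quad_nodes Gauss-Hermite order for multi-observation subjects.
#' @param starts Number of multi-start replicates.
#' @param seed Seed for start-value perturbations.
#' @param start_values Optional list overriding the automatic starts:
#'   a `struct_model` in `$model` and numerics `$omega` / `$sigma`.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return An object of class `mixed_fit`: the fitted [struct_model()],
#'   `omega`, `sigma`, standard errors, `loglik`, `aic`, counts,
#'   `converged`, and derived quantities (`value_infancy`, `value_12y`,
#'   `change_12y`, `iiv_cv`, `ruv_cv`).
#' @export
fit_mixed <- function(data, model_id, omega = "estimate", sigma = 0.2,
                      quad_nodes = 21, starts = 5, seed = 1,
                      start_values = NULL, maxit = 2000) {
  model_id <- normalize_model_id(model_id)
  n_subjects <- length(unique(data$subject_id))
  if (n_subjects < 10) stop("need at least 10 subjects", call. = FALSE)
  if (all(data$censored)) stop("all observations are censored",
                               call. = FALSE)
  est_omega <- identical(omega, "estimate")
  est_sigma <- identical(sigma, "estimate")
  if (!est_omega && (!is.numeric(omega) || omega < 0)) {
    stop("omega must be \"estimate\" or a non-negative number",
         call. = FALSE)
  }
  if (!est_sigma && (!is.numeric(sigma) || sigma <= 0)) {
    stop("sigma must be \"estimate\" or a positive number", call. = FALSE)
  }
  idx <- prepare_ll_index(data)
  pinfo <- model_par_info(model_id)
  npar_s <- length(pinfo$names)

  split_theta <- function(th) {
    k <- npar_s
    om <- if (est_omega) exp(th[k + 1]) else omega
    sg <- if (est_sigma) exp(th[length(th)]) else sigma
    list(model = theta_to_model(model_id, th[seq_len(k)]),
         omega = om, sigma = sg)
  }
  nll <- function(th) {
    p <- tryCatch(split_theta(th), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ll <- marginal_loglik_prepared(idx, p$model, p$omega, p$sigma,
                                   quad_nodes)
    if (!is.finite(ll)) 1e10 else -ll
  }

  st <- default_start_theta(model_id, data)
  base_theta <- st$theta
  if (!is.null(start_values)) {
    if (!is.null(start_values$model)) {
      nat <- model_to_natural(start_values$model)
      base_theta <- switch(model_id,
        M0_constant = log(nat[["beta0"]]),
        M1_linear = c(log(nat[["beta0"]]),
                      log(1 + 13 * nat[["beta1"]])),
        M2_exponential = c(log(nat[["beta0"]]), nat[["beta1"]]),
        M3_asymptote = c(log(nat[["beta0"]]), log(nat[["beta_asym"]]),
                         log(nat[["beta1"]])),
        M4_logistic = c(log(nat[["beta0"]]), log(nat[["beta_asym"]]),
                        log(nat[["beta1"]]), log(nat[["t50"]]))
      )
    }
    if (!is.null(start_values$omega)) st$omega0 <- start_values$omega
    if (!is.null(start_values$sigma)) st$sigma0 <- start_values$sigma
  }
  sigma0 <- if (!is.null(st$sigma0)) st$sigma0 else
    if (est_sigma) max(st$sd_res / sqrt(2), 0.05) else sigma
  omega0 <- if (!is.null(st$omega0)) st$omega0 else
    max(sqrt(max(st$sd_res^2 - sigma0^2, 1e-4)), 0.05)
  th0 <- c(base_theta,
           if (est_omega) log(omega0),
           if (est_sigma) log(sigma0))

  runs <- withr::with_seed(seed, {
    lapply(seq_len(starts), function(i) {
      thi <- if (i == 1) th0 else th0 + stats::rnorm(length(th0), 0, 0.3)
      stats::optim(thi, nll, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10))
    })
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  converged <- best$convergence == 0 && best$value < 1e9
  if (!converged) {
    warning("fit_mixed(", model_id, "): no start converged cleanly; ",
            "returning best attempt", call. = FALSE)
  }
  p <- split_theta(best$par)
  loglik <- -best$value
  k <- length(best$par)

  # SEs: finite-difference Hessian on the natural parameter scale
  nat <- model_to_natural(p$model)
  nat_names <- names(nat)
  full <- c(nat, if (est_omega) c(omega = p$omega),
            if (est_sigma) c(sigma = p$sigma))
  nll_nat <- function(v) {
    names(v) <- names(full)
    m <- tryCatch(natural_to_model(model_id, v[nat_names]),
                  error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    om <- if (est_omega) v[["omega"]] else omega
    sg <- if (est_sigma) v[["sigma"]] else sigma
    if (om < 0 || sg <= 0) return(NA_real_)
    -marginal_loglik_prepared(idx, m, om, sg, quad_nodes)
  }
  se <- rep(NA_real_, length(full))
  names(se) <- names(full)
  se_available <- FALSE
  H <- tryCatch(pracma::hessian(nll_nat, full), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) {
      se <- sqrt(diag(V))
      names(se) <- names(full)
      se_available <- TRUE
    }
  }

  v0 <- median_at_age(p$model, 0)
  v12 <- median_at_age(p$model, 12)
  structure(list(
    model = p$model, omega = p$omega, sigma = p$sigma,
    omega_fixed = !est_omega, sigma_fixed = !est_sigma,
    se = se, se_available = se_available,
    loglik = loglik, k = k, aic = 2 * k - 2 * loglik,
    n_subjects = n_subjects, n_obs = nrow(data),
    n_censored = sum(data$censored),
    converged = converged, quad_nodes = quad_nodes,
    value_infancy = v0, value_12y = v12,
    change_12y = percent_change(v0, v12),
    iiv_cv = iiv_cv_percent(p$omega),
    ruv_cv = iiv_cv_percent(p$sigma),
    data = idx$data,
    lloq_eff = attr(data, "lloq_eff"),
    uloq_eff = attr(data, "uloq_eff")
  ), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("<mixed_fit>", x$model$model_id,
      sprintf("(n = %d subjects, %d obs, %d censored)\n",
              x$n_subjects, x$n_obs, x$n_censored))
  cat(sprintf("  beta0 %.4g  beta1 %.4g", x$model$beta0, x$model$beta1))
  if (!is.null(x$model$beta_asym)) {
    cat(sprintf("  beta_asym %.4g", x$model$beta_asym))
  }
  if (!is.null(x$model$t50)) cat(sprintf("  t50 %.3g", x$model$t50))
  cat(sprintf("\n  omega %.4g (IIV CV %.1f%%)  sigma %.4g%s\n",
              x$omega, x$iiv_cv, x$sigma,
              if (x$sigma_fixed) " [fixed]" else ""))
  cat(sprintf("  logLik %.3f  AIC %.3f  converged: %s\n",
              x$loglik, x$aic, x$converged))
  cat(sprintf("  infancy %.4g pg/mL -> 12 y %.4g pg/mL (change %+d%%)\n",
              x$value_infancy, x$value_12y, x$change_12y))
  invisible(x)
}

#' Select among fitted structural models by AIC with a parsimony tie-break
#'
#' Ranks converged fits by AIC; all models within 2 AIC units of the best
#' are treated as statistically equivalent and the tie is resolved toward
#' the fewest estimated parameters (then toward the lower AIC).
#'
#' @param fits A list of [fit_mixed()] results (any names).
#' @return A list with `chosen` (model_id), `fit` (the chosen `mixed_fit`)
#'   and `ranking` (a tibble with model_id, k, loglik, aic, delta_aic).
#' @export
select_model <- function(fits) {
  fits <- fits[vapply(fits, function(f) inherits(f, "mixed_fit"),
                      logical(1))]
  conv <- fits[vapply(fits, `[[`, logical(1), "converged")]
  if (!length(conv)) stop("no converged fits to select from", call. = FALSE)
  ranking <- tibble::tibble(
    model_id = vapply(conv, function(f) f$model$model_id, character(1)),
    k = vapply(conv, `[[`, numeric(1), "k"),
    loglik = vapply(conv, `[[`, numeric(1), "loglik"),
    aic = vapply(conv, `[[`, numeric(1), "aic")
  ) |>
    dplyr::mutate(delta_aic = .data$aic - min(.data$aic)) |>
    dplyr::arrange(.data$aic)
  tied <- ranking |> dplyr::filter(.data$delta_aic < 2) |>
    dplyr::arrange(.data$k, .data$aic)
  chosen <- tied$model_id[1]
  list(chosen = chosen,
       fit = conv[[which(vapply(conv, function(f) f$model$model_id,
                                character(1)) == chosen)[1]]],
       ranking = ranking)
}

#' Percent of between-subject variance explained by age
#'
#' Compares the between-subject variance of an age-dependent fit with the
#' nested age-free fit on the same data:
#' \eqn{100 (1 - \omega^2_{age} / \omega^2_{no\,age})}, floored at 0 (a
#' nominally negative share is sampling noise).
#'
#' @param fit_with_age,fit_no_age [fit_mixed()] results on identical data;
#'   `fit_no_age` is the model with the age coefficient fixed at zero
#'   (model `"M0"`).
#' @return Percent in `[0, 100]`.
#' @export
variance_explained_by_age <- function(fit_with_age, fit_no_age) {
  stopifnot(inherits(fit_with_age, "mixed_fit"),
            inherits(fit_no_age, "mixed_fit"))
  if (fit_no_age$n_obs != fit_with_age$n_obs) {
    stop("fits must be on the same data", call. = FALSE)
  }
  if (fit_no_age$omega <= 0) stop("omega of the age-free fit is zero",
                                  call. = FALSE)
  max(0, 100 * (1 - fit_with_age$omega^2 / fit_no_age$omega^2))
}

#' Serialize a mixed fit to JSON
#'
#' @param fit A [fit_mixed()] result.
#' @param path Optional file path; if given, the JSON is written there.
#' @return The JSON string (invisibly if `path` is given).
#' @export
mixed_fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "mixed_fit"))
  x <- list(
    model_id = fit$model$model_id,
    beta0 = fit$model$beta0, beta1 = fit$model$beta1,
    beta_asym = fit$model$beta_asym, t50 = fit$model$t50,
    omega = fit$omega, sigma = fit$sigma,
    sigma_fixed = fit$sigma_fixed,
    se = as.list(fit$se), se_available = fit$se_available,
    loglik = fit$loglik, aic = fit$aic, k = fit$k,
    n_subjects = fit$n_subjects, n_obs = fit$n_obs,
    n_censored = fit$n_censored, converged = fit$converged,
    value_infancy = fit$value_infancy, value_12y = fit$value_12y,
    change_12y = fit$change_12y, iiv_cv = fit$iiv_cv, ruv_cv = fit$ruv_cv
  )
  x <- x[!vapply(x, is.null, logical(1))]
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
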