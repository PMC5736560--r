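# Shared fixtures and independent oracles used across the suite.

# A single-entry panel tibble from explicit parameters
panel_entry <- function(cytokine = "TNFa", condition = "SEB",
                        beta0 = 4740, value_12y = 10859, iiv_cv = 66,
                        sigma = 0.2, model_id = "M2_exponential",
                        beta1 = log(value_12y / beta0) / 12) {
  tibble::tibble(cytokine = cytokine, condition = condition,
                 model_id = model_id, beta0 = beta0,
                 value_12y = value_12y, beta1 = beta1, iiv_cv = iiv_cv,
                 omega = cv_to_omega(iiv_cv), sigma = sigma,
                 quantifiable = TRUE)
}

# Simulate one cytokine x condition cohort ready for fitting
simulate_entry_data <- function(n = 271, seed = 1, panel = panel_entry(),
                                limits = default_assay_limits()) {
  co <- simulate_cohort(n, seed = seed)
  obs <- simulate_concentrations(co, panel, seed = seed + 1000) |>
    apply_quantification_limits(limits)
  prepare_mixed_data(obs, co, panel$cytokine[1], panel$condition[1],
                     limits)
}

# O(n^2) pair-enumeration Kendall tau-b oracle
kendall_tau_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  # counts of pairs tied in x (incl. both) and in y
  tied_x <- sum(choose(table(x), 2))
  tied_y <- sum(choose(table(y), 2))
  (conc - disc) / sqrt((n0 - tied_x) * (n0 - tied_y))
}

# Dense iterative grid search over (alpha0, alpha1, log sigma) maximising
# the left-censored Gaussian likelihood; independent of fit_tobit.
tobit_grid_oracle <- function(y, cens, x, passes = 10, width0 = 3,
                              n_grid = 21) {
  ll <- function(a0, a1, s) {
    mu <- a0 + a1 * x
    sum(dnorm(y[!cens], mu[!cens], s, log = TRUE)) +
      sum(pnorm((y[cens] - mu[cens]) / s, log.p = TRUE))
  }
  ctr <- c(mean(y), 0, 0)
  width <- c(width0, width0, 5)
  for (p in seq_len(passes)) {
    g0 <- seq(ctr[1] - width[1], ctr[1] + width[1], length.out = n_grid)
    g1 <- seq(ctr[2] - width[2], ctr[2] + width[2], length.out = n_grid)
    g2 <- seq(ctr[3] - width[3], ctr[3] + width[3], length.out = n_grid)
    best <- -Inf
    for (a0 in g0) for (a1 in g1) for (ls in g2) {
      v <- ll(a0, a1, exp(ls))
      if (v > best) {
        best <- v
        ctr <- c(a0, a1, ls)
      }
    }
    width <- width * 0.3  # new window spans +/- 3 grid cells of the old
  }
  list(alpha0 = ctr[1], alpha1 = ctr[2], sigma = exp(ctr[3]),
       loglik = best)
}

# Brute-force trapezoid marginal log-likelihood oracle
trapezoid_loglik <- function(model, omega, sigma, data, half_width = 6,
                             n_points = 2001) {
  sum(vapply(split(seq_len(nrow(data)), data$subject_id), function(i) {
    eta <- seq(-half_width * omega, half_width * omega,
               length.out = n_points)
    mu <- log(median_at_age(model, data$age[i]))
    f <- vapply(eta, function(e) {
      li <- ifelse(data$censored[i],
                   pnorm((data$log_value[i] - mu - e) / sigma),
                   dnorm(data$log_value[i], mu + e, sigma))
      prod(li) * dnorm(e, 0, omega)
    }, numeric(1))
    log(pracma::trapz(eta, f))
  }, numeric(1)))
}
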