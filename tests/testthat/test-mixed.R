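make_multiobs_data <- function() {
  d <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 2),
    age = c(1, 1, 4, 4, 9, 9),
    log_value = c(log(20), log(25), log(3.2), log(18), log(40), log(55)),
    censored = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  attr(d, "lloq_eff") <- 3.2
  d
}

test_that("marginal likelihood reduces to closed forms at omega = 0", {
  lim <- attr(make_multiobs_data(), "lloq_eff")
  m <- struct_model("M2", 20, 0.05)
  # one uncensored observation: exactly the lognormal density of the value
  d1 <- tibble::tibble(subject_id = "a", age = 3, log_value = log(30),
                       censored = FALSE)
  v <- variability_model(0, 0.25)
  expect_equal(marginal_loglik(m, v, d1),
               dnorm(log(30), log(median_at_age(m, 3)), 0.25, log = TRUE))
  # one censored observation with the median at the bound: ln 0.5
  m_b <- struct_model("M2", lim, 0)
  d2 <- tibble::tibble(subject_id = "a", age = 3, log_value = log(lim),
                       censored = TRUE)
  expect_equal(marginal_loglik(m_b, v, d2), log(0.5))
})

test_that("adaptive quadrature matches brute-force trapezoid integration", {
  d <- make_multiobs_data()
  m <- struct_model("M2", 20, 0.05)
  for (om in c(0.3, 0.5, 1.0)) {
    v <- variability_model(om, 0.25)
    ll <- marginal_loglik(m, v, d)
    oracle <- trapezoid_loglik(m, om, 0.25, d)
    expect_equal(ll, oracle, tolerance = 1e-6)
  }
})

test_that("marginal likelihood is invariant to row and subject order", {
  d <- make_multiobs_data()
  m <- struct_model("M2", 20, 0.05)
  v <- variability_model(0.5, 0.25)
  ll <- marginal_loglik(m, v, d)
  perm <- withr::with_seed(3, sample(nrow(d)))
  d_perm <- d[perm, ]
  attr(d_perm, "lloq_eff") <- attr(d, "lloq_eff")
  expect_equal(marginal_loglik(m, v, d_perm), ll)
})

test_that("increasing quadrature order leaves the likelihood unchanged", {
  d <- make_multiobs_data()
  m <- struct_model("M2", 20, 0.05)
  v <- variability_model(0.5, 0.25)
  expect_lt(abs(marginal_loglik(m, v, d, quad_nodes = 21) -
                  marginal_loglik(m, v, d, quad_nodes = 41)), 1e-4)
})

test_that("noise-free data recover the generating parameters", {
  pan <- panel_entry(beta0 = 100, value_12y = 300, iiv_cv = 0,
                     sigma = 0.01)
  d <- simulate_entry_data(n = 100, seed = 101, panel = pan)
  f <- fit_mixed(d, "M2", omega = 0, sigma = "estimate", starts = 3)
  expect_true(f$converged)
  expect_equal(f$model$beta0, 100, tolerance = 0.01)
  expect_equal(f$model$beta1, log(3) / 12, tolerance = 0.01)
})

test_that("with omega = 0 and no censoring the fit equals log-scale NLS", {
  pan <- panel_entry(beta0 = 500, value_12y = 1500, iiv_cv = 0,
                     sigma = 0.4)
  d <- simulate_entry_data(n = 120, seed = 103, panel = pan)
  expect_equal(sum(d$censored), 0)
  f <- fit_mixed(d, "M2", omega = 0, sigma = "estimate", starts = 3)
  nls_fit <- nls(log_value ~ lb0 + b1 * age, data = d,
                 start = list(lb0 = log(500), b1 = 0.1))
  expect_equal(f$model$beta0, exp(coef(nls_fit)[["lb0"]]),
               tolerance = 1e-3)
  expect_equal(f$model$beta1, coef(nls_fit)[["b1"]], tolerance = 1e-3)
})

test_that("refitting the same data with the same seed is deterministic", {
  d <- simulate_entry_data(n = 80, seed = 105)
  f1 <- fit_mixed(d, "M2", starts = 3, seed = 7)
  f2 <- fit_mixed(d, "M2", starts = 3, seed = 7)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("fit output is internally consistent and tidies cleanly", {
  d <- simulate_entry_data(n = 120, seed = 107)
  f <- fit_mixed(d, "M2", starts = 3)
  expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
  expect_equal(f$value_infancy, median_at_age(f$model, 0))
  expect_equal(f$change_12y,
               percent_change(f$value_infancy, f$value_12y))
  expect_equal(f$iiv_cv, iiv_cv_percent(f$omega))
  td <- tidy(f)
  expect_setequal(td$term, c("beta0", "beta1", "omega"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(f)
  expect_equal(gl$AIC, f$aic)
  js <- jsonlite::fromJSON(mixed_fit_to_json(f))
  expect_equal(js$beta0, f$model$beta0)
  expect_equal(js$change_12y, f$change_12y)
})

test_that("the asymptote model nests a decreasing exponential", {
  pan <- panel_entry(cytokine = "TNFa", condition = "nil", beta0 = 19.5,
                     value_12y = 7.5, iiv_cv = 73)
  d <- simulate_entry_data(n = 271, seed = 109, panel = pan)
  f2 <- fit_mixed(d, "M2", starts = 3)
  f3 <- fit_mixed(d, "M3", starts = 3,
                  start_values = list(model = struct_model(
                    "M3", f2$model$beta0, -f2$model$beta1,
                    beta_asym = 1e-3), omega = f2$omega))
  expect_gte(f3$loglik, f2$loglik - 0.01)
})

test_that("model selection ranks by AIC and breaks ties by parsimony", {
  d <- simulate_entry_data(n = 150, seed = 111)
  fits <- lapply(c("M0", "M1", "M2", "M3"), fit_mixed, data = d,
                 starts = 2)
  sel <- select_model(fits)
  expect_true(sel$chosen %in% sel$ranking$model_id)
  expect_equal(sel$ranking$aic, sort(sel$ranking$aic))
  best_aic <- min(sel$ranking$aic)
  tied <- sel$ranking[sel$ranking$aic - best_aic < 2, ]
  expect_equal(sel$chosen,
               tied$model_id[order(tied$k, tied$aic)][1])
  # single converged fit is returned trivially
  one <- select_model(fits[3])
  expect_equal(one$chosen, "M2_exponential")
  expect_error(select_model(list()), "no converged fits")
})

test_that("variance explained by age recovers a constructed partition", {
  # age absorbs a designed share of log-variance: log y = log b0 +
  # b1 * age + eta, so the age share is b1^2 var(age) over the total
  b1 <- 0.12
  omega_res <- 0.45
  pan <- panel_entry(beta0 = 100, value_12y = 100 * exp(12 * b1),
                     iiv_cv = iiv_cv_percent(omega_res), sigma = 0.05)
  d <- simulate_entry_data(n = 271, seed = 113, panel = pan)
  share <- b1^2 * var(d$age) / (b1^2 * var(d$age) + omega_res^2)
  f_age <- fit_mixed(d, "M2", sigma = 0.05, starts = 3)
  f_null <- fit_mixed(d, "M0", sigma = 0.05, starts = 3)
  got <- variance_explained_by_age(f_age, f_null)
  expect_equal(got / 100, share, tolerance = 0.2)
  # identical omegas give exactly zero; noise floors at zero
  expect_equal(variance_explained_by_age(f_age, f_age), 0)
})

test_that("degenerate fitting inputs error clearly", {
  d <- simulate_entry_data(n = 30, seed = 115)
  expect_error(fit_mixed(d[d$subject_id %in% unique(d$subject_id)[1:5], ],
                         "M2"), "10 subjects")
  d_cens <- dplyr::mutate(d, censored = TRUE)
  attr(d_cens, "lloq_eff") <- attr(d, "lloq_eff")
  expect_error(fit_mixed(d_cens, "M2"), "censored")
  expect_error(fit_mixed(d, "M7"), "unknown model_id")
})
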