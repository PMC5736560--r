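test_that("simulate_cohort respects bounds, size and determinism", {
  co <- simulate_cohort(271, seed = 5)
  expect_equal(nrow(co), 271)
  expect_true(all(co$age >= 0.1 & co$age <= 12.8))
  expect_true(all(co$vitd >= 11 & co$vitd <= 142))
  expect_true(all(co$sex %in% c("boy", "girl")))
  expect_identical(co, simulate_cohort(271, seed = 5))
  expect_false(identical(co, simulate_cohort(271, seed = 6)))
  expect_error(simulate_cohort(0, seed = 1), "n")
})

test_that("cohort marginals match their calibration targets at large n", {
  co <- simulate_cohort(50000, seed = 21)
  # boy fraction within binomial 0.74 +/- 0.01
  expect_lt(abs(mean(co$sex == "boy") - 0.74), 0.01)
  q_age <- quantile(co$age, c(0.25, 0.5, 0.75))
  expect_equal(unname(q_age), c(3.5, 5.3, 7.9), tolerance = 0.05)
  q_vd <- quantile(co$vitd, c(0.25, 0.5, 0.75))
  expect_equal(unname(q_vd), c(40, 54, 69), tolerance = 0.05)
  expect_lt(abs(mean(co$weight_z) - 0.25), 0.03)
})

test_that("age-vitamin D dependence recovers the configured Kendall tau", {
  co <- simulate_cohort(10000, seed = 31)
  expect_lt(abs(kendall_tau(co$age, co$vitd) - (-0.13)), 0.03)
})

test_that("simulated concentrations follow the lognormal age model", {
  # noise-free limit: values equal the median function
  pan0 <- panel_entry(beta0 = 100, value_12y = 300, iiv_cv = 0,
                      sigma = 1e-9)
  co <- simulate_cohort(200, seed = 41)
  obs0 <- simulate_concentrations(co, pan0, seed = 42)
  m <- struct_model("M2", 100, log(3) / 12)
  expect_equal(obs0$true_value,
               median_at_age(m, co$age[match(obs0$subject_id,
                                             co$subject_id)]),
               tolerance = 1e-6)
  # median in the youngest age band tracks beta0 (Monte-Carlo oracle)
  pan <- panel_entry()   # beta0 4740, IIV CV 66%, sigma 0.2
  cfg <- cohort_config(age_meanlog = log(1), age_sdlog = 0.05,
                       age_range = c(0.8, 1.2))
  young <- simulate_cohort(10000, seed = 43, config = cfg)
  obs <- simulate_concentrations(young, pan, seed = 44)
  m_true <- struct_model("M2", 4740, log(10859 / 4740) / 12)
  expected_med <- median(median_at_age(m_true, young$age))
  expect_equal(median(obs$true_value) / expected_med, 1, tolerance = 0.03)
  # log-scale variance at (nearly) fixed age is omega^2 + sigma^2
  v_emp <- var(log(obs$true_value) -
                 log(median_at_age(m_true, young$age)))
  v_true <- cv_to_omega(66)^2 + 0.2^2
  se <- v_true * sqrt(2 / (nrow(obs) - 1))
  expect_lt(abs(v_emp - v_true), 3 * se)
})

test_that("shared-eta mode correlates a subject's conditions, independent does not", {
  pan2 <- dplyr::bind_rows(panel_entry(condition = "SEB"),
                           panel_entry(condition = "PHA", beta0 = 352,
                                       value_12y = 930, iiv_cv = 157))
  co <- simulate_cohort(2000, seed = 51)
  get_cor <- function(mode, seed) {
    obs <- simulate_concentrations(co, pan2, seed = seed, eta_mode = mode)
    wide <- tidyr::pivot_wider(obs[c("subject_id", "condition",
                                     "true_value")],
                               names_from = "condition",
                               values_from = "true_value")
    cor(log(wide$SEB), log(wide$PHA))
  }
  expect_gt(get_cor("shared", 52), 0.5)
  expect_lt(abs(get_cor("independent", 53)), 0.1)
})

test_that("quantification limits partition observations and keep bounds", {
  obs <- tibble::tibble(
    subject_id = sprintf("S%d", 1:4),
    cytokine = "TNFa",
    condition = c("nil", "SEB", "SEB", "SEB"),
    value = c(2.0, 50000, 200000, 35),
    true_value = c(2.0, 50000, 200000, 35),
    status = "observed"
  )
  out <- apply_quantification_limits(obs)
  expect_equal(out$status, c("below_lloq", "observed",
                             "above_uloq_extrapolated", "observed"))
  expect_equal(out$value, c(3.2, 50000, 200000, 35))
  # every observation has exactly one status; counts partition the total
  expect_equal(sum(table(out$status)), nrow(out))
  expect_error(apply_quantification_limits(dplyr::mutate(obs,
                                                         value = -1)),
               "negative")
  expect_error(apply_quantification_limits(
    dplyr::mutate(obs, condition = "unknown")), "limits")
})

test_that("empirical censoring matches below_lloq_probability", {
  pan <- panel_entry(cytokine = "IFNg", condition = "nil", beta0 = 5.4,
                     value_12y = 5.4, iiv_cv = 248, sigma = 0.2)
  cfg <- cohort_config(age_meanlog = log(5), age_sdlog = 0.02,
                       age_range = c(4.5, 5.5))
  co <- simulate_cohort(1e5, seed = 61)
  obs <- simulate_concentrations(co, pan, seed = 62) |>
    apply_quantification_limits()
  p <- below_lloq_probability(struct_model("M2", 5.4, 0),
                              variability_model(cv_to_omega(248), 0.2),
                              5, assay_limits(3.2, 10000))
  emp <- mean(obs$status == "below_lloq")
  expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("datasets and panels round-trip through their file formats", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(40, seed = 71)
  obs <- simulate_concentrations(co, panel_entry(), seed = 72) |>
    apply_quantification_limits()
  write_dataset(co, obs, dir)
  co2 <- read_subjects(file.path(dir, "subjects.csv"))
  obs2 <- read_observations(file.path(dir, "observations.csv"))
  expect_equal(co2$age, co$age)
  expect_equal(obs2$value, obs$value)
  expect_equal(obs2$status, obs$status)
  # identical seeds -> identical bytes
  dir2 <- withr::local_tempdir()
  write_dataset(simulate_cohort(40, seed = 71),
                simulate_concentrations(simulate_cohort(40, seed = 71),
                                        panel_entry(), seed = 72) |>
                  apply_quantification_limits(), dir2)
  expect_identical(readLines(file.path(dir, "observations.csv")),
                   readLines(file.path(dir2, "observations.csv")))
  # panel YAML round-trip
  pfile <- file.path(dir, "panel.yaml")
  write_panel(default_panel(), pfile)
  pan2 <- read_panel(pfile)
  expect_equal(as.data.frame(pan2), as.data.frame(default_panel()),
               tolerance = 1e-12)
})

test_that("the default panel mirrors the reference parameterisation", {
  pan <- default_panel()
  expect_equal(nrow(pan), 32)  # 8 cytokines x 4 conditions
  seb_tnfa <- pan[pan$cytokine == "TNFa" & pan$condition == "SEB", ]
  expect_equal(seb_tnfa$beta0, 4740)
  expect_equal(seb_tnfa$beta1, log(10859 / 4740) / 12)
  expect_equal(seb_tnfa$omega, cv_to_omega(66))
  # unquantifiable unstimulated interleukins simulate flat below the LLOQ
  na_rows <- pan[!pan$quantifiable, ]
  expect_setequal(na_rows$cytokine, c("IL2", "IL4", "IL6", "IL10"))
  expect_true(all(na_rows$condition == "nil"))
  expect_true(all(na_rows$beta0 == 2 & na_rows$beta1 == 0))
})
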