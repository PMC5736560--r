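#' Age-dependent percentile (reference-range) curves
#'
#' Computes percentile curves of the modelled concentration distribution on
#' an age grid. With basis `"between_subject"` (default) the curves describe
#' the distribution of subjects' underlying levels,
#' \eqn{P_q(age) = m(age) e^{z_q \omega}}; basis `"total"` adds residual
#' variability, replacing omega with \eqn{\sqrt{\omega^2 + \sigma^2}}, and
#' describes single noisy measurements. `method = "monte_carlo"` instead
#' takes empirical percentiles of `nsim` simulated individuals per grid age
#' (seeded), which must agree with the closed form up to simulation error.
#'
#' @param fit A converged [fit_mixed()] result (or a list with elements
#'   `model` and `variability`).
#' @param age_grid Ages (years) at which to evaluate; default 0--13 by 0.1.
#' @param levels Percentile levels in (0, 100); default 5, 50, 95.
#' @param basis `"between_subject"` or `"total"`.
#' @param method `"closed_form"` or `"monte_carlo"`.
#' @param nsim,seed Monte-Carlo settings.
#' @return A tibble of class `centile_curves` with columns `age`, `level`,
#'   `value`; attributes `basis` and `method`.
#' @export
percentile_curves <- function(fit, age_grid = seq(0, 13, by = 0.1),
                              levels = c(5, 50, 95),
                              basis = c("between_subject", "total"),
                              method = c("closed_form", "monte_carlo"),
                              nsim = 10000, seed = NULL) {
  basis <- match.arg(basis)
  method <- match.arg(method)
  if (inherits(fit, "mixed_fit")) {
    if (!fit$converged) stop("fit did not converge", call. = FALSE)
    model <- fit$model
    omega <- fit$omega
    sigma <- fit$sigma
  } else {
    model <- fit$model
    omega <- fit$variability$omega
    sigma <- fit$variability$sigma
  }
  if (any(levels <= 0 | levels >= 100)) {
    stop("levels must lie strictly between 0 and 100", call. = FALSE)
  }
  s <- if (basis == "total") sqrt(omega^2 + sigma^2) else omega
  m <- median_at_age(model, age_grid)
  out <- if (method == "closed_form") {
    tidyr::expand_grid(age = age_grid, level = sort(levels)) |>
      dplyr::mutate(value = median_at_age(model, .data$age) *
                      exp(stats::qnorm(.data$level / 100) * s))
  } else {
    draw <- function() {
      purrr::map2_dfr(age_grid, m, function(a, mi) {
        y <- mi * exp(stats::rnorm(nsim, 0, s))
        tibble::tibble(age = a, level = sort(levels),
                       value = unname(stats::quantile(
                         y, sort(levels) / 100, type = 7)))
      })
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  structure(out, basis = basis, method = method, nsim = nsim,
            class = c("centile_curves", class(out)))
}

make_age_bins <- function(age, n_bins, min_per_bin = 3) {
  edges <- unique(stats::quantile(age, probs = seq(0, 1, length.out =
                                                     n_bins + 1),
                                  type = 7))
  bin <- cut(age, edges, include.lowest = TRUE, labels = FALSE)
  # merge under-filled bins into their left neighbour (right for bin 1)
  repeat {
    counts <- tabulate(bin, nbins = max(bin))
    small <- which(counts > 0 & counts < min_per_bin)
    if (!length(small)) break
    b <- small[1]
    target <- if (b == 1) min(setdiff(unique(bin), b)) else
      max(unique(bin)[unique(bin) < b])
    message("vpc: merging age bin ", b, " (n = ", counts[b],
            ") into bin ", target)
    bin[bin == b] <- target
  }
  match(bin, sort(unique(bin)))
}

#' Visual predictive check of a fitted age model
#'
#' Simulates `n_replicates` complete datasets at the observed ages from the
#' fitted model (including left-censoring at the effective LLOQ, with
#' censored values placed at the bound), computes the 5th/50th/95th
#' percentile of each replicate within age bins, and compares the observed
#' binned percentiles to the 90% prediction band of each percentile across
#' replicates.
#'
#' @param fit A converged [fit_mixed()] result.
#' @param data Observation tibble as used for fitting (default: the data
#'   stored in `fit`); columns `age`, `log_value`, `censored`.
#' @param n_replicates Number of replicate datasets (minimum 100).
#' @param age_bins Number of quantile-based age bins (bins with fewer than
#'   3 observations are merged with a neighbour).
#' @param levels Percentiles to check.
#' @param seed Integer seed.
#' @return An object of class `vpc_result`: `$bins` (one row per bin x
#'   level with observed value, band and coverage flag), `$coverage`
#'   (fraction of bins covered per level) and settings.
#' @export
vpc <- function(fit, data = fit$data, n_replicates = 200, age_bins = 6,
                levels = c(5, 50, 95), seed = NULL) {
  stopifnot(inherits(fit, "mixed_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (n_replicates < 100) {
    stop("n_replicates must be at least 100 for stable bands",
         call. = FALSE)
  }
  lloq_eff <- if (!is.null(fit$lloq_eff)) fit$lloq_eff else
    attr(data, "lloq_eff")
  if (is.null(lloq_eff)) lloq_eff <- -Inf
  age <- data$age
  obs_value <- exp(data$log_value)   # censored rows already at the bound
  bin <- make_age_bins(age, age_bins)
  n_bins <- max(bin)
  probs <- sort(levels) / 100

  bin_pct <- function(values) {
    vapply(seq_len(n_bins), function(b) {
      stats::quantile(values[bin == b], probs, type = 7)
    }, numeric(length(probs)))
  }
  obs_p <- bin_pct(obs_value)   # levels x bins

  m <- median_at_age(fit$model, age)
  simulate_bands <- function() {
    sims <- array(NA_real_, dim = c(length(probs), n_bins, n_replicates))
    below <- matrix(NA_real_, n_bins, n_replicates)
    for (r in seq_len(n_replicates)) {
      y <- m * exp(stats::rnorm(length(m), 0, fit$omega) +
                     stats::rnorm(length(m), 0, fit$sigma))
      cen <- y < lloq_eff
      y[cen] <- lloq_eff
      sims[, , r] <- bin_pct(y)
      below[, r] <- vapply(seq_len(n_bins),
                           function(b) mean(cen[bin == b]), numeric(1))
    }
    list(lo = apply(sims, c(1, 2), stats::quantile, probs = 0.05,
                    type = 7),
         hi = apply(sims, c(1, 2), stats::quantile, probs = 0.95,
                    type = 7),
         mid = apply(sims, c(1, 2), stats::median),
         below_lloq_frac = rowMeans(below))
  }
  bands <- if (is.null(seed)) simulate_bands() else
    withr::with_seed(seed, simulate_bands())

  age_stats <- vapply(seq_len(n_bins), function(b) {
    c(lo = min(age[bin == b]), hi = max(age[bin == b]),
      mid = stats::median(age[bin == b]), n = sum(bin == b))
  }, numeric(4))
  bins <- tidyr::expand_grid(bin = seq_len(n_bins),
                             level = sort(levels)) |>
    dplyr::mutate(
      age_lo = age_stats["lo", .data$bin],
      age_hi = age_stats["hi", .data$bin],
      age_mid = age_stats["mid", .data$bin],
      n = as.integer(age_stats["n", .data$bin]),
      observed = purrr::map2_dbl(.data$bin, match(.data$level,
                                                  sort(levels)),
                                 ~ obs_p[.y, .x]),
      band_lo = purrr::map2_dbl(.data$bin, match(.data$level,
                                                 sort(levels)),
                                ~ bands$lo[.y, .x]),
      band_hi = purrr::map2_dbl(.data$bin, match(.data$level,
                                                 sort(levels)),
                                ~ bands$hi[.y, .x]),
      band_mid = purrr::map2_dbl(.data$bin, match(.data$level,
                                                  sort(levels)),
                                 ~ bands$mid[.y, .x]),
      inside = .data$observed >= .data$band_lo &
        .data$observed <= .data$band_hi,
      sim_below_lloq_frac = bands$below_lloq_frac[.data$bin]
    )
  coverage <- bins |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(n_bins = dplyr::n(), covered = sum(.data$inside),
                     fraction = mean(.data$inside), .groups = "drop")
  structure(list(bins = bins, coverage = coverage, n_bins = n_bins,
                 n_replicates = n_replicates, seed = seed,
                 lloq_eff = lloq_eff),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat("<vpc_result>", x$n_bins, "age bins,", x$n_replicates,
      "replicate datasets\n")
  print(x$coverage)
  invisible(x)
}
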