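#' Pipeline configuration
#'
#' Bundles everything a full run needs; a run is a pure function of its
#' config (including the seed). The resolved config is written as
#' `config.json` next to the outputs and round-trips losslessly.
#'
#' @param seed Master seed; per-stage seeds are derived as
#'   `(seed * 131 + stage_index * 7919) mod (2^31 - 1)`.
#' @param n_subjects Cohort size.
#' @param panel Simulation panel tibble (see [default_panel()]).
#' @param limits Per-condition assay limits tibble.
#' @param covariates Covariates for the screening stage.
#' @param models Structural models to fit per entry.
#' @param fit_entries Tibble with columns `cytokine`, `condition` naming the
#'   panel entries to fit; default: all `quantifiable` panel rows.
#' @param quad_nodes,starts Mixed-model estimation settings.
#' @param eta_mode Random-effect simulation mode (see
#'   [simulate_concentrations()]).
#' @param vpc_replicates Replicate datasets per VPC.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 271,
                            panel = default_panel(),
                            limits = default_assay_limits(),
                            covariates = c("age", "weight_z", "sex",
                                           "vitd"),
                            models = c("M1", "M2", "M3"),
                            fit_entries = NULL,
                            quad_nodes = 21, starts = 3,
                            eta_mode = "independent",
                            vpc_replicates = 200) {
  if (is.null(fit_entries)) {
    fit_entries <- panel |>
      dplyr::filter(.data$quantifiable) |>
      dplyr::select("cytokine", "condition")
  }
  structure(list(seed = seed, n_subjects = n_subjects, panel = panel,
                 limits = limits, covariates = covariates, models = models,
                 fit_entries = fit_entries, quad_nodes = quad_nodes,
                 starts = starts, eta_mode = eta_mode,
                 vpc_replicates = vpc_replicates),
            class = "pipeline_config")
}

stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 131 + stage * 7919) %% 2147483647)
}

#' Write / read a pipeline config
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `read_config()` returns the `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$panel <- tibble::as_tibble(x$panel)
  x$limits <- tibble::as_tibble(x$limits)
  x$fit_entries <- tibble::as_tibble(x$fit_entries)
  structure(x, class = "pipeline_config")
}

run_stage <- function(name, log_path, expr) {
  cat(sprintf("stage %s: start\n", name), file = log_path, append = TRUE)
  out <- tryCatch(expr, error = function(e) {
    cat(sprintf("stage %s: FAILED (%s)\n", name, conditionMessage(e)),
        file = log_path, append = TRUE)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  cat(sprintf("stage %s: done\n", name), file = log_path, append = TRUE)
  out
}

#' Run the full analysis pipeline
#'
#' Five stages: (1) simulate a cohort and its censored observations,
#' (2) censoring-aware concentration summaries, (3) censored-regression
#' covariate screening, (4) censored mixed-effects age-model fitting with
#' AIC selection per cytokine x condition, (5) percentile curves and VPC
#' for each selected model. All outputs are CSV/JSON files under `out_dir`,
#' reproducible byte-for-byte from the config alone.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the output paths and in-memory results
#'   (`subjects`, `observations`, `summary`, `associations`, `fits`,
#'   `table3`, `centiles`, `vpc`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  cat(sprintf("cytoage %s\nmaster seed %d\nstage seeds: %s\n",
              as.character(utils::packageVersion("cytoage")), config$seed,
              paste(vapply(1:5, function(i) stage_seed(config$seed, i),
                           integer(1)), collapse = " ")),
      file = log_path)
  write_config(config, file.path(out_dir, "config.json"))

  sim <- run_stage("simulate", log_path, {
    subjects <- simulate_cohort(config$n_subjects,
                                seed = stage_seed(config$seed, 1))
    observations <- simulate_concentrations(
      subjects, config$panel, seed = stage_seed(config$seed, 2),
      eta_mode = config$eta_mode) |>
      apply_quantification_limits(config$limits)
    write_dataset(subjects, observations, out_dir)
    list(subjects = subjects, observations = observations)
  })
  subjects <- sim$subjects
  observations <- sim$observations

  summary_tab <- run_stage("summarize", log_path, {
    s <- summarize_concentrations(observations, config$limits)
    readr::write_csv(s, file.path(out_dir, "summary_table.csv"))
    s
  })

  associations <- run_stage("screen", log_path, {
    a <- screen_covariates(observations, subjects, config$covariates)
    readr::write_csv(a, file.path(out_dir, "associations.csv"))
    a
  })

  fit_out <- run_stage("fit", log_path, {
    entries <- config$fit_entries
    res <- purrr::pmap(entries, function(cytokine, condition) {
      d <- prepare_mixed_data(observations, subjects, cytokine, condition,
                              config$limits)
      fset <- lapply(config$models, function(mid) {
        f <- tryCatch(
          fit_mixed(d, mid, quad_nodes = config$quad_nodes,
                    starts = config$starts,
                    seed = stage_seed(config$seed, 4)),
          error = function(e) e)
        if (inherits(f, "mixed_fit")) {
          mixed_fit_to_json(f, file.path(out_dir, sprintf(
            "fit_%s_%s_%s.json", cytokine, condition, mid)))
        }
        f
      })
      fset <- fset[vapply(fset, inherits, logical(1), "mixed_fit")]
      if (!length(fset)) return(NULL)
      sel <- select_model(fset)
      list(cytokine = cytokine, condition = condition, sel = sel)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    table3 <- purrr::map_dfr(res, function(r) {
      f <- r$sel$fit
      tibble::tibble(cytokine = r$cytokine, condition = r$condition,
                     model_id = f$model$model_id,
                     value_infancy = f$value_infancy,
                     value_12y = f$value_12y,
                     change_12y = f$change_12y,
                     iiv_cv = f$iiv_cv, ruv_cv = f$ruv_cv,
                     loglik = f$loglik, aic = f$aic)
    })
    readr::write_csv(table3, file.path(out_dir, "table3_analogue.csv"))
    list(fits = res, table3 = table3)
  })
  fits <- fit_out$fits
  table3 <- fit_out$table3

  cv_out <- run_stage("centiles_vpc", log_path, {
    cent <- purrr::map_dfr(fits, function(r) {
      percentile_curves(r$sel$fit) |>
        tibble::as_tibble() |>
        dplyr::mutate(cytokine = r$cytokine, condition = r$condition)
    })
    readr::write_csv(cent, file.path(out_dir, "centiles.csv"))
    vpcs <- purrr::map_dfr(fits, function(r) {
      v <- vpc(r$sel$fit, n_replicates = config$vpc_replicates,
               seed = stage_seed(config$seed, 5))
      dplyr::mutate(v$bins, cytokine = r$cytokine,
                    condition = r$condition)
    })
    readr::write_csv(vpcs, file.path(out_dir, "vpc.csv"))
    list(centiles = cent, vpc = vpcs)
  })

  invisible(list(out_dir = out_dir, subjects = subjects,
                 observations = observations, summary = summary_tab,
                 associations = associations, fits = fits,
                 table3 = table3, centiles = cv_out$centiles,
                 vpc = cv_out$vpc))
}

#' Render report tables from pipeline outputs
#'
#' Formats the pipeline's CSV outputs into human-readable analogues: the
#' censoring-aware summary with `"<3.2"`-style tokens, the association
#' matrix (signed percent change per unit for significant cells, blank for
#' non-significant, `"X"` where more than half the data were below the
#' LLOQ), the age-model summary table, and semi-log percentile plots.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return A list with `summary` (tibble), `association_matrix` (tibble,
#'   one column per covariate), `table3` (tibble) and `centile_plots`
#'   (named list of ggplot objects). The association matrix is also written
#'   to `associations_matrix.csv`.
#' @export
render_tables <- function(out_dir) {
  need <- c("summary_table.csv", "associations.csv",
            "table3_analogue.csv", "centiles.csv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing)) {
    stop("missing pipeline output(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  summary_tab <- readr::read_csv(file.path(out_dir, "summary_table.csv"),
                                 show_col_types = FALSE)
  assoc <- readr::read_csv(file.path(out_dir, "associations.csv"),
                           show_col_types = FALSE)
  table3 <- readr::read_csv(file.path(out_dir, "table3_analogue.csv"),
                            show_col_types = FALSE)
  centiles <- readr::read_csv(file.path(out_dir, "centiles.csv"),
                              show_col_types = FALSE)

  matrix_tab <- if (nrow(assoc)) {
    assoc |>
      dplyr::mutate(cell = dplyr::case_when(
        .data$skipped ~ "X",
        .data$significant ~ sprintf("%+d%%", round_half_away(
          .data$pct_change_per_unit)),
        TRUE ~ ""
      )) |>
      dplyr::select("cytokine", "condition", "covariate", "cell") |>
      tidyr::pivot_wider(names_from = "covariate",
                         values_from = "cell")
  } else {
    tibble::tibble(cytokine = character(), condition = character())
  }
  readr::write_csv(matrix_tab, file.path(out_dir,
                                         "associations_matrix.csv"))

  plots <- centiles |>
    dplyr::group_by(.data$cytokine, .data$condition) |>
    dplyr::group_map(function(g, key) {
      cc <- structure(g, basis = "between_subject",
                      class = c("centile_curves", class(g)))
      autoplot.centile_curves(cc) +
        ggplot2::ggtitle(paste(key$cytokine, key$condition))
    })
  names(plots) <- centiles |>
    dplyr::distinct(.data$cytokine, .data$condition) |>
    (\(d) paste(d$cytokine, d$condition, sep = "_"))()

  list(summary = summary_tab, association_matrix = matrix_tab,
       table3 = table3, centile_plots = plots)
}
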