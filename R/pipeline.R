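#' Configuration of an end-to-end pipeline run
#'
#' Either simulates a cohort (when `cohort` is a [cohort_config()]) or reads
#' the phenotype and CGM CSVs from `phenotype_csv` / `cgm_csv`, then runs
#' metrics, association, mediation and reporting.
#'
#' @param cohort A [cohort_config()] for simulate mode, or `NULL`.
#' @param phenotype_csv,cgm_csv Input paths (read mode; ignored in simulate
#'   mode).
#' @param out_dir Output directory (created if absent).
#' @param covariates Adjustment covariates (default age, sex,
#'   offspring/partner status).
#' @param mediators Candidate mediators for the mediation stage.
#' @param mediation_outcome Outcome submitted to mediation.
#' @param outcomes Outcome columns for the comparison table.
#' @param log_scale_outcomes Outcomes analysed on the log scale and reported
#'   as geometric means (default: fasting insulin).
#' @param n_perm Permutations per outcome (default 1000).
#' @param min_coverage Window-mean coverage threshold.
#' @param seed Integer seed governing simulation and permutation.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            phenotype_csv = NULL, cgm_csv = NULL,
                            out_dir = "glycovar-out",
                            covariates = c("age", "sex", "offspring"),
                            mediators = c("weight", "pbf"),
                            mediation_outcome = "mean_nocturnal",
                            outcomes = c("fasting_glucose", "fasting_insulin",
                                         "mean_24h", "mean_nocturnal",
                                         "mean_diurnal", "sd_24h", "conga4",
                                         "modd", "range"),
                            log_scale_outcomes = "fasting_insulin",
                            n_perm = 1000, min_coverage = 0.7,
                            seed = 1L) {
  stopifnot(n_perm >= 1)
  if (is.null(cohort) && (is.null(phenotype_csv) || is.null(cgm_csv))) {
    stop("either a cohort_config or both input CSV paths are required",
         call. = FALSE)
  }
  structure(list(
    cohort = cohort, phenotype_csv = phenotype_csv, cgm_csv = cgm_csv,
    out_dir = out_dir, covariates = covariates, mediators = mediators,
    mediation_outcome = mediation_outcome, outcomes = outcomes,
    log_scale_outcomes = log_scale_outcomes, n_perm = as.integer(n_perm),
    min_coverage = min_coverage, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `cohort`
#' key holds [cohort_config()] arguments. Keys not present keep their
#' defaults; `simulate: false` disables simulate mode.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (isFALSE(y$simulate)) NULL else {
    do.call(cohort_config, y$cohort %||% list())
  }
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  args$cohort <- cohort
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Stages: (1) simulate or read the cohort; (2) per-participant CGM
#' summaries; (3) characteristics table by genotype group with adjusted,
#' cluster-robust p-values; (4) outcomes table with adjusted (geometric)
#' means, 95 percent CIs, model and permutation p-values; (5) mediation of
#' the configured outcome by body composition; (6) mean 72-h glucose profile
#' per genotype group (CSV + PNG); (7) a JSON manifest with the seed, a
#' config hash, package version, per-stage row counts and per-file MD5s.
#' A stage failure aborts with a stage-named error and removes the partial
#' outputs of this run.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory tables and output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  note <- function(...) if (!quiet) message(...)
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    created <<- c(created, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(created)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # stage 1: cohort ---------------------------------------------------------
  inputs <- stage("cohort", {
    if (!is.null(config$cohort)) {
      note("simulating cohort (n = ", config$cohort$n_participants, ")")
      ppl <- simulate_cohort(config$cohort, seed = config$seed)
      ser <- simulate_cgm_cohort(ppl, config$cohort,
                                 seed = config$seed + 1L)
      write_cohort_csv(ppl, ser, out("participants.csv"), out("cgm.csv"))
      list(participants = ppl, series = ser)
    } else {
      note("reading cohort from CSV inputs")
      ppl <- readr::read_csv(config$phenotype_csv, show_col_types = FALSE)
      if (!"risk_group" %in% names(ppl)) {
        ppl$risk_group <- ppl$genotype != "CC"
      }
      list(participants = ppl, series = read_cgm_csv(config$cgm_csv))
    }
  })

  # stage 2: metrics --------------------------------------------------------
  summaries <- stage("metrics", {
    s <- summarize_cohort(inputs$series, min_coverage = config$min_coverage)
    readr::write_csv(fmt_num(s), out("summary.csv"))
    s
  })
  merged <- stage("merge", {
    dplyr::inner_join(inputs$participants, summaries, by = "participant_id")
  })

  # stage 3: characteristics table ------------------------------------------
  table1 <- stage("characteristics", {
    t1 <- characteristics_table(merged, config$covariates)
    readr::write_csv(fmt_num(t1), out("table1.csv"))
    t1
  })

  # stage 4: outcomes table --------------------------------------------------
  table2 <- stage("outcomes", {
    rows <- lapply(seq_along(config$outcomes), function(i) {
      oc <- config$outcomes[i]
      log_scale <- oc %in% config$log_scale_outcomes
      cmp <- fit_adjusted_comparison(merged, oc,
                                     covariates = config$covariates,
                                     log_scale = log_scale)
      pp <- permutation_pvalue(merged, oc, covariates = config$covariates,
                               log_scale = log_scale,
                               n_perm = config$n_perm,
                               seed = config$seed + 100L + i)
      dplyr::mutate(tidy_comparison(cmp), p_permutation = pp)
    })
    t2 <- dplyr::bind_rows(rows)
    readr::write_csv(fmt_num(t2), out("table2.csv"))
    t2
  })

  # stage 5: mediation -------------------------------------------------------
  mediation <- stage("mediation", {
    med <- run_mediation(merged, config$mediation_outcome,
                         mediators = config$mediators,
                         covariates = config$covariates)
    med_df <- tibble::tibble(
      outcome = med$outcome_name,
      mediators = paste(med$mediators, collapse = "+"),
      beta_unadjusted = med$beta_unadjusted,
      se_unadjusted = med$se_unadjusted,
      p_unadjusted = med$p_unadjusted,
      beta_adjusted = med$beta_adjusted,
      se_adjusted = med$se_adjusted,
      p_adjusted = med$p_adjusted,
      percent_mediated = med$percent_mediated,
      min_interaction_p = min(med$interaction_p),
      interaction_invalid = med$interaction_invalid,
      n_analyzed = med$n_analyzed
    )
    readr::write_csv(fmt_num(med_df), out("mediation.csv"))
    med
  })

  # stage 6: profile ---------------------------------------------------------
  profile <- stage("profile", {
    plot_mean_profile(inputs$series, inputs$participants,
                      csv_path = out("profile.csv"),
                      image_path = out("profile.png"))
  })

  # stage 7: manifest --------------------------------------------------------
  manifest <- stage("manifest", {
    csvs <- created[grepl("\\.csv$", created)]
    m <- list(
      package = "glycovar",
      version = as.character(utils::packageVersion("glycovar")),
      seed = config$seed,
      config_hash = config_hash(config),
      n_participants = nrow(inputs$participants),
      n_summarized = nrow(summaries),
      n_analyzed = nrow(merged),
      n_perm = config$n_perm,
      files = as.list(unname(tools::md5sum(csvs))) |>
        stats::setNames(basename(csvs))
    )
    jsonlite::write_json(m, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    m
  })
  note("pipeline complete: ", config$out_dir)
  invisible(list(participants = inputs$participants, summaries = summaries,
                 merged = merged, table1 = table1, table2 = table2,
                 mediation = mediation, profile = profile,
                 manifest = manifest, files = created))
}

# Stable rounding for CSV output so reruns are byte-identical across
# platforms printing long doubles differently.
fmt_num <- function(df, digits = 10) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                  ~ signif(.x, digits)))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL # path does not affect the science
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

characteristics_table <- function(merged, covariates) {
  chars <- c("age", "weight", "pbf", "bmi", "whr",
             "fasting_glucose", "fasting_insulin")
  chars <- intersect(chars, names(merged))
  rows <- lapply(chars, function(v) {
    # a characteristic is never adjusted for itself
    covs <- setdiff(covariates, v)
    p <- tryCatch(
      fit_adjusted_comparison(merged, v, covariates = covs)$p_model,
      error = function(e) NA_real_)
    by_g <- dplyr::group_by(merged, .data$risk_group)
    st <- dplyr::summarise(
      by_g,
      mean = mean(.data[[v]], na.rm = TRUE),
      sem = stats::sd(.data[[v]], na.rm = TRUE) /
        sqrt(sum(!is.na(.data[[v]]))),
      .groups = "drop")
    tibble::tibble(
      characteristic = v,
      mean_cc = st$mean[!st$risk_group],
      sem_cc = st$sem[!st$risk_group],
      mean_ctt = st$mean[st$risk_group],
      sem_ctt = st$sem[st$risk_group],
      p_adjusted = p
    )
  })
  counts <- tibble::tibble(
    characteristic = c("n", "female_fraction", "offspring_fraction"),
    mean_cc = c(sum(!merged$risk_group),
                mean(merged$sex[!merged$risk_group] == "female"),
                mean(merged$offspring[!merged$risk_group] == "offspring")),
    sem_cc = NA_real_,
    mean_ctt = c(sum(merged$risk_group),
                 mean(merged$sex[merged$risk_group] == "female"),
                 mean(merged$offspring[merged$risk_group] == "offspring")),
    sem_ctt = NA_real_,
    p_adjusted = NA_real_
  )
  dplyr::bind_rows(counts, dplyr::bind_rows(rows))
}

#' Mean 72-hour glucose profile per genotype group
#'
#' Averages, per genotype group, the glucose values of all participants at
#' each grid slot of the trimmed 72-hour analysis span, writes the plotted
#' values as CSV (slots with no data kept as missing) and renders the
#' profile with the 03:00--06:00 nocturnal window of each day demarcated.
#'
#' @param series_list Named list of [cgm_series()] (untrimmed; trimming is
#'   applied here).
#' @param participants Phenotype tibble with `participant_id` and
#'   `risk_group`.
#' @param csv_path,image_path Output paths; the CSV is always written, the
#'   image only when `image_path` is non-NULL.
#' @return Invisibly, the profile tibble (`group`, `elapsed_hours`,
#'   `clock_min`, `mean_glucose`, `n`).
#' @export
plot_mean_profile <- function(series_list, participants,
                              csv_path = NULL, image_path = NULL) {
  groups <- split(participants$participant_id, participants$risk_group)
  if (!all(lengths(groups) > 0) || length(groups) < 2) {
    empty <- setdiff(c("FALSE", "TRUE"), names(groups)[lengths(groups) > 0])
    stop("empty genotype group: ",
         paste(ifelse(empty == "FALSE", "CC", "CT/TT"), collapse = ", "),
         call. = FALSE)
  }
  prof <- purrr::map_dfr(names(groups), function(g) {
    ids <- intersect(groups[[g]], names(series_list))
    mats <- lapply(series_list[ids], function(s) {
      tr <- trim_to_analysis_days(s)
      tibble::tibble(slot = seq_along(tr$glucose) - 1L,
                     clock_min = tr$clock_min,
                     glucose = tr$glucose)
    })
    dplyr::bind_rows(mats) |>
      dplyr::group_by(.data$slot, .data$clock_min) |>
      dplyr::summarise(
        mean_glucose = if (all(is.na(.data$glucose))) NA_real_
                       else mean(.data$glucose, na.rm = TRUE),
        n = sum(!is.na(.data$glucose)),
        .groups = "drop") |>
      dplyr::mutate(group = if (g == "TRUE") "CT/TT" else "CC")
  })
  prof <- dplyr::mutate(
    prof,
    elapsed_hours = .data$slot * series_list[[1]]$interval / 60) |>
    dplyr::select("group", "elapsed_hours", "clock_min", "mean_glucose", "n") |>
    dplyr::arrange(.data$group, .data$elapsed_hours)
  if (!is.null(csv_path)) readr::write_csv(fmt_num(prof), csv_path)
  if (!is.null(image_path)) {
    noct <- tidyr::expand_grid(day = 0:2, edge = c(3, 6)) |>
      dplyr::mutate(x = .data$day * 24 + .data$edge)
    p <- ggplot2::ggplot(prof,
                         ggplot2::aes(x = .data$elapsed_hours,
                                      y = .data$mean_glucose,
                                      colour = .data$group)) +
      ggplot2::geom_vline(xintercept = noct$x, linetype = "dotted",
                          colour = "grey30") +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::scale_colour_manual(values = c("CC" = "black",
                                              "CT/TT" = "grey55")) +
      ggplot2::labs(x = "Time since start of analysis window (h)",
                    y = "Mean interstitial glucose (mmol/L)",
                    colour = "rs7903146") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(image_path, p, width = 9, height = 4, dpi = 150)
  }
  invisible(prof)
}
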