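#' Simulate a study cohort with genotypes, families and phenotypes
#'
#' Draws participants whose rs7903146-style genotype follows Hardy-Weinberg
#' proportions (CC, CT, TT with frequencies q^2, 2pq, p^2 for T-allele
#' frequency p), with a configurable fraction of participants grouped into
#' two-person sibling family clusters. Siblings inherit alleles from a shared
#' parental pool, so their genotypes are correlated while the marginal
#' distribution stays at Hardy-Weinberg. Carriers of at least one T allele
#' (`risk_group`) receive the configured shifts in body weight and percent
#' body fat, the pathway through which part of the genotype effect on
#' nocturnal glucose is mediated.
#'
#' Height is resampled until BMI falls in the eligibility band 19--33 kg/m^2,
#' leaving the weight distribution (and hence the configured genotype effect
#' on weight) untouched.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble with one row per participant: `participant_id`,
#'   `family_id`, `genotype`, `risk_group`, `age`, `sex`, `offspring`,
#'   `weight`, `pbf`, `bmi`, `whr`, `fasting_glucose`, `fasting_insulin`,
#'   plus the generator-internal columns `mediator_z` (standardized
#'   body-composition composite) and `family_intercept` (mmol/L) consumed by
#'   [simulate_cgm_cohort()].
#' @export
#' @examples
#' ppl <- simulate_cohort(cohort_config(n_participants = 20, seed = 1))
#' table(ppl$genotype)
simulate_cohort <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  withr::with_seed(seed, {
    n <- config$n_participants
    p <- config$t_allele_freq

    n_pairs <- floor(config$sibling_fraction * n / 2)
    n_singleton <- n - 2L * n_pairs
    n_fam <- n_pairs + n_singleton

    family_id <- sprintf("F%04d", c(rep(seq_len(n_pairs), each = 2),
                                    n_pairs + seq_len(n_singleton)))

    # sibling pairs draw one allele from each of two shared parents
    t_alleles <- integer(n)
    if (n_pairs > 0) {
      mother <- matrix(stats::rbinom(2L * n_pairs, 1L, p), ncol = 2)
      father <- matrix(stats::rbinom(2L * n_pairs, 1L, p), ncol = 2)
      for (i in seq_len(n_pairs)) {
        for (child in 1:2) {
          idx <- 2L * (i - 1L) + child
          t_alleles[idx] <- mother[i, sample.int(2L, 1L)] +
            father[i, sample.int(2L, 1L)]
        }
      }
    }
    if (n_singleton > 0) {
      idx <- 2L * n_pairs + seq_len(n_singleton)
      t_alleles[idx] <- stats::rbinom(n_singleton, 2L, p)
    }
    genotype <- c("CC", "CT", "TT")[t_alleles + 1L]
    risk_group <- genotype != "CC"

    cm <- config$covariate_means_sds
    age <- stats::rnorm(n, cm$age[1], cm$age[2])
    sex <- ifelse(stats::runif(n) < config$female_fraction,
                  "female", "male")
    offspring <- ifelse(stats::runif(n) < config$offspring_fraction,
                        "offspring", "partner")

    weight <- cm$weight[1] + config$mediator_effect_weight * risk_group +
      stats::rnorm(n, 0, cm$weight[2])
    weight <- pmax(weight, 40)
    pbf <- cm$pbf[1] + config$mediator_effect_pbf * risk_group +
      stats::rnorm(n, 0, cm$pbf[2])
    pbf <- pmin(pmax(pbf, 5), 60)

    # BMI eligibility band enforced through height, keeping weight marginal
    height <- stats::rnorm(n, 1.72, 0.087)
    bmi <- weight / height^2
    for (iter in 1:50) {
      out <- which(bmi < 19 | bmi > 33)
      if (!length(out)) break
      height[out] <- stats::rnorm(length(out), 1.72, 0.087)
      bmi[out] <- weight[out] / height[out]^2
    }
    bmi <- pmin(pmax(bmi, 19), 33)

    whr <- stats::rnorm(n, 0.91, 0.08) + 0.01 * risk_group
    fasting_glucose <- stats::rnorm(n, 5.14, 0.5) + 0.08 * risk_group
    fasting_insulin <- exp(log(2.1) + 0.08 * risk_group +
                             stats::rnorm(n, 0, 0.45))

    z_w <- (weight - cm$weight[1]) / cm$weight[2]
    z_p <- (pbf - cm$pbf[1]) / cm$pbf[2]
    mediator_z <- (z_w + z_p) / sqrt(2)

    fam_int <- stats::rnorm(n_fam, 0, config$family_intercept_sd)
    names(fam_int) <- sprintf("F%04d", seq_len(n_fam))

    tibble::tibble(
      participant_id = sprintf("P%04d", seq_len(n)),
      family_id = family_id,
      genotype = genotype,
      risk_group = risk_group,
      age = age,
      sex = sex,
      offspring = offspring,
      weight = weight,
      pbf = pbf,
      bmi = bmi,
      whr = whr,
      fasting_glucose = fasting_glucose,
      fasting_insulin = fasting_insulin,
      mediator_z = mediator_z,
      family_intercept = unname(fam_int[family_id])
    )
  })
}

# Deterministic circadian baseline (mmol/L) on a clock-minute grid:
# 24-h raised cosine with its nadir at nadir_time plus Gaussian meal bumps.
circadian_baseline <- function(clock_min, config) {
  hr <- clock_min / 60
  base <- config$nocturnal_nadir + config$circadian_amplitude *
    (1 - cos(2 * pi * (hr - config$nadir_time) / 24)) / 2
  for (mt in config$meal_times) {
    d <- abs(clock_min - mt * 60)
    d <- pmin(d, 1440 - d) # circular distance in minutes
    base <- base + config$meal_amplitude * exp(-0.5 * (d / config$meal_width)^2)
  }
  base
}

# Raised-cosine nocturnal weight over 00:00-07:00, normalized so its mean
# over the 03:00-06:00 analysis window equals exactly 1 on the given grid.
nocturnal_weight <- function(clock_min) {
  hr <- clock_min / 60
  w <- ifelse(hr < 7, 0.5 * (1 - cos(2 * pi * hr / 7)), 0)
  in_noct <- clock_min >= 180 & clock_min < 360
  w / mean(w[in_noct])
}

#' Simulate CGM traces for a whole cohort
#'
#' Builds one interstitial-glucose trace per participant: a smooth circadian
#' baseline with meal excursions, a genotype shift concentrated in the night
#' (raised-cosine weight over 00:00--07:00, scaled so carriers' mean
#' 03:00--06:00 glucose rises by exactly `direct_effect`), a whole-day shift
#' proportional to the standardized body-composition composite, a
#' family-shared intercept, and first-order autoregressive sensor noise whose
#' marginal SD is `noise_sd`. A fraction `missing_rate` of samples is removed
#' completely at random. All traces start at local midnight and run for
#' `n_days` days at `sample_interval` minutes.
#'
#' @param participants Tibble from [simulate_cohort()].
#' @param config The same [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed + 1`.
#' @param start Timestamp of the first sample (UTC midnight by default).
#' @return A named list of [cgm_series()] objects, one per participant.
#' @export
simulate_cgm_cohort <- function(participants, config,
                                seed = config$seed + 1L,
                                start = as.POSIXct("2015-03-02 00:00:00",
                                                   tz = "UTC")) {
  validate_cohort_config(config)
  n <- nrow(participants)
  interval <- config$sample_interval
  n_per_day <- 1440L %/% interval
  T_len <- n_per_day * config$n_days
  clock_min <- ((seq_len(T_len) - 1L) * interval) %% 1440L

  base <- circadian_baseline(clock_min, config)
  wnoct <- nocturnal_weight(clock_min)

  shift <- config$direct_effect * outer(wnoct, as.numeric(participants$risk_group))
  level <- config$mediator_to_glucose * participants$mediator_z +
    participants$family_intercept

  withr::with_seed(seed, {
    phi <- config$noise_ar_coeff
    innov_sd <- config$noise_sd * sqrt(1 - phi^2)
    noise <- matrix(0, T_len, n)
    if (config$noise_sd > 0) {
      noise[1, ] <- stats::rnorm(n, 0, config$noise_sd)
      eps <- matrix(stats::rnorm((T_len - 1L) * n, 0, innov_sd), T_len - 1L, n)
      for (t in 2:T_len) noise[t, ] <- phi * noise[t - 1L, ] + eps[t - 1L, ]
    }
    glucose <- base + shift + matrix(level, T_len, n, byrow = TRUE) + noise
    if (config$missing_rate > 0) {
      glucose[matrix(stats::runif(T_len * n) < config$missing_rate,
                     T_len, n)] <- NA_real_
    }
    out <- lapply(seq_len(n), function(i) {
      cgm_series(participants$participant_id[i], start, interval,
                 glucose[, i])
    })
    names(out) <- participants$participant_id
    out
  })
}

#' Simulate a single participant's CGM trace
#'
#' Convenience wrapper around [simulate_cgm_cohort()] for one participant;
#' deterministic under a fixed seed.
#'
#' @param participant One row of the tibble from [simulate_cohort()].
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed + 1`.
#' @return A [cgm_series()].
#' @export
simulate_cgm_trace <- function(participant, config,
                               seed = config$seed + 1L) {
  stopifnot(nrow(participant) == 1)
  simulate_cgm_cohort(participant, config, seed = seed)[[1]]
}

#' Write a simulated cohort to the pipeline's CSV formats
#'
#' Writes the phenotype table and the long-format CGM table
#' (`participant_id`, ISO-8601 `timestamp`, `glucose_mmol_l`; missing samples
#' omitted, as a sensor would) that [read_cgm_csv()] consumes.
#'
#' @param participants Tibble from [simulate_cohort()].
#' @param series List of [cgm_series()] from [simulate_cgm_cohort()].
#' @param phenotype_path,cgm_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort_csv <- function(participants, series, phenotype_path, cgm_path) {
  pheno <- dplyr::select(participants, -dplyr::any_of(
    c("mediator_z", "family_intercept")))
  readr::write_csv(pheno, phenotype_path)
  long <- purrr::map_dfr(series, function(s) {
    keep <- !is.na(s$glucose)
    tibble::tibble(
      participant_id = s$participant_id,
      timestamp = format(series_times(s)[keep], "%Y-%m-%dT%H:%M:%S",
                         tz = "UTC"),
      glucose_mmol_l = round(s$glucose[keep], 4)
    )
  })
  readr::write_csv(long, cgm_path)
  invisible(c(phenotype_path, cgm_path))
}
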