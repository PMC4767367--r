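#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic cohort: sample size, risk-allele
#' frequency, family structure, the genotype effect on nocturnal glucose
#' (split into a direct path and a path mediated by body composition),
#' the circadian shape of the glucose trace, sensor noise, and missingness.
#'
#' The genotype effect on the interstitial glucose trace is parameterised so
#' that `direct_effect` is the *nocturnal-window* (03:00--06:00) mean shift in
#' mmol/L for CT/TT carriers that does not pass through body composition,
#' while `mediator_to_glucose` scales a standardized body-composition
#' composite (weight and percent body fat z-scores) into a whole-day glucose
#' shift. The implied mediated fraction of the total nocturnal effect is
#' returned by [implied_effects()].
#'
#' @param n_participants Number of participants (>= 4).
#' @param t_allele_freq Population frequency of the risk (T) allele in
#'   `[0, 1]`; genotypes follow Hardy-Weinberg proportions.
#' @param sibling_fraction Fraction of participants paired into two-person
#'   sibling family clusters; the remainder are singleton families.
#' @param direct_effect Direct (non-mediated) genotype effect on the mean
#'   nocturnal glucose, mmol/L.
#' @param mediator_effect_weight Genotype effect on body weight, kg.
#' @param mediator_effect_pbf Genotype effect on percent body fat,
#'   percentage points.
#' @param mediator_to_glucose Glucose shift (mmol/L) per SD of the
#'   standardized body-composition composite.
#' @param family_intercept_sd SD (mmol/L) of a family-shared random shift of
#'   the glucose trace, inducing within-family outcome correlation.
#' @param covariate_means_sds Named list with entries `age`, `weight`, `pbf`,
#'   each `c(mean, sd)`; `weight`/`pbf` are the non-carrier (CC) baselines.
#' @param female_fraction,offspring_fraction Marginal probabilities of female
#'   sex and offspring (vs partner) status.
#' @param noise_ar_coeff First-order autocorrelation of sensor noise between
#'   consecutive 5-minute samples, in `[0, 1)`.
#' @param noise_sd Marginal SD of the sensor noise, mmol/L.
#' @param meal_times Meal peak times, hours of day.
#' @param meal_amplitude Peak height of each meal excursion, mmol/L.
#' @param meal_width Gaussian SD of each meal excursion, minutes.
#' @param circadian_amplitude Peak-to-nadir amplitude of the smooth 24-h
#'   cosine component, mmol/L.
#' @param nocturnal_nadir Glucose at the circadian nadir, mmol/L.
#' @param nadir_time Clock time of the circadian nadir, hours.
#' @param missing_rate Probability that any given sample is lost.
#' @param n_days Days of monitoring (>= 3; default 5, of which the first and
#'   last are later discarded by [trim_to_analysis_days()]).
#' @param sample_interval Sampling interval in minutes; must divide 1440.
#' @param seed Integer seed making the generator reproducible.
#'
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()], [simulate_cgm_cohort()], [implied_effects()]
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 50, seed = 7)
#' implied_effects(cfg)$mediated_fraction
cohort_config <- function(n_participants = 235,
                          t_allele_freq = 0.28,
                          sibling_fraction = 0.4,
                          direct_effect = 0.124,
                          mediator_effect_weight = 2.5,
                          mediator_effect_pbf = 1.5,
                          mediator_to_glucose = 0.245,
                          family_intercept_sd = 0.1,
                          covariate_means_sds = list(
                            age = c(64.7, 5.9),
                            weight = c(76.7, 12.3),
                            pbf = c(30.3, 8.3)
                          ),
                          female_fraction = 0.5,
                          offspring_fraction = 0.626,
                          noise_ar_coeff = 0.7,
                          noise_sd = 0.5,
                          meal_times = c(8, 13, 19),
                          meal_amplitude = 1.5,
                          meal_width = 35,
                          circadian_amplitude = 1.0,
                          nocturnal_nadir = 4.45,
                          nadir_time = 4,
                          missing_rate = 0.02,
                          n_days = 5,
                          sample_interval = 5,
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    t_allele_freq = t_allele_freq,
    sibling_fraction = sibling_fraction,
    direct_effect = direct_effect,
    mediator_effect_weight = mediator_effect_weight,
    mediator_effect_pbf = mediator_effect_pbf,
    mediator_to_glucose = mediator_to_glucose,
    family_intercept_sd = family_intercept_sd,
    covariate_means_sds = covariate_means_sds,
    female_fraction = female_fraction,
    offspring_fraction = offspring_fraction,
    noise_ar_coeff = noise_ar_coeff,
    noise_sd = noise_sd,
    meal_times = meal_times,
    meal_amplitude = meal_amplitude,
    meal_width = meal_width,
    circadian_amplitude = circadian_amplitude,
    nocturnal_nadir = nocturnal_nadir,
    nadir_time = nadir_time,
    missing_rate = missing_rate,
    n_days = as.integer(n_days),
    sample_interval = as.integer(sample_interval),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  probs <- c(
    t_allele_freq = cfg$t_allele_freq,
    sibling_fraction = cfg$sibling_fraction,
    missing_rate = cfg$missing_rate,
    female_fraction = cfg$female_fraction,
    offspring_fraction = cfg$offspring_fraction
  )
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) {
    stop("cohort_config probabilities outside [0, 1]: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (cfg$noise_ar_coeff < 0 || cfg$noise_ar_coeff >= 1) {
    stop("noise_ar_coeff must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$n_participants < 4) {
    stop("n_participants must be >= 4 to form clusters and genotype groups",
         call. = FALSE)
  }
  if (cfg$n_days < 3) stop("n_days must be >= 3", call. = FALSE)
  if (1440L %% cfg$sample_interval != 0L) {
    stop("sample_interval must divide 1440 minutes", call. = FALSE)
  }
  needed <- c("age", "weight", "pbf")
  if (!all(needed %in% names(cfg$covariate_means_sds))) {
    stop("covariate_means_sds needs entries: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  eff <- implied_effects(x)
  cat("<cohort_config>\n")
  cat(sprintf("  n = %d, T-allele freq = %.3f, sibling fraction = %.2f\n",
              x$n_participants, x$t_allele_freq, x$sibling_fraction))
  cat(sprintf("  nocturnal effect: direct %.3f + indirect %.3f = %.3f mmol/L",
              eff$direct, eff$indirect, eff$total))
  cat(sprintf(" (mediated fraction %.3f)\n", eff$mediated_fraction))
  cat(sprintf("  trace: %d days @ %d min, noise SD %.2f (AR %.2f), missing %.1f%%\n",
              x$n_days, x$sample_interval, x$noise_sd, x$noise_ar_coeff,
              100 * x$missing_rate))
  invisible(x)
}

#' Genotype effects implied by a cohort configuration
#'
#' Decomposes the configured genotype effect on mean nocturnal glucose into
#' the direct path and the path mediated by body composition. The indirect
#' effect is `mediator_to_glucose` times the expected carrier shift of the
#' standardized body-composition composite,
#' `(effect_weight/sd_weight + effect_pbf/sd_pbf) / sqrt(2)`.
#'
#' @param config A [cohort_config()].
#' @return List with `direct`, `indirect`, `total` (mmol/L) and
#'   `mediated_fraction` = indirect / total (NA when total is 0).
#' @export
implied_effects <- function(config) {
  validate_cohort_config(config)
  cm <- config$covariate_means_sds
  dz <- (config$mediator_effect_weight / cm$weight[2] +
           config$mediator_effect_pbf / cm$pbf[2]) / sqrt(2)
  indirect <- config$mediator_to_glucose * dz
  total <- config$direct_effect + indirect
  list(
    direct = config$direct_effect,
    indirect = indirect,
    total = total,
    mediated_fraction = if (total != 0) indirect / total else NA_real_
  )
}

#' Configure a target total effect and mediated fraction
#'
#' Solves for `direct_effect` and `mediator_to_glucose` so that the total
#' genotype effect on nocturnal glucose equals `total_effect` and the
#' mediated fraction equals `fraction`, keeping every other field of `base`.
#'
#' @param total_effect Total nocturnal genotype effect, mmol/L.
#' @param fraction Mediated fraction in `[0, 1]`.
#' @param base Template [cohort_config()] supplying all other fields.
#' @return A `cohort_config` with the two effect fields replaced.
#' @export
config_with_mediated_fraction <- function(total_effect, fraction,
                                          base = cohort_config()) {
  stopifnot(fraction >= 0, fraction <= 1)
  cm <- base$covariate_means_sds
  dz <- (base$mediator_effect_weight / cm$weight[2] +
           base$mediator_effect_pbf / cm$pbf[2]) / sqrt(2)
  if (fraction > 0 && dz == 0) {
    stop("cannot place effect on mediators: mediator effects are both 0",
         call. = FALSE)
  }
  base$direct_effect <- total_effect * (1 - fraction)
  base$mediator_to_glucose <- if (dz > 0) total_effect * fraction / dz else 0
  validate_cohort_config(base)
  base
}
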