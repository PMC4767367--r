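#' Covariate-adjusted genotype-group comparison with cluster-robust errors
#'
#' Fits an ordinary least-squares regression of an outcome (optionally
#' log-transformed) on a binary risk-group indicator plus covariates, with
#' standard errors from the cluster-robust sandwich estimator grouped by
#' family. The sandwich uses the small-sample factor
#' `G/(G-1) * (N-1)/(N-k)` and p-values use a t reference with `G - 1`
#' degrees of freedom (G clusters, N rows, k coefficients), mirroring the
#' conventional clustered-robust behaviour of mainstream survey/econometric
#' software. Adjusted group means are evaluated at the sample means of the
#' covariate design columns; on the log scale they are exponentiated back to
#' geometric means.
#'
#' @param data Data frame with one row per participant (phenotypes joined to
#'   CGM summaries).
#' @param outcome Name of the outcome column.
#' @param group Name of the binary group column (logical, 0/1, or
#'   two-level factor; the higher level is the risk group).
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param cluster Name of the family/cluster id column.
#' @param log_scale Analyse `log(outcome)` and report geometric means.
#' @param conf_level Confidence level for group-mean intervals.
#' @return Object of class `comparison_result`: a list with `outcome_name`,
#'   `beta`, `se_robust`, `df`, `p_model`, `group_means` (tibble with
#'   `group`, `mean`, `lwr`, `upr`), `n_cc`, `n_ctt`, `n_clusters`, `scale`,
#'   and the fitted `model`.
#' @export
fit_adjusted_comparison <- function(data, outcome, group = "risk_group",
                                    covariates = c("age", "sex", "offspring"),
                                    cluster = "family_id",
                                    log_scale = FALSE,
                                    conf_level = 0.95) {
  prep <- prepare_model_frame(data, outcome, group, covariates, cluster,
                              log_scale)
  if (sum(!is.na(prep$df$.y)) < 10) {
    stop("outcome '", outcome, "' non-missing for fewer than 10 rows",
         call. = FALSE)
  }
  fit <- stats::lm(prep$formula, data = prep$df)
  if (anyNA(stats::coef(fit))) {
    stop("singular design for outcome '", outcome, "'; collinear columns: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  cl <- prep$df$.cluster
  G <- length(unique(cl))
  N <- nrow(prep$df)
  k <- length(stats::coef(fit))
  vc <- sandwich::vcovCL(fit, cluster = cl, type = "HC1", cadjust = TRUE)
  beta <- unname(stats::coef(fit)[".group"])
  se <- sqrt(vc[".group", ".group"])
  dfree <- G - 1
  # numerically degenerate fits (constant outcome): beta and se both at
  # rounding-error scale relative to the outcome
  y_scale <- max(abs(prep$df$.y), 1)
  if (abs(beta) < 1e-10 * y_scale && se < 1e-10 * y_scale) {
    beta <- 0
    se <- 0
  }
  p <- if (se > 0) {
    2 * stats::pt(-abs(beta / se), df = dfree)
  } else if (beta == 0) 1 else 0

  X <- stats::model.matrix(fit)
  xbar <- colMeans(X)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = dfree)
  gm <- lapply(c(0, 1), function(g) {
    x <- xbar
    x[".group"] <- g
    est <- sum(x * stats::coef(fit))
    sem <- sqrt(drop(t(x) %*% vc %*% x))
    c(est, est - tcrit * sem, est + tcrit * sem)
  })
  means <- tibble::tibble(
    group = c("CC", "CT/TT"),
    mean = c(gm[[1]][1], gm[[2]][1]),
    lwr = c(gm[[1]][2], gm[[2]][2]),
    upr = c(gm[[1]][3], gm[[2]][3])
  )
  if (log_scale) {
    means$mean <- exp(means$mean)
    means$lwr <- exp(means$lwr)
    means$upr <- exp(means$upr)
  }
  structure(list(
    outcome_name = outcome,
    beta = beta,
    se_robust = se,
    df = dfree,
    p_model = p,
    group_means = means,
    n_cc = sum(prep$df$.group == 0),
    n_ctt = sum(prep$df$.group == 1),
    n_clusters = G,
    n = N,
    k = k,
    scale = if (log_scale) "log" else "identity",
    model = fit,
    cluster = cl
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result: %s (%s scale)>\n", x$outcome_name, x$scale))
  cat(sprintf("  beta (CT/TT - CC) = %.4f, robust SE = %.4f, t(%d), p = %.4g\n",
              x$beta, x$se_robust, x$df, x$p_model))
  cat(sprintf("  adjusted means: CC %.3f (%.3f-%.3f), CT/TT %.3f (%.3f-%.3f)\n",
              x$group_means$mean[1], x$group_means$lwr[1], x$group_means$upr[1],
              x$group_means$mean[2], x$group_means$lwr[2], x$group_means$upr[2]))
  cat(sprintf("  n = %d (%d CC, %d CT/TT) in %d family clusters\n",
              x$n, x$n_cc, x$n_ctt, x$n_clusters))
  invisible(x)
}

# Complete-case model frame with standardized column names .y, .group,
# .cluster; group coerced to 0/1.
prepare_model_frame <- function(data, outcome, group, covariates, cluster,
                                log_scale, extra = character(0)) {
  cols <- unique(c(outcome, group, covariates, cluster, extra))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  g <- df[[group]]
  if (is.factor(g) || is.character(g)) {
    lev <- sort(unique(as.character(g)))
    if (length(lev) != 2) stop("group must be binary", call. = FALSE)
    g <- as.numeric(as.character(g) == lev[2])
  } else {
    g <- as.numeric(g)
  }
  if (length(unique(g)) < 2) {
    stop("both groups must be represented", call. = FALSE)
  }
  y <- df[[outcome]]
  if (log_scale) {
    if (any(y <= 0)) stop("log scale requires positive outcome", call. = FALSE)
    y <- log(y)
  }
  df$.y <- y
  df$.group <- g
  df$.cluster <- as.character(df[[cluster]])
  rhs <- paste(c(".group", covariates), collapse = " + ")
  list(df = df, formula = stats::as.formula(paste(".y ~", rhs)))
}

#' Monte Carlo permutation p-value for the group effect
#'
#' Reference statistic is `|beta|` from the observed cluster-adjusted fit.
#' Under `unit = "cluster"` (default) the observed per-cluster patterns of
#' group labels are shuffled among clusters of equal size, so every member
#' of a cluster moves together and the marginal group counts are preserved;
#' this respects the exchangeability assumed by the clustered model. Under
#' `unit = "individual"` labels are shuffled freely across rows. The p-value
#' uses the add-one estimator `(1 + #{|beta*| >= |beta|}) / (n_perm + 1)`.
#'
#' @inheritParams fit_adjusted_comparison
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for reproducibility.
#' @param unit `"cluster"` or `"individual"` permutation unit.
#' @return Permutation p-value in (0, 1].
#' @export
permutation_pvalue <- function(data, outcome, group = "risk_group",
                               covariates = c("age", "sex", "offspring"),
                               cluster = "family_id",
                               log_scale = FALSE,
                               n_perm = 1000, seed = NULL,
                               unit = c("cluster", "individual")) {
  unit <- match.arg(unit)
  prep <- prepare_model_frame(data, outcome, group, covariates, cluster,
                              log_scale)
  df <- prep$df
  X <- stats::model.matrix(prep$formula, data = df)
  y <- df$.y
  gcol <- which(colnames(X) == ".group")
  beta_obs <- abs(stats::lm.fit(X, y)$coefficients[".group"])

  cl <- df$.cluster
  cl_idx <- split(seq_along(cl), cl)
  if (length(cl_idx) < 8) {
    warning("fewer than 8 distinct clusters: permutation resolution is coarse",
            call. = FALSE)
  }
  sizes <- lengths(cl_idx)
  run_one <- function() {
    gperm <- df$.group
    if (unit == "individual") {
      gperm <- sample(gperm)
    } else {
      for (s in unique(sizes)) {
        cls <- which(sizes == s)
        if (length(cls) < 2) next
        donor <- cls[sample.int(length(cls))]
        for (j in seq_along(cls)) {
          gperm[cl_idx[[cls[j]]]] <- df$.group[cl_idx[[donor[j]]]]
        }
      }
    }
    Xp <- X
    Xp[, gcol] <- gperm
    abs(stats::lm.fit(Xp, y)$coefficients[".group"])
  }
  runner <- function() {
    stats <- vapply(seq_len(n_perm), function(i) run_one(), numeric(1))
    tol <- 1e-12 * max(1, beta_obs)
    (1 + sum(stats >= beta_obs - tol)) / (n_perm + 1)
  }
  if (is.null(seed)) runner() else withr::with_seed(seed, runner())
}

#' Test multiplicative interaction between group and a candidate mediator
#'
#' Adds a group-by-mediator product term (mediator mean-centred) to the
#' covariate-adjusted model and returns the cluster-robust p-value of the
#' product term.
#'
#' @inheritParams fit_adjusted_comparison
#' @param mediator Name of the numeric mediator column.
#' @return p-value of the interaction term (t with G - 1 df).
#' @export
interaction_test <- function(data, outcome, group = "risk_group",
                             mediator, covariates = c("age", "sex", "offspring"),
                             cluster = "family_id", log_scale = FALSE) {
  prep <- prepare_model_frame(data, outcome, group, covariates, cluster,
                              log_scale, extra = mediator)
  df <- prep$df
  if (!is.numeric(df[[mediator]])) {
    stop("mediator '", mediator, "' must be numeric", call. = FALSE)
  }
  df$.med_c <- df[[mediator]] - mean(df[[mediator]])
  rhs <- paste(c(".group", covariates, ".med_c", ".group:.med_c"),
               collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  if (anyNA(stats::coef(fit))) {
    stop("singular design for interaction with '", mediator,
         "'; collinear columns: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  vc <- sandwich::vcovCL(fit, cluster = df$.cluster, type = "HC1",
                         cadjust = TRUE)
  term <- ".group:.med_c"
  tval <- stats::coef(fit)[term] / sqrt(vc[term, term])
  G <- length(unique(df$.cluster))
  unname(2 * stats::pt(-abs(tval), df = G - 1))
}

#' Percent of a group effect explained by mediators
#'
#' The difference-in-coefficients measure
#' `100 * (beta_unadjusted - beta_adjusted) / beta_unadjusted`: how much of
#' the group effect disappears when the mediators enter the model. Values
#' below 0 or above 100 indicate suppression and are flagged by
#' [run_mediation()], not truncated.
#'
#' @param beta_unadjusted Group coefficient without the mediators.
#' @param beta_adjusted Group coefficient with the mediators.
#' @return Percent mediated (may lie outside `[0, 100]`).
#' @export
#' @examples
#' percent_mediated(0.17, 0.11) # 35.29
percent_mediated <- function(beta_unadjusted, beta_adjusted) {
  if (beta_unadjusted == 0) {
    stop("percent mediated is undefined when the unadjusted effect is 0",
         call. = FALSE)
  }
  100 * (beta_unadjusted - beta_adjusted) / beta_unadjusted
}

#' Mediation of the group effect by additional study characteristics
#'
#' On the complete-case subset (outcome, covariates and all mediators
#' observed), fits the covariate-adjusted base model and the base-plus-
#' mediators model on the *same* rows, tests group-by-mediator
#' multiplicative interaction for each mediator first, and summarises the
#' attenuation of the group coefficient as percent mediated. A significant
#' interaction does not abort the computation but flags the result as not
#' interpretable as mediation.
#'
#' @inheritParams fit_adjusted_comparison
#' @param mediators Character vector of mediator column names.
#' @param interaction_alpha Significance level for the interaction screen.
#' @return Object of class `mediation_result`: `beta_unadjusted`,
#'   `se_unadjusted`, `p_unadjusted`, `beta_adjusted`, `se_adjusted`,
#'   `p_adjusted`, `percent_mediated`, `interaction_p` (named per mediator),
#'   `interaction_invalid`, `outside_0_100`, `n_analyzed`.
#' @export
run_mediation <- function(data, outcome, group = "risk_group",
                          mediators = c("weight", "pbf"),
                          covariates = c("age", "sex", "offspring"),
                          cluster = "family_id", log_scale = FALSE,
                          interaction_alpha = 0.05) {
  cols <- unique(c(outcome, group, covariates, mediators, cluster))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cc <- data[stats::complete.cases(data[cols]), , drop = FALSE]

  inter_p <- vapply(mediators, function(m) {
    interaction_test(cc, outcome, group, m, covariates, cluster, log_scale)
  }, numeric(1))

  base <- fit_adjusted_comparison(cc, outcome, group, covariates, cluster,
                                  log_scale)
  full <- fit_adjusted_comparison(cc, outcome, group,
                                  c(covariates, mediators), cluster,
                                  log_scale)
  pm <- percent_mediated(base$beta, full$beta)
  res <- structure(list(
    outcome_name = outcome,
    mediators = mediators,
    beta_unadjusted = base$beta,
    se_unadjusted = base$se_robust,
    p_unadjusted = base$p_model,
    beta_adjusted = full$beta,
    se_adjusted = full$se_robust,
    p_adjusted = full$p_model,
    percent_mediated = pm,
    interaction_p = inter_p,
    interaction_invalid = any(inter_p < interaction_alpha),
    outside_0_100 = pm < 0 || pm > 100,
    n_analyzed = base$n
  ), class = "mediation_result")
  if (res$interaction_invalid) {
    warning("mediation interpretation invalid under interaction (p < ",
            interaction_alpha, " for: ",
            paste(mediators[inter_p < interaction_alpha], collapse = ", "),
            ")", call. = FALSE)
  }
  res
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result: %s ~ %s via %s>\n", x$outcome_name,
              "risk group", paste(x$mediators, collapse = " + ")))
  cat(sprintf("  unadjusted beta = %.4f (SE %.4f, p = %.3g)\n",
              x$beta_unadjusted, x$se_unadjusted, x$p_unadjusted))
  cat(sprintf("  adjusted beta   = %.4f (SE %.4f, p = %.3g)\n",
              x$beta_adjusted, x$se_adjusted, x$p_adjusted))
  cat(sprintf("  percent mediated = %.1f%%%s\n", x$percent_mediated,
              if (x$outside_0_100) " [outside 0-100: suppression]" else ""))
  cat(sprintf("  interaction p: %s%s\n",
              paste(sprintf("%s %.3g", names(x$interaction_p),
                            x$interaction_p), collapse = ", "),
              if (x$interaction_invalid) " [interaction present]" else ""))
  cat(sprintf("  n analyzed = %d\n", x$n_analyzed))
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the Hardy-Weinberg expectation computed from the observed allele
#' frequency.
#'
#' @param n_cc,n_ct,n_tt Observed genotype counts (CC, CT, TT).
#' @return List with `chisq`, `p_value`, `t_allele_freq` and the `expected`
#'   counts. A monomorphic sample returns p = 1 by convention (with a
#'   message).
#' @export
#' @examples
#' hwe_test(30, 40, 30)$chisq # 4
hwe_test <- function(n_cc, n_ct, n_tt) {
  stopifnot(n_cc >= 0, n_ct >= 0, n_tt >= 0)
  n <- n_cc + n_ct + n_tt
  if (n == 0) stop("no genotyped individuals", call. = FALSE)
  p <- (2 * n_tt + n_ct) / (2 * n)
  q <- 1 - p
  if (p == 0 || p == 1) {
    message("monomorphic sample: HWE p-value set to 1 by convention")
    return(list(chisq = 0, p_value = 1, t_allele_freq = p,
                expected = c(cc = n * q^2, ct = 2 * n * p * q, tt = n * p^2)))
  }
  expected <- c(cc = n * q^2, ct = 2 * n * p * q, tt = n * p^2)
  chisq <- sum((c(n_cc, n_ct, n_tt) - expected)^2 / expected)
  list(chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       t_allele_freq = p,
       expected = expected)
}

#' Tidy a comparison result into one table row
#'
#' @param x A `comparison_result`.
#' @return One-row tibble suitable for building an outcomes table.
#' @export
tidy_comparison <- function(x) {
  tibble::tibble(
    outcome = x$outcome_name,
    scale = x$scale,
    n_cc = x$n_cc,
    n_ctt = x$n_ctt,
    mean_cc = x$group_means$mean[1],
    lwr_cc = x$group_means$lwr[1],
    upr_cc = x$group_means$upr[1],
    mean_ctt = x$group_means$mean[2],
    lwr_ctt = x$group_means$lwr[2],
    upr_ctt = x$group_means$upr[2],
    beta = x$beta,
    se_robust = x$se_robust,
    p_model = x$p_model
  )
}
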