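#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a mobility-limited trial population of adults aged 70+
#' with low appendicular lean mass and SPPB scores of 3-9: 396 men and 1026
#' women, with sex-specific marginal distributions for age, BMI, 5STS time,
#' appendicular lean mass, cognition (MMSE), depressive symptoms (CES-D),
#' and nutritional status (MNA). Stature is drawn per sex and body mass is
#' derived as BMI x stature^2, so the BMI marginals are preserved exactly.
#' Continuous variables are truncated normals (inverse-CDF sampling);
#' questionnaire scores are rounded to their instruments' granularity.
#'
#' @param n_men,n_women stratum sizes.
#' @param n_missing_5sts extra rows injected with a missing (not "unable")
#'   5STS time, to exercise the eligibility filter; default 0.
#' @param chair_height_m seat height used for every participant.
#' @param multimorbidity_prev prevalence of multimorbidity (3+ chronic
#'   conditions).
#' @param arm_prob probability of allocation to the intervention arm.
#' @param men,women per-sex `c(mean, sd)` pairs for `age` (years), `bmi`
#'   (kg/m^2), `stature` (m), `t5sts` (s), `alm` (kg), `mmse`, `cesd`, `mna`.
#' @param bounds named list of `c(lo, hi)` truncation bounds shared by both
#'   sexes.
#' @param balance_probs probabilities of balance scores 0-4.
#' @param gait_meanlog,gait_sdlog log-normal parameters of the 4-m walk time.
#' @param p_gait_unable,p_t5sts_unable probabilities of an "unable" result.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_men = 396L, n_women = 1026L,
                          n_missing_5sts = 0L,
                          chair_height_m = 0.45,
                          multimorbidity_prev = 0.25,
                          arm_prob = 0.5,
                          men = list(age = c(79.5, 6.2), bmi = c(29.2, 5.2),
                                     stature = c(1.68, 0.07),
                                     t5sts = c(19.1, 6.7), alm = c(21.1, 3.5),
                                     mmse = c(28.0, 1.7), cesd = c(4.6, 3.3),
                                     mna = c(13.0, 1.6)),
                          women = list(age = c(78.7, 5.7), bmi = c(28.3, 5.9),
                                       stature = c(1.56, 0.06),
                                       t5sts = c(19.3, 6.7),
                                       alm = c(14.7, 2.2),
                                       mmse = c(28.0, 1.8), cesd = c(6.1, 4.1),
                                       mna = c(12.6, 1.7)),
                          bounds = list(age = c(70, 100), bmi = c(16, 55),
                                        stature = c(1.30, 2.05),
                                        t5sts = c(6, 59.9), alm = c(7, 36),
                                        mmse = c(24, 30), cesd = c(0, 30),
                                        mna = c(6, 14)),
                          balance_probs = c(0.04, 0.10, 0.22, 0.30, 0.34),
                          gait_meanlog = log(7.2), gait_sdlog = 0.25,
                          p_gait_unable = 0.01, p_t5sts_unable = 0.02) {
  stopifnot(n_men >= 0, n_women >= 0, n_missing_5sts >= 0,
            chair_height_m >= 0,
            multimorbidity_prev >= 0, multimorbidity_prev <= 1,
            length(balance_probs) == 5, all(balance_probs >= 0))
  for (p in c(men, women)) stopifnot(length(p) == 2, p[2] >= 0)
  for (b in bounds) {
    if (b[1] >= b[2]) stop("infeasible truncation bounds (empty support)")
  }
  cfg <- list(n_men = as.integer(n_men), n_women = as.integer(n_women),
              n_missing_5sts = as.integer(n_missing_5sts),
              chair_height_m = chair_height_m,
              multimorbidity_prev = multimorbidity_prev, arm_prob = arm_prob,
              men = men, women = women, bounds = bounds,
              balance_probs = balance_probs / sum(balance_probs),
              gait_meanlog = gait_meanlog, gait_sdlog = gait_sdlog,
              p_gait_unable = p_gait_unable,
              p_t5sts_unable = p_t5sts_unable)
  class(cfg) <- "cohort_config"
  cfg
}

#' Configuration for the event-time model
#'
#' Event times for mobility disability, hospitalization, and death are drawn
#' from a Weibull proportional-hazards model on a chosen SPPB index plus
#' covariates, with administrative censoring and optional independent
#' exponential dropout. The per-point index coefficients default to the log
#' adjusted hazard ratios reported for the traditional SPPB in a
#' mobility-limited trial cohort (0.759 for disability, 0.864 for
#' hospitalization, 0.716 for death), so a one-point higher index lowers each
#' hazard. Covariates and the index are centred at their realized cohort
#' means; the baseline Weibull scale for each outcome is then solved
#' numerically so the cohort-average event probability at the censoring
#' horizon equals `target_incidence`.
#'
#' @param target_incidence named proportions of participants with each event
#'   by `censor_days`; defaults 44.5% / 32.4% / 4.3%.
#' @param shape named Weibull shape parameters (> 0); 1 = exponential.
#' @param index_coef named per-index-point log-hazard coefficients.
#' @param index name of the scored column driving the hazard.
#' @param covariate_coefs named log-hazard coefficients for cohort columns
#'   (`arm_intervention` is the 0/1 indicator of the intervention arm).
#' @param censor_days administrative censoring time (days).
#' @param dropout_rate per-day rate of independent exponential dropout;
#'   default 0 (administrative censoring only).
#' @return a list of class `event_config`.
#' @export
event_config <- function(target_incidence = c(disability = 0.445,
                                              hospitalization = 0.324,
                                              death = 0.043),
                         shape = c(disability = 1, hospitalization = 1,
                                   death = 1),
                         index_coef = c(disability = log(0.759),
                                        hospitalization = log(0.864),
                                        death = log(0.716)),
                         index = "sppb_t",
                         covariate_coefs = c(age_years = 0.03,
                                             bmi_kgm2 = 0.01, mmse = -0.03,
                                             cesd = 0.03, mna = -0.05,
                                             multimorbidity = 0.30,
                                             arm_intervention = -0.10),
                         censor_days = 730, dropout_rate = 0) {
  outcomes <- c("disability", "hospitalization", "death")
  stopifnot(all(outcomes %in% names(target_incidence)),
            all(outcomes %in% names(shape)),
            all(outcomes %in% names(index_coef)),
            all(shape > 0), censor_days > 0, dropout_rate >= 0,
            all(target_incidence > 0), all(target_incidence < 1))
  cfg <- list(outcomes = outcomes,
              target_incidence = target_incidence[outcomes],
              shape = shape[outcomes], index_coef = index_coef[outcomes],
              index = index, covariate_coefs = covariate_coefs,
              censor_days = censor_days, dropout_rate = dropout_rate)
  class(cfg) <- "event_config"
  cfg
}

# inverse-CDF truncated normal; errors when the support is (numerically) empty
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12)
    stop("infeasible truncation (empty support) for mean ", mean, ", sd ", sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# moments of N(mu, sigma) truncated to [lo, hi]
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# latent (mu, sigma) such that the truncated distribution has the target
# moments; published cohort marginals already reflect eligibility truncation
# (e.g. age >= 70), so the targets are post-truncation moments. When the
# target SD exceeds what the family supports on [lo, hi] (tightly bounded
# questionnaire scores), the closest achievable fit is used. Solutions are
# cached since the same configuration is solved repeatedly.
.truncnorm_cache <- new.env(parent = emptyenv())

truncnorm_params <- function(target_mean, target_sd, lo, hi) {
  if (target_sd <= 0) return(c(target_mean, 0))
  key <- paste(target_mean, target_sd, lo, hi, sep = "|")
  hit <- .truncnorm_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    if (stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma) < 1e-10)
      return(1e6)  # numerically empty support
    mom <- truncnorm_moments(mu, sigma, lo, hi)
    if (!all(is.finite(mom))) return(1e6)
    (mom[1] - target_mean)^2 / target_sd^2 + (mom[2] / target_sd - 1)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  out <- c(fit$par[1], exp(fit$par[2]))
  .truncnorm_cache[[key]] <- out
  out
}

draw_stratum <- function(n, sex, p, cfg) {
  b <- cfg$bounds
  d <- function(var) {
    lat <- truncnorm_params(p[[var]][1], p[[var]][2],
                            b[[var]][1], b[[var]][2])
    rtruncnorm(n, lat[1], lat[2], b[[var]][1], b[[var]][2])
  }
  stature <- d("stature")
  bmi <- d("bmi")
  balance <- sample(0:4, n, replace = TRUE, prob = cfg$balance_probs)
  side <- ifelse(balance >= 1, 10, stats::runif(n, 0, 9.9))
  semi <- ifelse(balance >= 2, 10,
                 ifelse(balance == 1, stats::runif(n, 0, 9.9), NA_real_))
  semi[balance == 0] <- NA_real_
  tand <- rep(NA_real_, n)
  tand[balance == 2] <- stats::runif(sum(balance == 2), 0, 2.99)
  tand[balance == 3] <- stats::runif(sum(balance == 3), 3, 9.9)
  tand[balance == 4] <- 10
  gait_unable <- stats::runif(n) < cfg$p_gait_unable
  gait <- exp(stats::rnorm(n, cfg$gait_meanlog, cfg$gait_sdlog))
  gait <- pmin(pmax(gait, 2.5), 30)
  gait[gait_unable] <- NA_real_
  t5sts_unable <- stats::runif(n) < cfg$p_t5sts_unable
  t5sts <- d("t5sts")
  t5sts[t5sts_unable] <- NA_real_
  data.frame(sex = sex,
             age_years = round(d("age"), 1),
             bmi_kgm2 = bmi,
             stature_m = stature,
             body_mass_kg = bmi * stature^2,
             alm_kg = d("alm"),
             chair_height_m = cfg$chair_height_m,
             balance_side_by_side_s = side,
             balance_semitandem_s = semi,
             balance_tandem_s = tand,
             gait4m_s = gait,
             gait4m_unable = gait_unable,
             t5sts_s = t5sts,
             t5sts_unable = t5sts_unable,
             mmse = round(d("mmse")),
             cesd = round(d("cesd")),
             mna = round(d("mna") * 2) / 2,
             multimorbidity = as.integer(stats::runif(n) <
                                           cfg$multimorbidity_prev),
             arm = ifelse(stats::runif(n) < cfg$arm_prob,
                          "intervention", "control"))
}

# Enforces the traditional-SPPB 3-9 eligibility range by rejection sampling
# of the balance and gait components only: the 5STS time feeds the power
# equations, so its marginal distribution is kept exactly as configured and
# the conditioning falls on the components whose marginals are not anchored.
draw_eligible_stratum <- function(n, sex, p, cfg, max_iter = 500L) {
  out <- draw_stratum(n, sex, p, cfg)
  bg_cols <- c("balance_side_by_side_s", "balance_semitandem_s",
               "balance_tandem_s", "gait4m_s", "gait4m_unable")
  for (iter in seq_len(max_iter)) {
    sppb <- score_balance(out$balance_side_by_side_s, out$balance_semitandem_s,
                          out$balance_tandem_s) +
      score_gait(out$gait4m_s, out$gait4m_unable) +
      score_chair_time(out$t5sts_s, out$t5sts_unable)
    bad <- which(sppb < 3 | sppb > 9)
    if (!length(bad)) return(out)
    out[bad, bg_cols] <- draw_stratum(length(bad), sex, p, cfg)[, bg_cols]
  }
  stop("could not satisfy SPPB eligibility within ", max_iter, " resamples")
}

#' Solve the Weibull baseline scale for a target event proportion
#'
#' Under a Weibull proportional-hazards model,
#' \eqn{S(t \mid x) = \exp\{-(t/\lambda)^k e^{\eta(x)}\}}, the cohort-average
#' event probability at a horizon depends on the baseline scale \eqn{\lambda}
#' and the distribution of linear predictors \eqn{\eta}. This solves for
#' \eqn{\lambda} so that the mean of \eqn{1 - S(h \mid x)} over the supplied
#' linear predictors equals `target`.
#'
#' @param lp numeric vector of linear predictors (centred or not).
#' @param shape Weibull shape \eqn{k > 0}.
#' @param target event proportion in (0, 1).
#' @param horizon time horizon (same units as the scale returned).
#' @return the baseline scale \eqn{\lambda}.
#' @export
weibull_scale_for_incidence <- function(lp, shape, target, horizon) {
  stopifnot(shape > 0, target > 0, target < 1, horizon > 0)
  f <- function(log_scale) {
    mean(1 - exp(-(horizon / exp(log_scale))^shape * exp(lp))) - target
  }
  exp(stats::uniroot(f, log(horizon) + c(-25, 25), tol = 1e-12)$root)
}

#' Generate a synthetic mobility-limited cohort with event times
#'
#' Draws a cohort per [cohort_config()], scores power measures and the five
#' SPPB indexes (within-cohort sex-specific quartiles), enforces the
#' eligibility range (traditional SPPB 3-9) by rejection sampling, and
#' simulates Weibull proportional-hazards times to mobility disability,
#' hospitalization, and death per [event_config()]. Hospitalization and
#' disability are treated as time-to-first-event with administrative
#' censoring (no competing-risks structure). Event days are reported as
#' whole days (ceiling), which creates realistic ties.
#'
#' The master `seed` is split into per-stage substreams (cohort draw, then
#' one per outcome), so the same seed yields an identical table.
#'
#' @param cohort_cfg a [cohort_config()].
#' @param event_cfg an [event_config()].
#' @param seed integer master seed.
#' @return a scored cohort data frame with columns `<outcome>_event` (0/1)
#'   and `<outcome>_days` for each outcome, plus an attribute
#'   `"power_cutoffs"` holding the quartile tables used.
#' @export
simulate_cohort <- function(cohort_cfg = cohort_config(),
                            event_cfg = event_config(), seed = 1L) {
  stopifnot(inherits(cohort_cfg, "cohort_config"),
            inherits(event_cfg, "event_config"))
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max, 2 + length(event_cfg$outcomes))

  set.seed(stage_seeds[1])
  parts <- list()
  if (cohort_cfg$n_men > 0)
    parts$men <- draw_eligible_stratum(cohort_cfg$n_men, "male",
                                       cohort_cfg$men, cohort_cfg)
  if (cohort_cfg$n_women > 0)
    parts$women <- draw_eligible_stratum(cohort_cfg$n_women, "female",
                                         cohort_cfg$women, cohort_cfg)
  if (!length(parts)) stop("cohort has no participants")
  cohort <- do.call(rbind, unname(parts))

  if (cohort_cfg$n_missing_5sts > 0) {
    set.seed(stage_seeds[2])
    n_mis <- cohort_cfg$n_missing_5sts
    n_mis_men <- stats::rbinom(1, n_mis, cohort_cfg$n_men /
                                 max(cohort_cfg$n_men + cohort_cfg$n_women, 1))
    mis <- rbind(draw_stratum(n_mis_men, "male", cohort_cfg$men, cohort_cfg),
                 draw_stratum(n_mis - n_mis_men, "female", cohort_cfg$women,
                              cohort_cfg))
    mis$t5sts_s <- NA_real_
    mis$t5sts_unable <- FALSE
    cohort <- rbind(cohort, mis)
  }
  cohort$id <- sprintf("P%04d", seq_len(nrow(cohort)))
  cohort <- cohort[, c("id", setdiff(names(cohort), "id"))]

  cohort <- add_power_measures(cohort, chair_height = cohort_cfg$chair_height_m)
  cohort <- score_sppb(cohort)

  index <- cohort[[event_cfg$index]]
  cov_names <- names(event_cfg$covariate_coefs)
  X <- sapply(cov_names, function(nm) {
    if (nm == "arm_intervention") as.numeric(cohort$arm == "intervention")
    else cohort[[nm]]
  })
  lp_cov <- as.vector(scale(X, scale = FALSE) %*% event_cfg$covariate_coefs)

  for (k in seq_along(event_cfg$outcomes)) {
    oc <- event_cfg$outcomes[k]
    set.seed(stage_seeds[2 + k])
    lp <- event_cfg$index_coef[[oc]] * (index - mean(index)) + lp_cov
    sc <- weibull_scale_for_incidence(lp, event_cfg$shape[[oc]],
                                      event_cfg$target_incidence[[oc]],
                                      event_cfg$censor_days)
    t_event <- sc * (-log(stats::runif(nrow(cohort))) / exp(lp)) ^
      (1 / event_cfg$shape[[oc]])
    t_cens <- rep(event_cfg$censor_days, nrow(cohort))
    if (event_cfg$dropout_rate > 0)
      t_cens <- pmin(t_cens, stats::rexp(nrow(cohort),
                                         event_cfg$dropout_rate))
    cohort[[paste0(oc, "_event")]] <- as.integer(t_event <= t_cens)
    cohort[[paste0(oc, "_days")]] <- pmax(ceiling(pmin(t_event, t_cens)), 1)
  }
  cohort
}

#' Apply the analysis eligibility filter
#'
#' Removes participants with a missing (but not "unable") 5STS time, then
#' those whose traditional SPPB falls outside the 3-9 eligibility range, and
#' reports how many rows each rule removed.
#'
#' @param cohort a scored cohort (must carry `sppb_t`).
#' @return a list with `cohort` (retained rows) and `exclusions`, a data
#'   frame with columns `rule` and `n`.
#' @export
apply_eligibility <- function(cohort) {
  if (is.null(cohort$sppb_t)) stop("cohort must be scored (run score_sppb)")
  missing_5sts <- is.na(cohort$t5sts_s) & !cohort$t5sts_unable
  kept <- cohort[!missing_5sts, ]
  out_of_range <- kept$sppb_t < 3 | kept$sppb_t > 9
  exclusions <- data.frame(rule = c("missing 5STS", "SPPB out of 3-9"),
                           n = c(sum(missing_5sts), sum(out_of_range)))
  list(cohort = kept[!out_of_range, ], exclusions = exclusions)
}
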