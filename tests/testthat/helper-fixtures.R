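# Small generator configuration used where full cohort sizes are unnecessary.
small_cohort <- function(seed = 1, n_men = 60, n_women = 100, ...) {
  simulate_cohort(cohort_config(n_men = n_men, n_women = n_women, ...),
                  event_config(), seed = seed)
}

# Ten handcrafted participants with component results chosen so every score
# can be verified by independent arithmetic.
handmade_cohort <- function() {
  data.frame(
    id = sprintf("H%02d", 1:10),
    sex = rep(c("male", "female"), each = 5),
    age_years = seq(71, 89, by = 2),
    bmi_kgm2 = rep(28, 10),
    stature_m = c(1.70, 1.72, 1.68, 1.75, 1.66, 1.55, 1.58, 1.52, 1.60, 1.56),
    body_mass_kg = 28 * c(1.70, 1.72, 1.68, 1.75, 1.66,
                          1.55, 1.58, 1.52, 1.60, 1.56)^2,
    alm_kg = c(21, 22, 20, 23, 19, 15, 14, 13, 16, 15),
    chair_height_m = 0.45,
    balance_side_by_side_s = c(10, 10, 10, 10, 5, 10, 10, 10, 10, 10),
    balance_semitandem_s = c(10, 10, 10, 8, NA, 10, 10, 10, 10, 10),
    balance_tandem_s = c(10, 4, 2, NA, NA, 10, 7, 1, 10, 2.5),
    gait4m_s = c(4.5, 5.0, 6.2, 8.7, 8.71, 4.81, 4.82, 6.21, 9.5, NA),
    gait4m_unable = c(rep(FALSE, 9), TRUE),
    t5sts_s = c(10, 11.19, 13.69, 16.69, 59.99, 11.2, 13.7, 16.7, 60, NA),
    t5sts_unable = c(rep(FALSE, 9), TRUE),
    mmse = rep(28L, 10),
    cesd = rep(5L, 10),
    mna = rep(12.5, 10),
    multimorbidity = rep(0L, 10),
    arm = rep(c("intervention", "control"), 5),
    disability_event = c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0),
    disability_days = c(100, 730, 200, 730, 300, 730, 400, 730, 500, 730),
    hospitalization_event = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1),
    hospitalization_days = c(730, 150, 730, 250, 730, 350, 730, 450, 730, 550),
    death_event = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 1),
    death_days = c(730, 730, 730, 730, 600, 730, 730, 730, 730, 650)
  )
}

# Hand-picked quartile cut-offs usable with cohorts too small for
# within-sample estimation.
hand_cutoffs <- function() {
  qs <- list(amp = c(100, 150, 200), rmp = c(1.2, 1.6, 2.0),
             almp = c(40, 50, 60), smp = c(5, 7, 9))
  cuts <- lapply(names(qs), function(m) {
    out <- data.frame(metric = m, sex = c("male", "female"),
                      q25 = qs[[m]][1], q50 = qs[[m]][2], q75 = qs[[m]][3])
    class(out) <- c("power_cutoffs", "data.frame")
    out
  })
  names(cuts) <- names(qs)
  cuts
}

# Exhaustive case-control pair count with ties at 1/2: the independent AUC
# oracle used against the rank-based implementation.
auc_pairs <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (x in cases) for (y in controls)
    total <- total + (x > y) + 0.5 * (x == y)
  total / (length(cases) * length(controls))
}

# Brute-force Cox partial log-likelihood (no ties): risk-set sum evaluated
# term by term, independent of the fitting route.
cox_loglik_brute <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}
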