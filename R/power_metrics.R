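#' Sit-to-stand muscle power measures
#'
#' The five-repetition sit-to-stand test (5STS) times how long a person needs
#' to rise from a chair five times with arms crossed. Combined with body mass,
#' stature, and chair height, the mean mechanical power of the concentric
#' (rising) phases can be estimated:
#'
#' \deqn{AMP = \frac{0.9 \, m \, g \, (0.5\,h - h_{chair})}{(t_{5STS}/n_{reps}) \times 0.5}}
#'
#' where \eqn{m} is body mass (kg), \eqn{h} stature (m), \eqn{h_{chair}} the
#' seat height (m), and \eqn{g} gravitational acceleration. The factor 0.9
#' accounts for the body fraction actually lifted (legs stay partly grounded);
#' the vertical displacement of the centre of mass is taken as half the
#' stature minus seat height; and only half of each repetition's duration is
#' concentric, hence the 0.5 in the denominator. Three normalized measures
#' divide absolute power (AMP, W) by body mass (relative, RMP, W/kg), squared
#' stature (allometric, ALMP, W/m^2), or appendicular lean mass (specific,
#' SMP, W/kg of ALM).
#'
#' A participant who cannot perform the 5STS at all has no defined power;
#' pass `unable = TRUE` (or a missing time with the flag) and `NA` is
#' returned, which downstream scoring maps to a chair-component score of 0.
#'
#' @param body_mass body mass in kg (> 0).
#' @param stature standing height in metres. Values above 3 are rejected as
#'   probable centimetre entries.
#' @param chair_height seat height in metres; default 0.45 m.
#' @param t5sts 5STS test time in seconds (> 0), or `NA` when unable.
#' @param n_reps number of sit-to-stand repetitions timed; default 5.
#' @param g gravitational acceleration in m/s^2; default 9.81.
#' @param unable logical; `TRUE` marks an "unable to perform" result (no
#'   time). Recycled against the other arguments.
#' @return `compute_amp()` returns absolute power in W (`NA` where unable).
#' @examples
#' compute_amp(body_mass = 70, stature = 1.60, chair_height = 0.45,
#'             t5sts = 19.2)
#' @export
compute_amp <- function(body_mass, stature, chair_height = 0.45, t5sts,
                        n_reps = 5L, g = 9.81, unable = FALSE) {
  n <- max(length(body_mass), length(stature), length(chair_height),
           length(t5sts), length(unable))
  body_mass <- rep_len(body_mass, n)
  stature <- rep_len(stature, n)
  chair_height <- rep_len(chair_height, n)
  t5sts <- rep_len(t5sts, n)
  unable <- rep_len(as.logical(unable), n)

  if (any(!is.na(body_mass) & body_mass <= 0))
    stop("body_mass must be positive")
  if (any(!is.na(stature) & stature <= 0))
    stop("stature must be positive")
  if (any(!is.na(stature) & stature > 3))
    stop("stature > 3 m looks like a centimetre value; supply metres")
  if (any(!is.na(chair_height) & chair_height < 0))
    stop("chair_height must be non-negative")
  if (any(!is.na(chair_height) & !is.na(stature) & chair_height >= stature))
    stop("chair_height must be below stature")
  if (any(n_reps < 1)) stop("n_reps must be >= 1")
  bad_t <- !unable & !is.na(t5sts) & t5sts <= 0
  if (any(bad_t)) stop("t5sts must be positive when the test was completed")
  missing_t <- !unable & is.na(t5sts)

  amp <- body_mass * 0.9 * g * (stature * 0.5 - chair_height) /
    ((t5sts / n_reps) * 0.5)
  amp[unable | missing_t] <- NA_real_
  amp
}

#' @rdname compute_amp
#' @param amp absolute muscle power in W.
#' @return `compute_rmp()`: power per body mass, W/kg.
#' @export
compute_rmp <- function(amp, body_mass) {
  if (any(!is.na(body_mass) & body_mass <= 0))
    stop("body_mass must be positive")
  amp / body_mass
}

#' @rdname compute_amp
#' @return `compute_almp()`: power per squared stature, W/m^2.
#' @export
compute_almp <- function(amp, stature) {
  if (any(!is.na(stature) & stature <= 0))
    stop("stature must be positive")
  amp / stature^2
}

#' @rdname compute_amp
#' @param alm appendicular lean mass in kg (> 0).
#' @return `compute_smp()`: power per appendicular lean mass, W/kg.
#' @export
compute_smp <- function(amp, alm) {
  if (any(!is.na(alm) & alm <= 0))
    stop("alm must be positive")
  amp / alm
}

#' Add the four power measures to a cohort table
#'
#' Batch entry point over a per-participant data frame. Expects columns
#' `body_mass_kg`, `stature_m`, `t5sts_s`, `t5sts_unable`, `alm_kg`, and
#' optionally `chair_height_m` (filled with `chair_height` where absent).
#' Appends `amp_w`, `rmp_wkg`, `almp_wm2`, `smp_wkg`; participants unable to
#' perform the 5STS get `NA` in all four.
#'
#' @param cohort a cohort data frame.
#' @param chair_height default seat height in metres used where
#'   `chair_height_m` is absent or `NA`.
#' @param g gravitational acceleration in m/s^2.
#' @return the cohort with four power columns appended.
#' @export
add_power_measures <- function(cohort, chair_height = 0.45, g = 9.81) {
  needed <- c("body_mass_kg", "stature_m", "t5sts_s", "t5sts_unable", "alm_kg")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
  ch <- if ("chair_height_m" %in% names(cohort)) cohort$chair_height_m
        else rep(NA_real_, nrow(cohort))
  ch[is.na(ch)] <- chair_height
  amp <- compute_amp(cohort$body_mass_kg, cohort$stature_m, ch,
                     cohort$t5sts_s, g = g, unable = cohort$t5sts_unable)
  cohort$amp_w <- amp
  cohort$rmp_wkg <- compute_rmp(amp, cohort$body_mass_kg)
  cohort$almp_wm2 <- compute_almp(amp, cohort$stature_m)
  cohort$smp_wkg <- compute_smp(amp, cohort$alm_kg)
  cohort
}
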