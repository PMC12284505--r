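#' Default SPPB component cut-points
#'
#' Boundaries for converting the 4-m gait time and the 5STS time into 0-4
#' component scores, following the original battery's reference quartiles.
#' Band convention (documented and unit-tested): upper bounds are inclusive
#' for the slower (worse) score, i.e. a gait time of exactly 8.70 s still
#' scores 2 and 8.71 s scores 1.
#'
#' @return a list with elements `gait` (times in s: 4.82, 6.20, 8.70) and
#'   `chair` (times in s: 11.19, 13.69, 16.69, 59.99). Gait times strictly
#'   below `gait[1]` score 4; chair times at or above 60 s score 0.
#' @export
sppb_cutpoints <- function() {
  list(gait = c(4.82, 6.20, 8.70),
       chair = c(11.19, 13.69, 16.69, 59.99))
}

#' Score the hierarchical standing-balance test
#'
#' Participants attempt side-by-side, semi-tandem, and tandem stands for 10 s
#' each; each stance is attempted only after holding the previous one for the
#' full 10 s. Scores: 0 = cannot hold side-by-side 10 s; 1 = side-by-side
#' held, semi-tandem < 10 s; 2 = semi-tandem held, tandem < 3 s; 3 = tandem
#' held 3-9.99 s; 4 = tandem held 10 s.
#'
#' `NA` hold times mean "not attempted" (or unable); a recorded time for a
#' stance whose prerequisite was not held 10 s violates the protocol
#' hierarchy and raises an error.
#'
#' @param side_by_side_s,semitandem_s,tandem_s hold times in seconds, `NA`
#'   when not attempted. Vectorized.
#' @return integer scores 0-4.
#' @export
score_balance <- function(side_by_side_s, semitandem_s, tandem_s) {
  n <- max(length(side_by_side_s), length(semitandem_s), length(tandem_s))
  side <- rep_len(side_by_side_s, n)
  semi <- rep_len(semitandem_s, n)
  tand <- rep_len(tandem_s, n)
  if (any(c(side, semi, tand) < 0, na.rm = TRUE))
    stop("balance hold times must be non-negative")
  if (any(!is.na(semi) & (is.na(side) | side < 10)))
    stop("semi-tandem time recorded without a 10-s side-by-side hold")
  if (any(!is.na(tand) & (is.na(semi) | semi < 10)))
    stop("tandem time recorded without a 10-s semi-tandem hold")

  score <- integer(n)
  held_side <- !is.na(side) & side >= 10
  held_semi <- held_side & !is.na(semi) & semi >= 10
  score[held_side] <- 1L
  score[held_semi & (is.na(tand) | tand < 3)] <- 2L
  score[held_semi & !is.na(tand) & tand >= 3 & tand < 10] <- 3L
  score[held_semi & !is.na(tand) & tand >= 10] <- 4L
  score
}

#' Score the 4-m usual-pace walk
#'
#' @param gait4m_s walk time in seconds, `NA` when unable.
#' @param unable logical, `TRUE` when the participant could not walk the
#'   course; scores 0.
#' @param cutpoints boundary list from [sppb_cutpoints()].
#' @return integer scores 0-4 (faster = higher).
#' @export
score_gait <- function(gait4m_s, unable = is.na(gait4m_s),
                       cutpoints = sppb_cutpoints()) {
  n <- max(length(gait4m_s), length(unable))
  t <- rep_len(gait4m_s, n)
  unable <- rep_len(as.logical(unable), n)
  if (any(!unable & !is.na(t) & t <= 0))
    stop("gait time must be positive when the test was completed")
  cp <- cutpoints$gait
  score <- rep(1L, n)
  score[!is.na(t) & t <= cp[3]] <- 2L
  score[!is.na(t) & t <= cp[2]] <- 3L
  score[!is.na(t) & t < cp[1]] <- 4L
  score[unable | is.na(t)] <- 0L
  score
}

#' Score the 5STS by time (traditional chair-stand component)
#'
#' @param t5sts_s 5STS time in seconds, `NA` when unable.
#' @param unable logical "unable to perform" flag; scores 0, as do times of
#'   60 s or more.
#' @inheritParams score_gait
#' @return integer scores 0-4 (faster = higher).
#' @export
score_chair_time <- function(t5sts_s, unable = is.na(t5sts_s),
                             cutpoints = sppb_cutpoints()) {
  n <- max(length(t5sts_s), length(unable))
  t <- rep_len(t5sts_s, n)
  unable <- rep_len(as.logical(unable), n)
  if (any(!unable & !is.na(t) & t <= 0))
    stop("5STS time must be positive when the test was completed")
  cp <- cutpoints$chair
  score <- rep(0L, n)
  score[!is.na(t) & t <= cp[4]] <- 1L
  score[!is.na(t) & t <= cp[3]] <- 2L
  score[!is.na(t) & t <= cp[2]] <- 3L
  score[!is.na(t) & t <= cp[1]] <- 4L
  score[unable | is.na(t)] <- 0L
  score
}

#' Sex-specific power quartile cut-offs
#'
#' Estimates the 25th, 50th, and 75th empirical percentiles of a muscle power
#' measure within each sex stratum (linear-interpolation percentile
#' definition, `stats::quantile` type 7). "Unable" participants (missing
#' power) are excluded from estimation. These cut-offs re-score the
#' chair-stand component on the power scale.
#'
#' @param values numeric power values (one measure); `NA` allowed.
#' @param sex character vector, `"male"`/`"female"`, same length.
#' @param metric label for the measure, one of `"amp"`, `"rmp"`, `"almp"`,
#'   `"smp"`.
#' @param min_n smallest acceptable number of non-missing values per stratum.
#' @return a data frame of class `power_cutoffs` with columns `metric`,
#'   `sex`, `q25`, `q50`, `q75`.
#' @export
fit_quartile_cutoffs <- function(values, sex, metric, min_n = 8L) {
  metric <- match.arg(metric, c("amp", "rmp", "almp", "smp"))
  if (length(values) != length(sex))
    stop("values and sex must have equal length")
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  sexes <- intersect(c("male", "female"), unique(sex))
  rows <- lapply(sexes, function(s) {
    v <- values[sex == s & !is.na(values)]
    if (length(v) < min_n)
      stop(sprintf("stratum '%s' has only %d non-missing values (need >= %d)",
                   s, length(v), min_n))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(metric = metric, sex = s, q25 = q[1], q50 = q[2], q75 = q[3])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_cutoffs", "data.frame")
  out
}

#' Score a power value against sex-specific quartile cut-offs
#'
#' Higher power means better performance, so the lowest quartile scores 1 and
#' the highest scores 4; 0 is reserved for participants unable to perform the
#' 5STS (missing power). Ties at a cut-off go to the lower score (the
#' boundaries are upper-inclusive).
#'
#' @param values numeric power values (`NA` = unable, scored 0).
#' @param sex `"male"`/`"female"` per value.
#' @param cutoffs a `power_cutoffs` data frame from [fit_quartile_cutoffs()].
#' @param metric measure label; must match `cutoffs$metric`.
#' @return integer scores 0-4.
#' @export
score_power <- function(values, sex, cutoffs, metric) {
  metric <- match.arg(metric, c("amp", "rmp", "almp", "smp"))
  if (!all(cutoffs$metric == metric))
    stop(sprintf("cutoffs are for metric '%s', not '%s'",
                 cutoffs$metric[1], metric))
  n <- length(values)
  sex <- rep_len(sex, n)
  if (!all(sex %in% cutoffs$sex))
    stop("cutoffs lack a stratum for some sex values")
  score <- integer(n)
  for (s in unique(sex)) {
    cs <- cutoffs[cutoffs$sex == s, ]
    i <- sex == s
    v <- values[i]
    sc <- rep(4L, sum(i))
    sc[!is.na(v) & v <= cs$q75] <- 3L
    sc[!is.na(v) & v <= cs$q50] <- 2L
    sc[!is.na(v) & v <= cs$q25] <- 1L
    sc[is.na(v)] <- 0L
    score[i] <- sc
  }
  score
}

#' Score the SPPB and its four power-substituted indexes
#'
#' Scores the three battery components and assembles five composites: the
#' traditional SPPB (balance + gait + timed chair stand) and four variants in
#' which the chair-stand component is replaced by the quartile score of one
#' muscle power measure (AMP, RMP, ALMP, SMP). All composites share the
#' balance and gait components, so they differ only through the chair score.
#'
#' The cohort must already carry the power columns from
#' [add_power_measures()]. Quartile cut-offs default to within-cohort,
#' sex-specific estimation; pass `cutoffs` (a named list with elements
#' `amp`, `rmp`, `almp`, `smp`) to score against externally fitted values.
#'
#' @param cohort data frame with component results (`balance_side_by_side_s`,
#'   `balance_semitandem_s`, `balance_tandem_s`, `gait4m_s`, `gait4m_unable`,
#'   `t5sts_s`, `t5sts_unable`, `sex`) and power columns.
#' @param cutoffs optional named list of `power_cutoffs` tables.
#' @param cutpoints time boundaries from [sppb_cutpoints()].
#' @return the cohort with component scores (`balance_score`, `gait_score`,
#'   `chair_score_t`, `chair_score_amp`, ..., `chair_score_smp`) and
#'   composites `sppb_t`, `sppb_amp`, `sppb_rmp`, `sppb_almp`, `sppb_smp`
#'   appended; the cut-offs used are attached as attribute `"power_cutoffs"`.
#' @export
score_sppb <- function(cohort, cutoffs = NULL, cutpoints = sppb_cutpoints()) {
  power_cols <- c(amp = "amp_w", rmp = "rmp_wkg", almp = "almp_wm2",
                  smp = "smp_wkg")
  missing_cols <- setdiff(power_cols, names(cohort))
  if (length(missing_cols))
    stop("run add_power_measures() first; missing: ",
         paste(missing_cols, collapse = ", "))

  cohort$balance_score <- score_balance(cohort$balance_side_by_side_s,
                                        cohort$balance_semitandem_s,
                                        cohort$balance_tandem_s)
  cohort$gait_score <- score_gait(cohort$gait4m_s, cohort$gait4m_unable,
                                  cutpoints)
  cohort$chair_score_t <- score_chair_time(cohort$t5sts_s,
                                           cohort$t5sts_unable, cutpoints)

  if (is.null(cutoffs)) {
    cutoffs <- lapply(names(power_cols), function(m)
      fit_quartile_cutoffs(cohort[[power_cols[[m]]]], cohort$sex, m))
    names(cutoffs) <- names(power_cols)
  }
  for (m in names(power_cols)) {
    sc <- score_power(cohort[[power_cols[[m]]]], cohort$sex, cutoffs[[m]], m)
    cohort[[paste0("chair_score_", m)]] <- sc
    cohort[[paste0("sppb_", m)]] <-
      cohort$balance_score + cohort$gait_score + sc
  }
  cohort$sppb_t <- cohort$balance_score + cohort$gait_score +
    cohort$chair_score_t
  attr(cohort, "power_cutoffs") <- cutoffs
  cohort
}

#' Write / read quartile cut-offs as a JSON artifact
#'
#' Persists the sex-specific quartile tables so new individuals can be scored
#' against a reference cohort's cut-offs.
#'
#' @param cutoffs named list of `power_cutoffs` data frames.
#' @param path file path of the JSON artifact.
#' @return `write_cutoffs()` returns `path` invisibly; `read_cutoffs()`
#'   returns the named list of `power_cutoffs` tables.
#' @export
write_cutoffs <- function(cutoffs, path) {
  jsonlite::write_json(lapply(cutoffs, as.data.frame), path, digits = NA)
  invisible(path)
}

#' @rdname write_cutoffs
#' @export
read_cutoffs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(df) {
    class(df) <- c("power_cutoffs", "data.frame")
    df
  })
}
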