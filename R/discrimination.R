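#' Fixed-horizon binary outcome labels from time-to-event data
#'
#' ROC analysis at a common horizon needs every participant classified as a
#' case (event by the horizon) or a control (followed event-free past it).
#' Participants censored event-free before the horizon have an undetermined
#' status and are marked unusable; the default policy excludes them (counted
#' by downstream stages).
#'
#' @param times follow-up times in days.
#' @param events 0/1 event indicators.
#' @param horizon_days classification horizon (> 0); default 730.
#' @return data frame with `event_by_horizon` (0/1, `NA` when unusable) and
#'   `usable` (logical).
#' @export
horizon_labels <- function(times, events, horizon_days = 730) {
  stopifnot(horizon_days > 0, length(times) == length(events),
            all(events %in% c(0, 1)))
  case <- events == 1 & times <= horizon_days
  control <- times >= horizon_days & !case
  usable <- case | control
  data.frame(event_by_horizon = ifelse(usable, as.integer(case), NA_integer_),
             usable = usable)
}

#' Covariate-adjusted risk score for fixed-horizon ROC
#'
#' Fits a logistic regression of the horizon outcome on the SPPB index plus
#' the adjustment covariates (age, BMI, MMSE, CES-D, MNA, multimorbidity,
#' randomization arm), over usable rows only, and returns each participant's
#' fitted linear predictor as the ROC input score. This operationalizes an
#' "adjusted ROC": the score is the full adjusted model's risk ranking.
#'
#' @param cohort scored cohort data frame.
#' @param index index column name.
#' @param labels output of [horizon_labels()] aligned with `cohort` rows.
#' @param covariates adjustment covariate names.
#' @return numeric vector of linear-predictor scores, `NA` for unusable rows
#'   (and rows with missing covariates); the glm fit is attached as
#'   attribute `"fit"`.
#' @export
adjusted_risk_score <- function(cohort, index, labels,
                                covariates = adjustment_covariates()) {
  stopifnot(nrow(cohort) == nrow(labels))
  dat <- cohort[, c(index, covariates)]
  dat$.y <- labels$event_by_horizon
  use <- labels$usable & stats::complete.cases(dat)
  if (sum(use) < 20)
    stop("fewer than 20 usable complete rows for adjusted ROC")
  if (length(unique(dat$.y[use])) < 2)
    stop("need at least one case and one control by the horizon")
  fit <- stats::glm(stats::reformulate(c(index, covariates), ".y"),
                    data = dat[use, ], family = stats::binomial())
  if (!fit$converged)
    warning("logistic model did not converge (possible separation); ",
            "scores may be unstable")
  scores <- rep(NA_real_, nrow(cohort))
  scores[use] <- stats::predict(fit, type = "link")
  attr(scores, "fit") <- fit
  scores
}

auc_band_label <- function(auc) {
  if (auc < 0.7) "poor"
  else if (auc < 0.8) "acceptable"
  else if (auc <= 0.9) "excellent"
  else "outstanding"
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC is computed as the Mann-Whitney concordance probability: the
#' proportion of case-control pairs in which the case has the higher score,
#' counting ties as 1/2. Implemented via midranks, which is exactly the
#' exhaustive pair count. Bands follow the conventional reading: < 0.7 poor,
#' 0.7-0.8 acceptable, 0.8-0.9 excellent, > 0.9 outstanding (boundaries: 0.7
#' and 0.8 belong to the band above, 0.9 to excellent).
#'
#' @param scores numeric risk scores (higher = riskier); `NA` rows dropped.
#' @param labels 0/1 outcome per score (or a [horizon_labels()] data frame,
#'   in which case its usable rows are used).
#' @return object of class `auc_result`: list with `auc`, `band`, `n_cases`,
#'   `n_controls`.
#' @export
compute_auc <- function(scores, labels) {
  if (is.data.frame(labels)) labels <- labels$event_by_horizon
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  stopifnot(all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0) stop("no cases among usable rows")
  if (n0 == 0) stop("no controls among usable rows")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  out <- list(auc = auc, band = auc_band_label(auc),
              n_cases = n1, n_controls = n0)
  class(out) <- "auc_result"
  out
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%s); %d cases / %d controls\n",
              x$auc, x$band, x$n_cases, x$n_controls))
  invisible(x)
}
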