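#' Kaplan-Meier survival curves per group
#'
#' Thin wrapper around [survival::survfit()] returning the product-limit
#' estimate as a tidy data frame. The estimate is a right-continuous step
#' function; rows give its value at (and just after) each observed time.
#'
#' @param times follow-up times (> 0).
#' @param events 0/1 event indicators.
#' @param groups optional grouping factor; empty groups are dropped with a
#'   warning.
#' @return data frame with `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
fit_km <- function(times, events, groups = NULL) {
  stopifnot(all(times > 0), all(events %in% c(0, 1)))
  if (is.null(groups)) groups <- rep("all", length(times))
  if (!is.factor(groups)) groups <- factor(groups)
  empty <- levels(groups)[!levels(groups) %in% unique(as.character(groups))]
  if (length(empty))
    warning("empty group(s) skipped: ", paste(empty, collapse = ", "))
  groups <- droplevels(groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata <- if (is.null(fit$strata)) rep("all", length(fit$time))
            else rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

# adjustment set used across the Cox and ROC stages
adjustment_covariates <- function() {
  c("age_years", "bmi_kgm2", "mna", "cesd", "mmse", "multimorbidity", "arm")
}

#' Fit a Cox proportional-hazards model for one SPPB index and outcome
#'
#' The index enters as a continuous per-point predictor; the adjusted model
#' adds age, BMI, nutritional risk (MNA), depressive symptoms (CES-D),
#' cognition (MMSE), multimorbidity, and randomization arm. Rows missing any
#' model variable are dropped listwise; tied event times are handled by the
#' Efron approximation by default. The stored AIC is \eqn{2k - 2\ell} with
#' \eqn{\ell} the maximized log partial likelihood and \eqn{k} the number of
#' estimated coefficients.
#'
#' @param cohort a scored cohort data frame with `<outcome>_event` and
#'   `<outcome>_days` columns.
#' @param index name of the index column (e.g. `"sppb_t"`, `"sppb_rmp"`).
#' @param outcome one of `"disability"`, `"hospitalization"`, `"death"`.
#' @param adjusted logical; `FALSE` fits the index alone.
#' @param covariates adjustment covariate names (columns of `cohort`).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return an object of class `sppb_cox`: a list with the per-point
#'   coefficient, hazard ratio and Wald 95% CI, p-value, covariate
#'   coefficients, log partial likelihood, parameter count `k`, `aic`, `n`,
#'   `n_events`, the ids of rows used, and a convergence flag.
#' @export
fit_cox <- function(cohort, index, outcome, adjusted = TRUE,
                    covariates = adjustment_covariates(), ties = "efron") {
  ties <- match.arg(ties, c("efron", "breslow"))
  time_col <- paste0(outcome, "_days")
  event_col <- paste0(outcome, "_event")
  if (!all(c(time_col, event_col, index) %in% names(cohort)))
    stop("cohort lacks ", index, " or ", outcome, " columns")
  vars <- c(index, if (adjusted) covariates)
  dat <- cohort[, c("id", time_col, event_col, vars)]
  dat <- dat[stats::complete.cases(dat), ]
  if (sum(dat[[event_col]]) < 1) stop("no events for outcome ", outcome)

  fml <- stats::reformulate(vars, response = sprintf("survival::Surv(%s, %s)",
                                                     time_col, event_col))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  converged <- is.finite(fit$loglik[2]) &&
    !any(is.na(stats::coef(fit))) &&
    all(is.finite(sqrt(diag(fit$var))))
  beta <- stats::coef(fit)[index]
  se <- sqrt(diag(fit$var))[1]
  ll <- fit$loglik[2]
  k <- length(stats::coef(fit))
  out <- list(outcome = outcome, index = index, adjusted = adjusted,
              coef = unname(beta),
              hazard_ratio = exp(unname(beta)),
              ci_lower = exp(unname(beta) - 1.96 * se),
              ci_upper = exp(unname(beta) + 1.96 * se),
              p_value = unname(2 * stats::pnorm(-abs(beta / se))),
              covariate_coefs = stats::coef(fit)[-1],
              log_partial_likelihood = ll,
              k = k,
              aic = 2 * k - 2 * ll,
              n = nrow(dat),
              n_events = sum(dat[[event_col]]),
              ids_used = sort(dat$id),
              ties = ties,
              converged = converged)
  class(out) <- "sppb_cox"
  out
}

#' @export
print.sppb_cox <- function(x, ...) {
  cat(sprintf("Cox PH fit: %s ~ %s (%s)\n", x$outcome, x$index,
              if (x$adjusted) "adjusted" else "unadjusted"))
  cat(sprintf("  HR per point %.3f (95%% CI %.3f, %.3f), p = %.4g\n",
              x$hazard_ratio, x$ci_lower, x$ci_upper, x$p_value))
  cat(sprintf("  n = %d, events = %d, logLik = %.2f, k = %d, AIC = %.1f\n",
              x$n, x$n_events, x$log_partial_likelihood, x$k, x$aic))
  invisible(x)
}

aic_band <- function(delta) {
  ifelse(delta <= 2, "equally plausible",
         ifelse(delta < 4, "weak difference",
                ifelse(delta <= 7, "moderate difference",
                       ifelse(delta <= 10, "considerable difference",
                              "strong difference"))))
}

canonical_index_order <- function() c("t", "amp", "rmp", "almp", "smp")

#' Rank competing index models by AIC
#'
#' Computes each model's AIC difference from the best (lowest-AIC) model and
#' flags that model (LAIC). Accepts either a list of `sppb_cox` fits — in
#' which case it verifies that every fit converged and used the identical
#' estimation sample (same rows, same event count), since AICs are only
#' comparable on a common sample — or a data frame with columns `index` and
#' `aic` (e.g. published values). Qualitative bands follow the usual reading
#' of AIC differences: <= 2 equally plausible, 4-7 moderate, > 10 strong.
#' Ties for the minimum are broken by the canonical index order
#' (t, amp, rmp, almp, smp) and otherwise by input order.
#'
#' @param fits list of `sppb_cox` objects, or a data frame with `index` and
#'   `aic` columns.
#' @return a data frame of class `sppb_aic_comparison`: `index`, `aic`,
#'   `delta_aic`, `is_laic`, `band`.
#' @export
compare_aic <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- data.frame(index = as.character(fits$index), aic = fits$aic)
  } else {
    if (length(fits) < 2) stop("need at least two fits to compare")
    stopifnot(all(vapply(fits, inherits, logical(1), "sppb_cox")))
    bad <- !vapply(fits, `[[`, logical(1), "converged")
    if (any(bad)) {
      warning("non-converged fit(s) excluded: ",
              paste(vapply(fits[bad], `[[`, character(1), "index"),
                    collapse = ", "))
      fits <- fits[!bad]
      if (length(fits) < 2) stop("fewer than two converged fits remain")
    }
    ref <- fits[[1]]
    for (f in fits[-1]) {
      if (!identical(f$ids_used, ref$ids_used) ||
          f$n_events != ref$n_events)
        stop("fits were not estimated on the identical sample; ",
             "AICs are not comparable")
    }
    tab <- data.frame(index = vapply(fits, `[[`, character(1), "index"),
                      aic = vapply(fits, `[[`, numeric(1), "aic"))
  }
  key <- sub("^sppb_?", "", tolower(tab$index))
  ord <- match(key, canonical_index_order())
  ord[is.na(ord)] <- length(canonical_index_order()) + seq_len(sum(is.na(ord)))
  best <- order(tab$aic, ord)[1]
  tab$delta_aic <- tab$aic - tab$aic[best]
  tab$is_laic <- seq_len(nrow(tab)) == best
  tab$band <- aic_band(tab$delta_aic)
  class(tab) <- c("sppb_aic_comparison", "data.frame")
  tab
}
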