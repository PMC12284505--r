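#' Baseline characteristics table for a scored cohort
#'
#' Produces the conventional baseline-characteristics table of a clinical
#' cohort study: per sex stratum and overall,
#' mean +/- SD for continuous variables, n (%) for events, and median
#' (min-max) for the traditional SPPB. Percentages are computed exactly as
#' 100 x count / stratum n and rounded to one decimal for display; the raw
#' counts are kept alongside.
#'
#' @param cohort scored, filtered cohort data frame.
#' @return a data frame with one row per variable and columns `variable`,
#'   `total`, `men`, `women`, plus numeric count columns for events.
#' @export
summarize_cohort <- function(cohort) {
  strata <- list(total = cohort,
                 men = cohort[cohort$sex == "male", ],
                 women = cohort[cohort$sex == "female", ])
  mean_sd <- function(x) {
    if (!length(x) || all(is.na(x))) return(NA_character_)
    sprintf("%.1f ± %.1f", mean(x, na.rm = TRUE),
            stats::sd(x, na.rm = TRUE))
  }
  n_pct <- function(x, n) {
    if (!n) return(NA_character_)
    sprintf("%d (%.1f)", sum(x, na.rm = TRUE), 100 * sum(x, na.rm = TRUE) / n)
  }
  med_range <- function(x) {
    if (!length(x) || all(is.na(x))) return(NA_character_)
    sprintf("%g (%g−%g)", stats::median(x, na.rm = TRUE),
            min(x, na.rm = TRUE), max(x, na.rm = TRUE))
  }
  cont <- c("Age, years" = "age_years", "BMI, kg/m2" = "bmi_kgm2",
            "5STS, s" = "t5sts_s", "AMP, W" = "amp_w",
            "RMP, W/kg" = "rmp_wkg", "ALMP, W/m2" = "almp_wm2",
            "SMP, W/kg" = "smp_wkg", "ALM, kg" = "alm_kg",
            "MMSE, score" = "mmse", "CES-D, points" = "cesd",
            "MNA, points" = "mna")
  events <- c("Mobility disability, n (%)" = "disability_event",
              "Hospitalization, n (%)" = "hospitalization_event",
              "Death, n (%)" = "death_event")
  rows <- list(data.frame(variable = "n",
                          t(vapply(strata, function(s)
                            sprintf("%d", nrow(s)), character(1)))))
  rows <- c(rows, list(
    data.frame(variable = "SPPB, score",
               t(vapply(strata, function(s) med_range(s$sppb_t),
                        character(1))))))
  for (v in names(cont)) {
    rows <- c(rows, list(data.frame(
      variable = v,
      t(vapply(strata, function(s) mean_sd(s[[cont[[v]]]]), character(1))))))
  }
  for (v in names(events)) {
    rows <- c(rows, list(data.frame(
      variable = v,
      t(vapply(strata, function(s) n_pct(s[[events[[v]]]], nrow(s)),
               character(1))))))
  }
  out <- do.call(rbind, rows)
  names(out) <- c("variable", "total", "men", "women")
  rownames(out) <- NULL
  out
}

index_columns <- function() {
  stats::setNames(paste0("sppb_", canonical_index_order()),
                  paste0("SPPB", canonical_index_order()))
}

#' Run the full comparison pipeline
#'
#' Orchestrates simulate (or load) -> power -> score -> eligibility filter ->
#' per-sex Cox models (unadjusted and adjusted) for every index and outcome
#' -> AIC comparison per sex x outcome -> fixed-horizon adjusted ROC grid,
#' and assembles a manifest (seed, sample sizes, exclusion counts, per-model
#' estimation sample sizes). All five index models per stratum are checked to
#' share the identical estimation sample before AIC comparison.
#'
#' @param cohort an already-generated raw cohort data frame, or `NULL` to
#'   simulate one from the configs.
#' @param cohort_cfg,event_cfg generator configurations (used when `cohort`
#'   is `NULL`; the event config also names the outcomes analyzed).
#' @param seed master seed for simulation.
#' @param horizon_days ROC classification horizon.
#' @param outdir optional directory; when given, every table is written as
#'   CSV and the manifest as JSON.
#' @return a list of class `sppb_report`: `summary`, `cox` (long data frame
#'   over sex x outcome x index x adjustment), `aic` (per-stratum comparison
#'   tables), `auc` (grid shaped rows = index, columns = sex x outcome),
#'   `exclusions`, `cutoffs`, `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, cohort_cfg = cohort_config(),
                         event_cfg = event_config(), seed = 1L,
                         horizon_days = 730, outdir = NULL) {
  if (is.null(cohort)) {
    cohort <- simulate_cohort(cohort_cfg, event_cfg, seed)
  } else {
    if (is.null(cohort$amp_w)) cohort <- add_power_measures(cohort)
    if (is.null(cohort$sppb_t)) cohort <- score_sppb(cohort)
  }
  elig <- apply_eligibility(cohort)
  dat <- elig$cohort
  outcomes <- c("disability", "hospitalization", "death")
  idx <- index_columns()
  sexes <- c(men = "male", women = "female")

  cox_rows <- list()
  aic_tables <- list()
  model_ns <- list()
  sexes <- sexes[vapply(sexes, function(s) any(dat$sex == s), logical(1))]
  for (sx in names(sexes)) {
    sub <- dat[dat$sex == sexes[[sx]], ]
    for (oc in outcomes) {
      fits_adj <- lapply(idx, function(ic) fit_cox(sub, ic, oc,
                                                   adjusted = TRUE))
      fits_un <- lapply(idx, function(ic) fit_cox(sub, ic, oc,
                                                  adjusted = FALSE))
      for (nm in names(idx)) {
        for (fit in list(fits_un[[nm]], fits_adj[[nm]])) {
          cox_rows[[length(cox_rows) + 1]] <- data.frame(
            sex = sx, outcome = oc, index = nm,
            adjusted = fit$adjusted, hr = fit$hazard_ratio,
            ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
            p_value = fit$p_value, aic = fit$aic, n = fit$n,
            n_events = fit$n_events)
        }
      }
      cmp <- compare_aic(fits_adj)
      cmp$index <- names(idx)[match(cmp$index, idx)]
      aic_tables[[paste(sx, oc, sep = ".")]] <- cmp
      model_ns[[paste(sx, oc, sep = ".")]] <-
        list(n = fits_adj[[1]]$n, n_events = fits_adj[[1]]$n_events)
    }
  }
  cox_tab <- do.call(rbind, cox_rows)

  auc_rows <- list()
  for (nm in names(idx)) {
    row <- list(index = nm)
    for (sx in names(sexes)) {
      sub <- dat[dat$sex == sexes[[sx]], ]
      for (oc in outcomes) {
        labs <- horizon_labels(sub[[paste0(oc, "_days")]],
                               sub[[paste0(oc, "_event")]], horizon_days)
        sc <- adjusted_risk_score(sub, idx[[nm]], labs)
        row[[paste(sx, oc, sep = "_")]] <- compute_auc(sc, labs)$auc
      }
    }
    auc_rows[[nm]] <- as.data.frame(row)
  }
  auc_tab <- do.call(rbind, auc_rows)
  rownames(auc_tab) <- NULL

  manifest <- list(seed = seed, horizon_days = horizon_days,
                   n_raw = nrow(cohort), n_analyzed = nrow(dat),
                   exclusions = elig$exclusions,
                   model_samples = model_ns)
  out <- list(summary = summarize_cohort(dat), cox = cox_tab,
              aic = aic_tables, auc = auc_tab,
              exclusions = elig$exclusions,
              cutoffs = attr(cohort, "power_cutoffs"),
              manifest = manifest)
  class(out) <- "sppb_report"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$summary, file.path(outdir, "cohort_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(out$cox, file.path(outdir, "cox_models.csv"),
                     row.names = FALSE)
    aic_long <- do.call(rbind, lapply(names(out$aic), function(k) {
      cbind(stratum = k, as.data.frame(out$aic[[k]]))
    }))
    utils::write.csv(aic_long, file.path(outdir, "aic_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(out$auc, file.path(outdir, "auc_grid.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.sppb_report <- function(x, ...) {
  cat("SPPB index comparison report\n")
  cat(sprintf("  analyzed n = %d (raw %d)\n", x$manifest$n_analyzed,
              x$manifest$n_raw))
  cat("  AIC best model per stratum:\n")
  for (k in names(x$aic)) {
    best <- x$aic[[k]]$index[x$aic[[k]]$is_laic]
    cat(sprintf("    %-22s %s\n", k, best))
  }
  invisible(x)
}
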