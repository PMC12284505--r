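test_that("product-limit estimates match closed forms", {
  # no events: survival stays at 1
  km0 <- fit_km(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # all events at distinct times: steps 0.75, 0.5, 0.25, 0
  km1 <- fit_km(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km1$surv, c(0.75, 0.5, 0.25, 0))
  # censoring-free estimate equals 1 - ECDF at every event time
  set.seed(21)
  tt <- rexp(40, 0.01)
  km <- fit_km(tt, rep(1, 40))
  expect_equal(km$surv, 1 - ecdf(tt)(km$time))
  expect_warning(fit_km(c(1, 2), c(1, 0), factor(c("a", "a"), c("a", "b"))),
                 "empty group")
})

test_that("a hand-evaluated partial likelihood matches the fitted one", {
  # five rows, no ties: the risk-set sum can be written out term by term
  dat <- data.frame(id = as.character(1:5),
                    x = c(2, 1, 3, 0, 4),
                    disability_days = c(10, 20, 30, 40, 50),
                    disability_event = c(1, 0, 1, 1, 0))
  fit <- fit_cox(dat, "x", "disability", adjusted = FALSE)
  ll_hand <- cox_loglik_brute(fit$coef, dat$x, dat$disability_days,
                              dat$disability_event)
  expect_equal(fit$log_partial_likelihood, ll_hand, tolerance = 1e-8)
  # and the coefficient maximizes the brute-force likelihood
  opt <- optimize(function(b) cox_loglik_brute(b, dat$x, dat$disability_days,
                                               dat$disability_event),
                  c(-5, 5), maximum = TRUE)
  expect_equal(fit$coef, opt$maximum, tolerance = 1e-4)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$log_partial_likelihood)
  expect_equal(fit$k, 1)
})

test_that("a known two-group hazard ratio is recovered", {
  set.seed(31)
  n <- 2000
  x <- rep(0:1, each = n / 2)
  t_event <- rexp(n, 0.002 * exp(log(0.5) * x))
  dat <- data.frame(id = as.character(1:n), x = x,
                    disability_days = pmin(t_event, 730),
                    disability_event = as.integer(t_event <= 730))
  fit <- fit_cox(dat, "x", "disability", adjusted = FALSE)
  expect_true(fit$ci_lower <= 0.5 && 0.5 <= fit$ci_upper)
  expect_lt(abs(fit$hazard_ratio - 0.5), 0.07)
  expect_true(fit$converged)
})

test_that("a permuted index behaves as a null predictor", {
  co <- small_cohort(seed = 41, n_men = 0, n_women = 300)
  set.seed(42)
  hrs <- replicate(25, {
    co$perm <- sample(co$sppb_t)
    fit_cox(co, "perm", "disability", adjusted = FALSE)$hazard_ratio
  })
  expect_lt(abs(mean(log(hrs))), 3 * sd(log(hrs)) / sqrt(25))
})

test_that("adding covariates never decreases the partial likelihood", {
  co <- small_cohort(seed = 43)
  for (oc in c("disability", "hospitalization")) {
    un <- fit_cox(co, "sppb_rmp", oc, adjusted = FALSE)
    ad <- fit_cox(co, "sppb_rmp", oc, adjusted = TRUE)
    expect_gte(ad$log_partial_likelihood, un$log_partial_likelihood)
    expect_gt(ad$k, un$k)
    expect_equal(ad$aic, 2 * ad$k - 2 * ad$log_partial_likelihood)
  }
  expect_error(fit_cox(transform(co, death_event = 0), "sppb_t", "death"),
               "no events")
})

test_that("listwise deletion yields a common estimation sample", {
  co <- small_cohort(seed = 44)
  co$mna[1:5] <- NA
  co$cesd[6:8] <- NA
  fits <- lapply(paste0("sppb_", c("t", "amp", "rmp", "almp", "smp")),
                 function(ic) fit_cox(co, ic, "disability"))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  expect_true(all(ns == nrow(co) - 8))
  cmp <- compare_aic(fits)
  expect_equal(sum(cmp$is_laic), 1L)
  expect_true(all(cmp$delta_aic >= 0))
  expect_equal(cmp$delta_aic, cmp$aic - min(cmp$aic))
  # a fit on a different sample is refused
  other <- fit_cox(co[-(31:40), ], "sppb_t", "disability")
  expect_error(compare_aic(list(fits[[1]], other)), "identical sample")
})

test_that("AIC differences reproduce published five-model comparisons", {
  men_mob <- data.frame(index = c("t", "amp", "rmp", "almp", "smp"),
                        aic = c(2108.0, 1965.3, 1963.0, 1966.7, 1971.7))
  cmp <- compare_aic(men_mob)
  expect_equal(cmp$delta_aic, c(145.0, 2.3, 0, 3.7, 8.7), tolerance = 1e-12)
  expect_true(cmp$is_laic[3])
  expect_equal(cmp$band,
               c("strong difference", "weak difference", "equally plausible",
                 "weak difference", "considerable difference"))
  women_death <- data.frame(index = c("t", "amp", "rmp", "almp", "smp"),
                            aic = c(464.2, 454.7, 453.5, 455.1, 454.2))
  expect_equal(compare_aic(women_death)$delta_aic,
               c(10.7, 1.2, 0, 1.6, 0.7), tolerance = 1e-12)
})

test_that("comparison output is order-invariant up to the tie-break", {
  tab <- data.frame(index = c("smp", "t", "rmp", "amp", "almp"),
                    aic = c(1971.7, 2108.0, 1963.0, 1965.3, 1966.7))
  cmp <- compare_aic(tab)
  expect_equal(cmp$delta_aic[cmp$index == "t"], 145.0)
  expect_true(cmp$is_laic[cmp$index == "rmp"])
  # exact ties: canonical order decides the flagged model
  tie <- data.frame(index = c("smp", "amp", "t"), aic = c(100, 100, 100))
  cmp_tie <- compare_aic(tie)
  expect_true(all(cmp_tie$delta_aic == 0))
  expect_true(cmp_tie$is_laic[cmp_tie$index == "t"])
})
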