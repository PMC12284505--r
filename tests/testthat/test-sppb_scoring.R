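test_that("balance scoring reproduces an independent truth table", {
  # enumerate every protocol-consistent branch and map it independently
  cases <- list(
    list(side = 4, semi = NA, tand = NA, want = 0L),   # side-by-side failed
    list(side = NA, semi = NA, tand = NA, want = 0L),  # unable
    list(side = 10, semi = 4, tand = NA, want = 1L),
    list(side = 10, semi = NA, tand = NA, want = 1L),  # semi not attempted
    list(side = 10, semi = 10, tand = NA, want = 2L),
    list(side = 10, semi = 10, tand = 0, want = 2L),
    list(side = 10, semi = 10, tand = 2.5, want = 2L),
    list(side = 10, semi = 10, tand = 2.99, want = 2L),
    list(side = 10, semi = 10, tand = 3, want = 3L),
    list(side = 10, semi = 10, tand = 9.99, want = 3L),
    list(side = 10, semi = 10, tand = 10, want = 4L))
  for (cs in cases)
    expect_identical(score_balance(cs$side, cs$semi, cs$tand), cs$want)
  # vectorized form agrees
  df <- do.call(rbind, lapply(cases, as.data.frame))
  expect_identical(score_balance(df$side, df$semi, df$tand), df$want)
})

test_that("balance hierarchy violations are rejected", {
  expect_error(score_balance(10, 5, 5), "tandem")
  expect_error(score_balance(5, 10, NA), "semi-tandem")
  expect_error(score_balance(NA, 5, NA), "semi-tandem")
  expect_error(score_balance(-1, NA, NA), "non-negative")
})

test_that("gait scoring honours the half-open band convention", {
  expect_identical(score_gait(4.0), 4L)
  expect_identical(score_gait(4.81), 4L)
  expect_identical(score_gait(4.82), 3L)   # first boundary is exclusive above
  expect_identical(score_gait(6.20), 3L)
  expect_identical(score_gait(6.21), 2L)
  expect_identical(score_gait(8.70), 2L)
  expect_identical(score_gait(8.71), 1L)
  expect_identical(score_gait(NA, unable = TRUE), 0L)
  expect_error(score_gait(0), "positive")
})

test_that("timed chair-stand scoring honours its boundaries", {
  expect_identical(score_chair_time(11.19), 4L)
  expect_identical(score_chair_time(11.20), 3L)
  expect_identical(score_chair_time(13.69), 3L)
  expect_identical(score_chair_time(13.70), 2L)
  expect_identical(score_chair_time(16.69), 2L)
  expect_identical(score_chair_time(16.70), 1L)
  expect_identical(score_chair_time(19.2), 1L)
  expect_identical(score_chair_time(59.99), 1L)
  expect_identical(score_chair_time(60), 0L)
  expect_identical(score_chair_time(NA, unable = TRUE), 0L)
  expect_error(score_chair_time(-1), "positive")
})

test_that("quartile cut-offs use linear-interpolation percentiles per sex", {
  cut <- fit_quartile_cutoffs(1:8, rep("male", 8), "rmp")
  expect_equal(cut$q25, 2.75)
  expect_equal(cut$q50, 4.5)
  expect_equal(cut$q75, 6.25)
  # degenerate distribution
  cut0 <- fit_quartile_cutoffs(rep(3, 10), rep("female", 10), "amp")
  expect_equal(unlist(cut0[, c("q25", "q50", "q75")], use.names = FALSE),
               rep(3, 3))
  # sex isolation: the men's row ignores the women's values entirely
  men_v <- c(5, 9, 2, 7, 4, 8, 1, 6)
  a <- fit_quartile_cutoffs(c(men_v, rnorm(20, 100)),
                            rep(c("male", "female"), c(8, 20)), "smp")
  b <- fit_quartile_cutoffs(c(men_v, rnorm(20, -50)),
                            rep(c("male", "female"), c(8, 20)), "smp")
  expect_equal(a[a$sex == "male", ], b[b$sex == "male", ])
  expect_error(fit_quartile_cutoffs(1:5, rep("male", 5), "amp"),
               "stratum 'male'")
})

test_that("power scores split a tie-free stratum into exact quarters", {
  set.seed(3)
  v <- sample(rnorm(40))
  cut <- fit_quartile_cutoffs(v, rep("female", 40), "rmp")
  sc <- score_power(v, rep("female", 40), cut, "rmp")
  expect_equal(as.vector(table(sc)), rep(10L, 4))
  expect_identical(score_power(min(v) - 1, "female", cut, "rmp"), 1L)
  expect_identical(score_power(max(v) + 1, "female", cut, "rmp"), 4L)
  expect_identical(score_power(NA_real_, "female", cut, "rmp"), 0L)
  # ties at a cut-off go to the lower score
  expect_identical(score_power(cut$q25, "female", cut, "rmp"), 1L)
  expect_identical(score_power(cut$q75, "female", cut, "rmp"), 3L)
  expect_error(score_power(v, rep("female", 40), cut, "amp"), "metric")
  expect_error(score_power(1, "male", cut, "rmp"), "stratum")
})

test_that("composites are additive and differ only through the chair score", {
  co <- score_sppb(add_power_measures(small_cohort(seed = 5)))
  for (m in c("t", "amp", "rmp", "almp", "smp")) {
    expect_equal(co[[paste0("sppb_", m)]],
                 co$balance_score + co$gait_score +
                   co[[paste0("chair_score_", m)]])
    expect_true(all(co[[paste0("sppb_", m)]] >= 0 &
                      co[[paste0("sppb_", m)]] <= 12))
  }
  # component isolation: balance and gait are shared across all five
  expect_equal(co$sppb_rmp - co$sppb_t, co$chair_score_rmp - co$chair_score_t)
})

test_that("power-substituted composites are monotone in the power value", {
  co <- score_sppb(add_power_measures(small_cohort(seed = 6)))
  for (s in c("male", "female")) {
    sub <- co[co$sex == s & !is.na(co$rmp_wkg), ]
    bg <- paste(sub$balance_score, sub$gait_score)
    for (grp in split(sub, bg)) {
      if (nrow(grp) < 2) next
      o <- order(grp$rmp_wkg)
      expect_true(all(diff(grp$sppb_rmp[o]) >= 0))
    }
  }
})

test_that("externally supplied cut-offs survive a JSON round trip", {
  co <- score_sppb(add_power_measures(small_cohort(seed = 7)))
  cuts <- attr(co, "power_cutoffs")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_cutoffs(cuts, path)
  cuts2 <- read_cutoffs(path)
  expect_equal(lapply(cuts2, as.data.frame), lapply(cuts, as.data.frame),
               tolerance = 1e-12)
  rescored <- score_sppb(add_power_measures(small_cohort(seed = 7)),
                         cutoffs = cuts2)
  expect_equal(rescored$sppb_rmp, co$sppb_rmp)
})

test_that("handcrafted participants score exactly as hand-derived", {
  co <- add_power_measures(handmade_cohort())
  expect_identical(score_balance(co$balance_side_by_side_s,
                                 co$balance_semitandem_s,
                                 co$balance_tandem_s),
                   c(4L, 3L, 2L, 1L, 0L, 4L, 3L, 2L, 4L, 2L))
  expect_identical(score_gait(co$gait4m_s, co$gait4m_unable),
                   c(4L, 3L, 3L, 2L, 1L, 4L, 3L, 2L, 1L, 0L))
  expect_identical(score_chair_time(co$t5sts_s, co$t5sts_unable),
                   c(4L, 4L, 3L, 2L, 1L, 3L, 2L, 1L, 0L, 0L))
  # score against hand-picked external cut-offs; expected score counts the
  # number of cut-offs strictly exceeded, an independent formulation
  cuts <- list()
  qs <- list(amp = c(100, 150, 200), rmp = c(1.2, 1.6, 2.0),
             almp = c(40, 50, 60), smp = c(5, 7, 9))
  for (m in names(qs)) {
    cuts[[m]] <- data.frame(metric = m, sex = c("male", "female"),
                            q25 = qs[[m]][1], q50 = qs[[m]][2],
                            q75 = qs[[m]][3])
    class(cuts[[m]]) <- c("power_cutoffs", "data.frame")
  }
  scored <- score_sppb(co, cutoffs = cuts)
  for (m in names(qs)) {
    v <- co[[c(amp = "amp_w", rmp = "rmp_wkg", almp = "almp_wm2",
               smp = "smp_wkg")[[m]]]]
    want <- ifelse(is.na(v), 0L,
                   1L + (v > qs[[m]][1]) + (v > qs[[m]][2]) + (v > qs[[m]][3]))
    expect_identical(scored[[paste0("chair_score_", m)]], as.integer(want))
  }
  expect_equal(scored$sppb_t,
               scored$balance_score + scored$gait_score + scored$chair_score_t)
})
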