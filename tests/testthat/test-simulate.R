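test_that("an empty herd yields empty visit, pen and roster tables", {
  sim <- simulate_herd(swedish_herd(n_pens = 0, tb_pen_count = 0), seed = 1)
  expect_equal(nrow(sim$visits), 0L)
  expect_equal(nrow(sim$pens), 0L)
  expect_equal(nrow(sim$roster), 0L)
})

test_that("simulation is a pure function of profile, drift and seed", {
  prof <- demo_profile(n_pens = 3L, tb_pen_count = 1L,
                       recording_halfspan_days = 15L)
  a <- simulate_herd(prof, seed = 5)
  b <- simulate_herd(prof, seed = 5)
  expect_identical(a, b)
  c <- simulate_herd(prof, seed = 6)
  expect_false(identical(a$visits, c$visits))
})

test_that("invalid configurations are rejected", {
  expect_error(swedish_herd(dfc_mean = -1), "positive")
  expect_error(swedish_herd(tb_pen_count = 99), "tb_pen_count")
  expect_error(swedish_herd(pigs_min = 0), "\\[1, 60\\]")
  expect_error(drift_model(onset_day = 3), "negative")
  expect_error(simulate_herd(demo_profile(), missing_rate = 1.2),
               "missing_rate")
})

test_that("daily feed consumption and visit counts hit the configured means", {
  # Swedish-like CTL-only herd; cluster (pen-level) standard errors, since
  # pen baselines do not average out within a pen
  prof <- swedish_herd(n_pens = 20L, tb_pen_count = 0L, pigs_min = 10L,
                       pigs_max = 10L, recording_halfspan_days = 70L)
  sim <- simulate_herd(prof, seed = 3)
  obs <- daily_observations(sim$visits, sim$pens, sim$roster)
  pen_means_dfc <- tapply(obs$dfc, obs$pen_id, mean)
  se <- sd(pen_means_dfc) / sqrt(length(pen_means_dfc))
  expect_lt(abs(mean(pen_means_dfc) - prof$dfc_mean), 2 * se)
  pen_means_dfv <- tapply(obs$dfv, obs$pen_id, mean)
  se_v <- sd(pen_means_dfv) / sqrt(length(pen_means_dfv))
  expect_lt(abs(mean(pen_means_dfv) - prof$dfv_mean), 2 * se_v)
})

test_that("null drift leaves TB pens indistinguishable from CTL pens", {
  prof <- demo_profile(recording_halfspan_days = 20L)
  pvals <- vapply(1:10, function(s) {
    sim <- simulate_herd(prof, drift = null_drift(), seed = 100 + s)
    obs <- daily_observations(sim$visits, sim$pens, sim$roster)
    pen_mean <- tapply(obs$dfv, obs$pen_id, mean)
    status <- sim$pens$status[match(names(pen_mean), sim$pens$pen_id)]
    t.test(pen_mean[status == "TB"], pen_mean[status == "CTL"])$p.value
  }, numeric(1))
  # p-values should behave like a uniform sample, not pile up near zero
  expect_lte(sum(pvals < 0.05), 3L)
  expect_gt(median(pvals), 0.05)
})

test_that("stronger drift gives a larger TB-window effect size", {
  smd <- function(mult) {
    drift <- drift_model(dfv_multiplier_at_day0 = mult,
                         dfc_multiplier_at_day0 = 1,
                         stdfc_multiplier_at_day0 = 1)
    sim <- simulate_herd(demo_profile(tb_pen_count = 8L,
                                      recording_halfspan_days = 40L),
                         drift = drift, seed = 9)
    obs <- daily_observations(sim$visits, sim$pens, sim$roster)
    tbd <- sim$pens$tb_date[match(obs$pen_id, sim$pens$pen_id)]
    rel <- as.integer(obs$date - tbd)
    inside <- rel >= -14 & rel <= 0   # deepest part of the ramp
    base <- rel < -42
    (mean(obs$dfv[base]) - mean(obs$dfv[inside])) /
      sd(obs$dfv[base | inside])
  }
  expect_gt(smd(0.6), smd(0.9))
  expect_gt(smd(0.9), 0)
})

test_that("sample_pig_day respects degenerate and scaled rates", {
  prof <- demo_profile()
  set.seed(1)
  zero <- sample_pig_day(list(dfv = 0, dfc = 1, stdfc = 1),
                         list(dfv = 1, dfc = 1, stdfc = 1), prof)
  expect_equal(zero$dfv, 0)
  expect_length(zero$grams, 0L)
  expect_error(sample_pig_day(list(dfv = -1, dfc = 1, stdfc = 1),
                              list(dfv = 1, dfc = 1, stdfc = 1), prof),
               "non-negative")

  draw_totals <- function(mult, n = 10000) {
    vapply(seq_len(n), function(i) {
      d <- sample_pig_day(list(dfv = 1, dfc = 1, stdfc = 1),
                          list(dfv = mult, dfc = 1, stdfc = 1), prof)
      sum(d$grams)
    }, numeric(1))
  }
  set.seed(2)
  tot <- draw_totals(1)
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - prof$dfc_mean), 2 * se)

  set.seed(3)
  counts <- vapply(seq_len(10000), function(i)
    sample_pig_day(list(dfv = 1, dfc = 1, stdfc = 1),
                   list(dfv = 0.7, dfc = 1, stdfc = 1), prof)$dfv,
    numeric(1))
  se_c <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 0.7 * prof$dfv_mean), 3 * se_c)
})

test_that("per-visit grams always sum to the pig-day totals downstream", {
  sums <- rowsum(fix_sim$visits$feed_g,
                 paste(fix_sim$visits$pig_id, fix_sim$visits$date))
  key <- paste(fix_obs$pig_id, fix_obs$date)
  m <- match(rownames(sums), key)
  expect_true(all(!is.na(m)))
  expect_equal(fix_obs$dfc[m], as.numeric(sums[, 1L]))
  expect_true(all(fix_obs$dfc[-m] == 0))
})

test_that("inject_missingness honours its rates and bookkeeping", {
  sim <- simulate_herd(demo_profile(n_pens = 10L, pigs_min = 10L,
                                    pigs_max = 10L,
                                    recording_halfspan_days = 20L),
                       seed = 4)
  expect_identical(inject_missingness(sim, 0, 0), sim)

  dropped <- inject_missingness(sim, pig_dropout_rate = 0.2, seed = 8)
  truncated <- sum(dropped$roster$last_day < sim$roster$last_day)
  # ~Binomial(100, 0.2)
  expect_gte(truncated, qbinom(0.0005, 100, 0.2))
  expect_lte(truncated, qbinom(0.9995, 100, 0.2))
  expect_identical(nrow(dropped$roster), nrow(sim$roster))
  # no visits survive beyond a truncated roster
  m <- match(dropped$visits$pig_id, dropped$roster$pig_id)
  expect_true(all(dropped$visits$date <= dropped$roster$last_day[m]))

  gappy <- inject_missingness(sim, day_gap_rate = 0.95, seed = 8)
  expect_identical(gappy$roster, sim$roster)
  expect_lt(nrow(gappy$visits), 0.1 * nrow(sim$visits))
})
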