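test_that("confusion metrics match the worked example", {
  truth <- rep(c("TB", "CTL", "TB", "CTL"), c(80, 5, 20, 95))
  pred <- rep(c("TB", "CTL"), c(85, 115))
  r <- confusion_report(pred, truth)
  expect_equal(c(r$tp, r$fp, r$fn, r$tn), c(80, 5, 20, 95))
  expect_equal(r$tpr, 0.80)
  expect_equal(r$tnr, 0.95)
  expect_equal(r$ppv, 80 / 85, tolerance = 1e-6)   # 0.9412
  expect_equal(r$acc, 0.875)
  expect_equal(r$kappa, 0.75)                      # pe = 0.5
  expect_equal(r$kappa_band, "substantial")
  expect_equal(r$nir, 0.5)
  expect_lt(r$p_value, 1e-10)
})

test_that("constant and perfect predictors hit the kappa identities", {
  truth <- rep(c("TB", "CTL"), c(30, 70))
  all_ctl <- confusion_report(rep("CTL", 100), truth)
  expect_equal(all_ctl$tpr, 0)
  expect_equal(all_ctl$tnr, 1)
  expect_true(is.na(all_ctl$ppv))        # 0/0, reported missing not zero
  expect_equal(all_ctl$kappa, 0)
  expect_equal(all_ctl$acc, all_ctl$nir)
  expect_gt(all_ctl$p_value, 0.3)        # no better than the NIR baseline

  perfect <- confusion_report(truth, truth)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$kappa_band, "almost perfect")

  expect_error(confusion_report(c("TB"), c("TB", "CTL")), "equal length")
  expect_error(confusion_report(c("TB", "maybe"), c("TB", "CTL")),
               "unknown class")
})

test_that("metrics match brute-force enumeration on random fixtures", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(2:40, 1)
    truth <- sample(c("TB", "CTL"), n, replace = TRUE)
    pred <- sample(c("TB", "CTL"), n, replace = TRUE)
    r <- confusion_report(pred, truth)
    o <- metrics_oracle(pred, truth)
    for (f in c("tp", "fp", "fn", "tn", "tpr", "tnr", "ppv", "acc", "kappa"))
      expect_equal(r[[f]], o[[f]], info = paste("fixture", i, "metric", f))
  }
})

test_that("CV splits are 75/25, stratified and deterministic", {
  w <- fix_windows
  n <- nrow(w$features)
  plan <- split_cv(w, seed = 7)
  expect_equal(length(plan$test), round(0.25 * n))
  expect_length(intersect(plan$train, plan$test), 0L)
  expect_identical(split_cv(w, seed = 7), plan)
  expect_false(identical(split_cv(w, seed = 8)$test, plan$test))
  # class proportions preserved within one window
  tb_total <- sum(w$info$label == "TB")
  tb_test <- sum(w$info$label[plan$test] == "TB")
  expect_lte(abs(tb_test - 0.25 * tb_total), 1)
})

test_that("LOOP splits never leak pens and respect stratification", {
  w <- fix_windows
  plan <- split_loop(w, fix_sim$pens, seed = 3)
  expect_length(intersect(w$info$pen_id[plan$train],
                          w$info$pen_id[plan$test]), 0L)
  held <- plan$held_out_pens
  status <- fix_sim$pens$status[match(held, fix_sim$pens$pen_id)]
  expect_setequal(status, c("TB", "CTL"))  # one of each per stratum here

  # 4 pens in one stratum at fraction 0.25: exactly one held out,
  # all of its windows in test
  sub_pens <- fix_sim$pens[fix_sim$pens$status == "CTL", ][1:4, ]
  keep <- w$info$pen_id %in% sub_pens$pen_id
  ws <- w; ws$features <- w$features[keep, ]; ws$info <- w$info[keep, ]
  ps <- suppressWarnings(split_loop(ws, sub_pens, 0.25, seed = 2))
  expect_length(ps$held_out_pens, 1L)
  expect_equal(sort(ps$test),
               which(ws$info$pen_id == ps$held_out_pens))
})

test_that("model comparison follows the paired-test contract", {
  set.seed(5)
  profs <- replicate(7, rbeta(40, 2, 2), simplify = FALSE)
  names(profs) <- tb_methods()
  cmp <- compare_models(profs)
  expect_equal(nrow(cmp), 21L)                     # C(7, 2)
  ok <- !is.na(cmp$p_raw) & cmp$p_raw > 0 & cmp$p_raw < 1 / 21
  expect_true(all(abs(cmp$p_adj[ok] / cmp$p_raw[ok] - 21) < 1e-9))
  expect_true(all(cmp$p_adj <= 1))

  self <- compare_models(list(a = profs[[1]], b = profs[[1]]))
  expect_equal(self$mean_diff, 0)
  expect_equal(self$p_raw, 1)

  # missing folds are dropped listwise
  pa <- profs[[1]]; pa[1:5] <- NA
  pair <- compare_models(list(a = pa, b = profs[[2]]))
  expect_equal(pair$n_folds, 35L)

  expect_error(compare_models(list(a = 1:5 / 5, b = 1:4 / 4)), "mismatched")
})

test_that("benchmarks produce tidy per-subset metrics", {
  sim <- simulate_herds(list(demo_profile(n_pens = 3L, tb_pen_count = 2L,
                                          recording_halfspan_days = 25L),
                             swiss_herd(n_pens = 3L, tb_pen_count = 2L,
                                        pigs_min = 11L, pigs_max = 12L,
                                        recording_halfspan_days = 25L)),
                        seed = 31)
  obs <- daily_observations(sim$visits, sim$pens, sim$roster)
  w <- build_windows(obs, sim$pens, demo_cfg())
  bm <- run_benchmark(w, sim$pens, methods = "knn", regime = "CV",
                      tune = tune_config(4, 2, 13))
  expect_setequal(bm$metrics$herd_subset, c("all", "swedish", "swiss"))
  expect_named(bm$metrics,
               c("model", "regime", "herd_subset", "acc", "acc_lo", "acc_hi",
                 "tpr", "tnr", "ppv", "kappa", "nir", "p_value"))
  expect_true(all(bm$metrics$acc >= bm$metrics$acc_lo - 1e-9 &
                    bm$metrics$acc <= bm$metrics$acc_hi + 1e-9))
})
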