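# Split regimes and performance reporting.
#
# Two leakage-contrasting train/test regimes:
#   CV    random window-level 75/25 split, stratified by class - windows from
#         the same pen can appear on both sides, so the model effectively has
#         previous data on every pen it predicts for;
#   LOOP  pen-held-out split - whole pens (stratified by herd and status) move
#         to the test side, so the model predicts for pens it has never seen.
# Performance is reported from the confusion matrix with TB as positive:
# TPR, TNR, PPV, ACC with exact binomial 95% CI, Cohen's kappa with the
# Landis-Koch band, the no-information rate (majority-class accuracy), and a
# one-sided exact binomial p-value for accuracy exceeding the NIR (the
# "always predict CTL" baseline).

#' Window-level 75/25 train/test split (CV regime)
#'
#' Uniform random split of windows stratified by class, so that both classes
#' appear on both sides whenever counts permit. With fewer than 2 windows of
#' a class the split falls back to unstratified sampling with a warning.
#'
#' @param windows A `tb_windows` object.
#' @param test_fraction Fraction of windows held out for testing.
#' @param seed Integer seed.
#' @return A `split_plan`: list with `mode`, `train`, `test` (integer row
#'   indices) and `seed`.
#' @export
split_cv <- function(windows, test_fraction = 0.25, seed = 1L) {
  n <- nrow(windows$features)
  if (n < 2L) stop("split_cv: need at least 2 windows")
  set.seed(as.integer(seed))
  lab <- windows$info$label
  n_test <- max(1L, round(test_fraction * n))
  if (any(table(lab) < 2L)) {
    warning("split_cv: a class has fewer than 2 windows; unstratified split")
    test <- sort(sample(n, n_test))
  } else {
    # largest-remainder allocation of the test quota across classes
    idx <- split(seq_len(n), lab)
    quota <- test_fraction * lengths(idx)
    take <- floor(quota)
    rem <- n_test - sum(take)
    if (rem > 0L) {
      ord <- order(quota - take, decreasing = TRUE)
      take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
    }
    take <- pmin(pmax(take, 1L), lengths(idx) - 1L)
    test <- sort(unlist(mapply(function(i, t) sample(i, t), idx, take,
                               SIMPLIFY = FALSE), use.names = FALSE))
  }
  structure(list(mode = "CV", train = setdiff(seq_len(n), test),
                 test = test, held_out_pens = NULL, seed = seed),
            class = "split_plan")
}

#' Pen-held-out train/test split (LOOP regime)
#'
#' Samples whole pens into the test side, stratified by (herd, status); all
#' windows of a held-out pen go to test, so no pen contributes windows to
#' both sides. A stratum with a single pen stays in training with a warning.
#'
#' @param windows A `tb_windows` object.
#' @param pens Pen metadata (for herd/status stratification).
#' @param pen_test_fraction Fraction of pens held out per stratum.
#' @param seed Integer seed.
#' @return A `split_plan` with `held_out_pens` recorded.
#' @export
split_loop <- function(windows, pens, pen_test_fraction = 0.25, seed = 1L) {
  used <- unique(windows$info$pen_id)
  if (length(used) < 2L) stop("split_loop: need at least 2 pens")
  set.seed(as.integer(seed))
  meta <- pens[match(used, pens$pen_id), ]
  strata <- split(used, paste(meta$herd_id, meta$status))
  held <- character(0)
  for (s in strata) {
    if (length(s) == 1L) {
      warning("split_loop: stratum with a single pen ('", s,
              "') kept in training")
      next
    }
    k <- min(max(1L, round(pen_test_fraction * length(s))), length(s) - 1L)
    held <- c(held, sample(s, k))
  }
  if (length(held) == 0L) stop("split_loop: no pen could be held out")
  test <- which(windows$info$pen_id %in% held)
  structure(list(mode = "LOOP",
                 train = setdiff(seq_len(nrow(windows$features)), test),
                 test = test, held_out_pens = sort(held), seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("split_plan (", x$mode, "): ", length(x$train), " train / ",
      length(x$test), " test windows", sep = "")
  if (!is.null(x$held_out_pens))
    cat("; held-out pens: ", paste(x$held_out_pens, collapse = ", "),
        sep = "")
  cat("\n")
  invisible(x)
}

landis_koch_band <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Confusion-matrix performance report
#'
#' Tallies the confusion matrix with TB as the positive class and computes
#' TPR, TNR, PPV, ACC (with exact Clopper-Pearson 95% CI), Cohen's kappa
#' (`(po - pe) / (1 - pe)` with the marginal chance agreement `pe`), the
#' Landis-Koch agreement band, the no-information rate, and a one-sided
#' exact binomial p-value for accuracy exceeding the NIR. Ratios with zero
#' denominators are reported as `NA`, never as 0.
#'
#' @param predicted,truth Vectors of `"TB"`/`"CTL"` labels of equal length.
#' @return An object of class `confusion_report`.
#' @examples
#' confusion_report(rep(c("TB", "CTL"), c(85, 115)),
#'                  rep(c("TB", "CTL", "TB", "CTL"), c(80, 5, 20, 95)))
#' @export
confusion_report <- function(predicted, truth) {
  predicted <- as_tb_factor(predicted)
  truth <- as_tb_factor(truth)
  if (length(predicted) != length(truth) || length(truth) == 0L)
    stop("confusion_report: predicted/truth must have equal length >= 1")
  tp <- sum(predicted == "TB" & truth == "TB")
  fp <- sum(predicted == "TB" & truth == "CTL")
  fn <- sum(predicted == "CTL" & truth == "TB")
  tn <- sum(predicted == "CTL" & truth == "CTL")
  n <- tp + fp + fn + tn
  rate <- function(num, den) if (den > 0L) num / den else NA_real_
  acc <- (tp + tn) / n
  po <- acc
  pe <- ((tp + fn) * (tp + fp) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  nir <- max(sum(truth == "CTL"), sum(truth == "TB")) / n
  ci <- binom.test(tp + tn, n)$conf.int
  p_value <- binom.test(tp + tn, n, p = nir,
                        alternative = "greater")$p.value
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
                 tpr = rate(tp, tp + fn), tnr = rate(tn, tn + fp),
                 ppv = rate(tp, tp + fp), acc = acc,
                 acc_ci = as.numeric(ci), kappa = kappa,
                 kappa_band = landis_koch_band(kappa), nir = nir,
                 p_value = p_value),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("Confusion report (TB positive), n =", x$n, "\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  ACC %.3f (95%% CI %.3f-%.3f)  TPR %s  TNR %s  PPV %s\n",
              x$acc, x$acc_ci[1], x$acc_ci[2],
              ifelse(is.na(x$tpr), "NA", sprintf("%.3f", x$tpr)),
              ifelse(is.na(x$tnr), "NA", sprintf("%.3f", x$tnr)),
              ifelse(is.na(x$ppv), "NA", sprintf("%.3f", x$ppv))))
  cat(sprintf("  kappa %s (%s)  NIR %.3f  p(acc > NIR) %.4g\n",
              ifelse(is.na(x$kappa), "NA", sprintf("%.3f", x$kappa)),
              x$kappa_band, x$nir, x$p_value))
  invisible(x)
}

#' Pairwise comparison of model resampling profiles
#'
#' Paired t-tests on fold-wise TPR differences between every pair of models
#' tuned with the same seed (hence the same folds); folds missing in either
#' profile are dropped listwise. P-values are Bonferroni-adjusted by the
#' number of pairs (21 for the full seven-model benchmark).
#'
#' @param profiles Named list of fold-wise TPR vectors (one per model), all
#'   the same length, e.g. `fit$profile` from [tb_train()].
#' @return Data frame with one row per pair: `model_a`, `model_b`,
#'   `mean_diff`, `n_folds`, `p_raw`, `p_adj`.
#' @export
compare_models <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  len <- lengths(profiles)
  if (length(unique(len)) != 1L)
    stop("compare_models: profiles have mismatched fold counts")
  if (is.null(names(profiles)))
    names(profiles) <- paste0("model_", seq_along(profiles))
  pairs <- combn(names(profiles), 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(j) {
    a <- profiles[[pairs[1L, j]]]; b <- profiles[[pairs[2L, j]]]
    ok <- !is.na(a) & !is.na(b)
    d <- a[ok] - b[ok]
    if (length(d) < 2L) {
      p <- NA_real_
    } else if (all(d == d[1L])) {
      p <- if (d[1L] == 0) 1 else NA_real_
    } else {
      p <- t.test(d)$p.value
    }
    data.frame(model_a = pairs[1L, j], model_b = pairs[2L, j],
               mean_diff = if (length(d) > 0L) mean(d) else NA_real_,
               n_folds = length(d), p_raw = p,
               p_adj = pmin(1, p * n_pairs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run a benchmark of classifiers under one split regime
#'
#' Splits the windows, fits the preprocessing (on the training side when
#' `preprocessing_fit = "train_only"`, on everything when `"global"`), tunes
#' and fits each requested classifier on the training windows, and reports a
#' [confusion_report()] on the test side - overall and per herd subset when
#' several herds are present. Pen-disjointness is asserted for LOOP plans on
#' every run.
#'
#' @param windows A `tb_windows` object.
#' @param pens Pen metadata.
#' @param methods Character vector of [tb_methods()] names.
#' @param regime `"CV"` or `"LOOP"`.
#' @param tune A [tune_config()].
#' @param test_fraction,pen_test_fraction Split fractions for the two
#'   regimes.
#' @param split_seed Seed for the split (defaults to the tuning seed).
#' @return An object of class `tb_benchmark`: list with `plan`, `fits`,
#'   `reports` (per model x herd-subset), `profiles`, and `metrics` (tidy
#'   data frame: `model`, `regime`, `herd_subset`, `acc`, `acc_lo`,
#'   `acc_hi`, `tpr`, `tnr`, `ppv`, `kappa`, `nir`, `p_value`).
#' @export
run_benchmark <- function(windows, pens, methods = tb_methods(),
                          regime = c("CV", "LOOP"), tune = tune_config(),
                          test_fraction = 0.25, pen_test_fraction = 0.25,
                          split_seed = NULL) {
  regime <- match.arg(regime)
  methods <- match.arg(methods, tb_methods(), several.ok = TRUE)
  if (is.null(split_seed)) split_seed <- tune$seed
  plan <- if (regime == "CV")
    split_cv(windows, test_fraction, seed = split_seed)
  else
    split_loop(windows, pens, pen_test_fraction, seed = split_seed)
  if (regime == "LOOP") {
    overlap <- intersect(windows$info$pen_id[plan$train],
                         windows$info$pen_id[plan$test])
    stopifnot("LOOP plan leaks pens across sides" = length(overlap) == 0L)
  }
  fit_rows <- if (windows$config$preprocessing_fit == "train_only")
    plan$train else seq_len(nrow(windows$features))
  prep <- preprocess_windows(windows, fit_on = fit_rows)
  x <- prep$x
  y <- windows$info$label

  fits <- list(); reports <- list(); metrics <- list()
  predictions <- list()
  herds <- unique(windows$info$herd_id)
  subsets <- if (length(herds) > 1L) c("all", herds) else "all"
  for (m in methods) {
    fit <- tb_train(x[plan$train, , drop = FALSE], y[plan$train], m, tune)
    fits[[m]] <- fit
    pred <- predict(fit, x[plan$test, , drop = FALSE])
    predictions[[m]] <- pred
    for (s in subsets) {
      rows <- if (s == "all") seq_along(plan$test) else
        which(windows$info$herd_id[plan$test] == s)
      if (length(rows) == 0L) next
      rep_ms <- confusion_report(pred[rows], y[plan$test][rows])
      reports[[paste(m, s, sep = "/")]] <- rep_ms
      metrics[[paste(m, s, sep = "/")]] <- data.frame(
        model = m, regime = regime, herd_subset = s,
        acc = rep_ms$acc, acc_lo = rep_ms$acc_ci[1L],
        acc_hi = rep_ms$acc_ci[2L], tpr = rep_ms$tpr, tnr = rep_ms$tnr,
        ppv = rep_ms$ppv, kappa = rep_ms$kappa, nir = rep_ms$nir,
        p_value = rep_ms$p_value, stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  structure(list(plan = plan, prep = prep$prep, fits = fits,
                 reports = reports, metrics = metrics,
                 predictions = predictions,
                 profiles = lapply(fits, `[[`, "profile"),
                 regime = regime),
            class = "tb_benchmark")
}

#' @export
print.tb_benchmark <- function(x, ...) {
  cat("tb_benchmark (", x$regime, " regime): ", length(x$fits),
      " model(s), ", length(x$plan$train), "/", length(x$plan$test),
      " train/test windows\n", sep = "")
  print(x$metrics, digits = 3)
  invisible(x)
}
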