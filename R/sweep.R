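# Sensitivity of the predictions to the analysis-window length and to the
# labeling horizon (TB window). The full pipeline - window building,
# preprocessing, tuning, evaluation - is re-run per grid cell with identical
# seeds, so cells differ only in the window configuration.

#' Window-size sensitivity sweep
#'
#' Re-runs the whole analysis for every combination of analysis-window
#' length and TB-window interval, for one classifier, under one or both
#' split regimes and over a set of seeds. The default grid crosses window
#' lengths 7/14/21 days with TB windows [-35,+10], [-49,+10] and [-10,+5].
#' Cells whose labeling yields a single class (e.g. a TB window that no
#' recording span can realize) are skipped with a warning.
#'
#' @param visits,pens,roster Raw feeder data as from [simulate_herd()] or
#'   [ingest_feeder_csv()].
#' @param base_cfg Base [window_config()]; each cell overrides its
#'   `window_days` and `tb_window`.
#' @param window_days Integer vector of analysis-window lengths to try.
#' @param tb_windows List of `c(lower, upper)` TB-window intervals to try.
#' @param method Classifier name (default `"rf"`, the usual choice for this
#'   analysis).
#' @param tune A [tune_config()].
#' @param regimes Subset of `c("CV", "LOOP")`.
#' @param seeds Integer vector; the sweep is repeated per seed (split and
#'   tuning both keyed on it).
#' @return Data frame with one row per (cell, regime, seed): the grid
#'   coordinates, all [confusion_report()] metrics, and
#'   `ctl_pen_tb_predictions`, the number of TB predictions the model made
#'   on test windows of CTL pens.
#' @export
sensitivity_sweep <- function(visits, pens, roster,
                              base_cfg = window_config(),
                              window_days = c(7L, 14L, 21L),
                              tb_windows = list(c(-35L, 10L), c(-49L, 10L),
                                                c(-10L, 5L)),
                              method = "rf", tune = tune_config(),
                              regimes = c("CV", "LOOP"), seeds = 1L) {
  regimes <- match.arg(regimes, several.ok = TRUE)
  obs <- daily_observations(visits, pens, roster)
  rows <- list()
  for (w in window_days) for (tw in tb_windows) {
    cfg <- base_cfg
    cfg$window_days <- as.integer(w)
    cfg$tb_window <- as.integer(tw)
    windows <- build_windows(obs, pens, cfg)
    if (length(unique(windows$info$label)) < 2L) {
      warning("sensitivity_sweep: cell window_days = ", w, ", tb_window = [",
              tw[1L], ", ", tw[2L], "] yields a single class; skipped")
      next
    }
    for (seed in seeds) for (rg in regimes) {
      tune_s <- tune; tune_s$seed <- as.integer(seed)
      bm <- run_benchmark(windows, pens, methods = method, regime = rg,
                          tune = tune_s, split_seed = seed)
      met <- bm$metrics[bm$metrics$herd_subset == "all", , drop = FALSE]
      pred <- bm$predictions[[method]]
      test_pens <- windows$info$pen_id[bm$plan$test]
      ctl_pens <- pens$pen_id[pens$status == "CTL"]
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(window_days = w, tb_lower = tw[1L], tb_upper = tw[2L],
                   seed = seed),
        met,
        data.frame(ctl_pen_tb_predictions =
                     sum(pred == "TB" & test_pens %in% ctl_pens)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
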