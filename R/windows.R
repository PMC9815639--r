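# Sliding, fixed-size, labeled analysis windows.
#
# An analysis window is a flattened block of |variables| x pigs x days daily
# observations from one pen, anchored at its first day (the A_date). The
# window slides along each pen's recording span in daily steps. Windows from
# CTL pens are always labeled CTL; windows from TB pens are labeled TB when
# the A_date lies inside the TB window (an inclusive interval of days around
# the outbreak date, default [-35, +10]) and CTL otherwise. At the defaults
# (3 variables x 10 pigs x 14 days) every window flattens to 420 cells.

#' Window-building configuration
#'
#' @param window_days Length of the analysis window in days.
#' @param tb_window Inclusive signed-day interval around day 0 during which a
#'   TB pen's windows are labeled TB, as `c(lower, upper)`.
#' @param pigs_per_window Number of pig slots per window; pens with fewer
#'   pigs get placeholder slots whose cells are missing (later imputed).
#' @param variables Ordered observation variables used as features.
#' @param stride_days Step of the sliding window in days.
#' @param pca_variance_retained Fraction of variance the PCA reduction keeps.
#' @param preprocessing_fit `"train_only"` fits imputation/scaling/PCA on the
#'   training windows and applies them to the test side (no leakage);
#'   `"global"` fits them on all windows before splitting.
#' @return An object of class `window_config`.
#' @export
window_config <- function(window_days = 14L, tb_window = c(-35L, 10L),
                          pigs_per_window = 10L,
                          variables = c("dfv", "dfc", "stdfc"),
                          stride_days = 1L, pca_variance_retained = 0.95,
                          preprocessing_fit = c("train_only", "global")) {
  cfg <- list(window_days = as.integer(window_days),
              tb_window = as.integer(tb_window),
              pigs_per_window = as.integer(pigs_per_window),
              variables = variables, stride_days = as.integer(stride_days),
              pca_variance_retained = pca_variance_retained,
              preprocessing_fit = match.arg(preprocessing_fit))
  if (cfg$window_days < 1L) stop("window_config: window_days must be >= 1")
  if (length(cfg$tb_window) != 2L || cfg$tb_window[1L] > cfg$tb_window[2L])
    stop("window_config: tb_window must be c(lower, upper) with lower <= upper")
  if (cfg$pigs_per_window < 1L)
    stop("window_config: pigs_per_window must be >= 1")
  if (cfg$stride_days < 1L) stop("window_config: stride_days must be >= 1")
  if (cfg$pca_variance_retained <= 0 || cfg$pca_variance_retained > 1)
    stop("window_config: pca_variance_retained must be in (0, 1]")
  class(cfg) <- "window_config"
  cfg
}

#' Select the pig slots for a pen
#'
#' Deterministically picks the `k` pigs with the most observation days
#' (ties broken by lexicographic pig id); pens with fewer than `k` pigs are
#' padded with placeholder slots (`NA`) whose feature cells stay missing
#' until imputation.
#'
#' @param pen_obs Observation table (from [daily_observations()]) restricted
#'   to one pen.
#' @param k Number of pig slots.
#' @return Character vector of length `k`; `NA` entries are placeholders.
#' @export
select_pigs <- function(pen_obs, k) {
  if (k < 1L) stop("select_pigs: k must be >= 1")
  if (nrow(pen_obs) == 0L) stop("select_pigs: pen has no pigs")
  days <- table(pen_obs$pig_id)
  ord <- order(-as.integer(days), names(days))
  chosen <- names(days)[ord]
  if (length(chosen) >= k) chosen[seq_len(k)] else
    c(chosen, rep(NA_character_, k - length(chosen)))
}

#' Label one analysis window
#'
#' Windows of CTL pens are always `"CTL"`. Windows of TB pens are `"TB"`
#' exactly when `tb_date + tb_window[1] <= a_date <= tb_date + tb_window[2]`
#' (inclusive bounds), `"CTL"` otherwise.
#'
#' @param pen One row of the pen metadata (list or single-row data frame).
#' @param a_date First day of the analysis window (`Date`).
#' @param cfg A [window_config()].
#' @return `"TB"` or `"CTL"`.
#' @export
assign_label <- function(pen, a_date, cfg = window_config()) {
  if (pen$status == "CTL") return("CTL")
  if (is.na(pen$tb_date))
    stop("assign_label: TB pen '", pen$pen_id, "' has no tb_date")
  rel <- as.integer(a_date - pen$tb_date)
  if (rel >= cfg$tb_window[1L] && rel <= cfg$tb_window[2L]) "TB" else "CTL"
}

#' Build labeled sliding analysis windows
#'
#' For each pen, one window per A_date from `rec_start` to
#' `rec_end - window_days + 1` in steps of `stride_days`. Features are laid
#' out variable-major, then pig slot, then day offset; cells of placeholder
#' pigs, of roster-absent pig-days, and of undefined StdFC values are `NA`.
#'
#' @param obs Observation table from [daily_observations()].
#' @param pens Pen metadata.
#' @param cfg A [window_config()].
#' @return An object of class `tb_windows`: list with `features` (numeric
#'   matrix, one row per window), `info` (data frame `pen_id`, `herd_id`,
#'   `a_date`, `label`), `config`, and `var_of` (variable index of each
#'   feature column).
#' @export
build_windows <- function(obs, pens, cfg = window_config()) {
  w <- cfg$window_days; k <- cfg$pigs_per_window
  vars <- cfg$variables
  flen <- length(vars) * k * w
  feat_list <- list(); info_list <- list()
  for (i in seq_len(nrow(pens))) {
    pen <- pens[i, ]
    pen_obs <- obs[obs$pen_id == pen$pen_id, , drop = FALSE]
    D <- as.integer(pen$rec_end - pen$rec_start) + 1L
    if (D < w) {
      warning("pen '", pen$pen_id, "' recorded ", D,
              " days, shorter than the analysis window; skipped")
      next
    }
    pigs <- select_pigs(pen_obs, k)
    days <- pen$rec_start + 0:(D - 1L)
    # observation matrix: rows = variable-major x pig slot, cols = days
    M <- matrix(NA_real_, nrow = length(vars) * k, ncol = D)
    for (p in seq_len(k)) {
      if (is.na(pigs[p])) next
      po <- pen_obs[pen_obs$pig_id == pigs[p], , drop = FALSE]
      ci <- match(po$date, days)
      for (v in seq_along(vars))
        M[(v - 1L) * k + p, ci] <- po[[vars[v]]]
    }
    starts <- seq.int(1L, D - w + 1L, by = cfg$stride_days)
    feats <- matrix(NA_real_, nrow = length(starts), ncol = flen)
    labels <- character(length(starts))
    for (j in seq_along(starts)) {
      s <- starts[j]
      feats[j, ] <- as.vector(t(M[, s:(s + w - 1L), drop = FALSE]))
      labels[j] <- assign_label(pen, days[s], cfg)
    }
    feat_list[[length(feat_list) + 1L]] <- feats
    info_list[[length(info_list) + 1L]] <- data.frame(
      pen_id = pen$pen_id, herd_id = pen$herd_id, a_date = days[starts],
      label = labels, stringsAsFactors = FALSE)
  }
  features <- if (length(feat_list) > 0L) do.call(rbind, feat_list) else
    matrix(numeric(0), nrow = 0L, ncol = flen)
  colnames(features) <- sprintf("f_%04d", seq_len(flen))
  info <- if (length(info_list) > 0L) do.call(rbind, info_list) else
    data.frame(pen_id = character(0), herd_id = character(0),
               a_date = as.Date(character(0)), label = character(0))
  rownames(info) <- NULL
  structure(list(features = features, info = info, config = cfg,
                 var_of = rep(seq_along(vars), each = k * w)),
            class = "tb_windows")
}

#' @export
print.tb_windows <- function(x, ...) {
  n <- nrow(x$features)
  cat("Analysis windows: ", n, " windows x ", ncol(x$features),
      " features (", paste(x$config$variables, collapse = ", "), " x ",
      x$config$pigs_per_window, " pigs x ", x$config$window_days,
      " days)\n", sep = "")
  if (n > 0L) {
    tab <- table(x$info$label)
    cat("  labels: ", paste(names(tab), tab, sep = " = ", collapse = ", "),
        "; pens: ", length(unique(x$info$pen_id)),
        "; missing cells: ", sum(is.na(x$features)), "\n", sep = "")
  }
  invisible(x)
}
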