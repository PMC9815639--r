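# Shared fixtures, built in code at load time.

# Scaled-down single-herd study: Swedish-like CTL moments, 8 pens (4 TB),
# 8-10 pigs per pen, 55 days recorded either side of the pen midpoint.
demo_profile <- function(...) {
  swedish_herd(n_pens = 8L, tb_pen_count = 4L, pigs_min = 8L, pigs_max = 10L,
               recording_halfspan_days = 55L, ...)
}

# Demo window configuration: default 14-day windows and [-35, +10] labeling,
# but a lighter PCA (60% retained variance) suited to the small design.
demo_cfg <- function(...) window_config(pca_variance_retained = 0.6, ...)

null_drift <- function() {
  drift_model(dfv_multiplier_at_day0 = 1, dfc_multiplier_at_day0 = 1,
              stdfc_multiplier_at_day0 = 1)
}

# One drifted demo simulation shared across test files.
fix_sim <- simulate_herds(list(demo_profile()), drift = drift_model(),
                          seed = 42)
fix_obs <- daily_observations(fix_sim$visits, fix_sim$pens, fix_sim$roster)
fix_windows <- build_windows(fix_obs, fix_sim$pens, demo_cfg())

# Hand-constructable window sets for preprocessing tests: `features` is a
# windows x cells matrix; each variable occupies an equal contiguous block.
make_windows <- function(features, herds, labels, n_vars = 1L,
                         cfg = window_config()) {
  features <- as.matrix(features)
  colnames(features) <- sprintf("f_%04d", seq_len(ncol(features)))
  cfg$variables <- paste0("v", seq_len(n_vars))
  structure(list(
    features = features,
    info = data.frame(pen_id = paste0("pen", seq_len(nrow(features))),
                      herd_id = herds,
                      a_date = as.Date("2020-01-01") + seq_len(nrow(features)),
                      label = labels, stringsAsFactors = FALSE),
    config = cfg,
    var_of = rep(seq_len(n_vars), each = ncol(features) / n_vars)),
    class = "tb_windows")
}

# Brute-force confusion-metric oracle: direct enumeration over label pairs.
metrics_oracle <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(truth)) {
    p <- as.character(pred[i]); t <- as.character(truth[i])
    if (p == "TB" && t == "TB") tp <- tp + 1L
    if (p == "TB" && t == "CTL") fp <- fp + 1L
    if (p == "CTL" && t == "TB") fn <- fn + 1L
    if (p == "CTL" && t == "CTL") tn <- tn + 1L
  }
  n <- length(truth)
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (fn + tn) * (fp + tn)) / n^2
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       tnr = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       acc = po, kappa = if (pe < 1) (po - pe) / (1 - pe) else NA_real_)
}

# Independent loop-based TPR oracle (kept deliberately naive).
fold_tpr_oracle <- function(pred, truth) {
  tp <- 0L; fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == "TB") {
      if (as.character(pred[i]) == "TB") tp <- tp + 1L else fn <- fn + 1L
    }
  }
  if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
}

# Tiny hand-written visit log: one pen, two pigs, three days.
tiny_visits <- function() {
  d0 <- as.Date("2020-03-01")
  visits <- data.frame(
    pen_id = "p1",
    pig_id = c("a", "a", "a", "b"),
    date = c(d0, d0, d0, d0 + 1),
    entry_time = c(3600, 7200, 10800, 100),
    exit_time = c(4000, 7600, 11200, 500),
    feed_g = c(300, 250, 350, 500), stringsAsFactors = FALSE)
  pens <- data.frame(pen_id = "p1", herd_id = "h1", status = "CTL",
                     tb_date = as.Date(NA), rec_start = d0,
                     rec_end = d0 + 2, stringsAsFactors = FALSE)
  roster <- data.frame(pen_id = "p1", pig_id = c("a", "b"),
                       first_day = d0, last_day = d0 + 2,
                       stringsAsFactors = FALSE)
  list(visits = visits, pens = pens, roster = roster)
}
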