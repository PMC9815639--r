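# Synthetic electronic-feeder event logs for multi-pen, multi-herd studies.
#
# The generator emulates two herds of grower-finisher pigs on single-space
# electronic feeders: every feeder entry/exit with the grams consumed is one
# event. Pens are either control (CTL) or tail-biting (TB); TB pens carry an
# outbreak date (day 0) and, optionally, a pre-outbreak behavioural drift that
# scales visit frequency, intake and intake variability multiplicatively.

#' Herd simulation profile
#'
#' Describes one herd: pen count, group sizes, recording span and the target
#' marginal moments of the three daily feeding-behaviour variables (DFV:
#' daily feeder visits per pig; DFC: daily feed consumption in grams; StdFC:
#' within-day SD of per-visit intake in grams). Between-pen and between-pig
#' heterogeneity are log-normal multipliers on the pig-day expectations;
#' the residual day-level dispersion is derived so that the marginal SDs
#' approximate the configured targets.
#'
#' @param herd_id Character label for the herd.
#' @param n_pens Number of pens.
#' @param pigs_min,pigs_max Inclusive range of pigs per pen (within 1..60).
#' @param recording_halfspan_days Days recorded each side of the pen midpoint;
#'   total span is `2 * recording_halfspan_days + 1` days.
#' @param dfc_mean,dfc_sd Target mean/SD of daily feed consumption (g/day).
#' @param dfv_mean,dfv_sd Target mean/SD of daily feeder visits (visits/day).
#' @param stdfc_mean,stdfc_sd Target mean/SD of the within-day SD of
#'   per-visit intake (g).
#' @param tb_pen_count Number of pens assigned TB status.
#' @param pen_effect_sd,pig_effect_sd Log-scale SDs of the pen-level and
#'   pig-level log-normal baseline multipliers (dimensionless).
#' @param start_date First recorded calendar day (`Date` or ISO string).
#' @return An object of class `herd_profile`.
#' @seealso [swedish_herd()], [swiss_herd()] for presets; [simulate_herd()].
#' @export
herd_profile <- function(herd_id, n_pens, pigs_min, pigs_max,
                         recording_halfspan_days,
                         dfc_mean, dfc_sd, dfv_mean, dfv_sd,
                         stdfc_mean, stdfc_sd, tb_pen_count,
                         pen_effect_sd = 0.15, pig_effect_sd = 0.25,
                         start_date = as.Date("2020-01-01")) {
  p <- list(herd_id = as.character(herd_id), n_pens = as.integer(n_pens),
            pigs_min = as.integer(pigs_min), pigs_max = as.integer(pigs_max),
            recording_halfspan_days = as.integer(recording_halfspan_days),
            dfc_mean = dfc_mean, dfc_sd = dfc_sd,
            dfv_mean = dfv_mean, dfv_sd = dfv_sd,
            stdfc_mean = stdfc_mean, stdfc_sd = stdfc_sd,
            tb_pen_count = as.integer(tb_pen_count),
            pen_effect_sd = pen_effect_sd, pig_effect_sd = pig_effect_sd,
            start_date = as.Date(start_date))
  class(p) <- "herd_profile"
  validate_herd_profile(p)
  p
}

validate_herd_profile <- function(p) {
  moments <- c("dfc_mean", "dfc_sd", "dfv_mean", "dfv_sd",
               "stdfc_mean", "stdfc_sd")
  for (f in moments)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0)
      stop("herd_profile: '", f, "' must be a single positive number")
  if (p$n_pens < 0L) stop("herd_profile: n_pens must be >= 0")
  if (p$tb_pen_count < 0L || p$tb_pen_count > p$n_pens)
    stop("herd_profile: tb_pen_count must be in [0, n_pens]")
  if (p$pigs_min < 1L || p$pigs_max > 60L || p$pigs_min > p$pigs_max)
    stop("herd_profile: pigs per pen range must lie within [1, 60]")
  if (p$recording_halfspan_days < 1L)
    stop("herd_profile: recording_halfspan_days must be >= 1")
  if (p$pen_effect_sd < 0 || p$pig_effect_sd < 0)
    stop("herd_profile: effect SDs must be >= 0")
  invisible(p)
}

#' @export
print.herd_profile <- function(x, ...) {
  cat("Herd profile '", x$herd_id, "': ", x$n_pens, " pens (",
      x$tb_pen_count, " TB), ", x$pigs_min, "-", x$pigs_max,
      " pigs/pen, +/-", x$recording_halfspan_days, " d\n", sep = "")
  cat(sprintf("  DFV %.1f (SD %.1f) visits/d, DFC %.0f (SD %.0f) g/d, StdFC %.0f (SD %.0f) g\n",
              x$dfv_mean, x$dfv_sd, x$dfc_mean, x$dfc_sd,
              x$stdfc_mean, x$stdfc_sd))
  invisible(x)
}

#' Preset herd profiles
#'
#' Two ready-made profiles emulating the study conditions of a Swedish
#' boar-testing station (42 pens, 7-14 boars/pen, recorded 70 days either side
#' of the outbreak date) and a Swiss experimental farm (23 pens, 11-55
#' pigs/pen, 100 days either side). Feeding-behaviour moments are calibrated
#' to the control-class summary statistics of the respective data sets
#' (Swedish CTL: DFC 2337.1 +/- 757.4 g, DFV 24.9 +/- 19.4 visits,
#' StdFC 128.6 +/- 85.9 g; Swiss CTL: DFC 2282.3 +/- 600.2 g,
#' DFV 12.3 +/- 6.0 visits, StdFC 166.8 +/- 96.3 g).
#'
#' @param ... Overrides passed on to [herd_profile()].
#' @return A `herd_profile`.
#' @export
swedish_herd <- function(...) {
  args <- list(herd_id = "swedish", n_pens = 42L, pigs_min = 7L,
               pigs_max = 14L, recording_halfspan_days = 70L,
               dfc_mean = 2337.1, dfc_sd = 757.4,
               dfv_mean = 24.9, dfv_sd = 19.4,
               stdfc_mean = 128.6, stdfc_sd = 85.9,
               tb_pen_count = 21L)
  args[names(list(...))] <- list(...)
  do.call(herd_profile, args)
}

#' @rdname swedish_herd
#' @export
swiss_herd <- function(...) {
  args <- list(herd_id = "swiss", n_pens = 23L, pigs_min = 11L,
               pigs_max = 55L, recording_halfspan_days = 100L,
               dfc_mean = 2282.3, dfc_sd = 600.2,
               dfv_mean = 12.3, dfv_sd = 6.0,
               stdfc_mean = 166.8, stdfc_sd = 96.3,
               tb_pen_count = 6L)
  args[names(list(...))] <- list(...)
  do.call(herd_profile, args)
}

#' Pre-outbreak behavioural drift model
#'
#' Multiplicative drift applied to TB pens' pig-day expectations. Between
#' `onset_day` and day 0 each variable's multiplier moves from 1 to its
#' day-0 value (`linear_ramp`: monotone linear; `step`: jumps at onset).
#' After day 0 the multipliers return linearly to 1 over
#' `post_day0_recovery_days` days. The default onset (-42 d) and the declining
#' visit frequency echo reports of reduced feeder visits several weeks before
#' an outbreak; the magnitudes themselves are synthetic choices, not measured
#' effect sizes.
#'
#' @param onset_day Signed day (relative to day 0) at which drift starts;
#'   must be negative.
#' @param dfv_multiplier_at_day0,dfc_multiplier_at_day0,stdfc_multiplier_at_day0
#'   Multipliers reached at day 0 (1 = no change).
#' @param shape `"linear_ramp"` or `"step"`.
#' @param post_day0_recovery_days Days after day 0 over which multipliers
#'   relax back to 1.
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(onset_day = -42L,
                        dfv_multiplier_at_day0 = 0.7,
                        dfc_multiplier_at_day0 = 0.85,
                        stdfc_multiplier_at_day0 = 0.85,
                        shape = c("linear_ramp", "step"),
                        post_day0_recovery_days = 28L) {
  shape <- match.arg(shape)
  d <- list(onset_day = as.integer(onset_day),
            multipliers = c(dfv = dfv_multiplier_at_day0,
                            dfc = dfc_multiplier_at_day0,
                            stdfc = stdfc_multiplier_at_day0),
            shape = shape,
            post_day0_recovery_days = as.integer(post_day0_recovery_days))
  if (d$onset_day >= 0L) stop("drift_model: onset_day must be negative")
  if (any(d$multipliers <= 0)) stop("drift_model: multipliers must be > 0")
  if (d$post_day0_recovery_days < 0L)
    stop("drift_model: post_day0_recovery_days must be >= 0")
  class(d) <- "drift_model"
  d
}

#' Drift multiplier at a relative day
#'
#' @param drift A [drift_model()].
#' @param day Integer vector of days relative to day 0 (the TB date).
#' @param var One of `"dfv"`, `"dfc"`, `"stdfc"`.
#' @return Numeric vector of multipliers (1 = baseline).
#' @export
drift_multiplier <- function(drift, day, var = c("dfv", "dfc", "stdfc")) {
  var <- match.arg(var)
  m0 <- drift$multipliers[[var]]
  out <- rep(1, length(day))
  ramp <- day >= drift$onset_day & day <= 0L
  if (drift$shape == "linear_ramp") {
    out[ramp] <- 1 + (m0 - 1) * (day[ramp] - drift$onset_day) /
      (0 - drift$onset_day)
  } else {
    out[ramp] <- m0
  }
  post <- day > 0L
  if (any(post)) {
    r <- drift$post_day0_recovery_days
    frac <- if (r > 0L) pmin(day[post] / r, 1) else 1
    out[post] <- m0 + (1 - m0) * frac
  }
  out
}

# Residual (within pig-day) dispersion implied by the profile's marginal
# targets after removing pen/pig log-normal heterogeneity.
herd_noise <- function(profile) {
  between_cv2 <- expm1(profile$pen_effect_sd^2 + profile$pig_effect_sd^2)
  cv2 <- function(m, s) (s / m)^2
  resid_v <- max(cv2(profile$dfv_mean, profile$dfv_sd) - between_cv2, 0.05)
  # negative binomial: CV^2 = 1/mu + 1/size at the herd-mean visit rate
  inv_size <- max(resid_v - 1 / profile$dfv_mean, 0.02)
  resid_c <- max(cv2(profile$dfc_mean, profile$dfc_sd) - between_cv2, 0.01)
  list(nb_size = 1 / inv_size, dfc_day_sdlog = sqrt(log1p(resid_c)))
}

# Vectorized pig-day draw shared by simulate_herd() and sample_pig_day().
# mu_v: expected visit counts; total_c: expected daily totals (g);
# sd_f: target per-visit SD (g). The daily total is set first (compensating
# for zero-visit days so the marginal mean equals total_c) and then
# partitioned over the visits with gamma-distributed relative sizes whose
# dispersion targets sd_f - daily intake is regulated at the day level, so
# per-visit amounts within a day are effectively anticorrelated, as with a
# pig eating to satiation. Returns visit counts and a flat grams vector
# (one entry per visit, grouped by pig-day).
draw_pig_days <- function(mu_v, total_c, sd_f, nb_size) {
  n <- length(mu_v)
  counts <- rnbinom(n, mu = mu_v, size = nb_size)
  nv <- sum(counts)
  if (nv == 0L) return(list(counts = counts, grams = numeric(0)))
  p0 <- pmin((nb_size / (nb_size + mu_v))^nb_size, 0.9)
  day_total <- total_c / (1 - p0)
  fed <- counts > 0L
  vmean <- rep.int(day_total / pmax(counts, 1L), counts)
  vsd <- rep.int(sd_f, counts)
  shape <- pmax((vmean / vsd)^2, 1e-3)
  grams <- rgamma(nv, shape = shape, rate = shape / vmean)
  day_of <- factor(rep.int(seq_len(n), counts), levels = which(fed))
  day_sum <- rowsum(grams, day_of, reorder = FALSE)[, 1L]
  grams <- grams * rep.int(day_total[fed] / pmax(day_sum, 1e-9), counts[fed])
  grams <- round(grams, 1)  # feeders report to 0.1 g
  list(counts = counts, grams = grams)
}

#' Draw one pig-day of feeder visits
#'
#' Samples a visit count from an over-dispersed (gamma-mixed Poisson, i.e.
#' negative binomial) distribution and per-visit intakes from a right-skewed
#' gamma distribution, so that the expected daily total and the per-visit SD
#' hit the profile's targets scaled by the supplied multipliers. Uses the
#' current RNG state; seed upstream for reproducibility.
#'
#' @param pig_baseline Named list/vector of per-pig multipliers
#'   (`dfv`, `dfc`, `stdfc`).
#' @param day_multipliers Named list/vector of drift factors for the same
#'   three variables.
#' @param profile A [herd_profile()].
#' @return List with `dfv` (visit count) and `grams` (per-visit intakes;
#'   empty when `dfv` is 0).
#' @export
sample_pig_day <- function(pig_baseline, day_multipliers, profile) {
  b <- unlist(pig_baseline)[c("dfv", "dfc", "stdfc")]
  m <- unlist(day_multipliers)[c("dfv", "dfc", "stdfc")]
  if (any(!is.finite(b)) || any(!is.finite(m)) || any(b < 0) || any(m < 0))
    stop("sample_pig_day: multipliers must be non-negative numbers")
  noise <- herd_noise(profile)
  day_f <- rlnorm(1, -noise$dfc_day_sdlog^2 / 2, noise$dfc_day_sdlog)
  d <- draw_pig_days(mu_v = profile$dfv_mean * b[["dfv"]] * m[["dfv"]],
                     total_c = profile$dfc_mean * b[["dfc"]] * m[["dfc"]] * day_f,
                     sd_f = profile$stdfc_mean * b[["stdfc"]] * m[["stdfc"]],
                     nb_size = noise$nb_size)
  list(dfv = d$counts[1L], grams = d$grams)
}

empty_visits <- function() {
  data.frame(pen_id = character(0), pig_id = character(0),
              date = as.Date(character(0)), entry_time = numeric(0),
              exit_time = numeric(0), feed_g = numeric(0),
              stringsAsFactors = FALSE)
}

empty_pens <- function() {
  data.frame(pen_id = character(0), herd_id = character(0),
              status = character(0), tb_date = as.Date(character(0)),
              rec_start = as.Date(character(0)),
              rec_end = as.Date(character(0)), stringsAsFactors = FALSE)
}

empty_roster <- function() {
  data.frame(pen_id = character(0), pig_id = character(0),
              first_day = as.Date(character(0)),
              last_day = as.Date(character(0)), stringsAsFactors = FALSE)
}

#' Simulate one herd of feeder event logs
#'
#' Generates per-visit feeder records for every pig in every pen of a herd.
#' `tb_pen_count` pens are assigned TB status with an outbreak date (day 0)
#' placed uniformly at random within the middle third of the pen's recording
#' span, so that default-sized analysis windows never overrun the recording
#' edge. TB pens' pig-day expectations are scaled by the drift model between
#' its onset and day 0; CTL pens carry no drift. Between-pen and between-pig
#' log-normal baselines and day-level noise are always present. Identical
#' seeds give identical logs.
#'
#' @param profile A [herd_profile()].
#' @param drift A [drift_model()] applied to TB pens.
#' @param missing_rate Fraction of pig-days whose visits are lost to sensor
#'   gaps (roster unaffected), in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `visits` (one row per feeder visit: `pen_id`, `pig_id`,
#'   `date`, `entry_time`/`exit_time` in seconds since midnight, `feed_g`),
#'   `pens` (pen metadata incl. `status`, `tb_date`, recording span) and
#'   `roster` (pig presence intervals).
#' @examples
#' sim <- simulate_herd(swedish_herd(n_pens = 2, tb_pen_count = 1,
#'                                   recording_halfspan_days = 20), seed = 1)
#' head(sim$visits)
#' @export
simulate_herd <- function(profile, drift = drift_model(), missing_rate = 0,
                          seed = 1L) {
  validate_herd_profile(profile)
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop("simulate_herd: missing_rate must be in [0, 1)")
  if (profile$n_pens == 0L)
    return(list(visits = empty_visits(), pens = empty_pens(),
                roster = empty_roster()))
  set.seed(as.integer(seed))
  noise <- herd_noise(profile)
  span <- 2L * profile$recording_halfspan_days  # rec_end - rec_start
  n_days <- span + 1L
  tb_pens <- sample(profile$n_pens, profile$tb_pen_count)
  vars <- c("dfv", "dfc", "stdfc")

  visits_list <- vector("list", profile$n_pens)
  pens_list <- vector("list", profile$n_pens)
  roster_list <- vector("list", profile$n_pens)
  for (i in seq_len(profile$n_pens)) {
    pen_id <- sprintf("%s_p%02d", profile$herd_id, i)
    is_tb <- i %in% tb_pens
    rec_start <- profile$start_date
    rec_end <- rec_start + span
    tb_date <- if (is_tb) {
      lo <- floor(span / 3); hi <- floor(2 * span / 3)
      rec_start + sample(lo:hi, 1L)
    } else as.Date(NA)
    np <- if (profile$pigs_min == profile$pigs_max) profile$pigs_min else
      sample(profile$pigs_min:profile$pigs_max, 1L)
    pig_ids <- sprintf("%s_g%02d", pen_id, seq_len(np))

    pen_mult <- setNames(rlnorm(3, -profile$pen_effect_sd^2 / 2,
                                profile$pen_effect_sd), vars)
    pig_mult <- matrix(rlnorm(3 * np, -profile$pig_effect_sd^2 / 2,
                              profile$pig_effect_sd), nrow = np,
                       dimnames = list(NULL, vars))

    rel_day <- if (is_tb) as.integer(rec_start + 0:span - tb_date) else
      rep(NA_integer_, n_days)
    dm <- sapply(vars, function(v)
      if (is_tb) drift_multiplier(drift, rel_day, v) else rep(1, n_days))

    # pig-day grid: pig-major, day within pig
    g_idx <- rep(seq_len(np), each = n_days)
    d_idx <- rep.int(seq_len(n_days), np)
    day_f <- rlnorm(np * n_days, -noise$dfc_day_sdlog^2 / 2,
                    noise$dfc_day_sdlog)
    mu_v <- profile$dfv_mean * pen_mult["dfv"] * pig_mult[g_idx, "dfv"] *
      dm[d_idx, "dfv"]
    total_c <- profile$dfc_mean * pen_mult["dfc"] * pig_mult[g_idx, "dfc"] *
      dm[d_idx, "dfc"] * day_f
    sd_f <- profile$stdfc_mean * pen_mult["stdfc"] *
      pig_mult[g_idx, "stdfc"] * dm[d_idx, "stdfc"]
    drawn <- draw_pig_days(mu_v, total_c, sd_f, noise$nb_size)
    counts <- drawn$counts
    if (missing_rate > 0) {
      gap <- runif(length(counts)) < missing_rate
      keep_visit <- rep.int(!gap, counts)
      drawn$grams <- drawn$grams[keep_visit]
      counts[gap] <- 0L
    }
    nv <- sum(counts)
    if (nv > 0L) {
      entry <- floor(unlist(lapply(counts[counts > 0L],
                                   function(k) sort(runif(k, 0, 86340)))))
      dur <- floor(runif(nv, 60, 1200))
      visits_list[[i]] <- data.frame(
        pen_id = pen_id,
        pig_id = rep.int(pig_ids[g_idx], counts),
        date = rec_start + rep.int(d_idx - 1L, counts),
        entry_time = entry,
        exit_time = pmin(entry + dur, 86399),
        feed_g = drawn$grams,
        stringsAsFactors = FALSE)
    }
    pens_list[[i]] <- data.frame(pen_id = pen_id, herd_id = profile$herd_id,
                                 status = if (is_tb) "TB" else "CTL",
                                 tb_date = tb_date, rec_start = rec_start,
                                 rec_end = rec_end, stringsAsFactors = FALSE)
    roster_list[[i]] <- data.frame(pen_id = pen_id, pig_id = pig_ids,
                                   first_day = rec_start, last_day = rec_end,
                                   stringsAsFactors = FALSE)
  }
  list(visits = do.call(rbind, visits_list[!vapply(visits_list, is.null,
                                                   logical(1))]),
       pens = do.call(rbind, pens_list),
       roster = do.call(rbind, roster_list))
}

#' Simulate several herds into one combined data set
#'
#' @param profiles List of [herd_profile()]s.
#' @param drift A [drift_model()] shared by all herds.
#' @param missing_rate Sensor-gap rate passed to [simulate_herd()].
#' @param seed Integer seed; each herd uses a sub-seed derived from it.
#' @return Combined `visits`/`pens`/`roster` list as in [simulate_herd()].
#' @export
simulate_herds <- function(profiles, drift = drift_model(), missing_rate = 0,
                           seed = 1L) {
  sims <- lapply(seq_along(profiles), function(i)
    simulate_herd(profiles[[i]], drift, missing_rate,
                  seed = as.integer(seed) + 7919L * i))
  list(visits = do.call(rbind, lapply(sims, `[[`, "visits")),
       pens = do.call(rbind, lapply(sims, `[[`, "pens")),
       roster = do.call(rbind, lapply(sims, `[[`, "roster")))
}

#' Inject pig dropout and sensor day-gaps
#'
#' Emulates the two ways real feeder data go missing: pigs leaving a pen
#' early (the roster interval is truncated, so downstream code treats later
#' days as "absent", not "zero visits") and whole pig-days lost to sensor
#' gaps (visits removed, roster intact, so the day is a real observation with
#' zero visits).
#'
#' @param sim A `visits`/`pens`/`roster` list as returned by
#'   [simulate_herd()].
#' @param pig_dropout_rate Probability a pig's roster is truncated early.
#' @param day_gap_rate Probability any pig-day loses all its visits.
#' @param seed Integer seed.
#' @return A list with the same shape as `sim`.
#' @export
inject_missingness <- function(sim, pig_dropout_rate = 0, day_gap_rate = 0,
                               seed = 1L) {
  if (pig_dropout_rate < 0 || pig_dropout_rate >= 1 ||
      day_gap_rate < 0 || day_gap_rate >= 1)
    stop("inject_missingness: rates must be in [0, 1)")
  if (pig_dropout_rate == 0 && day_gap_rate == 0) return(sim)
  set.seed(as.integer(seed))
  visits <- sim$visits; roster <- sim$roster
  if (pig_dropout_rate > 0 && nrow(roster) > 0L) {
    drop <- runif(nrow(roster)) < pig_dropout_rate
    for (j in which(drop)) {
      lo <- roster$first_day[j]; hi <- roster$last_day[j]
      ndays <- as.integer(hi - lo)
      if (ndays < 2L) next
      new_last <- lo + sample(seq_len(ndays - 1L), 1L)
      roster$last_day[j] <- new_last
      cut <- visits$pig_id == roster$pig_id[j] & visits$date > new_last
      visits <- visits[!cut, , drop = FALSE]
    }
  }
  if (day_gap_rate > 0 && nrow(visits) > 0L) {
    key <- paste(visits$pig_id, visits$date)
    days <- unique(key)
    gap <- days[runif(length(days)) < day_gap_rate]
    visits <- visits[!(key %in% gap), , drop = FALSE]
  }
  rownames(visits) <- NULL
  list(visits = visits, pens = sim$pens, roster = roster)
}
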