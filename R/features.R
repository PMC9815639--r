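# Daily per-pig feeding-behaviour observations derived from raw visit logs:
#   DFV   number of feeder visits whose entry falls within the calendar day
#   DFC   total feed consumed over those visits (g)
#   StdFC sample SD of the per-visit intakes that day (g); undefined (NA)
#         with fewer than 2 visits, since one visit carries no dispersion
#         information.
# A visit belongs to the day of its entry time; visits spanning midnight are
# not split. Days a pig is on the roster but never visits are real
# observations (dfv = 0, dfc = 0, stdfc = NA); days outside the roster
# interval produce no row at all.

#' Per-pig per-day feeding observations
#'
#' Aggregates a raw feeder visit log into one row per pig per roster day with
#' the three observation variables DFV (visit count), DFC (grams consumed)
#' and StdFC (within-day SD of per-visit grams, `NA` when fewer than two
#' visits).
#'
#' @param visits Visit data frame (`pen_id`, `pig_id`, `date`, `feed_g`, ...)
#'   as produced by [simulate_herd()] or [read_visits_csv()].
#' @param pens Pen metadata data frame.
#' @param roster Pig roster data frame (`pen_id`, `pig_id`, `first_day`,
#'   `last_day`).
#' @return Data frame with columns `pen_id`, `pig_id`, `date`, `dfv`, `dfc`,
#'   `stdfc`; one row per pig-day on the roster.
#' @export
daily_observations <- function(visits, pens, roster) {
  if (nrow(roster) == 0L)
    return(data.frame(pen_id = character(0), pig_id = character(0),
                      date = as.Date(character(0)), dfv = integer(0),
                      dfc = numeric(0), stdfc = numeric(0)))
  known <- paste(roster$pen_id, roster$pig_id)
  if (nrow(visits) > 0L) {
    vkey <- paste(visits$pen_id, visits$pig_id)
    bad <- which(!(vkey %in% known))
    if (length(bad) > 0L)
      stop("daily_observations: visit row ", bad[1L],
           " references unknown pen/pig '", vkey[bad[1L]], "'")
  }
  # expand roster intervals into the full pig-day grid
  ndays <- as.integer(roster$last_day - roster$first_day) + 1L
  idx <- rep.int(seq_len(nrow(roster)), ndays)
  grid <- data.frame(
    pen_id = roster$pen_id[idx],
    pig_id = roster$pig_id[idx],
    date = roster$first_day[idx] +
      (sequence(ndays) - 1L),
    stringsAsFactors = FALSE)
  gkey <- paste(grid$pig_id, grid$date)

  if (nrow(visits) > 0L) {
    key <- paste(visits$pig_id, visits$date)
    f <- factor(key, levels = gkey)
    if (anyNA(f)) {
      off <- which(is.na(f))[1L]
      stop("daily_observations: visit on ", visits$date[off], " for pig '",
           visits$pig_id[off], "' falls outside its roster interval")
    }
    dfv <- as.integer(tabulate(f, nbins = length(gkey)))
    dfc <- numeric(length(gkey))
    sums <- rowsum(visits$feed_g, key)
    m <- match(gkey, rownames(sums))
    dfc[!is.na(m)] <- sums[m[!is.na(m)], 1L]
    stdfc <- rep(NA_real_, length(gkey))
    multi <- names(which(table(key) >= 2L))
    if (length(multi) > 0L) {
      sds <- vapply(split(visits$feed_g, key)[multi], sd, numeric(1))
      mm <- match(multi, gkey)
      stdfc[mm] <- sds
    }
  } else {
    dfv <- integer(length(gkey))
    dfc <- numeric(length(gkey))
    stdfc <- rep(NA_real_, length(gkey))
  }
  out <- cbind(grid, dfv = dfv, dfc = dfc, stdfc = stdfc)
  rownames(out) <- NULL
  out
}

#' Summary statistics of the daily observations
#'
#' Reproduces the layout of a data-set characteristics table: per-group mean
#' and SD of DFV, DFC and StdFC over non-missing values, with group sizes.
#' Grouping can be by herd, by pen status, and/or by observation class
#' (whether the date of a TB pen's observation falls inside the labeling
#' window around its outbreak date).
#'
#' @param obs Observation table from [daily_observations()].
#' @param pens Pen metadata.
#' @param group_by Character subset of `c("herd", "status", "class")`.
#' @param cfg A [window_config()]; only needed when grouping by `"class"`
#'   (its `tb_window` defines the class of each observation date).
#' @return Data frame with one row per group: grouping columns, `n_obs`, and
#'   `<var>_mean` / `<var>_sd` for each variable.
#' @export
observation_summary <- function(obs, pens,
                                group_by = c("herd", "class"),
                                cfg = window_config()) {
  if (nrow(obs) == 0L) stop("observation_summary: empty observation table")
  group_by <- match.arg(group_by, c("herd", "status", "class"),
                        several.ok = TRUE)
  m <- match(obs$pen_id, pens$pen_id)
  g <- list()
  if ("herd" %in% group_by) g$herd <- pens$herd_id[m]
  if ("status" %in% group_by) g$status <- pens$status[m]
  if ("class" %in% group_by) {
    tbd <- pens$tb_date[m]
    rel <- as.integer(obs$date - tbd)
    g$class <- ifelse(pens$status[m] == "TB" & !is.na(rel) &
                        rel >= cfg$tb_window[1L] & rel <= cfg$tb_window[2L],
                      "TB", "CTL")
  }
  key <- interaction(g, drop = TRUE, sep = "/")
  groups <- split(seq_len(nrow(obs)), key)
  rows <- lapply(names(groups), function(k) {
    i <- groups[[k]]
    parts <- strsplit(k, "/", fixed = TRUE)[[1L]]
    st <- as.list(setNames(parts, names(g)))
    st$n_obs <- length(i)
    for (v in c("dfv", "dfc", "stdfc")) {
      x <- obs[[v]][i]
      x <- x[!is.na(x)]
      st[[paste0(v, "_mean")]] <- if (length(x) >= 1L) mean(x) else NA_real_
      st[[paste0(v, "_sd")]] <- if (length(x) >= 2L) sd(x) else NA_real_
    }
    as.data.frame(st, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
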