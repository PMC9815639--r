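# CSV interchange. All writers/readers round-trip bit-exactly on their own
# output: dates are ISO-8601, times HH:MM:SS, and floating-point columns are
# written with 17 significant digits (enough to reproduce the double
# exactly). The same dialect is accepted from real farm exports.

secs_to_hms <- function(s) {
  s <- as.integer(round(s))
  sprintf("%02d:%02d:%02d", s %/% 3600L, (s %% 3600L) %/% 60L, s %% 60L)
}

hms_to_secs <- function(x) {
  p <- matrix(as.integer(unlist(strsplit(x, ":", fixed = TRUE))), ncol = 3L,
              byrow = TRUE)
  p[, 1L] * 3600L + p[, 2L] * 60L + p[, 3L]
}

num_chr <- function(x) sprintf("%.17g", x)

#' Read and write feeder data CSV files
#'
#' Visits are written with header
#' `pen_id,pig_id,date,entry_time,exit_time,feed_g`; pens with
#' `pen_id,herd_id,status,tb_date,rec_start,rec_end`; the roster with
#' `pen_id,pig_id,first_day,last_day`.
#'
#' @param visits,pens,roster Data frames as produced by [simulate_herd()].
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the data frame.
#' @export
write_visits_csv <- function(visits, path) {
  out <- data.frame(pen_id = visits$pen_id, pig_id = visits$pig_id,
                    date = format(visits$date, "%Y-%m-%d"),
                    entry_time = secs_to_hms(visits$entry_time),
                    exit_time = secs_to_hms(visits$exit_time),
                    feed_g = num_chr(visits$feed_g))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_visits_csv
#' @export
read_visits_csv <- function(path) {
  x <- read.csv(path, colClasses = "character")
  data.frame(pen_id = x$pen_id, pig_id = x$pig_id,
             date = as.Date(x$date),
             entry_time = if (nrow(x)) hms_to_secs(x$entry_time) else integer(0),
             exit_time = if (nrow(x)) hms_to_secs(x$exit_time) else integer(0),
             feed_g = as.numeric(x$feed_g), stringsAsFactors = FALSE)
}

#' @rdname write_visits_csv
#' @export
write_pens_csv <- function(pens, path) {
  out <- data.frame(pen_id = pens$pen_id, herd_id = pens$herd_id,
                    status = pens$status,
                    tb_date = ifelse(is.na(pens$tb_date), "",
                                     format(pens$tb_date, "%Y-%m-%d")),
                    rec_start = format(pens$rec_start, "%Y-%m-%d"),
                    rec_end = format(pens$rec_end, "%Y-%m-%d"))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_visits_csv
#' @export
read_pens_csv <- function(path) {
  x <- read.csv(path, colClasses = "character")
  data.frame(pen_id = x$pen_id, herd_id = x$herd_id, status = x$status,
             tb_date = as.Date(ifelse(x$tb_date == "", NA, x$tb_date)),
             rec_start = as.Date(x$rec_start), rec_end = as.Date(x$rec_end),
             stringsAsFactors = FALSE)
}

#' @rdname write_visits_csv
#' @export
write_roster_csv <- function(roster, path) {
  out <- data.frame(pen_id = roster$pen_id, pig_id = roster$pig_id,
                    first_day = format(roster$first_day, "%Y-%m-%d"),
                    last_day = format(roster$last_day, "%Y-%m-%d"))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_visits_csv
#' @export
read_roster_csv <- function(path) {
  x <- read.csv(path, colClasses = "character")
  data.frame(pen_id = x$pen_id, pig_id = x$pig_id,
             first_day = as.Date(x$first_day), last_day = as.Date(x$last_day),
             stringsAsFactors = FALSE)
}

#' Read and write daily observation tables
#'
#' Columns `pen_id,pig_id,date,dfv,dfc,stdfc`; a missing StdFC (fewer than
#' two visits that day) is an empty field.
#'
#' @param obs Observation table from [daily_observations()].
#' @param path File path.
#' @export
write_observations_csv <- function(obs, path) {
  out <- data.frame(pen_id = obs$pen_id, pig_id = obs$pig_id,
                    date = format(obs$date, "%Y-%m-%d"), dfv = obs$dfv,
                    dfc = num_chr(obs$dfc),
                    stdfc = ifelse(is.na(obs$stdfc), "", num_chr(obs$stdfc)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  x <- read.csv(path, colClasses = "character")
  data.frame(pen_id = x$pen_id, pig_id = x$pig_id, date = as.Date(x$date),
             dfv = as.integer(x$dfv), dfc = as.numeric(x$dfc),
             stdfc = suppressWarnings(
               as.numeric(ifelse(x$stdfc == "", NA, x$stdfc))),
             stringsAsFactors = FALSE)
}

#' Read and write analysis-window matrices
#'
#' Columns `pen_id,herd_id,a_date,label,f_0001..f_NNNN` (width adapts to the
#' configuration); cell ordering is the documented variable-major, pig-slot,
#' day-offset layout and round-trips bit-exactly.
#'
#' @param windows A `tb_windows` object.
#' @param path File path.
#' @param cfg The [window_config()] the windows were built with (stored
#'   alongside when reading back).
#' @export
write_windows_csv <- function(windows, path) {
  feats <- apply(windows$features, 2L,
                 function(col) ifelse(is.na(col), "", num_chr(col)))
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = nrow(windows$features))
  colnames(feats) <- colnames(windows$features)
  out <- cbind(data.frame(pen_id = windows$info$pen_id,
                          herd_id = windows$info$herd_id,
                          a_date = format(windows$info$a_date, "%Y-%m-%d"),
                          label = windows$info$label),
               as.data.frame(feats))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_windows_csv
#' @export
read_windows_csv <- function(path, cfg = window_config()) {
  x <- read.csv(path, colClasses = "character")
  fcols <- grep("^f_", names(x), value = TRUE)
  features <- vapply(x[fcols], function(col)
    suppressWarnings(as.numeric(ifelse(col == "", NA, col))),
    numeric(nrow(x)))
  if (is.null(dim(features)))
    features <- matrix(features, nrow = nrow(x),
                       dimnames = list(NULL, fcols))
  info <- data.frame(pen_id = x$pen_id, herd_id = x$herd_id,
                     a_date = as.Date(x$a_date), label = x$label,
                     stringsAsFactors = FALSE)
  k <- cfg$pigs_per_window; w <- cfg$window_days
  structure(list(features = features, info = info, config = cfg,
                 var_of = rep(seq_along(cfg$variables), each = k * w)),
            class = "tb_windows")
}

#' Serialize fitted preprocessing parameters
#'
#' Writes the medians, centers, scales and PCA rotation fitted by
#' [preprocess_windows()] to a JSON sidecar so that the identical transform
#' can be re-applied to new windows in a later session.
#'
#' @param prep Fitted parameters from [preprocess_windows()].
#' @param path File path.
#' @export
write_prep_json <- function(prep, path) {
  enc_mat <- function(m) list(rows = rownames(m), cols = colnames(m),
                              values = as.vector(m))
  obj <- list(medians = enc_mat(prep$medians),
              centers = enc_mat(prep$centers),
              scales = enc_mat(prep$scales),
              pca = list(center = as.vector(prep$rotation$center),
                         ncomp = prep$rotation$ncomp,
                         rotation = as.vector(prep$rotation$rotation),
                         nrow = nrow(prep$rotation$rotation)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prep_json
#' @export
read_prep_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec_mat <- function(e) matrix(e$values, nrow = length(e$rows),
                                dimnames = list(e$rows, e$cols))
  rot <- matrix(obj$pca$rotation, nrow = obj$pca$nrow)
  colnames(rot) <- sprintf("PC%d", seq_len(ncol(rot)))
  list(medians = dec_mat(obj$medians), centers = dec_mat(obj$centers),
       scales = dec_mat(obj$scales),
       rotation = list(center = obj$pca$center, rotation = rot,
                       ncomp = obj$pca$ncomp))
}

#' Ingest and validate feeder CSV exports
#'
#' Reads visit/pen/roster CSVs in the documented dialect and validates every
#' visit: known pen, known pig, date inside the pen recording span and the
#' pig's roster interval, non-negative intake, exit not before entry.
#' Offending rows are collected into a reject report (optionally written to
#' a file); the run aborts when the rejected fraction exceeds
#' `max_reject_fraction`.
#'
#' @param visits_path,pens_path,roster_path CSV file paths.
#' @param max_reject_fraction Abort threshold on the rejected row fraction.
#' @param reject_path Optional path for the reject report CSV.
#' @return List with validated `visits`, `pens`, `roster`, and `rejects`
#'   (data frame of offending rows with a `reason` column).
#' @export
ingest_feeder_csv <- function(visits_path, pens_path, roster_path,
                              max_reject_fraction = 0.05,
                              reject_path = NULL) {
  visits <- read_visits_csv(visits_path)
  pens <- read_pens_csv(pens_path)
  roster <- read_roster_csv(roster_path)
  reason <- rep(NA_character_, nrow(visits))
  pm <- match(visits$pen_id, pens$pen_id)
  reason[is.na(pm)] <- "unknown pen"
  rk <- paste(roster$pen_id, roster$pig_id)
  gm <- match(paste(visits$pen_id, visits$pig_id), rk)
  reason[is.na(reason) & is.na(gm)] <- "unknown pig"
  ok <- is.na(reason)
  span_bad <- ok & (visits$date < pens$rec_start[pm] |
                      visits$date > pens$rec_end[pm])
  reason[span_bad] <- sprintf(
    "date outside pen recording span [%s, %s]",
    format(pens$rec_start[pm[span_bad]]), format(pens$rec_end[pm[span_bad]]))
  ok <- is.na(reason)
  roster_bad <- ok & (visits$date < roster$first_day[gm] |
                        visits$date > roster$last_day[gm])
  reason[roster_bad] <- "date outside pig roster interval"
  reason[is.na(reason) & visits$feed_g < 0] <- "negative intake"
  reason[is.na(reason) & visits$exit_time < visits$entry_time] <-
    "exit before entry"
  bad <- !is.na(reason)
  rejects <- cbind(visits[bad, , drop = FALSE],
                   data.frame(reason = reason[bad]))
  rownames(rejects) <- NULL
  if (!is.null(reject_path) && nrow(rejects) > 0L)
    write.csv(rejects, reject_path, row.names = FALSE)
  if (nrow(visits) > 0L && mean(bad) > max_reject_fraction)
    stop("ingest_feeder_csv: ", sum(bad), "/", nrow(visits), " rows rejected",
         " (> ", max_reject_fraction * 100, "% threshold)")
  list(visits = visits[!bad, , drop = FALSE], pens = pens, roster = roster,
       rejects = rejects)
}
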