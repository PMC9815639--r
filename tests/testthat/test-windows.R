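# A pen with hand-set observation values, for layout and labeling checks.
pen_fixture <- function(n_pigs = 3L, n_days = 20L, status = "CTL",
                        tb_offset = NULL) {
  d0 <- as.Date("2021-06-01")
  pens <- data.frame(pen_id = "px", herd_id = "h1", status = status,
                     tb_date = if (is.null(tb_offset)) as.Date(NA) else
                       d0 + tb_offset,
                     rec_start = d0, rec_end = d0 + n_days - 1L,
                     stringsAsFactors = FALSE)
  grid <- expand.grid(pig = seq_len(n_pigs), day = seq_len(n_days))
  obs <- data.frame(pen_id = "px",
                    pig_id = sprintf("pig%02d", grid$pig),
                    date = d0 + grid$day - 1L,
                    dfv = grid$pig * 100L + grid$day,
                    dfc = grid$pig * 1000 + grid$day,
                    stdfc = grid$pig * 10 + grid$day,
                    stringsAsFactors = FALSE)
  list(obs = obs, pens = pens)
}

test_that("pig selection is deterministic: completeness first, then id", {
  fx <- pen_fixture(n_pigs = 12L, n_days = 10L)
  # two pigs lose half their days
  drop <- fx$obs$pig_id %in% c("pig03", "pig07") &
    as.integer(fx$obs$date - min(fx$obs$date)) %% 2L == 0L
  obs <- fx$obs[!drop, ]
  sel <- select_pigs(obs, 10L)
  expect_length(sel, 10L)
  expect_false(any(c("pig03", "pig07") %in% sel))
  expect_equal(sel, sort(sel))  # equal completeness -> lexicographic

  short <- select_pigs(pen_fixture(n_pigs = 7L)$obs, 10L)
  expect_equal(short[1:7], sprintf("pig%02d", 1:7))
  expect_true(all(is.na(short[8:10])))

  expect_error(select_pigs(fx$obs[0L, ], 10L), "no pigs")
  expect_error(select_pigs(fx$obs, 0L), "k must be")
})

test_that("window labels obey the inclusive TB-window rule", {
  cfg <- window_config()
  ctl <- pen_fixture(status = "CTL")$pens[1L, ]
  expect_equal(assign_label(ctl, ctl$rec_start + 5, cfg), "CTL")

  tb <- pen_fixture(n_days = 200L, status = "TB", tb_offset = 100L)$pens[1L, ]
  at <- function(rel) assign_label(tb, tb$tb_date + rel, cfg)
  expect_equal(at(-35), "TB")
  expect_equal(at(-36), "CTL")
  expect_equal(at(10), "TB")
  expect_equal(at(11), "CTL")
  expect_equal(at(0), "TB")

  broken <- tb; broken$tb_date <- as.Date(NA)
  expect_error(assign_label(broken, tb$rec_start, cfg), "no tb_date")
})

test_that("window counts follow the sliding-window formula", {
  # enumeration oracle: count valid start days directly
  count_oracle <- function(D, w, stride) {
    n <- 0L
    for (s in seq_len(D)) if (s + w - 1L <= D &&
                              (s - 1L) %% stride == 0L) n <- n + 1L
    n
  }
  for (p in list(c(141L, 14L, 1L), c(20L, 7L, 3L), c(14L, 14L, 1L),
                 c(30L, 21L, 5L))) {
    fx <- pen_fixture(n_pigs = 2L, n_days = p[1L])
    cfg <- window_config(window_days = p[2L], stride_days = p[3L],
                         pigs_per_window = 2L)
    w <- build_windows(fx$obs, fx$pens, cfg)
    expect_equal(nrow(w$features), count_oracle(p[1L], p[2L], p[3L]))
    # no window may cross the recording end
    expect_true(all(w$info$a_date + cfg$window_days - 1L <=
                      fx$pens$rec_end))
  }
  expect_equal(nrow(build_windows(pen_fixture(n_days = 141L)$obs,
                                  pen_fixture(n_days = 141L)$pens,
                                  window_config(pigs_per_window = 3L)
                                  )$features), 128L)
  short <- pen_fixture(n_days = 10L)
  expect_warning(w0 <- build_windows(short$obs, short$pens, window_config()),
                 "shorter than the analysis window")
  expect_equal(nrow(w0$features), 0L)
})

test_that("TB-labeled window counts equal the TB-window length in days", {
  fx <- pen_fixture(n_pigs = 2L, n_days = 141L, status = "TB",
                    tb_offset = 70L)
  for (p in list(list(c(-35L, 10L), 46L), list(c(-49L, 10L), 60L),
                 list(c(-10L, 5L), 16L))) {
    cfg <- window_config(tb_window = p[[1L]], pigs_per_window = 2L)
    w <- build_windows(fx$obs, fx$pens, cfg)
    expect_equal(sum(w$info$label == "TB"), p[[2L]])
  }
})

test_that("feature cells follow the variable-major, pig, day layout", {
  fx <- pen_fixture(n_pigs = 3L, n_days = 20L)
  cfg <- window_config(pigs_per_window = 3L)
  w <- build_windows(fx$obs, fx$pens, cfg)
  expect_equal(ncol(w$features), 3L * 3L * 14L)
  # cell (variable v, pig slot p, day offset d) for the window at a_date s:
  # column ((v-1)*k + (p-1))*w + d; fixture value encodes (variable, pig, day)
  vals <- list(function(p, day) p * 100 + day,    # dfv
               function(p, day) p * 1000 + day,   # dfc
               function(p, day) p * 10 + day)     # stdfc
  for (j in c(1L, 4L)) {   # windows with a_date day j
    s <- j
    for (v in 1:3) for (p in 1:3) for (d in c(1L, 14L)) {
      col <- ((v - 1L) * 3L + (p - 1L)) * 14L + d
      expect_equal(unname(w$features[j, col]), vals[[v]](p, s + d - 1L))
    }
  }
})

test_that("placeholder pigs and missing observations appear as NA cells", {
  fx <- pen_fixture(n_pigs = 2L, n_days = 20L)
  cfg <- window_config(pigs_per_window = 4L)
  w <- build_windows(fx$obs, fx$pens, cfg)
  # slots 3 and 4 are placeholders: their cells are all missing
  for (v in 1:3) for (p in 3:4) {
    cols <- ((v - 1L) * 4L + (p - 1L)) * 14L + 1:14
    expect_true(all(is.na(w$features[, cols])))
  }
  # real pigs' dfv/dfc cells are complete
  cols_p1 <- 0L * 14L + 1:14
  expect_true(all(!is.na(w$features[, cols_p1])))
})
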