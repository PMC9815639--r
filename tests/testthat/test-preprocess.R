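test_that("median imputation fills cells with per-herd medians", {
  f <- matrix(c(1, 2, 3, 4, 100, NA), nrow = 6)
  w <- make_windows(f, herds = rep("h1", 6), labels = rep("CTL", 6))
  out <- impute_median(w)
  expect_equal(unname(out$windows$features[6, 1]), 3)  # median of {1,2,3,4,100}
  expect_equal(out$medians["h1", 1], 3)

  # no missing cells: identity
  w2 <- make_windows(matrix(1:6, nrow = 3), herds = rep("h1", 3),
                     labels = rep("CTL", 3))
  expect_equal(impute_median(w2)$windows$features, w2$features)

  # idempotence
  once <- impute_median(w)$windows
  twice <- impute_median(once)$windows
  expect_identical(once$features, twice$features)
})

test_that("imputation is stratified by herd and errors on empty strata", {
  f <- rbind(c(10, NA), c(12, 20), c(NA, 2), c(1, 4))
  w <- make_windows(f, herds = c("h1", "h1", "h2", "h2"),
                    labels = rep("CTL", 4), n_vars = 2L)
  out <- impute_median(w)
  expect_equal(unname(out$windows$features[1, 2]), 20)  # h1 median of var 2
  expect_equal(unname(out$windows$features[3, 1]), 1)   # h2 median of var 1

  # a herd x variable stratum with no data at all
  f2 <- rbind(c(NA, 5), c(NA, 6))
  w2 <- make_windows(f2, herds = c("h1", "h1"), labels = rep("CTL", 2),
                     n_vars = 2L)
  expect_error(impute_median(w2), "herd 'h1', variable 'v1'")

  # fitted medians transfer to unseen windows without refitting
  unseen <- make_windows(rbind(c(NA, NA)), herds = "h1", labels = "CTL",
                         n_vars = 2L)
  tr <- impute_median(unseen, medians = out$medians)
  expect_equal(as.numeric(tr$windows$features), c(11, 20))
})

test_that("standardization gives per-stratum zero mean and unit SD", {
  set.seed(1)
  f <- cbind(rnorm(20, 50, 5), rnorm(20, -3, 0.1))
  herds <- rep(c("h1", "h2"), each = 10)
  w <- make_windows(f, herds = herds, labels = rep("CTL", 20), n_vars = 2L)
  out <- standardize_windows(w)
  for (h in c("h1", "h2")) for (v in 1:2) {
    cells <- out$windows$features[herds == h, v]
    expect_equal(mean(cells), 0, tolerance = 1e-12)
    expect_equal(sd(cells), 1, tolerance = 1e-12)
  }
  # oracle: transform recomputed by hand for one stratum
  expect_equal(unname(out$windows$features[1, 1]),
               (f[1, 1] - mean(f[1:10, 1])) / sd(f[1:10, 1]))

  # constant variable: scale 1, all zeros, with warning
  wc <- make_windows(matrix(7, 5, 1), herds = rep("h1", 5),
                     labels = rep("CTL", 5))
  expect_warning(outc <- standardize_windows(wc), "constant stratum")
  expect_true(all(outc$windows$features == 0))

  expect_error(standardize_windows(make_windows(matrix(NA_real_, 2, 1),
                                                herds = c("h1", "h1"),
                                                labels = c("CTL", "CTL"))),
               "impute")
})

test_that("PCA keeps the smallest component set reaching the variance target", {
  set.seed(2)
  # data confined to a 2-D subspace of 30-D
  basis <- qr.Q(qr(matrix(rnorm(30 * 2), 30)))
  scores2 <- matrix(rnorm(40 * 2, sd = c(3, 1)), 40, byrow = TRUE)
  f <- scores2 %*% t(basis)
  w <- make_windows(f, herds = rep("h1", 40), labels = rep("CTL", 40))
  out <- pca_reduce(w, variance_retained = 0.95)
  expect_equal(out$rotation$ncomp, 2L)

  # full retention on full-rank data: reconstruction to numerical precision
  set.seed(3)
  ffull <- matrix(rnorm(25 * 6), 25)
  wf <- make_windows(ffull, herds = rep("h1", 25), labels = rep("CTL", 25))
  outf <- pca_reduce(wf, variance_retained = 1)
  rec <- outf$scores %*% t(outf$rotation$rotation)
  rec <- sweep(rec, 2L, outf$rotation$center, `+`)
  expect_equal(unname(rec), unname(ffull), tolerance = 1e-10)
})

test_that("preprocessing fitted on training rows never sees the test rows", {
  set.seed(4)
  f <- matrix(rnorm(30 * 8), 30)
  f[sample(length(f), 20)] <- NA
  w <- make_windows(f, herds = rep(c("h1", "h2"), 15),
                    labels = rep("CTL", 30))
  train <- 1:20
  a <- preprocess_windows(w, fit_on = train)
  # permuting the held-out rows leaves the fitted transform unchanged
  wp <- w
  perm <- c(train, sample(21:30))
  wp$features <- w$features[perm, ]
  wp$info <- w$info[perm, ]
  b <- preprocess_windows(wp, fit_on = 1:20)
  expect_equal(a$prep$medians, b$prep$medians)
  expect_equal(a$prep$centers, b$prep$centers)
  expect_equal(a$prep$rotation$rotation, b$prep$rotation$rotation)
  # and applying the fitted transform commutes with the permutation
  expect_equal(unname(b$x), unname(a$x[perm, ]))
  # apply_preprocessing reproduces the in-sample transform
  expect_equal(apply_preprocessing(a$prep, w), a$x)
})
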