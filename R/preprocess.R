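# Preprocessing of analysis windows: per-herd median imputation, per-herd
# centering/scaling, and PCA reduction. All three are fit/apply transforms:
# parameters are estimated on a designated subset of windows (by default the
# training side, to keep test statistics out of the fit) and can then be
# applied unchanged to unseen windows. Imputation and standardization are
# stratified by herd ("by data set") and by observation variable, and remain
# per-herd even when herds are merged into one analysis.

stratum_cells <- function(windows, rows, herd, v) {
  cols <- which(windows$var_of == v)
  windows$features[rows[windows$info$herd_id[rows] == herd], cols,
                   drop = FALSE]
}

#' Median imputation of missing window cells
#'
#' Replaces every missing cell by the median of the non-missing values of the
#' same variable within the same herd, computed on the `fit_on` windows.
#' Passing previously fitted `medians` applies the identical transform to
#' unseen windows.
#'
#' @param windows A `tb_windows` object.
#' @param fit_on Integer row indices to fit the medians on (default: all).
#' @param medians Optional fitted medians (herd x variable matrix) from an
#'   earlier call.
#' @return List with `windows` (no missing cells) and `medians`.
#' @export
impute_median <- function(windows, fit_on = NULL, medians = NULL) {
  herds <- unique(windows$info$herd_id)
  vars <- windows$config$variables
  if (is.null(medians)) {
    if (is.null(fit_on)) fit_on <- seq_len(nrow(windows$features))
    if (length(fit_on) == 0L) stop("impute_median: empty fit set")
    medians <- matrix(NA_real_, length(herds), length(vars),
                      dimnames = list(herds, vars))
    for (h in herds) for (v in seq_along(vars)) {
      cells <- stratum_cells(windows, fit_on, h, v)
      ok <- cells[!is.na(cells)]
      if (length(ok) == 0L)
        stop("impute_median: no observed values for herd '", h,
             "', variable '", vars[v], "' in the fit set")
      medians[h, vars[v]] <- median(ok)
    }
  }
  miss_h <- setdiff(herds, rownames(medians))
  if (length(miss_h) > 0L)
    stop("impute_median: no fitted medians for herd '", miss_h[1L], "'")
  F <- windows$features
  for (h in herds) for (v in seq_along(vars)) {
    cols <- which(windows$var_of == v)
    rows <- which(windows$info$herd_id == h)
    block <- F[rows, cols, drop = FALSE]
    block[is.na(block)] <- medians[h, vars[v]]
    F[rows, cols] <- block
  }
  windows$features <- F
  list(windows = windows, medians = medians)
}

#' Per-herd centering and scaling of window cells
#'
#' Standardizes every cell as `(x - mean) / SD`, with mean and SD per
#' herd x variable stratum estimated on the `fit_on` windows (after
#' imputation). A zero-variance stratum gets scale 1 with a warning.
#'
#' @param windows A `tb_windows` object without missing cells.
#' @param fit_on Integer row indices to fit on (default: all).
#' @param centers,scales Optional fitted parameters from an earlier call.
#' @return List with `windows`, `centers`, `scales`.
#' @export
standardize_windows <- function(windows, fit_on = NULL, centers = NULL,
                                scales = NULL) {
  if (anyNA(windows$features))
    stop("standardize_windows: impute missing cells first")
  herds <- unique(windows$info$herd_id)
  vars <- windows$config$variables
  if (is.null(centers)) {
    if (is.null(fit_on)) fit_on <- seq_len(nrow(windows$features))
    centers <- scales <- matrix(NA_real_, length(herds), length(vars),
                                dimnames = list(herds, vars))
    for (h in herds) for (v in seq_along(vars)) {
      cells <- as.vector(stratum_cells(windows, fit_on, h, v))
      centers[h, vars[v]] <- mean(cells)
      s <- sd(cells)
      if (!is.finite(s) || s == 0) {
        warning("standardize_windows: constant stratum (herd '", h,
                "', variable '", vars[v], "'); scale set to 1")
        s <- 1
      }
      scales[h, vars[v]] <- s
    }
  }
  F <- windows$features
  for (h in herds) for (v in seq_along(vars)) {
    cols <- which(windows$var_of == v)
    rows <- which(windows$info$herd_id == h)
    F[rows, cols] <- (F[rows, cols] - centers[h, vars[v]]) /
      scales[h, vars[v]]
  }
  windows$features <- F
  list(windows = windows, centers = centers, scales = scales)
}

#' PCA reduction of standardized windows
#'
#' Fits an orthogonal rotation on the `fit_on` windows and keeps the smallest
#' leading set of components whose cumulative explained variance reaches
#' `variance_retained`; the same rotation is applied to all windows. With
#' `variance_retained = 1` on full-rank data the transform is invertible up
#' to numerical precision.
#'
#' @param windows A standardized `tb_windows` object.
#' @param fit_on Integer row indices to fit on (default: all).
#' @param variance_retained Fraction of variance to retain (default from the
#'   window config).
#' @param rotation Optional fitted rotation from an earlier call.
#' @return List with `scores` (windows x components matrix for all rows) and
#'   `rotation` (list: `center`, `rotation`, `ncomp`, `sdev`).
#' @export
pca_reduce <- function(windows, fit_on = NULL, variance_retained = NULL,
                       rotation = NULL) {
  X <- windows$features
  if (is.null(rotation)) {
    if (is.null(fit_on)) fit_on <- seq_len(nrow(X))
    if (length(fit_on) < 2L) stop("pca_reduce: need at least 2 fit windows")
    if (is.null(variance_retained))
      variance_retained <- windows$config$pca_variance_retained
    pc <- prcomp(X[fit_on, , drop = FALSE], center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2
    if (sum(ev) <= 0) stop("pca_reduce: degenerate (rank-0) input")
    cum <- cumsum(ev) / sum(ev)
    ncomp <- which(cum >= variance_retained - 1e-12)[1L]
    if (is.na(ncomp)) ncomp <- length(ev)
    rotation <- list(center = pc$center,
                     rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
                     ncomp = ncomp, sdev = pc$sdev)
  }
  scores <- sweep(X, 2L, rotation$center) %*% rotation$rotation
  colnames(scores) <- sprintf("pc_%03d", seq_len(ncol(scores)))
  list(scores = scores, rotation = rotation)
}

#' Fit the full preprocessing chain and transform all windows
#'
#' Convenience wrapper chaining [impute_median()], [standardize_windows()]
#' and [pca_reduce()], all fitted on `fit_on` and applied to every window.
#'
#' @param windows A `tb_windows` object.
#' @param fit_on Integer row indices the transforms are fitted on (default:
#'   all windows, i.e. "global" fitting).
#' @return List with `x` (reduced feature matrix for all windows) and `prep`
#'   (fitted parameters reusable via [apply_preprocessing()]).
#' @export
preprocess_windows <- function(windows, fit_on = NULL) {
  imp <- impute_median(windows, fit_on = fit_on)
  std <- standardize_windows(imp$windows, fit_on = fit_on)
  pca <- pca_reduce(std$windows, fit_on = fit_on)
  list(x = pca$scores,
       prep = list(medians = imp$medians, centers = std$centers,
                   scales = std$scales, rotation = pca$rotation,
                   config = windows$config))
}

#' Apply previously fitted preprocessing to new windows
#'
#' @param prep Fitted parameters from [preprocess_windows()].
#' @param windows A `tb_windows` object (same config/layout).
#' @return Reduced feature matrix.
#' @export
apply_preprocessing <- function(prep, windows) {
  imp <- impute_median(windows, medians = prep$medians)
  std <- standardize_windows(imp$windows, centers = prep$centers,
                             scales = prep$scales)
  pca_reduce(std$windows, rotation = prep$rotation)$scores
}
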