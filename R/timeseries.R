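#' Two-region BOLD time-series container
#'
#' @param values numeric time x region matrix (no missing values). For the
#'   study design: 360 rows at `tr_seconds = 1`.
#' @param tr_seconds repetition time in seconds (> 0).
#' @param region_names column identifiers; defaults to existing colnames or
#'   `region1..k`.
#' @return an object of class `bold_series`: list with `values`, `tr_seconds`,
#'   `region_names`.
#' @export
time_series <- function(values, tr_seconds = 1, region_names = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("time series contains missing values")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be > 0")
  if (is.null(region_names)) {
    region_names <- colnames(values)
    if (is.null(region_names))
      region_names <- paste0("region", seq_len(ncol(values)))
  }
  if (length(region_names) != ncol(values))
    stop("region_names length must match number of columns")
  colnames(values) <- region_names
  structure(list(values = values, tr_seconds = tr_seconds,
                 region_names = region_names),
            class = "bold_series")
}

as_time_series <- function(x, tr_seconds = 1) {
  if (inherits(x, "bold_series")) x else time_series(x, tr_seconds)
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("BOLD series: %d volumes x %d regions, TR = %g s (%s)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds,
              paste(x$region_names, collapse = ", ")))
  invisible(x)
}

#' Analysis frequency band
#'
#' The band of endogenous BOLD fluctuations used throughout: 0.0078-0.1 Hz.
#' `f_min` also sets the cut-off of the high-pass drift basis.
#'
#' @param f_min,f_max band edges in Hz, `0 < f_min < f_max`.
#' @return list of class `spectral_config`.
#' @export
spectral_config <- function(f_min = 0.0078, f_max = 0.1) {
  if (!(f_min > 0 && f_min < f_max)) stop("need 0 < f_min < f_max")
  structure(list(f_min = f_min, f_max = f_max), class = "spectral_config")
}

check_band <- function(config, tr_seconds) {
  nyquist <- 1 / (2 * tr_seconds)
  if (config$f_min >= nyquist)
    stop(sprintf("f_min (%g Hz) is at or above Nyquist (%g Hz)",
                 config$f_min, nyquist))
  if (config$f_max > nyquist)
    stop(sprintf("f_max (%g Hz) exceeds Nyquist (%g Hz)", config$f_max, nyquist))
  invisible(config)
}

#' Regress confounds out of a BOLD series
#'
#' Least-squares residuals of every region on an intercept plus the confound
#' set (e.g. six head-movement parameters and the white-matter and CSF
#' series). Idempotent: the residuals are orthogonal to the confound span.
#'
#' @param series a `bold_series` (or plain matrix).
#' @param confounds numeric time x regressor matrix with the same number of
#'   rows; must not be rank deficient after adding the intercept.
#' @return a `bold_series` of residuals with unchanged `tr_seconds`.
#' @export
regress_confounds <- function(series, confounds) {
  series <- as_time_series(series)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(series$values))
    stop("confounds must have the same number of rows as the series")
  X <- cbind(intercept = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("confound matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  resid <- qr.resid(qrX, series$values)
  time_series(resid, series$tr_seconds, series$region_names)
}

#' Discrete-cosine drift basis
#'
#' DCT-II regressors `cos(pi * k * (2t + 1) / (2n))`, `k = 0..order`, whose
#' k-th component has frequency `k / (2 n tr)` Hz.
#'
#' @param n number of time points.
#' @param order highest component index (inclusive; `k = 0` is the constant).
#' @return n x (order + 1) matrix.
#' @keywords internal
dct_basis <- function(n, order) {
  t <- seq_len(n) - 1
  vapply(0:order, function(k) cos(pi * k * (2 * t + 1) / (2 * n)),
         numeric(n))
}

#' High-pass filter by cosine-drift projection
#'
#' Projects out the discrete-cosine subspace of slow drifts below `f_min`
#' (including the constant), leaving fluctuations inside the analysis band
#' essentially untouched (gain >= 0.95 for tones in `[f_min, f_max]`).
#' Frequencies above `f_max` are not attenuated here; the band restriction is
#' enforced at the cross-spectrum stage.
#'
#' @param series a `bold_series` (or plain matrix).
#' @param config a [spectral_config()].
#' @return the filtered `bold_series`.
#' @export
highpass_cosine <- function(series, config = spectral_config()) {
  series <- as_time_series(series)
  check_band(config, series$tr_seconds)
  n <- nrow(series$values)
  # components with frequency k / (2 n tr) strictly below f_min, plus k = 0
  order <- max(0L, ceiling(2 * n * series$tr_seconds * config$f_min) - 1L)
  drift <- dct_basis(n, order)
  resid <- qr.resid(qr(drift), series$values)
  time_series(resid, series$tr_seconds, series$region_names)
}

#' Summarize voxel series into one regional series
#'
#' First principal component of the column-centered voxel matrix (the
#' principal eigenvariate of an 8-mm sphere in the published pipeline),
#' sign-aligned so that its correlation with the mean voxel series is
#' non-negative, and scaled to unit variance.
#'
#' @param voxel_series numeric time x voxel matrix, at least one column, no
#'   missing values.
#' @return numeric vector of length `nrow(voxel_series)` with unit variance.
#' @export
summarize_region <- function(voxel_series) {
  voxel_series <- as.matrix(voxel_series)
  if (anyNA(voxel_series)) stop("voxel series contains missing values")
  centered <- scale(voxel_series, center = TRUE, scale = FALSE)
  if (all(abs(centered) < .Machine$double.eps * 1e3))
    stop("zero-variance voxel input: no summary series")
  if (ncol(centered) == 1L) {
    score <- centered[, 1]
  } else {
    score <- stats::prcomp(centered, center = FALSE, scale. = FALSE)$x[, 1]
  }
  reference <- rowMeans(centered)
  if (sum(score * reference) < 0) score <- -score
  as.numeric(score / stats::sd(score))
}
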