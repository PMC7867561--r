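# Welch cross-spectral oracle: Hann-windowed, 50%-overlap averaged
# cross-periodograms, two-sided PSD normalization. Independent of the AR
# estimator it cross-checks.
welch_csd <- function(x, tr, seg) {
  n <- nrow(x)
  step <- seg / 2
  nseg <- floor((n - seg) / step) + 1
  w <- 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / seg))
  norm <- sum(w^2)
  acc <- array(0 + 0i, c(2, 2, seg))
  for (k in 0:(nseg - 1)) {
    xs <- x[(k * step + 1):(k * step + seg), , drop = FALSE]
    xs <- sweep(xs, 2, colMeans(xs))
    X <- stats::mvfft(xs * w)
    for (a in 1:2) for (b in 1:2)
      acc[a, b, ] <- acc[a, b, ] + X[, a] * Conj(X[, b])
  }
  list(freqs = (0:(seg - 1)) / (seg * tr),
       csd = tr * acc / (nseg * norm),
       n_segments = nseg)
}

# average a welch csd over bins within +/- half_bins around a target frequency
welch_at <- function(wl, f0, half_bins = 2) {
  i <- which.min(abs(wl$freqs - f0))
  idx <- max(1, i - half_bins):min(length(wl$freqs), i + half_bins)
  apply(wl$csd[, , idx, drop = FALSE], c(1, 2), mean)
}

# closed-form paired t pieces, independent of the package implementation
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- mean(d)
  s <- sqrt(sum((d - m)^2) / (n - 1))
  list(mean = m, sd = s, t = m / (s / sqrt(n)), df = n - 1)
}

# quick subject_posterior builder for group-level tests
make_posterior <- function(mean, cov = diag(0.01, 4), id = NULL) {
  structure(list(subject_id = id,
                 mean = stats::setNames(as.numeric(mean),
                                        c("dlpfc_self", "str_to_dlpfc",
                                          "dlpfc_to_str", "str_self")),
                 covariance = cov),
            class = "subject_posterior")
}

band_coherence <- function(csd) {
  mean(Mod(csd$csd[1, 2, ]) /
         sqrt(Re(csd$csd[1, 1, ]) * Re(csd$csd[2, 2, ])))
}
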