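#' Whittle information bound for connectivity recovery
#'
#' Expected (Fisher) information about the four log scaling factors carried
#' by a stationary two-region BOLD record of given length, under the model's
#' own spectrum: `I_ab = sum_f tr(S^-1 dS_a S^-1 dS_b)` over the independent
#' Fourier frequencies of the record inside the analysis band. Combined with
#' the prior, this gives the best posterior standard deviation any spectral
#' estimator can achieve, and hence a ceiling on the true-vs-estimate
#' correlation attainable in recovery studies:
#' `r_max = sqrt(1 - var_post / var_prior)` for parameters drawn from the
#' prior.
#'
#' With the study's acquisition (360 volumes at TR = 1 s) this ceiling is
#' about 0.3-0.4 per parameter: single-subject point estimates are mostly
#' prior-dominated, which is exactly why the group level pools subjects by
#' posterior precision.
#'
#' @param n_timepoints record length in volumes.
#' @param tr repetition time (s).
#' @param theta expansion point (default: the prior mean).
#' @param priors a [prior_spec()]; its covariance sets the prior variance.
#' @param noise,fixed,config model constants as elsewhere.
#' @return list with `info` (4x4 Fisher information), `posterior_sd`
#'   (per-parameter bound) and `r_max` (per-parameter recovery ceiling).
#' @export
recovery_ceiling <- function(n_timepoints, tr = 1,
                             theta = connection_params(),
                             priors = prior_spec(),
                             noise = noise_params(),
                             fixed = fixed_neural_params(),
                             config = spectral_config()) {
  freqs <- (1:floor(n_timepoints / 2)) / (n_timepoints * tr)
  freqs <- freqs[freqs >= config$f_min & freqs <= config$f_max]
  S0 <- predicted_csd(theta, fixed, noise, freqs)$csd
  h <- 1e-4
  th0 <- as.numeric(theta)
  dS <- lapply(1:4, function(j) {
    e <- th0
    e[j] <- e[j] + h
    (predicted_csd(e, fixed, noise, freqs)$csd - S0) / h
  })
  info <- matrix(0, 4, 4, dimnames = list(CONNECTIONS, CONNECTIONS))
  for (k in seq_along(freqs)) {
    Si <- solve(S0[, , k])
    B <- lapply(dS, function(d) Si %*% d[, , k])
    for (a in 1:4) for (b in a:4) {
      v <- Re(sum(diag(B[[a]] %*% B[[b]])))
      info[a, b] <- info[a, b] + v
      if (a != b) info[b, a] <- info[b, a] + v
    }
  }
  post <- solve(info + solve(priors$covariance))
  prior_var <- diag(priors$covariance)
  sd_post <- sqrt(diag(post))
  list(info = info, posterior_sd = stats::setNames(sd_post, CONNECTIONS),
       r_max = stats::setNames(sqrt(pmax(0, 1 - diag(post) / prior_var)),
                               CONNECTIONS))
}
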