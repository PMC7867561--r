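CONNECTIONS <- c("dlpfc_self", "str_to_dlpfc", "dlpfc_to_str", "str_self")

#' Free connectivity parameters (log scaling factors)
#'
#' The four free parameters of the two-state model, each the log of a scaling
#' factor applied to the default connection strength: +1/8 Hz for the two
#' between-region excitatory (EE, glutamatergic) connections and -1/8 Hz for
#' the two within-region inhibitory-to-excitatory (IE, GABAergic) connections.
#' The exponential parameterization enforces the sign of every connection for
#' any finite value. Ordering follows the published subject table:
#' `dlpfc_self` (IE within LDLPFC), `str_to_dlpfc` (EE), `dlpfc_to_str` (EE),
#' `str_self` (IE within LSTR).
#'
#' @param dlpfc_self,str_to_dlpfc,dlpfc_to_str,str_self log scale factors
#'   (prior mean 0, i.e. the default strengths).
#' @return named numeric vector of class `connection_params`.
#' @export
connection_params <- function(dlpfc_self = 0, str_to_dlpfc = 0,
                              dlpfc_to_str = 0, str_self = 0) {
  theta <- c(dlpfc_self = dlpfc_self, str_to_dlpfc = str_to_dlpfc,
             dlpfc_to_str = dlpfc_to_str, str_self = str_self)
  if (!all(is.finite(theta))) stop("connection parameters must be finite")
  structure(theta, class = "connection_params")
}

as_connection_params <- function(theta) {
  if (inherits(theta, "connection_params")) return(theta)
  theta <- as.numeric(theta)
  if (length(theta) != 4L) stop("need 4 connection parameters")
  do.call(connection_params, as.list(theta))
}

#' Effective connection strength in Hz
#'
#' `+0.125 * exp(theta)` for between-region connections and
#' `-0.125 * exp(theta)` for within-region connections.
#'
#' @param theta log scale factor(s).
#' @param kind `"between"` (EE, positive) or `"within"` (IE, negative).
#' @return numeric strength(s) in Hz.
#' @export
effective_strength <- function(theta, kind = c("between", "within")) {
  kind <- match.arg(kind)
  sgn <- if (kind == "between") 1 else -1
  sgn * 0.125 * exp(theta)
}

#' Fixed neural parameters
#'
#' The excitatory-to-inhibitory gain and the two self-decay rates are fixed,
#' never estimated; only the IE and EE connections are free. Defaults
#' (`se_decay = si_decay = -0.5` Hz, `ei_gain = 0.5` Hz) give a stable system
#' at the prior mean.
#'
#' @param se_decay excitatory self-inhibition rate, must be < 0 (Hz).
#' @param si_decay inhibitory self-inhibition rate, must be < 0 (Hz).
#' @param ei_gain excitatory-to-inhibitory coupling, must be > 0 (Hz).
#' @return list of class `fixed_neural_params`.
#' @export
fixed_neural_params <- function(se_decay = -0.5, si_decay = -0.5,
                                ei_gain = 0.5) {
  if (!(se_decay < 0 && si_decay < 0 && ei_gain > 0))
    stop("require se_decay < 0, si_decay < 0, ei_gain > 0")
  structure(list(se_decay = se_decay, si_decay = si_decay, ei_gain = ei_gain),
            class = "fixed_neural_params")
}

#' Jacobian of the two-region two-state neural system
#'
#' Linear dynamics of the states `(E_dlpfc, I_dlpfc, E_str, I_str)`: each
#' excitatory population decays (SE), is inhibited by its local inhibitory
#' population (IE, strength `-0.125 exp(theta)`), and is driven by the other
#' region's excitatory population (EE, `+0.125 exp(theta)`); each inhibitory
#' population decays (SI) and is driven by its local excitatory population
#' (EI).
#'
#' @param params a [connection_params()] vector.
#' @param fixed a [fixed_neural_params()] list.
#' @return 4x4 matrix with attribute `stable` (TRUE iff all eigenvalues have
#'   negative real part) and `max_re_eig`.
#' @export
system_jacobian <- function(params, fixed = fixed_neural_params()) {
  theta <- as_connection_params(params)
  A <- matrix(0, 4, 4,
              dimnames = rep(list(c("E_dlpfc", "I_dlpfc", "E_str", "I_str")), 2))
  A["E_dlpfc", "E_dlpfc"] <- fixed$se_decay
  A["E_dlpfc", "I_dlpfc"] <- effective_strength(theta[["dlpfc_self"]], "within")
  A["E_dlpfc", "E_str"]   <- effective_strength(theta[["str_to_dlpfc"]], "between")
  A["I_dlpfc", "E_dlpfc"] <- fixed$ei_gain
  A["I_dlpfc", "I_dlpfc"] <- fixed$si_decay
  A["E_str", "E_str"]     <- fixed$se_decay
  A["E_str", "I_str"]     <- effective_strength(theta[["str_self"]], "within")
  A["E_str", "E_dlpfc"]   <- effective_strength(theta[["dlpfc_to_str"]], "between")
  A["I_str", "E_str"]     <- fixed$ei_gain
  A["I_str", "I_str"]     <- fixed$si_decay
  max_re <- max(Re(eigen(A, only.values = TRUE)$values))
  structure(A, stable = max_re < 0, max_re_eig = max_re)
}

#' Hemodynamic transfer function
#'
#' Fourier transfer values of a canonical double-gamma hemodynamic response
#' kernel `h(t) = gamma(t; a1, b) - gamma(t; a2, b) / ratio` (gamma densities;
#' defaults a1 = 6, a2 = 16, b = 1 1/s, ratio 6), evaluated in closed form:
#' `H(f) = (b / (b + i 2 pi f))^a1 - (1/ratio) (b / (b + i 2 pi f))^a2`.
#' The magnitude decreases across the analysis band; the DC gain is
#' `1 - 1/ratio`.
#'
#' @param freqs frequencies in Hz (may be empty).
#' @param hrf_params list with `a1`, `a2`, `b`, `ratio`.
#' @return complex vector of transfer values, one per frequency.
#' @export
hemodynamic_gain <- function(freqs,
                             hrf_params = list(a1 = 6, a2 = 16, b = 1,
                                               ratio = 6)) {
  if (length(freqs) == 0L) return(complex(0))
  s <- 2i * pi * freqs
  base <- hrf_params$b / (hrf_params$b + s)
  base^hrf_params$a1 - base^hrf_params$a2 / hrf_params$ratio
}

#' Hemodynamic response kernel (time domain)
#'
#' The double-gamma kernel matching [hemodynamic_gain()], sampled on a grid;
#' used by the time-domain simulator.
#'
#' @param dt sampling interval (s).
#' @param duration kernel support (s).
#' @inheritParams hemodynamic_gain
#' @return numeric vector `h(0), h(dt), ...`.
#' @export
hemodynamic_kernel <- function(dt = 0.1, duration = 32,
                               hrf_params = list(a1 = 6, a2 = 16, b = 1,
                                                 ratio = 6)) {
  t <- seq(0, duration, by = dt)
  stats::dgamma(t, shape = hrf_params$a1, rate = hrf_params$b) -
    stats::dgamma(t, shape = hrf_params$a2, rate = hrf_params$b) /
      hrf_params$ratio
}

#' Spectra of endogenous fluctuations and observation noise
#'
#' Power-law forms `g(f) = alpha * f^(-beta)` (two-sided PSD, signal^2/Hz) for
#' the neural fluctuations driving the excitatory states, and for the additive
#' observation noise (white by default, `beta_obs = 0`). The default neural
#' amplitude normalizes the band-integrated fluctuation power to 1; the
#' default observation amplitude sets the band-integrated noise power to
#' one tenth of the band-integrated BOLD signal power of the model at the
#' prior mean (a power signal-to-noise ratio of 10).
#'
#' @param alpha_neural,beta_neural amplitude and spectral exponent of the
#'   neural fluctuations.
#' @param alpha_obs,beta_obs observation-noise spectrum; `alpha_obs = NULL`
#'   triggers the SNR-10 default above.
#' @param config the analysis band, used for the normalizations.
#' @param fixed fixed neural parameters used for the SNR calibration.
#' @return list of class `noise_params`.
#' @export
noise_params <- function(alpha_neural = NULL, beta_neural = 0.5,
                         alpha_obs = NULL, beta_obs = 0,
                         config = spectral_config(),
                         fixed = fixed_neural_params()) {
  if (is.null(alpha_neural))
    alpha_neural <- band_unit_amplitude(beta_neural, config)
  if (alpha_neural <= 0) stop("alpha_neural must be > 0")
  np <- structure(list(alpha_neural = alpha_neural,
                       beta_neural = beta_neural,
                       alpha_obs = 1, beta_obs = beta_obs),
                  class = "noise_params")
  if (is.null(alpha_obs)) {
    np$alpha_obs <- 0           # noise-free signal power first
    sig <- predicted_csd(connection_params(), fixed, np,
                         default_freqs(64, config))
    pow <- band_power(sig)
    alpha_obs <- 0.1 * pow / (config$f_max - config$f_min)
  }
  if (alpha_obs < 0) stop("alpha_obs must be >= 0")
  np$alpha_obs <- alpha_obs
  np
}

# amplitude alpha making  integral of alpha f^-beta over the band equal 1
band_unit_amplitude <- function(beta, config) {
  if (abs(beta - 1) < 1e-12)
    return(1 / log(config$f_max / config$f_min))
  (1 - beta) / (config$f_max^(1 - beta) - config$f_min^(1 - beta))
}

# band-integrated mean diagonal power of a cross-spectrum (trapezoid rule)
band_power <- function(csd_data) {
  diag_mean <- vapply(seq_along(csd_data$freqs),
                      function(k) Re(csd_data$csd[1, 1, k] +
                                     csd_data$csd[2, 2, k]) / 2,
                      numeric(1))
  f <- csd_data$freqs
  sum(diff(f) * (diag_mean[-1] + diag_mean[-length(f)]) / 2)
}

#' Frequency grid on the analysis band
#'
#' @param n number of evenly spaced points (default 32).
#' @param config a [spectral_config()].
#' @return numeric vector of frequencies in Hz.
#' @export
default_freqs <- function(n = 32, config = spectral_config()) {
  seq(config$f_min, config$f_max, length.out = n)
}

#' Cross-spectral data container
#'
#' @param freqs frequencies (Hz).
#' @param csd complex 2 x 2 x length(freqs) array, Hermitian positive
#'   semidefinite at each frequency.
#' @param region_names identifiers for the two regions.
#' @return object of class `cross_spectra`.
#' @export
cross_spectra <- function(freqs, csd, region_names = c("dlpfc", "striatum")) {
  if (dim(csd)[3] != length(freqs)) stop("csd third dimension must match freqs")
  dimnames(csd) <- list(region_names, region_names, NULL)
  structure(list(freqs = freqs, csd = csd, region_names = region_names),
            class = "cross_spectra")
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat(sprintf("Cross-spectra: %d frequencies on [%.4g, %.4g] Hz (%s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              paste(x$region_names, collapse = ", ")))
  invisible(x)
}

#' Validate cross-spectral invariants
#'
#' Checks Hermitian symmetry, real non-negative diagonals and positive
#' semidefiniteness at every frequency.
#'
#' @param x a `cross_spectra` object.
#' @param tol numerical tolerance.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_csd <- function(x, tol = 1e-8) {
  for (k in seq_along(x$freqs)) {
    S <- x$csd[, , k]
    scale_k <- max(abs(S), 1e-300)
    if (max(abs(S - Conj(t(S)))) > tol * scale_k)
      stop("cross-spectrum not Hermitian at frequency index ", k)
    ev <- eigen((S + Conj(t(S))) / 2, only.values = TRUE)$values
    if (min(Re(ev)) < -tol * scale_k)
      stop("cross-spectrum not positive semidefinite at frequency index ", k)
  }
  invisible(x)
}

#' Predicted BOLD cross-spectral density
#'
#' Maps connectivity parameters to the model's cross-spectrum at each
#' analysis frequency:
#' `S(f) = |H(f)|^2 T(f) G_u(f) T(f)* + g_obs(f) I`, where `T(f)` is the
#' transfer function from the fluctuation inputs (which drive the excitatory
#' states) to the excitatory states, derived from the neural Jacobian;
#' `H(f)` the hemodynamic transfer; `G_u` and `g_obs` the power-law
#' fluctuation and observation-noise spectra. The result is Hermitian PSD by
#' construction.
#'
#' @param params a [connection_params()] vector.
#' @param fixed fixed neural parameters.
#' @param noise a [noise_params()] list.
#' @param freqs frequency grid (Hz), see [default_freqs()].
#' @param hrf_params hemodynamic kernel parameters.
#' @return a [cross_spectra()] object.
#' @export
predicted_csd <- function(params, fixed = fixed_neural_params(),
                          noise = noise_params(), freqs = default_freqs(),
                          hrf_params = list(a1 = 6, a2 = 16, b = 1, ratio = 6)) {
  A <- system_jacobian(params, fixed)
  if (!attr(A, "stable"))
    stop(sprintf("unstable neural system (max Re eigenvalue %.3g >= 0)",
                 attr(A, "max_re_eig")))
  h <- hemodynamic_gain(freqs, hrf_params)
  e_idx <- c(1L, 3L)                       # excitatory states
  B <- matrix(0, 4, 2); B[1, 1] <- 1; B[3, 2] <- 1
  nf <- length(freqs)
  S <- array(complex(real = 0), dim = c(2, 2, nf))
  iw <- 2i * pi * freqs
  # resolvent via eigendecomposition: (iw I - A)^-1 = V diag(1/(iw-lambda)) V^-1
  eg <- eigen(A)
  Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
  g_u <- noise$alpha_neural * freqs^(-noise$beta_neural)
  g_o <- noise$alpha_obs * freqs^(-noise$beta_obs)
  w_h <- Mod(h)^2 * g_u
  cond_V <- if (is.null(Vinv)) Inf else {
    sv <- svd(eg$vectors)$d
    max(sv) / max(min(sv), 1e-300)
  }
  if (cond_V < 1e8) {
    W1 <- eg$vectors[e_idx, , drop = FALSE]       # C V, 2 x 4
    W2 <- Vinv %*% B                              # V^-1 B, 4 x 2
    Tarr <- array(0i, dim = c(2, 2, nf))
    for (m in 1:4) {
      gm <- 1 / (iw - eg$values[m])               # length nf
      Tarr <- Tarr + outer(W1[, m] %o% W2[m, ], gm)
    }
    for (a in 1:2) for (b in 1:2)
      S[a, b, ] <- w_h * (Tarr[a, 1, ] * Conj(Tarr[b, 1, ]) +
                          Tarr[a, 2, ] * Conj(Tarr[b, 2, ]))
    S[1, 1, ] <- Re(S[1, 1, ]) + g_o
    S[2, 2, ] <- Re(S[2, 2, ]) + g_o
    S[2, 1, ] <- Conj(S[1, 2, ])
  } else {
    # defective Jacobian: per-frequency solve
    I4 <- diag(4)
    for (k in seq_len(nf)) {
      Tf <- solve(iw[k] * I4 - A, B)[e_idx, , drop = FALSE]
      Sk <- w_h[k] * (Tf %*% Conj(t(Tf))) + g_o[k] * diag(2)
      S[, , k] <- (Sk + Conj(t(Sk))) / 2
    }
  }
  cross_spectra(freqs, S)
}
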