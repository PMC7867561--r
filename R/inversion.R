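#' Estimate observed BOLD cross-spectra
#'
#' Multivariate autoregressive (Yule-Walker) spectral estimate of the
#' two-region series, evaluated on the analysis frequency grid. With AR
#' coefficient matrices `A_j` and innovation covariance `Sigma`,
#' `S(f) = tr * A(f)^-1 Sigma A(f)^-H`, `A(f) = I - sum_j A_j e^(-i 2 pi f j tr)`
#' — Hermitian positive semidefinite at every frequency by construction.
#'
#' The alternative `method = "welch"` averages raw cross-periodogram bins
#' within each grid cell: noisier per frequency but free of parametric
#' smoothing bias, and approximately complex-Wishart with known degrees of
#' freedom — the feature of choice for recovery validation on long records.
#'
#' @param series a `bold_series` (two regions) or time x 2 matrix.
#' @param config a [spectral_config()]; the grid is [default_freqs()] on this
#'   band.
#' @param ar_order autoregressive model order (default 8; smooth spectra at
#'   360 volumes). The series must be longer than `4 * ar_order`.
#' @param n_freq number of grid frequencies.
#' @param method `"ar"` (multivariate Yule-Walker, default) or `"welch"`
#'   (bin-averaged cross-periodogram).
#' @return a [cross_spectra()] object.
#' @export
estimate_csd <- function(series, config = spectral_config(), ar_order = 8,
                         n_freq = 32, method = c("ar", "welch")) {
  method <- match.arg(method)
  series <- as_time_series(series)
  check_band(config, series$tr_seconds)
  x <- series$values
  if (ncol(x) != 2L) stop("estimate_csd expects exactly two regions")
  if (nrow(x) <= 4L * ar_order)
    stop(sprintf("series too short (%d rows) for AR order %d (need > %d)",
                 nrow(x), ar_order, 4L * ar_order))
  if (method == "welch") return(periodogram_grid_csd(series, config, n_freq))
  fit <- tryCatch(
    stats::ar(x, aic = FALSE, order.max = ar_order,
              method = "yule-walker", demean = TRUE),
    error = function(e) {
      # perfectly dependent regions make Yule-Walker singular; regularize
      # with a reproducible infinitesimal dither and refit
      old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
      set.seed(0)
      dither <- matrix(stats::rnorm(length(x)), nrow(x), ncol(x)) *
        rep(pmax(apply(x, 2, stats::sd), 1e-12) * 1e-3, each = nrow(x))
      stats::ar(x + dither, aic = FALSE, order.max = ar_order,
                method = "yule-walker", demean = TRUE)
    })
  Sigma <- (fit$var.pred + t(fit$var.pred)) / 2
  freqs <- default_freqs(n_freq, config)
  tr <- series$tr_seconds
  S <- array(complex(real = 0), dim = c(2, 2, length(freqs)))
  for (k in seq_along(freqs)) {
    Af <- diag(2) + 0i
    for (j in seq_len(ar_order))
      Af <- Af - fit$ar[j, , ] * exp(-2i * pi * freqs[k] * j * tr)
    Ainv <- solve(Af)
    Sk <- tr * Ainv %*% Sigma %*% Conj(t(Ainv))
    S[, , k] <- (Sk + Conj(t(Sk))) / 2
  }
  cross_spectra(freqs, S, series$region_names)
}

# bin-averaged cross-periodogram on the analysis grid
periodogram_grid_csd <- function(series, config, n_freq) {
  x <- series$values
  n <- nrow(x)
  tr <- series$tr_seconds
  xs <- sweep(x, 2, colMeans(x))
  X <- stats::mvfft(xs)
  f <- (0:(n - 1)) / (n * tr)
  P <- array(0i, c(2, 2, n))
  for (a in 1:2) for (b in 1:2)
    P[a, b, ] <- tr * X[, a] * Conj(X[, b]) / n
  grid <- default_freqs(n_freq, config)
  half <- diff(grid)[1] / 2
  S <- array(0i, c(2, 2, n_freq))
  for (k in seq_len(n_freq)) {
    sel <- which(f >= grid[k] - half & f < grid[k] + half & f > 0)
    if (length(sel) == 0L) sel <- which.min(abs(f - grid[k]))
    Sk <- apply(P[, , sel, drop = FALSE], c(1, 2), mean)
    S[, , k] <- (Sk + Conj(t(Sk))) / 2
  }
  cross_spectra(grid, S, series$region_names)
}

#' First-level priors for the spectral inversion
#'
#' Shrinkage priors on the four log scaling factors (mean 0 = the default
#' strengths; variance 1/16, i.e. SD 0.25 on the log scale) plus Gaussian
#' hyperpriors on the log amplitudes of the fluctuation and observation-noise
#' spectra and on the log precision of the spectral residuals.
#'
#' @param mean prior mean of the 4 connectivity parameters.
#' @param covariance 4x4 symmetric PSD prior covariance.
#' @param lambda_mean,lambda_var hyperpriors for the two log noise-amplitude
#'   scalings (neural, observation).
#' @param gamma_mean,gamma_var hyperprior for the residual hyperparameter
#'   (log precision under the Gaussian likelihood; same variance is used for
#'   the Whittle degrees-of-freedom parameter).
#' @param nu_mean hyperprior mean of `log(nu - 1)`, the Whittle effective
#'   degrees of freedom per frequency.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(mean = rep(0, 4), covariance = diag(1 / 16, 4),
                       lambda_mean = c(0, 0), lambda_var = c(1, 1),
                       gamma_mean = 0, gamma_var = 16, nu_mean = 2) {
  covariance <- (covariance + t(covariance)) / 2
  if (min(eigen(covariance, only.values = TRUE)$values) < 0)
    stop("prior covariance must be positive semidefinite")
  structure(list(mean = mean, covariance = covariance,
                 lambda_mean = lambda_mean, lambda_var = lambda_var,
                 gamma_mean = gamma_mean, gamma_var = gamma_var,
                 nu_mean = nu_mean),
            class = "prior_spec")
}

# stack the informative entries of a cross-spectrum:
# per frequency Re S11, Re S22, Re S12, Im S12
stack_csd <- function(csd_data) {
  S <- csd_data$csd
  as.numeric(rbind(Re(S[1, 1, ]), Re(S[2, 2, ]), Re(S[1, 2, ]), Im(S[1, 2, ])))
}

#' Percentage of explained variance of a cross-spectral fit
#'
#' `100 * (1 - ||vec(obs) - vec(pred)||^2 / ||vec(obs) - mean||^2)` over the
#' stacked real and imaginary parts of all cross-spectral entries. Can be
#' negative for fits worse than the grand mean.
#'
#' @param observed,predicted `cross_spectra` on the same frequency grid.
#' @return explained variance in percent.
#' @export
explained_variance <- function(observed, predicted) {
  if (!isTRUE(all.equal(observed$freqs, predicted$freqs)))
    stop("observed and predicted spectra must share the frequency grid")
  yo <- c(Re(as.vector(observed$csd)), Im(as.vector(observed$csd)))
  yp <- c(Re(as.vector(predicted$csd)), Im(as.vector(predicted$csd)))
  denom <- sum((yo - mean(yo))^2)
  if (denom <= 0) stop("zero-variance observed cross-spectrum")
  100 * (1 - sum((yo - yp)^2) / denom)
}

# prior pieces as a 7-parameter Gaussian: theta[4], lambda[2], and one
# residual hyperparameter (log precision for the gaussian likelihood,
# log(nu - 1) effective dof for the whittle likelihood)
full_prior <- function(priors, likelihood = "whittle") {
  P0 <- matrix(0, 7, 7)
  P0[1:4, 1:4] <- priors$covariance
  P0[5, 5] <- priors$lambda_var[1]
  P0[6, 6] <- priors$lambda_var[2]
  P0[7, 7] <- priors$gamma_var
  m7 <- if (likelihood == "whittle") priors$nu_mean else priors$gamma_mean
  list(mean = c(priors$mean, priors$lambda_mean, m7),
       cov = P0, inv = solve(P0), logdet = determinant(P0)$modulus[1])
}

#' Invert one subject's cross-spectra by variational Laplace
#'
#' Gauss-Newton / Fisher-scoring ascent on the variational free energy
#' `F = accuracy - complexity` of the spectral model: Gaussian prior over the
#' four log scaling factors, log noise amplitudes and a residual
#' hyperparameter; Gaussian (Laplace) posterior from the negative inverse
#' curvature at the mode. Steps that would decrease F are halved (so the
#' accepted-F trajectory is non-decreasing); iteration stops when |dF| < `tol`
#' for three consecutive accepted steps or after `max_iter` iterations.
#'
#' Two residual models are available. `"whittle"` (default) treats each
#' observed cross-spectral matrix as complex-Wishart around the model
#' prediction with an estimated effective degrees-of-freedom hyperparameter —
#' the natural likelihood for spectral estimates, weighting diagonal and
#' cross terms by their sampling precision. `"gaussian"` stacks the real and
#' imaginary cross-spectral entries and fits them with an isotropic
#' Gaussian residual whose log precision is estimated.
#'
#' @param observed a [cross_spectra()] object (validated: Hermitian PSD).
#' @param priors a [prior_spec()].
#' @param subject_id identifier carried into the result.
#' @param fixed fixed neural parameters.
#' @param hrf_params hemodynamic kernel parameters.
#' @param likelihood `"whittle"` or `"gaussian"` (see above).
#' @param tol free-energy convergence tolerance in nats (default 0.01).
#' @param max_iter maximum Gauss-Newton iterations (default 128).
#' @param data_weight weight of the data term; 0 returns the prior as
#'   posterior (no-data limit).
#' @return object of class `subject_posterior`: `mean` (4 named log scaling
#'   factors), `covariance` (4x4), `free_energy`, `explained_variance_pct`,
#'   plus the full 7-parameter posterior, the accepted free-energy
#'   trajectory, iteration count, convergence and improvement flags.
#' @export
invert_subject <- function(observed, priors = prior_spec(), subject_id = NULL,
                           fixed = fixed_neural_params(),
                           hrf_params = list(a1 = 6, a2 = 16, b = 1, ratio = 6),
                           likelihood = c("whittle", "gaussian"),
                           tol = 0.01, max_iter = 128, data_weight = 1) {
  likelihood <- match.arg(likelihood)
  validate_csd(observed, tol = 1e-6)
  pr <- full_prior(priors, likelihood)
  par_names <- c(CONNECTIONS, "lambda_neural", "lambda_obs",
                 if (likelihood == "whittle") "log_nu" else "gamma")

  if (data_weight == 0) {
    post <- structure(list(
      subject_id = subject_id,
      mean = stats::setNames(pr$mean[1:4], CONNECTIONS),
      covariance = pr$cov[1:4, 1:4],
      full_mean = stats::setNames(pr$mean, par_names),
      full_covariance = pr$cov,
      free_energy = 0, explained_variance_pct = NA_real_,
      f_trajectory = 0, iterations = 0L, converged = TRUE,
      improved = TRUE), class = "subject_posterior")
    return(post)
  }

  config <- spectral_config(min(observed$freqs), max(observed$freqs))
  base_noise <- noise_params(config = config, fixed = fixed)
  freqs <- observed$freqs
  nf <- length(freqs)

  predict_spectra <- function(phi) {
    noise <- base_noise
    noise$alpha_neural <- base_noise$alpha_neural * exp(phi[5])
    noise$alpha_obs <- base_noise$alpha_obs * exp(phi[6])
    predicted_csd(phi[1:4], fixed, noise, freqs, hrf_params)
  }

  ld2 <- function(S, k)  # log det of a 2x2 Hermitian slice
    log(max(Re(S[1, 1, k]) * Re(S[2, 2, k]) - Mod(S[1, 2, k])^2, 1e-300))

  if (likelihood == "gaussian") {
    y <- stack_csd(observed)
    accuracy <- function(phi, S) {
      e <- y - stack_csd(S)
      ssq <- sum(e * e)
      list(L = data_weight * (-0.5 * exp(phi[7]) * ssq +
                                0.5 * length(y) * phi[7] -
                                0.5 * length(y) * log(2 * pi)),
           e = e, ssq = ssq)
    }
    hyper_pieces <- function(phi, acc, J) {
      g7 <- data_weight * (0.5 * length(y) - 0.5 * exp(phi[7]) * acc$ssq)
      C77 <- data_weight * 0.5 * exp(phi[7]) * acc$ssq
      g16 <- data_weight * exp(phi[7]) * crossprod(J, acc$e)
      C16 <- data_weight * exp(phi[7]) * crossprod(J)
      list(g16 = g16, C16 = C16, g7 = g7, C77 = C77)
    }
  } else {
    P <- observed$csd
    ldP <- vapply(seq_len(nf), function(k) ld2(P, k), numeric(1))
    # batched 2x2 complex algebra over the frequency grid: a matrix field is
    # a list of four nf-vectors (m11, m12, m21, m22)
    as_field <- function(A3) list(A3[1, 1, ], A3[1, 2, ], A3[2, 1, ], A3[2, 2, ])
    mm2 <- function(X, Y) list(
      X[[1]] * Y[[1]] + X[[2]] * Y[[3]],
      X[[1]] * Y[[2]] + X[[2]] * Y[[4]],
      X[[3]] * Y[[1]] + X[[4]] * Y[[3]],
      X[[3]] * Y[[2]] + X[[4]] * Y[[4]])
    trprod2 <- function(X, Y)    # per-frequency trace of X %*% Y
      X[[1]] * Y[[1]] + X[[2]] * Y[[3]] + X[[3]] * Y[[2]] + X[[4]] * Y[[4]]
    Pf <- as_field(P)
    accuracy <- function(phi, S) {
      nu <- 1 + exp(phi[7])
      Sf <- as_field(S$csd)
      det <- Sf[[1]] * Sf[[4]] - Sf[[2]] * Sf[[3]]
      Sinv <- list(Sf[[4]] / det, -Sf[[2]] / det, -Sf[[3]] / det, Sf[[1]] / det)
      ldS <- log(pmax(Re(det), 1e-300))
      trk <- Re(trprod2(Sinv, Pf))
      L <- sum((nu - 2) * ldP - nu * ldS + 2 * nu * log(nu) - nu * trk) -
        nf * (log(pi) + lgamma(nu) + lgamma(nu - 1))
      list(L = data_weight * L, Sinv = Sinv, ldS = ldS, trk = trk, nu = nu)
    }
    hyper_pieces <- function(phi, acc, dS_list) {
      nu <- acc$nu
      Si <- acc$Sinv
      SiPSi <- mm2(mm2(Si, Pf), Si)
      M <- list(SiPSi[[1]] - Si[[1]], SiPSi[[2]] - Si[[2]],
                SiPSi[[3]] - Si[[3]], SiPSi[[4]] - Si[[4]])
      dF <- lapply(dS_list, as_field)
      Bs <- lapply(dF, function(d) mm2(Si, d))
      g16 <- vapply(1:6, function(a)
        nu * Re(sum(trprod2(M, dF[[a]]))), numeric(1))
      C16 <- matrix(0, 6, 6)
      for (a in 1:6) for (b in a:6) {
        v <- nu * Re(sum(trprod2(Bs[[a]], Bs[[b]])))
        C16[a, b] <- v
        C16[b, a] <- v
      }
      dLdnu <- sum(ldP - acc$ldS + 2 * log(nu) + 2 - acc$trk) -
        nf * (digamma(nu) + digamma(nu - 1))
      g7 <- data_weight * dLdnu * exp(phi[7])
      C77 <- data_weight *
        (nf * (trigamma(nu) + trigamma(nu - 1) - 2 / nu) * exp(phi[7])^2 + 1e-6)
      list(g16 = data_weight * g16, C16 = data_weight * C16, g7 = g7,
           C77 = C77)
    }
  }

  eval_state <- function(phi) {
    phi[7] <- min(max(phi[7], -16), 16)
    S <- tryCatch(predict_spectra(phi), error = function(e) NULL)
    if (is.null(S)) return(NULL)
    acc <- accuracy(phi, S)
    if (!is.finite(acc$L)) return(NULL)
    # forward differences of the prediction wrt the 6 model parameters
    h <- 1e-4
    if (likelihood == "gaussian") {
      y0 <- stack_csd(S)
      J <- matrix(0, length(y0), 6)
      for (j in 1:6) {
        phj <- phi
        phj[j] <- phj[j] + h
        Sj <- tryCatch(predict_spectra(phj), error = function(e) NULL)
        if (is.null(Sj)) return(NULL)
        J[, j] <- (stack_csd(Sj) - y0) / h
      }
      hp <- hyper_pieces(phi, acc, J)
    } else {
      dS_list <- vector("list", 6)
      for (j in 1:6) {
        phj <- phi
        phj[j] <- phj[j] + h
        Sj <- tryCatch(predict_spectra(phj), error = function(e) NULL)
        if (is.null(Sj)) return(NULL)
        dS_list[[j]] <- (Sj$csd - S$csd) / h
      }
      hp <- hyper_pieces(phi, acc, dS_list)
    }
    delta <- phi - pr$mean
    L <- acc$L - 0.5 * sum(delta * (pr$inv %*% delta)) -
      0.5 * pr$logdet - 3.5 * log(2 * pi)
    C <- matrix(0, 7, 7)
    C[1:6, 1:6] <- hp$C16
    C[7, 7] <- hp$C77
    C <- C + pr$inv
    g <- numeric(7)
    g[1:6] <- hp$g16
    g[7] <- hp$g7
    g <- g - pr$inv %*% delta
    ldC <- determinant(C)$modulus[1]
    Fval <- L - 0.5 * ldC + 3.5 * log(2 * pi)
    list(phi = phi, C = C, g = g, F = Fval, S = S)
  }

  state <- eval_state(pr$mean)
  if (is.null(state)) stop("model prediction failed at the prior mean")
  f_init <- state$F
  f_traj <- state$F
  small_steps <- 0L
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(state$C, state$g), error = function(e) {
      ridge <- diag(pmax(diag(state$C), 1) * 1e-8, 7)
      solve(state$C + ridge, state$g)
    })
    accepted <- FALSE
    scale <- 1
    for (half in 0:8) {
      cand <- eval_state(state$phi + scale * step)
      if (!is.null(cand) && is.finite(cand$F) && cand$F >= state$F - 1e-9) {
        dF <- cand$F - state$F
        state <- cand
        f_traj <- c(f_traj, cand$F)
        accepted <- TRUE
        small_steps <- if (abs(dF) < tol) small_steps + 1L else 0L
        break
      }
      scale <- scale / 2
    }
    if (!accepted || small_steps >= 3L) break
  }

  Sigma <- solve(state$C)
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE)
  Sigma <- ev$vectors %*% diag(pmax(ev$values, 1e-12)) %*% t(ev$vectors)

  improved <- state$F >= f_init - 1e-9
  if (!improved)
    warning("free energy did not improve over the prior-only baseline",
            call. = FALSE)
  structure(list(
    subject_id = subject_id,
    mean = stats::setNames(state$phi[1:4], CONNECTIONS),
    covariance = Sigma[1:4, 1:4],
    full_mean = stats::setNames(state$phi, par_names),
    full_covariance = Sigma,
    free_energy = state$F,
    explained_variance_pct = explained_variance(observed, state$S),
    predicted = state$S,
    f_trajectory = f_traj,
    iterations = iter,
    converged = small_steps >= 3L,
    improved = improved), class = "subject_posterior")
}

#' @export
print.subject_posterior <- function(x, ...) {
  cat(sprintf("Subject %s: F = %.2f, explained variance %.1f%%, %d iterations%s\n",
              if (is.null(x$subject_id)) "?" else x$subject_id,
              x$free_energy,
              x$explained_variance_pct, x$iterations,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  est <- rbind(`log scaling` = x$mean, `exp(mean)` = exp(x$mean))
  print(round(est, 3))
  invisible(x)
}

#' Cohort-level model diagnostics
#'
#' Mean and SD of per-subject explained variance, flagging subjects below the
#' 10% acceptability threshold (strictly below; "at least 10%" passes).
#' Low-EV subjects are not excluded: the group level down-weights them
#' automatically through their posterior precision.
#'
#' @param x list of `subject_posterior` objects, or a numeric vector of
#'   explained-variance percentages.
#' @param subject_ids optional ids for the numeric method.
#' @param threshold acceptability threshold in percent (default 10).
#' @return list of class `cohort_diagnostics`: `n`, `mean`, `sd`, `flagged`
#'   (ids below threshold), `explained_variance` table.
#' @export
cohort_diagnostics <- function(x, subject_ids = NULL, threshold = 10) {
  if (is.numeric(x)) {
    ev <- as.numeric(x)
    ids <- if (is.null(subject_ids)) seq_along(ev) else subject_ids
  } else {
    ev <- vapply(x, function(p) p$explained_variance_pct, numeric(1))
    ids <- vapply(x, function(p)
      if (is.null(p$subject_id)) NA_character_ else as.character(p$subject_id),
      character(1))
    if (anyNA(ids)) ids <- seq_along(ev)
  }
  if (length(ev) < 1L) stop("need at least one subject")
  structure(list(
    n = length(ev),
    mean = mean(ev),
    sd = if (length(ev) > 1L) stats::sd(ev) else NA_real_,
    flagged = ids[ev < threshold],
    threshold = threshold,
    explained_variance = data.frame(subject_id = ids,
                                    explained_variance_pct = ev)),
    class = "cohort_diagnostics")
}

#' @export
print.cohort_diagnostics <- function(x, ...) {
  cat(sprintf("Explained variance over %d subjects: mean %.2f%% (SD %.2f%%)\n",
              x$n, x$mean, x$sd))
  if (length(x$flagged) > 0L) {
    cat(sprintf("below %g%% (down-weighted by posterior precision at group level): %s\n",
                x$threshold, paste(x$flagged, collapse = ", ")))
  } else {
    cat(sprintf("all subjects at or above %g%%\n", x$threshold))
  }
  invisible(x)
}
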