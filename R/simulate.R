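ITEM_RANGES <- list(p1 = c(4, 7), p2 = c(1, 6), p3 = c(1, 6), n1 = c(1, 5),
                    n4 = c(1, 5), n6 = c(1, 4), g5 = c(1, 4), g9 = c(2, 6))

#' Generate a synthetic PANSS-8 clinical table
#'
#' Item scores are drawn uniformly within the per-item ranges observed in the
#' study cohort (e.g. P1 in 4..7 — acutely ill, untreated first-episode
#' samples show uniformly high delusion scores), about 40% of subjects carry
#' no antipsychotic exposure, and DUP is log-normal on the observed 1-72
#' month range with occasional missing values.
#'
#' @param n number of subjects (>= 2).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a validated `panss_cohort` data frame.
#' @export
generate_clinical <- function(n, seed = NULL) {
  if (n < 2L) stop("need at least 2 subjects")
  if (!is.null(seed)) set.seed(seed)
  rec <- data.frame(subject_id = seq_len(n))
  for (item in names(ITEM_RANGES)) {
    r <- ITEM_RANGES[[item]]
    rec[[item]] <- sample(seq(r[1], r[2]), n, replace = TRUE)
  }
  rec$medication <- stats::rbinom(n, 1, 0.6)   # ~40% with no exposure
  dup <- round(exp(stats::rnorm(n, mean = log(6), sd = 1.1)))
  dup <- pmin(pmax(dup, 1), 72)
  dup[stats::runif(n) < 2 / 19] <- NA          # occasional non-reliable DUP
  rec$dup_months <- dup
  suppressMessages(validate_panss(rec))
}

#' Ground truth of a synthetic study
#'
#' Second-level generating effects on the log scaling factors. The default
#' mirrors the qualitative published pattern: positive-symptom load increases
#' within-region inhibition and decreases between-region excitation
#' (+0.1 / -0.1 log units per symptom point on IE / EE connections), with no
#' medication or DUP effects and zero group-mean deviation from the priors.
#'
#' @param beta generating effects, regressors (constant, covariate,
#'   medication, dup) x 4 connections; `NULL` for the default above.
#' @param subject_sd between-subject SD of the log scaling factors around the
#'   design prediction (default 0.1).
#' @param noise_scale observation-noise amplitude relative to the SNR-10
#'   default (default 1).
#' @param model the generating covariate model label (default
#'   `"total positive"`); `"null"` means no symptom effect.
#' @param seed integer seed making the whole cohort reproducible.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(beta = NULL, subject_sd = 0.1, noise_scale = 1,
                            model = "total positive", seed = 1) {
  if (is.null(beta)) {
    beta <- rbind(constant   = c(0, 0, 0, 0),
                  covariate  = if (identical(model, "null")) c(0, 0, 0, 0)
                               else c(0.1, -0.1, -0.1, 0.1),
                  medication = c(0, 0, 0, 0),
                  dup        = c(0, 0, 0, 0))
    colnames(beta) <- CONNECTIONS
  }
  if (subject_sd < 0) stop("subject_sd must be >= 0")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  structure(list(beta = beta, subject_sd = subject_sd,
                 noise_scale = noise_scale, model = model, seed = seed),
            class = "synthetic_truth")
}

# band-limited fluctuation series by spectral synthesis: two-sided PSD
# alpha * f^-beta on [f_min, f_max], zero outside
synth_fluctuations <- function(n, dt, alpha, beta, config) {
  U <- complex(real = rep(0, n))
  kmax <- floor((n - 1) / 2)
  f <- (1:kmax) / (n * dt)
  in_band <- f >= config$f_min & f <= config$f_max
  ks <- (1:kmax)[in_band]
  amp <- sqrt(n * alpha * f[in_band]^(-beta) / dt)
  z <- complex(real = stats::rnorm(length(ks)),
               imaginary = stats::rnorm(length(ks))) / sqrt(2)
  U[ks + 1] <- amp * z
  U[n - ks + 1] <- Conj(U[ks + 1])
  Re(stats::fft(U, inverse = TRUE)) / n
}

#' Simulate a subject's two-region BOLD series
#'
#' Euler integration of the linear two-state stochastic system driven by
#' band-limited endogenous fluctuations (spectral synthesis of the power-law
#' spectrum on the analysis band), hemodynamic convolution of the excitatory
#' states with the double-gamma kernel, decimation to the repetition time and
#' additive white observation noise.
#'
#' @param theta a [connection_params()] vector (must yield a stable system).
#' @param noise_scale observation-noise amplitude relative to the SNR-10
#'   default; 0 gives noise-free BOLD.
#' @param n_timepoints number of volumes (default 360).
#' @param tr repetition time in seconds (default 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param dt integration step in seconds (default 0.1).
#' @param burn initial transient discarded, in seconds (default 64).
#' @param fixed,noise,config,hrf_params model constants as elsewhere.
#' @return a `bold_series` with `n_timepoints` rows and regions
#'   `dlpfc`, `striatum`.
#' @export
generate_subject_series <- function(theta, noise_scale = 1,
                                    n_timepoints = 360, tr = 1, seed = NULL,
                                    dt = 0.1, burn = 64,
                                    fixed = fixed_neural_params(),
                                    noise = NULL,
                                    config = spectral_config(),
                                    hrf_params = list(a1 = 6, a2 = 16, b = 1,
                                                      ratio = 6)) {
  if (!is.null(seed)) set.seed(seed)
  A <- system_jacobian(theta, fixed)
  if (!attr(A, "stable"))
    stop(sprintf("unstable connectivity (max Re eigenvalue %.3g >= 0)",
                 attr(A, "max_re_eig")))
  if (is.null(noise)) noise <- noise_params(config = config, fixed = fixed)
  n_sim <- as.integer(round((burn + n_timepoints * tr) / dt))
  u <- cbind(synth_fluctuations(n_sim, dt, noise$alpha_neural,
                                noise$beta_neural, config),
             synth_fluctuations(n_sim, dt, noise$alpha_neural,
                                noise$beta_neural, config))
  Ad <- diag(4) + dt * unclass(A)
  x <- .euler_integrate(Ad, u, dt)
  kernel <- hemodynamic_kernel(dt, hrf_params = hrf_params)
  bold <- dt * cbind(
    as.numeric(stats::filter(x[, 1], kernel, method = "convolution", sides = 1)),
    as.numeric(stats::filter(x[, 3], kernel, method = "convolution", sides = 1)))
  take <- seq(from = as.integer(round(burn / dt)) + 1L, by = as.integer(round(tr / dt)),
              length.out = n_timepoints)
  y <- bold[take, , drop = FALSE]
  if (anyNA(y)) stop("burn-in shorter than the hemodynamic kernel")
  if (noise_scale > 0) {
    sd_obs <- noise_scale * sqrt(noise$alpha_obs / tr)
    y <- y + matrix(stats::rnorm(length(y), sd = sd_obs), nrow(y), ncol(y))
  }
  time_series(y, tr_seconds = tr, region_names = c("dlpfc", "striatum"))
}

#' Generate a complete synthetic cohort
#'
#' Clinical covariates, ground-truth connectivity and (optionally) simulated
#' BOLD series with the statistical structure the analysis assumes: the
#' subject-level log scaling factors are the design-weighted generating
#' effects plus independent Gaussian between-subject variation,
#' `theta_i = X_i beta + N(0, subject_sd^2)`, with the design built (and
#' centered) exactly as in the group analysis.
#'
#' @param truth a [synthetic_truth()].
#' @param n number of subjects (default 19, the study size).
#' @param simulate_series if `FALSE`, skip the BOLD simulation and return
#'   only clinical records and true parameters (fast construction checks).
#' @param n_timepoints,tr,dt passed to [generate_subject_series()].
#' @return list of class `synthetic_cohort`: `clinical`, `design`, `theta`
#'   (n x 4 true log scaling factors), `series` (list of `bold_series` or
#'   `NULL`), `truth`.
#' @export
generate_cohort <- function(truth = synthetic_truth(), n = 19,
                            simulate_series = TRUE, n_timepoints = 360,
                            tr = 1, dt = 0.1) {
  set.seed(truth$seed)
  clinical <- generate_clinical(n, seed = NULL)
  design_model <- if (identical(truth$model, "null")) "total positive"
                  else truth$model
  design <- suppressMessages(build_design_matrix(clinical, design_model))
  X <- unclass(design)
  if (!identical(rownames(truth$beta), colnames(X)))
    truth$beta <- truth$beta[colnames(X), , drop = FALSE]
  theta <- X %*% truth$beta +
    matrix(stats::rnorm(n * 4, sd = truth$subject_sd), n, 4)
  colnames(theta) <- CONNECTIONS
  series <- NULL
  if (simulate_series) {
    series <- lapply(seq_len(n), function(i)
      generate_subject_series(theta[i, ], noise_scale = truth$noise_scale,
                              n_timepoints = n_timepoints, tr = tr,
                              seed = NULL, dt = dt))
  }
  structure(list(clinical = clinical, design = design, theta = theta,
                 series = series, truth = truth),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes `clinical.csv`, one `series_<id>.csv` per subject (two columns,
#' one row per volume) and `truth.json` into `dir`; the on-disk layout
#' matches what [run_pipeline()] consumes.
#'
#' @param cohort a [generate_cohort()] result with simulated series.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$series)) stop("cohort has no simulated series")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clin <- as.data.frame(cohort$clinical)
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  for (i in seq_len(nrow(clin))) {
    utils::write.csv(as.data.frame(cohort$series[[i]]$values),
                     file.path(dir, sprintf("series_%02d.csv", clin$subject_id[i])),
                     row.names = FALSE)
  }
  truth <- cohort$truth
  jsonlite::write_json(
    list(model = truth$model, subject_sd = truth$subject_sd,
         noise_scale = truth$noise_scale, seed = truth$seed,
         beta = as.data.frame(truth$beta),
         theta = as.data.frame(cohort$theta)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
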