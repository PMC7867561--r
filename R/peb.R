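#' Second-level (PEB) model of connectivity
#'
#' Hierarchical Bayesian linear model over the subjects' first-level
#' posteriors: each subject's four log scaling factors are modelled as a
#' design-weighted combination of group effects plus a between-subject random
#' effect with precision `pi_b`. Each subject enters as the Gaussian
#' likelihood message implied by their posterior (posterior precision minus
#' prior precision), so imprecise subjects are down-weighted automatically.
#' Group effects, the random-effect precision and the group free energy are
#' estimated by the empirical-prior recursion: given `pi_b`, the group
#' posterior is exact Gaussian algebra; `pi_b` is then re-optimized against
#' the group free energy (with a Gamma-style hyperprior), and the loop runs
#' until the free energy changes by less than `tol` (max `max_rounds`).
#' The re-estimated subject posteriors under the empirical group priors are
#' returned alongside.
#'
#' @param posteriors list of `subject_posterior` objects (one per design row,
#'   same order).
#' @param design a [build_design_matrix()] result (rows = subjects).
#' @param first_level_prior the [prior_spec()] used at the first level (needed
#'   to strip the prior from each posterior).
#' @param beta_prior_var prior variance of each group effect; defaults to 16
#'   for the constant column (weakly informative group mean) and 1/16 for
#'   covariate effects.
#' @param re_hyper Gamma-style hyperprior on `pi_b` (`shape`, `rate`); the
#'   default mode `(shape-1)/rate = 256` equals 16 times the mean first-level
#'   prior precision.
#' @param re_precision fix the random-effect precision at this value instead
#'   of optimizing it (mostly for closed-form checks).
#' @param tol,max_rounds convergence control of the recursion.
#' @return object of class `peb_model`: `name`, `design`, `beta_mean`
#'   (regressors x 4 connections), `beta_covariance` (4k x 4k, connection
#'   index fastest), `random_effect_precision`, `free_energy`, `n_subjects`,
#'   `subject_means` (re-estimated under the empirical priors), `rounds`.
#' @export
fit_peb <- function(posteriors, design,
                    first_level_prior = prior_spec(),
                    beta_prior_var = NULL,
                    re_hyper = list(shape = 2, rate = 1 / 256),
                    re_precision = NULL,
                    tol = 0.01, max_rounds = 16) {
  X <- unclass(design)
  n <- nrow(X)
  k <- ncol(X)
  if (length(posteriors) != n)
    stop("design has ", n, " rows but ", length(posteriors),
         " posteriors were given")
  ids <- vapply(posteriors, function(p)
    if (is.null(p$subject_id)) NA_character_ else as.character(p$subject_id),
    character(1))
  design_ids <- attr(design, "subject_id")
  if (!is.null(design_ids) && !anyNA(ids) &&
      !identical(as.character(design_ids), ids))
    stop("subject ordering of posteriors does not match the design matrix")
  if (qr(X)$rank < k) stop("rank-deficient design matrix")

  S0 <- first_level_prior$covariance
  m0 <- first_level_prior$mean
  iS0 <- solve(S0)
  # Gaussian likelihood message of each subject (prior stripped from posterior)
  msg <- lapply(posteriors, function(p) {
    iC <- solve(p$covariance)
    P <- (iC + t(iC)) / 2 - iS0
    es <- eigen((P + t(P)) / 2, symmetric = TRUE)
    P <- es$vectors %*% diag(pmax(es$values, 1e-6), 4) %*% t(es$vectors)
    mu <- solve(P, iC %*% p$mean - iS0 %*% m0)
    list(P = P, W0 = solve(P), mu = as.numeric(mu))
  })

  if (is.null(beta_prior_var)) {
    beta_prior_var <- ifelse(colnames(X) == "constant", 16, 1 / 16)
  }
  beta_prior_var <- rep(beta_prior_var, length.out = k)
  s_beta <- rep(beta_prior_var, each = 4)          # connection index fastest
  iS_beta <- diag(1 / s_beta, 4 * k)
  ld_S_beta <- sum(log(s_beta))

  group_pass <- function(pi_b) {
    Sb <- diag(1 / pi_b, 4)
    A <- iS_beta
    b <- numeric(4 * k)
    quad <- 0
    ldW <- 0
    for (i in seq_len(n)) {
      W <- msg[[i]]$W0 + Sb
      V <- solve(W)
      V <- (V + t(V)) / 2
      A <- A + kronecker(tcrossprod(X[i, ]), V)
      Vmu <- V %*% msg[[i]]$mu
      b <- b + kronecker(X[i, ], as.numeric(Vmu))
      quad <- quad + sum(msg[[i]]$mu * Vmu)
      ldW <- ldW + determinant(W)$modulus[1]
    }
    A <- (A + t(A)) / 2
    cholA <- chol(A)
    vbeta <- backsolve(cholA, forwardsolve(t(cholA), b))
    ld_A <- 2 * sum(log(diag(cholA)))
    logev <- -0.5 * (quad - sum(b * vbeta) + ldW + 4 * n * log(2 * pi) +
                       ld_S_beta + ld_A)
    logF <- logev + stats::dgamma(pi_b, shape = re_hyper$shape,
                                  rate = re_hyper$rate, log = TRUE)
    list(pi_b = pi_b, F = logF, logev = logev, vbeta = vbeta, A = A,
         chol = cholA)
  }

  if (!is.null(re_precision)) {
    state <- group_pass(re_precision)
    rounds <- 1L
  } else {
    state <- group_pass((re_hyper$shape - 1) / re_hyper$rate)  # hyperprior mode
    rounds <- 0L
    repeat {
      rounds <- rounds + 1L
      opt <- stats::optimize(function(lp) group_pass(exp(lp))$F,
                             interval = log(c(1e-2, 1e6)), maximum = TRUE,
                             tol = 1e-4)
      new_state <- group_pass(exp(opt$maximum))
      dF <- new_state$F - state$F
      if (new_state$F >= state$F) state <- new_state
      if (abs(dF) < tol || rounds >= max_rounds) break
    }
  }

  Sigma_beta <- chol2inv(state$chol)
  beta_mean <- matrix(state$vbeta, nrow = k, ncol = 4, byrow = TRUE,
                      dimnames = list(colnames(X), CONNECTIONS))

  # send the group posterior back as empirical priors and re-estimate subjects
  Sb <- diag(1 / state$pi_b, 4)
  subject_means <- matrix(NA_real_, n, 4, dimnames = list(NULL, CONNECTIONS))
  subject_covs <- vector("list", n)
  for (i in seq_len(n)) {
    M <- kronecker(matrix(X[i, ], nrow = 1), diag(4))   # 4 x 4k
    eta <- as.numeric(M %*% state$vbeta)
    Omega <- Sb + M %*% Sigma_beta %*% t(M)
    iOmega <- solve(Omega)
    Cn <- solve(msg[[i]]$P + iOmega)
    subject_means[i, ] <- as.numeric(
      Cn %*% (msg[[i]]$P %*% msg[[i]]$mu + iOmega %*% eta))
    subject_covs[[i]] <- (Cn + t(Cn)) / 2
  }

  structure(list(
    name = attr(design, "model"),
    design = design,
    beta_mean = beta_mean,
    beta_covariance = Sigma_beta,
    beta_prior_var = s_beta,
    random_effect_precision = state$pi_b,
    free_energy = state$F,
    n_subjects = n,
    subject_means = subject_means,
    subject_covariances = subject_covs,
    rounds = rounds), class = "peb_model")
}

#' @export
print.peb_model <- function(x, ...) {
  cat(sprintf("PEB model '%s': %d subjects, F = %.2f, pi_b = %.1f\n",
              x$name, x$n_subjects, x$free_energy,
              x$random_effect_precision))
  print(round(x$beta_mean, 4))
  invisible(x)
}

#' Free-energy Bayesian model comparison
#'
#' Log Bayes factors `ln BF_i = F_i - F_best` relative to the best model and
#' posterior model probabilities by normalized exponentiation of the free
#' energies under a flat prior over models. The probabilities sum to one;
#' each model's evidence is model-space independent, while the probabilities
#' renormalize as the space changes. `BF > 20` (ln BF about 3) corresponds to
#' `PP > 0.95`, the usual selection threshold.
#'
#' @param models list of `peb_model` objects (at least two, same subjects),
#'   or a named numeric vector of free energies.
#' @return object of class `model_comparison`: `names`, `free_energies`,
#'   `ln_bf`, `posterior_probs`.
#' @export
compare_models <- function(models) {
  if (is.numeric(models)) {
    F <- as.numeric(models)
    nm <- names(models)
    if (is.null(nm)) nm <- paste0("model", seq_along(F))
  } else {
    if (length(models) < 2L) stop("need at least 2 models to compare")
    F <- vapply(models, function(m) m$free_energy, numeric(1))
    nm <- vapply(models, function(m)
      if (is.null(m$name)) NA_character_ else m$name, character(1))
    ns <- vapply(models, function(m) m$n_subjects, numeric(1))
    if (length(unique(ns)) > 1L)
      stop("models were fitted on different numbers of subjects")
  }
  if (length(F) < 2L) stop("need at least 2 models to compare")
  ln_bf <- F - max(F)
  pp <- exp(ln_bf) / sum(exp(ln_bf))
  structure(list(names = unname(nm), free_energies = unname(F),
                 ln_bf = unname(ln_bf),
                 posterior_probs = stats::setNames(unname(pp), nm)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  tab <- data.frame(model = x$names, free_energy = round(x$free_energies, 2),
                    ln_bf = round(x$ln_bf, 2),
                    posterior_prob = round(x$posterior_probs, 4))
  print(tab[order(-tab$posterior_prob), ], row.names = FALSE)
  invisible(x)
}

#' Per-connection posterior probability of a covariate effect
#'
#' For each of the four connections, the posterior probability that the
#' covariate-of-interest effect is nonzero, computed by Bayesian model
#' reduction: the free-energy difference between the full model and the
#' reduced model with that single effect pruned (prior shrunk to a point at
#' zero), which for Gaussian posteriors is the Savage-Dickey ratio
#' `ln BF_reduced = ln q(beta_j = 0) - ln p(beta_j = 0)`. The reported sign
#' is the sign of the posterior effect mean.
#'
#' @param model a fitted `peb_model` with a `covariate` column (the null
#'   model has no covariate of interest and raises an error).
#' @return data frame with `connection`, `effect_mean`, `sign`,
#'   `posterior_prob`.
#' @export
effect_probabilities <- function(model) {
  X <- model$design
  r <- match("covariate", colnames(X))
  if (is.na(r))
    stop("model '", model$name,
         "' has no covariate of interest (null model?)")
  out <- data.frame(connection = CONNECTIONS, effect_mean = NA_real_,
                    sign = NA_real_, posterior_prob = NA_real_)
  for (c_i in 1:4) {
    idx <- (r - 1L) * 4L + c_i
    m <- model$beta_mean[r, c_i]
    s2 <- model$beta_covariance[idx, idx]
    s02 <- model$beta_prior_var[idx]
    ln_bf_red <- stats::dnorm(0, m, sqrt(s2), log = TRUE) -
      stats::dnorm(0, 0, sqrt(s02), log = TRUE)
    out$effect_mean[c_i] <- m
    out$sign[c_i] <- sign(m)
    out$posterior_prob[c_i] <- 1 / (1 + exp(ln_bf_red))
  }
  out
}
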