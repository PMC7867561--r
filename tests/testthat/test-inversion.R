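test_that("AR cross-spectra behave on independent, duplicated and AR(1) input", {
  set.seed(4)
  # independent long white-noise series: near-zero band coherence
  x <- matrix(rnorm(2 * 2048), 2048, 2)
  expect_lt(band_coherence(estimate_csd(x)), 0.2)

  # duplicated region: coherence ~ 1 on the whole grid
  x1 <- rnorm(360)
  Sdup <- estimate_csd(cbind(x1, x1))
  coh <- Mod(Sdup$csd[1, 2, ]) / sqrt(Re(Sdup$csd[1, 1, ]) * Re(Sdup$csd[2, 2, ]))
  expect_true(all(coh > 0.99))

  # AR(1) diagonal spectra match the closed form sigma^2/|1-phi e^-i2pif|^2
  set.seed(5)
  n <- 8192
  ab <- cbind(as.numeric(arima.sim(list(ar = 0.9), n)),
              as.numeric(arima.sim(list(ar = 0.9), n)))
  S <- estimate_csd(ab)
  closed <- 1 / Mod(1 - 0.9 * exp(-2i * pi * S$freqs))^2
  expect_lt(max(abs(Re(S$csd[1, 1, ]) / closed - 1)), 0.2)
  expect_lt(max(abs(Re(S$csd[2, 2, ]) / closed - 1)), 0.2)

  expect_silent(validate_csd(S))
  expect_error(estimate_csd(x[1:30, ]), "too short")
  expect_error(estimate_csd(matrix(rnorm(300), 100, 3)), "two regions")
})

test_that("inversion recovers generating parameters from noise-free spectra", {
  theta_star <- c(0.4, -0.3, 0.2, 0.1)
  obs <- predicted_csd(theta_star)
  post <- invert_subject(obs, subject_id = "sim")
  z <- (post$mean - theta_star) / sqrt(diag(post$covariance))
  expect_true(all(abs(z) < 3))
  expect_gte(post$explained_variance_pct, 95)
  expect_true(all(exp(post$mean) > 0))
  # accepted free-energy trajectory is non-decreasing
  expect_true(all(diff(post$f_trajectory) >= -1e-9))
})

test_that("inversion at the generating prior mean stays near zero", {
  obs <- predicted_csd(connection_params())
  post <- invert_subject(obs)
  expect_lt(max(abs(post$mean)), 0.2)
})

test_that("with the data term weighted to zero the posterior is the prior", {
  obs <- predicted_csd(c(0.3, 0, -0.2, 0.1))
  pr <- prior_spec()
  post <- invert_subject(obs, priors = pr, data_weight = 0)
  expect_equal(unname(post$mean), pr$mean, tolerance = 1e-8)
  expect_equal(post$covariance, pr$covariance, tolerance = 1e-8)
})

test_that("fitting beats the prior-only baseline on model-generated data", {
  # free-energy sanity: F(fitted) > F(first evaluation) for data from the model
  set.seed(6)
  wins <- 0L
  for (i in 1:10) {
    th <- rnorm(4, 0, 0.25)
    s <- generate_subject_series(th, seed = NULL)
    post <- suppressWarnings(invert_subject(estimate_csd(highpass_cosine(s))))
    if (post$free_energy > post$f_trajectory[1]) wins <- wins + 1L
    expect_true(all(diff(post$f_trajectory) >= -1e-9))
  }
  expect_gte(wins, 9L)
})

test_that("posterior covariance is PSD and exp(mean) positive", {
  set.seed(7)
  s <- generate_subject_series(rnorm(4, 0, 0.25), seed = NULL)
  post <- suppressWarnings(invert_subject(estimate_csd(highpass_cosine(s))))
  ev <- eigen(post$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= 0))
  expect_true(all(exp(post$mean) > 0))
})

test_that("explained variance follows its definition", {
  obs <- predicted_csd(c(0.2, -0.1, 0, 0.3))
  expect_equal(explained_variance(obs, obs), 100)

  flat <- obs
  yo <- c(Re(as.vector(obs$csd)), Im(as.vector(obs$csd)))
  flat$csd[] <- complex(real = mean(yo), imaginary = mean(yo))
  expect_equal(explained_variance(obs, flat), 0, tolerance = 1e-10)

  zero <- obs
  zero$csd[] <- complex(real = 1, imaginary = 1)
  expect_error(explained_variance(zero, obs), "zero-variance")
  other <- predicted_csd(c(0, 0, 0, 0), freqs = obs$freqs + 0.001)
  expect_error(explained_variance(obs, other), "frequency grid")
})

test_that("cohort diagnostics reproduce the published summary", {
  tab <- utils::read.csv(panss_fixture_path("model_diagnostics.csv"))
  d <- cohort_diagnostics(tab$explained_variance_pct, tab$subject_id)
  expect_equal(d$mean, 25.01, tolerance = 0.005)
  expect_equal(d$sd, 14.22, tolerance = 0.005)
  expect_equal(sort(d$flagged), c(6, 8))
  expect_equal(tab$explained_variance_pct[tab$subject_id == 6], 7.22)
  expect_equal(tab$explained_variance_pct[tab$subject_id == 8], 1.78)

  one <- cohort_diagnostics(50)
  expect_equal(one$mean, 50)
  expect_length(one$flagged, 0L)

  # threshold reads "at least 10%": exactly 10 is acceptable
  edge <- cohort_diagnostics(rep(10, 5))
  expect_equal(edge$mean, 10)
  expect_length(edge$flagged, 0L)
})

test_that("recovery ceiling reports the information limit of short records", {
  ce360 <- recovery_ceiling(360)
  ce4k <- recovery_ceiling(4096)
  expect_true(all(ce360$r_max < ce4k$r_max))
  expect_true(all(ce360$r_max < 0.5))     # study-length records are prior-bound
  expect_true(all(ce360$posterior_sd <= 0.25 + 1e-9))
})
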