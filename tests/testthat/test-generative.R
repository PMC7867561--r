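test_that("log-scaling parameterization enforces the sign constraints", {
  expect_equal(effective_strength(0, "between"), 0.125)
  expect_equal(effective_strength(0, "within"), -0.125)
  # exp value printed for a strong within-region estimate: 6.663 scales -1/8 Hz
  expect_equal(effective_strength(log(6.663), "within"), -0.832875,
               tolerance = 1e-9)
  set.seed(1)
  th <- rnorm(100, 0, 3)
  expect_true(all(effective_strength(th, "between") > 0))
  expect_true(all(effective_strength(th, "within") < 0))
})

test_that("the neural Jacobian has the two-state structure and is stable", {
  A <- system_jacobian(connection_params())
  expect_true(attr(A, "stable"))
  expect_lt(attr(A, "max_re_eig"), 0)
  # diagonal decays, positive EI, negative IE, EE only between E states
  expect_true(all(diag(A) < 0))
  expect_gt(A["I_dlpfc", "E_dlpfc"], 0)
  expect_gt(A["I_str", "E_str"], 0)
  expect_lt(A["E_dlpfc", "I_dlpfc"], 0)
  expect_lt(A["E_str", "I_str"], 0)
  expect_equal(A["I_dlpfc", "E_str"], 0)
  expect_equal(A["E_dlpfc", "I_str"], 0)

  # vanishing EE strengths decouple the regions into diagonal blocks
  Ad <- system_jacobian(connection_params(str_to_dlpfc = -50,
                                          dlpfc_to_str = -50))
  expect_lt(abs(Ad["E_dlpfc", "E_str"]), 1e-20)
  expect_lt(abs(Ad["E_str", "E_dlpfc"]), 1e-20)

  # IE entry becomes monotonically more negative in theta
  ie <- vapply(seq(-1, 1, by = 0.25), function(d)
    system_jacobian(connection_params(dlpfc_self = d))["E_dlpfc", "I_dlpfc"],
    numeric(1))
  expect_true(all(diff(ie) < 0))
})

test_that("hemodynamic transfer has the canonical low-pass shape", {
  expect_equal(hemodynamic_gain(numeric(0)), complex(0))
  # DC gain is the kernel integral, 1 - 1/ratio
  expect_equal(Mod(hemodynamic_gain(1e-12)), 5 / 6, tolerance = 1e-6)
  expect_lt(Mod(hemodynamic_gain(0.1)), Mod(hemodynamic_gain(0.01)))
  # closed form agrees with the numeric transform of the sampled kernel
  k <- hemodynamic_kernel(dt = 0.01, duration = 50)
  f <- 0.05
  num <- 0.01 * sum(k * exp(-2i * pi * f * (seq_along(k) - 1) * 0.01))
  expect_equal(hemodynamic_gain(f), num, tolerance = 1e-3)
})

test_that("predicted cross-spectra satisfy the Hermitian PSD invariants", {
  set.seed(2)
  for (i in 1:10) {
    th <- rnorm(4, 0, 0.4)
    S <- predicted_csd(th)
    expect_silent(validate_csd(S))
    expect_true(all(Re(apply(S$csd, 3, function(m) diag(m))) >= 0))
  }
})

test_that("decoupled regions predict zero cross-spectrum", {
  S <- predicted_csd(connection_params(str_to_dlpfc = -50, dlpfc_to_str = -50))
  expect_lt(max(Mod(S$csd[1, 2, ])), 1e-12)
  expect_lt(max(Mod(S$csd[2, 1, ])), 1e-12)
})

test_that("coupling strength monotonically increases the cross-spectrum", {
  band_s12 <- vapply(seq(-2, 0, by = 0.25), function(th_f2s) {
    S <- predicted_csd(connection_params(dlpfc_to_str = th_f2s),
                       noise = noise_params(alpha_obs = 0))
    sum(Mod(S$csd[1, 2, ]))
  }, numeric(1))
  expect_true(all(diff(band_s12) > 0))
})

test_that("predicted spectra are locally smooth in the parameters", {
  th0 <- c(0.2, -0.1, 0.3, 0)
  S0 <- predicted_csd(th0)
  for (j in 1:4) {
    th <- th0
    th[j] <- th[j] + 1e-6
    S1 <- predicted_csd(th)
    rel <- max(Mod(S1$csd - S0$csd) / pmax(Mod(S0$csd), 1e-12))
    expect_lt(rel, 1e-4)
  }
})

test_that("unstable systems are refused, not silently used", {
  A <- system_jacobian(connection_params(str_to_dlpfc = 3, dlpfc_to_str = 3))
  expect_false(attr(A, "stable"))
  expect_error(predicted_csd(connection_params(str_to_dlpfc = 3,
                                               dlpfc_to_str = 3)),
               "unstable")
})
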