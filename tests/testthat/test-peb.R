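test_that("null-design PEB on identical precise posteriors returns the consensus", {
  posts <- replicate(12, make_posterior(c(0.3, -0.2, 0.1, 0.2),
                                        diag(1e-7, 4)), simplify = FALSE)
  d0 <- structure(matrix(1, 12, 1, dimnames = list(NULL, "constant")),
                  model = "null", class = "peb_design")
  fit <- fit_peb(posts, d0)
  expect_equal(unname(fit$beta_mean[1, ]), c(0.3, -0.2, 0.1, 0.2),
               tolerance = 1e-6)
})

test_that("null-design PEB equals the closed-form precision-weighted mean", {
  set.seed(8)
  n <- 10
  posts <- lapply(1:n, function(i)
    make_posterior(rnorm(4, 0, 0.2), crossprod(matrix(rnorm(16, 0, 0.05), 4)) +
                     diag(0.005, 4)))
  d0 <- structure(matrix(1, n, 1, dimnames = list(NULL, "constant")),
                  model = "null", class = "peb_design")
  pi_b <- 100
  fit <- fit_peb(posts, d0, re_precision = pi_b)

  # independent closed form: strip the prior from each posterior, add the
  # random-effect variance, and combine under the group-mean prior
  S0i <- solve(diag(1 / 16, 4))
  A <- diag(1 / 16, 4)         # group-mean prior precision (variance 16)
  b <- rep(0, 4)
  for (p in posts) {
    iC <- solve(p$covariance)
    P <- iC - S0i
    mu <- solve(P, iC %*% p$mean)
    V <- solve(solve(P) + diag(1 / pi_b, 4))
    A <- A + V
    b <- b + V %*% mu
  }
  expect_equal(unname(fit$beta_mean[1, ]), as.numeric(solve(A, b)),
               tolerance = 1e-8)
})

test_that("PEB recovers a known covariate effect and flags only that cell", {
  set.seed(9)
  coh <- suppressMessages(load_panss(panss_fixture_path()))
  design <- suppressMessages(build_design_matrix(coh, "total positive"))
  X <- unclass(design)
  beta_true <- matrix(0, 4, 4)
  beta_true[2, 3] <- 0.5            # covariate effect on dlpfc_to_str only
  th <- X %*% beta_true + matrix(rnorm(19 * 4, 0, 0.05), 19, 4)
  # posteriors built the way a Bayesian first level produces them: a noisy
  # likelihood message combined with the shrinkage prior
  P_msg <- diag(84, 4)                        # message precision
  C_post <- solve(P_msg + diag(16, 4))        # posterior covariance
  posts <- lapply(1:19, function(i) {
    mu_msg <- th[i, ] + rnorm(4, 0, sqrt(1 / 84))
    make_posterior(C_post %*% (P_msg %*% mu_msg), C_post,
                   id = coh$subject_id[i])
  })

  fit <- fit_peb(posts, design)
  idx <- (2 - 1) * 4 + 3
  sd_eff <- sqrt(fit$beta_covariance[idx, idx])
  expect_lt(abs(fit$beta_mean[2, 3] - 0.5), 2 * sd_eff)

  ep <- effect_probabilities(fit)
  expect_gt(ep$posterior_prob[ep$connection == "dlpfc_to_str"], 0.95)
  expect_true(all(ep$posterior_prob[ep$connection != "dlpfc_to_str"] < 0.95))
})

test_that("imprecise subjects barely move the group estimate", {
  set.seed(10)
  n <- 10
  base_means <- matrix(rnorm(n * 4, 0, 0.2), n, 4)
  posts <- lapply(1:n, function(i) make_posterior(base_means[i, ], diag(0.01, 4)))
  d0 <- function(k) structure(matrix(1, k, 1, dimnames = list(NULL, "constant")),
                              model = "null", class = "peb_design")
  fit0 <- fit_peb(posts, d0(n), re_precision = 100)

  outlier <- make_posterior(base_means[1, ] + 1, diag(0.01, 4))
  blurred <- make_posterior(base_means[1, ] + 1, diag(1, 4))
  fit_precise <- fit_peb(c(posts, list(outlier)), d0(n + 1), re_precision = 100)
  fit_blurred <- fit_peb(c(posts, list(blurred)), d0(n + 1), re_precision = 100)

  shift_precise <- sqrt(sum((fit_precise$beta_mean - fit0$beta_mean)^2))
  shift_blurred <- sqrt(sum((fit_blurred$beta_mean - fit0$beta_mean)^2))
  expect_lt(shift_blurred, 0.05 * shift_precise)
})

test_that("PEB validates its inputs", {
  posts <- replicate(5, make_posterior(rep(0, 4)), simplify = FALSE)
  d <- structure(matrix(1, 4, 1, dimnames = list(NULL, "constant")),
                 model = "null", class = "peb_design")
  expect_error(fit_peb(posts, d), "4 rows")
  dd <- structure(cbind(constant = rep(1, 5), covariate = rep(1, 5)),
                  model = "x", class = "peb_design")
  expect_error(fit_peb(posts, dd), "rank")
  posts_id <- lapply(1:5, function(i) make_posterior(rep(0, 4), id = i))
  d5 <- structure(matrix(1, 5, 1, dimnames = list(NULL, "constant")),
                  model = "null", subject_id = c(1, 2, 3, 5, 4),
                  class = "peb_design")
  expect_error(fit_peb(posts_id, d5), "ordering")
})

test_that("free energies convert to calibrated posterior model probabilities", {
  # published group free energies for the two best models
  cmp <- compare_models(c("total positive" = -5961, "delusions" = -5966))
  expect_equal(cmp$ln_bf, c(0, -5))
  expect_equal(cmp$posterior_probs, c(0.9933, 0.0067), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(sum(cmp$posterior_probs), 1, tolerance = 1e-10)

  tie <- compare_models(c(a = -100, b = -100))
  expect_equal(tie$posterior_probs, c(0.5, 0.5), ignore_attr = TRUE)

  # the selection threshold: BF = 20 corresponds to PP = 20/21 > 0.95
  thr <- compare_models(c(win = log(20), lose = 0))
  expect_equal(thr$posterior_probs[[1]], 20 / 21, tolerance = 1e-12)
  expect_gt(thr$posterior_probs[[1]], 0.95)

  expect_error(compare_models(c(a = 1)), "at least 2")
})

test_that("model evidence is model-space independent while PPs renormalize", {
  two <- compare_models(c(a = -10, b = -12))
  three <- compare_models(c(a = -10, b = -12, c = -11))
  # evidences unchanged; relative Bayes factor between a and b preserved
  expect_equal(diff(two$free_energies), diff(three$free_energies[1:2]))
  expect_equal(two$ln_bf[2] - two$ln_bf[1],
               three$ln_bf[2] - three$ln_bf[1])
  expect_equal(sum(three$posterior_probs), 1, tolerance = 1e-10)
  expect_lt(three$posterior_probs[[1]], two$posterior_probs[[1]])
})

test_that("effect probabilities follow the Savage-Dickey evidence ratio", {
  fake_model <- function(mean_eff, sd_eff, prior_var = 1 / 16) {
    k <- 4
    bm <- matrix(0, k, 4, dimnames = list(c("constant", "covariate",
                                            "medication", "dup"), NULL))
    bm[2, ] <- mean_eff
    bcov <- diag(rep(sd_eff^2, 4 * k))
    design <- structure(matrix(1, 3, k,
                               dimnames = list(NULL, rownames(bm))),
                        model = "synthetic", class = "peb_design")
    structure(list(name = "synthetic", design = design, beta_mean = bm,
                   beta_covariance = bcov,
                   beta_prior_var = rep(prior_var, 4 * k)),
              class = "peb_model")
  }
  strong <- effect_probabilities(fake_model(mean_eff = 5 * 0.02, sd_eff = 0.02))
  expect_true(all(strong$posterior_prob > 0.99))

  nulleff <- effect_probabilities(fake_model(mean_eff = 0, sd_eff = 0.1))
  expect_true(all(nulleff$posterior_prob <= 0.5))

  d0 <- structure(matrix(1, 3, 1, dimnames = list(NULL, "constant")),
                  model = "null", class = "peb_design")
  m0 <- structure(list(name = "null", design = d0), class = "peb_model")
  expect_error(effect_probabilities(m0), "covariate")
})
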