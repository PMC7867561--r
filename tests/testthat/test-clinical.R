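test_that("the packaged cohort loads, validates, and matches printed values", {
  coh <- suppressMessages(load_panss(panss_fixture_path()))
  expect_s3_class(coh, "panss_cohort")
  expect_equal(nrow(coh), 19L)
  s9 <- coh[coh$subject_id == 9, ]
  expect_equal(s9$p1, 7)
  expect_equal(s9$g9, 6)
  # missing DUP flagged, not dropped
  expect_message(load_panss(panss_fixture_path()), "DUP missing")
  expect_equal(coh$subject_id[is.na(coh$dup_months)], c(12, 15))

  cs <- composite_scores(coh)
  expect_equal(cs$total_positive, coh$printed_positive)
  expect_equal(cs$total_negative, coh$printed_negative)
  expect_equal(cs$panss8_total, coh$printed_total)
})

test_that("clinical validation rejects malformed tables", {
  coh <- suppressMessages(load_panss(panss_fixture_path()))
  bad <- as.data.frame(coh)
  bad$p2[3] <- 8L
  expect_error(validate_panss(bad), "P2.*subject 3")
  dup <- as.data.frame(coh)
  dup$subject_id[2] <- dup$subject_id[1]
  expect_error(validate_panss(dup), "duplicate")

  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(load_panss(empty), "empty")
  writeLines("subject_id,p1", empty)
  expect_error(load_panss(empty), "no subjects|lacks columns")
})

test_that("composite scores implement the item sums", {
  one <- data.frame(subject_id = 1, p1 = 1, p2 = 1, p3 = 1, n1 = 1, n4 = 1,
                    n6 = 1, g5 = 1, g9 = 1, medication = 0, dup_months = 1)
  cs <- composite_scores(one)
  expect_equal(cs$total_positive, 3)
  expect_equal(cs$total_negative, 3)
  expect_equal(cs$panss8_total, 8)

  coh <- suppressMessages(load_panss(panss_fixture_path()))
  cs <- composite_scores(coh)
  expect_equal(cs$total_positive[coh$subject_id == 9], 15)
  expect_equal(cs$total_negative[coh$subject_id == 9], 8)
  expect_equal(cs$panss8_total[coh$subject_id == 9], 31)
  expect_equal(cs$total_positive[coh$subject_id == 15], 17)
  # acute first-episode profile of the cohort
  expect_equal(range(cs$total_positive), c(9, 17))
  expect_equal(range(coh$p1), c(4, 7))
})

test_that("paired t test matches closed form and stats::t.test", {
  # fixed example with hand-computable numbers: differences 1,2,3
  r <- paired_difference_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$mean_diff, 2)
  expect_equal(r$sd_diff, 1)
  expect_equal(r$t_stat, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2L)

  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    a <- sample(1:7, n, replace = TRUE)
    b <- sample(1:7, n, replace = TRUE)
    if (stats::sd(a - b) == 0) next
    r <- paired_difference_test(a, b)
    o <- paired_t_oracle(a, b)
    tt <- stats::t.test(a, b, paired = TRUE)
    expect_equal(r$mean_diff, o$mean, tolerance = 1e-10)
    expect_equal(r$sd_diff, o$sd, tolerance = 1e-10)
    expect_equal(r$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(c(r$ci_low, r$ci_high), as.numeric(tt$conf.int),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_lt(r$ci_low, r$mean_diff)
    expect_gt(r$ci_high, r$mean_diff)
  }
})

test_that("degenerate paired tests are error states, not infinities", {
  expect_warning(r <- paired_difference_test(c(3, 3, 3), c(1, 1, 1)),
                 "zero-variance")
  expect_false(r$ok)
  expect_equal(r$mean_diff, 2)
  expect_true(is.na(r$t_stat))
  expect_error(paired_difference_test(1:3, 1:4), "equal length")
  expect_error(paired_difference_test(1, 2), "at least 2")
})

test_that("design matrices follow the nine-model space", {
  coh <- suppressMessages(load_panss(panss_fixture_path()))
  expect_length(model_space(), 9L)

  d0 <- build_design_matrix(coh, "null")
  expect_equal(dim(d0), c(19L, 1L))
  expect_true(all(d0 == 1))

  expect_message(dtp <- build_design_matrix(coh, "total positive"),
                 "imputing mean DUP")
  expect_equal(dim(dtp), c(19L, 4L))
  expect_equal(colnames(dtp), c("constant", "covariate", "medication", "dup"))
  cs <- composite_scores(coh)
  expect_equal(dtp[, "covariate"],
               cs$total_positive - mean(cs$total_positive))
  # centering: non-constant columns have zero mean (imputation included)
  expect_equal(colMeans(dtp[, -1]), c(covariate = 0, medication = 0, dup = 0),
               tolerance = 1e-12)

  for (m in model_space()) {
    d <- suppressMessages(build_design_matrix(coh, m))
    expect_equal(qr(d)$rank, ncol(d))
  }
  expect_error(build_design_matrix(coh, "grandiosity"), "valid labels")
})
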