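# build a minimal long-format cohort directly from the change model
make_long <- function(n = 40, beta_tract = -0.5, noise = 0.2,
                      subject_sd = 0.15, seed = 1) {
  set.seed(seed)
  age <- runif(n, 20, 60)
  onset <- runif(n, 5, 19)
  vol <- runif(n, 0.05, 0.2)
  pre <- rnorm(n)
  tract <- runif(n)
  b <- rnorm(n, 0, subject_sd)
  d <- expand.grid(subject_id = seq_len(n), timepoint = c("3m", "12m"),
                   stringsAsFactors = FALSE)
  i <- d$subject_id
  d$age_surgery <- age[i]; d$age_onset <- onset[i]
  d$resection_volume <- vol[i]; d$pre_z <- pre[i]
  d$transection <- tract[i]
  d$change_z <- 0.1 + 0.25 * (d$timepoint == "12m") - 0.01 * age[i] -
    0.5 * vol[i] + 0.05 * pre[i] + beta_tract * tract[i] + b[i] +
    rnorm(nrow(d), 0, noise)
  d
}

test_that("noise-free data are reproduced exactly by the ML mixed model", {
  d <- make_long(n = 30, noise = 0, subject_sd = 0)
  # the optimizer's gradient check false-alarms when the residual variance
  # collapses to zero, so only the estimates are asserted here
  fit <- suppressWarnings(fit_change_lmm(d, tract_term = "transection"))
  est <- fit$coefficients[, "Estimate"]
  expect_equal(est[["transection"]], -0.5, tolerance = 1e-6)
  expect_equal(est[["timepoint12m"]], 0.25, tolerance = 1e-6)
  expect_equal(est[["age_surgery"]], -0.01, tolerance = 1e-6)
  expect_equal(est[["resection_volume"]], -0.5, tolerance = 1e-6)
  expect_equal(est[["pre_z"]], 0.05, tolerance = 1e-6)
  expect_equal(fit$n_obs, 60L)
})

test_that("well-posed noisy fits report convergence", {
  fit <- fit_change_lmm(make_long(n = 40, seed = 2),
                        tract_term = "transection")
  expect_true(fit$converged)
})

test_that("a tract term duplicating a covariate is rejected by name", {
  d <- make_long(n = 25)
  d$dupe <- d$resection_volume
  expect_error(fit_change_lmm(d, tract_term = "dupe"), "dupe")
})

test_that("missing outcomes drop rows but keep one-timepoint subjects", {
  d <- make_long(n = 30)
  d$change_z[d$subject_id == 1 & d$timepoint == "12m"] <- NA
  d$change_z[d$subject_id == 2] <- NA
  fit <- fit_change_lmm(d)
  expect_equal(fit$n_obs, 60L - 3L)
  expect_equal(fit$n_subjects, 29L)
})

test_that("random-intercept variance collapses without subject correlation", {
  d <- make_long(n = 80, subject_sd = 0, noise = 0.3, seed = 4)
  fit <- fit_change_lmm(d, tract_term = "transection")
  expect_lt(fit$ranef_variance, 0.01)
})

test_that("the LRT is zero for identical fits and counts one tract df", {
  d <- make_long(n = 40)
  f0 <- fit_change_lmm(d)
  f1 <- fit_change_lmm(d, tract_term = "transection")
  same <- likelihood_ratio_test(f0, f0)
  expect_equal(same$chi_sq, 0)
  expect_equal(same$p, 1)
  lrt <- likelihood_ratio_test(f0, f1)
  expect_equal(lrt$df, 1L)
  expect_gte(lrt$chi_sq, 0)

  d2 <- d[-1, ]
  f2 <- fit_change_lmm(d2)
  expect_error(likelihood_ratio_test(f2, f1), "different data")
})

test_that("the LRT is invariant to affine rescaling of covariates", {
  d <- make_long(n = 40, seed = 9)
  f0 <- fit_change_lmm(d); f1 <- fit_change_lmm(d, tract_term = "transection")
  chi_raw <- likelihood_ratio_test(f0, f1)$chi_sq
  d2 <- d
  d2$age_surgery <- d2$age_surgery * 100 - 40
  d2$transection <- d2$transection * 7 + 2
  g0 <- suppressWarnings(fit_change_lmm(d2))
  g1 <- suppressWarnings(fit_change_lmm(d2, tract_term = "transection"))
  chi_scaled <- likelihood_ratio_test(g0, g1)$chi_sq
  expect_equal(chi_raw, chi_scaled, tolerance = 1e-4)
})

test_that("logistic mixed model recovers a simulated disconnection log-odds", {
  set.seed(140)
  n <- 150
  disc <- rbinom(n, 1, 0.5)
  rtype <- sample(c("ATLR", "limited"), n, replace = TRUE)
  vol <- runif(n, 0.05, 0.2)
  b <- rnorm(n, 0, 0.3)
  d <- expand.grid(subject_id = seq_len(n), timepoint = c("3m", "12m"),
                   stringsAsFactors = FALSE)
  i <- d$subject_id
  eta <- -1.2 + 2.0 * disc[i] + 0.3 * (rtype[i] == "limited") + 1 * vol[i] +
    b[i]
  d$disconnected <- disc[i]; d$resection_type <- rtype[i]
  d$resection_volume <- vol[i]
  d$decline <- rbinom(nrow(d), 1, plogis(eta))
  fit <- fit_binary_glmm(d, outcome = "decline")
  est <- fit$coefficients["disconnected", "Estimate"]
  se <- fit$coefficients["disconnected", "Std. Error"]
  expect_lt(abs(est - 2.0), 3 * se)
  expect_false(fit$separation)
})

test_that("degenerate and separated binary outcomes are handled explicitly", {
  d <- data.frame(subject_id = 1:20,
                  disconnected = rep(c(0, 1), each = 10),
                  resection_type = "ATLR",
                  resection_volume = runif(20, 0.05, 0.2))
  d$all_one <- 1
  expect_error(fit_binary_glmm(d, outcome = "all_one"), "degenerate")
  d$bad <- rep(c(1, 2), 10)
  expect_error(fit_binary_glmm(d, outcome = "bad"), "0/1")

  # outcome identical to predictor: complete separation
  d$sep <- d$disconnected
  d$resection_type <- sample(c("ATLR", "limited"), 20, replace = TRUE)
  expect_warning(fit <- fit_binary_glmm(d, outcome = "sep"), "separation")
  expect_true(fit$separation)
  expect_true(is.finite(fit$coefficients["disconnected", "Estimate"]))
})

test_that("ILAE classes binarize to seizure freedom", {
  expect_identical(binarize_ilae(c(1L, 2L, 3L, 5L, 1L)),
                   c(1L, 0L, 0L, 0L, 1L))
  expect_identical(binarize_ilae(NA_integer_), NA_integer_)
  expect_error(binarize_ilae(0L), "invalid ILAE")
  expect_error(binarize_ilae(1.5), "invalid ILAE")
})
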