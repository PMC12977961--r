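test_that("Welch test matches the closed-form statistic", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  w <- welch_t_test(a, b)
  # independent closed-form computation
  se <- sqrt(var(a) / 3 + var(b) / 5)
  t_expect <- (mean(a) - mean(b)) / se
  df_expect <- (var(a) / 3 + var(b) / 5)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 5)^2 / 4)
  expect_equal(w$t, t_expect)
  expect_equal(w$df, df_expect)
  expect_equal(w$p, 2 * pt(-abs(t_expect), df_expect))

  # identical samples: t = 0, p = 1 (needs some variance)
  s <- c(1, 2, 3, 4)
  w0 <- welch_t_test(s, s)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)

  # antisymmetry
  w2 <- welch_t_test(b, a)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p, w$p)

  expect_error(welch_t_test(1, b), "at least 2")
  expect_error(welch_t_test(c(2, 2), c(3, 3)), "zero variance")
})

test_that("Welch df lies between min(n)-1 and n1+n2-2", {
  set.seed(17)
  for (rep in 1:20) {
    na <- sample(3:20, 1); nb <- sample(3:20, 1)
    w <- welch_t_test(rnorm(na, sd = runif(1, 0.5, 3)),
                      rnorm(nb, sd = runif(1, 0.5, 3)))
    expect_gte(w$df, min(na, nb) - 1 - 1e-9)
    expect_lte(w$df, na + nb - 2 + 1e-9)
  }
})

test_that("location and scale batch effects are removed exactly with EB off", {
  set.seed(23)
  n <- 40
  batch <- rep(c("A", "B"), each = n / 2)
  base <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  shifted <- base
  shifted[batch == "B", ] <- shifted[batch == "B", ] + 5   # pure offset
  adj <- combat_adjust(shifted, batch, eb = FALSE)
  for (j in 1:3)
    expect_lt(abs(mean(adj$adjusted[batch == "A", j]) -
                    mean(adj$adjusted[batch == "B", j])), 1e-10)

  scaled <- base
  scaled[batch == "B", ] <- sweep(scaled[batch == "B", ], 2,
                                  colMeans(scaled[batch == "B", ]), "-") * 2 +
    matrix(colMeans(scaled[batch == "B", ]), n / 2, 3, byrow = TRUE)
  adj2 <- combat_adjust(scaled, batch, eb = FALSE)
  for (j in 1:3)
    expect_lt(abs(var(adj2$adjusted[batch == "A", j]) -
                    var(adj2$adjusted[batch == "B", j])), 1e-8)
})

test_that("covariate-coded group effects survive harmonization", {
  set.seed(41)
  n <- 120
  batch <- rep(c("A", "B"), each = n / 2)
  group <- rep(c(0, 1), times = n / 2)   # orthogonal to batch
  true_diff <- 1.5
  y <- cbind(rnorm(n) + true_diff * group + 3 * (batch == "B"),
             rnorm(n) - true_diff * group + 2 * (batch == "B"))
  adj <- combat_adjust(y, batch, covariates = cbind(group = group),
                       eb = FALSE)
  d1 <- mean(adj$adjusted[group == 1, 1]) - mean(adj$adjusted[group == 0, 1])
  d2 <- mean(adj$adjusted[group == 1, 2]) - mean(adj$adjusted[group == 0, 2])
  expect_equal(d1, true_diff, tolerance = 0.3)
  expect_equal(d2, -true_diff, tolerance = 0.3)
  # batch means aligned after adjusting for the covariate
  r <- adj$adjusted[, 1] - true_diff * group
  expect_lt(abs(mean(r[batch == "A"]) - mean(r[batch == "B"])), 0.2)
})

test_that("re-harmonizing adjusted data finds no residual batch effect", {
  set.seed(67)
  n <- 60
  batch <- rep(c("A", "B"), each = n / 2)
  y <- matrix(rnorm(n * 4), n, 4)
  y[batch == "B", ] <- y[batch == "B", ] * 1.7 + 2
  adj <- combat_adjust(y, batch, eb = FALSE)
  re <- combat_adjust(adj$adjusted, batch, eb = FALSE)
  expect_lt(max(abs(re$gamma_hat)), 0.05)
  expect_lt(max(abs(re$delta_hat - 1)), 0.2)
})

test_that("EB shrinkage stays near the per-batch estimates and matches sva", {
  skip_if_not_installed("sva")
  set.seed(91)
  n <- 50; p <- 20
  batch <- rep(c("A", "B"), each = n / 2)
  y <- matrix(rnorm(n * p), n, p)
  y[batch == "B", ] <- y[batch == "B", ] * 1.3 + 0.8
  ours <- combat_adjust(y, batch, eb = TRUE)
  ref <- t(suppressMessages(sva::ComBat(dat = t(y), batch = batch)))
  expect_equal(unname(ours$adjusted), unname(ref), tolerance = 1e-3)
})

test_that("degenerate batch structures are rejected", {
  y <- matrix(rnorm(10), 5, 2)
  expect_error(combat_adjust(y, c("A", "A", "A", "A", "B")),
               "fewer than 2 subjects")
  expect_error(combat_adjust(y, rep("A", 5)), "at least 2 batches")
  # covariate confounded with batch
  batch <- c("A", "A", "A", "B", "B")
  expect_error(combat_adjust(y, batch,
                             covariates = cbind(as.numeric(batch == "B"))),
               "rank deficient")
})

test_that("the Welch gate harmonizes only significantly shifted features", {
  set.seed(13)
  n <- 80
  batch <- rep(c("A", "B"), each = n / 2)
  shifted <- rnorm(n) + 4 * (batch == "B")
  clean <- rnorm(n)
  out <- harmonize_features(cbind(shifted = shifted, clean = clean), batch,
                            eb = FALSE)
  expect_identical(out$harmonized_features, "shifted")
  expect_identical(out$adjusted[, "clean"], clean)   # untouched
  expect_lt(abs(mean(out$adjusted[batch == "A", "shifted"]) -
                  mean(out$adjusted[batch == "B", "shifted"])), 1e-8)
  expect_lt(out$p_values[["shifted"]], 0.05)
  expect_gt(out$p_values[["clean"]], 0.05)
})
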