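test_that("EM recovers a well-separated two-component mixture", {
  set.seed(7)
  x <- c(rnorm(400, 250, 40), rnorm(600, 900, 150))
  fit <- fit_em(x, seed = 7)
  expect_lt(abs(fit$lambda1 - 0.4), 0.05)
  expect_lt(abs(fit$mu1 - 250), 12)
  expect_lt(abs(fit$mu2 - 900), 25)
  expect_true(fit$converged)
  expect_lt(fit$mu1, fit$mu2)
  expect_equal(fit$lambda1 + fit$lambda2, 1, tolerance = 1e-12)
  # the log-likelihood trace never decreases
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(7)
  x <- c(rnorm(400, 250, 40), rnorm(600, 900, 150))
  fit <- fit_em(x, seed = 7)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mu_mc <- sort(mc$parameters$mean)
  expect_lt(abs(fit$mu1 - mu_mc[1]), 2)
  expect_lt(abs(fit$mu2 - mu_mc[2]), 2)
})

test_that("EM rejects degenerate inputs", {
  expect_error(fit_em(c(1, 2, 3, 4, 5)), "too small")
  expect_error(fit_em(rep(300, 50)), "zero-variance")
})

test_that("fits are shift-equivariant and order-invariant", {
  set.seed(7)
  x <- c(rnorm(300, 250, 40), rnorm(300, 900, 150))
  f0 <- fit_em(x, seed = 7)
  fs <- fit_em(x + 1234.5, seed = 7)
  expect_equal(fs$mu1, f0$mu1 + 1234.5, tolerance = 1e-6)
  expect_equal(fs$mu2, f0$mu2 + 1234.5, tolerance = 1e-6)
  expect_equal(fs$lambda1, f0$lambda1, tolerance = 1e-6)
  expect_equal(gaussian_intersection_cut(fs),
               gaussian_intersection_cut(f0) + 1234.5, tolerance = 1e-6)
  fp <- fit_em(sample(x), seed = 7)
  expect_equal(fp$mu1, f0$mu1, tolerance = 1e-9)
})

test_that("the density-crossing cut solves the component intersection", {
  # equal weights, equal variances: exact midpoint
  sym <- list(lambda1 = 0.5, lambda2 = 0.5, mu1 = 200, mu2 = 800,
              sigma1 = 100, sigma2 = 100)
  expect_identical(gaussian_intersection_cut(sym), 500)

  # unequal variances: root of the log-density quadratic, frozen from the
  # dense-grid oracle
  uneq <- list(lambda1 = 0.5, lambda2 = 0.5, mu1 = 0, mu2 = 4,
               sigma1 = 1, sigma2 = 2)
  cut <- gaussian_intersection_cut(uneq)
  expect_equal(cut, 1.6599, tolerance = 1e-3)
  expect_equal(cut, oracle_cut_grid(uneq), tolerance = 0.01)

  # dominated component: no crossing between the means
  dom <- list(lambda1 = 0.999, lambda2 = 0.001, mu1 = 300, mu2 = 310,
              sigma1 = 50, sigma2 = 50)
  expect_error(gaussian_intersection_cut(dom), "no crossing")
})

test_that("the cut matches a 0.01 ms grid oracle over random parameter sets", {
  set.seed(7)
  checked <- 0
  while (checked < 100) {
    fit <- list(lambda1 = runif(1, 0.15, 0.85), mu1 = runif(1, 100, 500),
                sigma1 = runif(1, 20, 120), mu2 = runif(1, 600, 1500),
                sigma2 = runif(1, 50, 300))
    fit$lambda2 <- 1 - fit$lambda1
    oracle <- oracle_cut_grid(fit, step = 0.01)
    if (is.na(oracle)) next  # no crossing for this draw; skip
    expect_lt(abs(gaussian_intersection_cut(fit) - oracle), 0.5)
    checked <- checked + 1
  }
})

test_that("mode assignment uses the per-duration cut with ties to first", {
  df <- make_trial_df(lat_is = c(-500, -230, NA, 300, -700),
                      fp = c(900, 900, 1400, 1900, 900))
  tab <- label_states3(trial_table(df), 170)
  # ws latencies: 400, 670, NA, 2200(v), 200
  cuts <- c("400" = 300, "900" = 400, "1400" = 500, "1900" = 600)
  out <- assign_modes(tab, cuts)
  expect_identical(out$state4, c("first", "second", "f", "v", "first"))
  # row 1 sits exactly at the 900 ms cut (ws 400): tie goes to first
  expect_identical(out$state4[1], "first")
  expect_error(assign_modes(tab, c("400" = 300)), "missing cut")
  # single unnamed cut applies everywhere (pooled fallback)
  out2 <- assign_modes(tab, 500)
  expect_identical(out2$state4, c("first", "second", "f", "v", "first"))
})

test_that("mixing proportions count first and second mode responses", {
  lat_is <- c(rep(-500, 3), rep(-100, 7))
  df <- make_trial_df(lat_is = lat_is, fp = rep(900, 10))
  tab <- label_states3(trial_table(df), 170)
  tab <- assign_modes(tab, c("400" = 650, "900" = 650, "1400" = 650, "1900" = 650))
  mp <- mixing_proportions(tab)
  row900 <- mp[mp$fp_ms == 900, ]
  expect_equal(row900$proportion_first, 0.3)
  expect_equal(row900$proportion_second, 0.7)
  expect_equal(row900$n, 10)
  expect_equal(row900$proportion_first + row900$proportion_second, 1, tolerance = 1e-12)
  # durations with no early saccades yield NA, not an error
  expect_true(all(is.na(mp$proportion_first[mp$fp_ms == 1400])))
})

test_that("per-duration fits fall back to pooling when a cell is small", {
  set.seed(7)
  by_dur <- list(
    "900" = c(rnorm(200, 400, 50), rnorm(200, 900, 80)),
    "1400" = c(rnorm(10, 450, 50), rnorm(10, 1300, 80)))  # too small
  res <- fit_mixture_cuts(by_dur, seed = 7, min_n = 30)
  expect_match(res$flags[["1400"]], "pooled")
  expect_equal(res$flags[["900"]], "")
  expect_true(res$cuts[["900"]] > 400 && res$cuts[["900"]] < 900)
})
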