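test_that("default parameter sets carry the published transition values", {
  p <- default_params("CONT", "NONE", "implicit")
  M3 <- collapse_latent4(p$latent_matrix)
  expect_equal(unname(M3["e", "e"]), 0.17)
  expect_equal(unname(M3["e", "v"]), 0.64)

  expect_equal(default_params("iPD", "OFF", "explicit")$latent_matrix["first", "first"], 0.30)
  expect_equal(default_params("iPD", "ON", "explicit")$latent_matrix["first", "first"], 0.20)
  expect_equal(default_params("CONT", "NONE", "explicit")$latent_matrix["second", "second"], 0.53)

  # deterministic: same call, identical params
  expect_identical(default_params("iPD", "ON", "implicit"),
                   default_params("iPD", "ON", "implicit"))
  expect_error(default_params("CONT", "ON", "implicit"), "unknown label")
  expect_error(default_params("iPD", "NONE", "explicit"), "unknown label")
})

test_that("sessions respect the task structure and are seed-deterministic", {
  p <- default_params("CONT", "NONE", "explicit", n_trials = 200, seed = 7)
  tab <- generate_session(p, "S1")
  expect_equal(nrow(tab), 200)
  expect_true(all(tab$fp_ms %in% c(400, 900, 1400, 1900)))
  expect_identical(tab$cue_ms, tab$fp_ms)  # explicit: cue equals foreperiod
  both <- !is.na(tab$lat_ws_ms)
  expect_true(all(abs(tab$lat_ws_ms[both] - tab$lat_is_ms[both] - tab$fp_ms[both]) < 1e-9))
  # failed latent trials carry no latency, visual trials always do
  latent <- attr(tab, "latent_states")
  expect_true(all(is.na(tab$lat_ws_ms[latent == "f"])))
  expect_true(all(!is.na(tab$lat_ws_ms[latent != "f"])))

  tab2 <- generate_session(p, "S1")
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  p2 <- p; p2$seed <- 8L
  expect_false(identical(as.data.frame(generate_session(p2, "S1")),
                         as.data.frame(tab)))
})

test_that("latent transition frequencies converge to the generating matrix", {
  # doubly stochastic matrix: every origin state visited ~n/4 times, so each
  # cell's sampling error is well inside the 0.02 band at n = 20000
  M <- rbind(c(0.4, 0.3, 0.2, 0.1), c(0.1, 0.4, 0.3, 0.2),
             c(0.2, 0.1, 0.4, 0.3), c(0.3, 0.2, 0.1, 0.4))
  p <- default_params("iPD", "ON", "explicit", n_trials = 20000, seed = 7,
                      n_blocks = 1, latent_matrix = M)
  tab <- generate_session(p, "S1")
  latent <- attr(tab, "latent_states")
  emp <- fit_transition_matrix(list(latent), states = rownames(p$latent_matrix))
  expect_true(all(abs(emp$probs - p$latent_matrix) < 0.02))
})

test_that("foreperiod frequencies are uniform within the binomial 99% band", {
  p <- default_params("CONT", "NONE", "implicit", n_trials = 4000, seed = 7)
  tab <- generate_session(p, "S1")
  counts <- table(tab$fp_ms)
  expect_setequal(names(counts), c("400", "900", "1400", "1900"))
  half_width <- qnorm(0.995) * sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(counts / 4000 - 0.25) < half_width))
})

test_that("visual trials never fall at or below the cut-off; well-separated early modes never exceed it", {
  p <- default_params("iPD", "OFF", "explicit", latency_profile = "well_separated",
                      n_trials = 5000, seed = 7)
  tab <- generate_session(p, "S1")
  latent <- attr(tab, "latent_states")
  expect_true(all(tab$lat_is_ms[latent == "v"] > 170))
  early <- latent %in% c("first", "second")
  expect_true(all(tab$lat_is_ms[early] <= 170))
})

test_that("EM recovers the generating early-saccade mixture per duration", {
  # boost early-state occupancy so one duration yields >= 1000 early latencies
  base <- default_params("CONT", "NONE", "explicit",
                         latency_profile = "well_separated")
  M <- matrix(rep(c(0.4, 0.4, 0.1, 0.1), 4), 4, byrow = TRUE)
  p <- generator_params("CONT", "NONE", "explicit", n_trials = 6000,
                        latent_matrix = M,
                        premature_sd_ms = base$premature_sd_ms,
                        antic_intercept_ms = base$antic_intercept_ms,
                        antic_slope = base$antic_slope,
                        antic_sd_ms = base$antic_sd_ms,
                        visual_sd_is_ms = base$visual_sd_is_ms,
                        truncate_early = TRUE, seed = 7)
  tab <- generate_session(p, "S1")
  latent <- attr(tab, "latent_states")
  sel <- tab$fp_ms == 1900 & latent %in% c("first", "second")
  x <- tab$lat_ws_ms[sel]
  expect_gt(length(x), 1000)
  fit <- fit_em(x, seed = 7)
  mu_first <- p$premature_mean_ms + p$premature_slope * 1900
  mu_second <- p$antic_intercept_ms + p$antic_slope * 1900
  expect_lt(abs(fit$mu1 - mu_first) / mu_first, 0.05)
  expect_lt(abs(fit$mu2 - mu_second) / mu_second, 0.05)
  expect_lt(abs(fit$lambda1 - mean(latent[sel] == "first")), 0.05)
})

test_that("cohorts have unique subjects and reproducible sub-seeding", {
  spec <- list(
    list(params = default_params("CONT", "NONE", "implicit", n_trials = 50),
         n_subjects = 18),
    list(params = default_params("iPD", "ON", "implicit", n_trials = 50),
         n_subjects = 20))
  tab <- generate_cohort(spec, master_seed = 7)
  expect_equal(length(unique(tab$subject_id)), 38)
  expect_equal(nrow(tab), 38 * 50)

  tab2 <- generate_cohort(spec, master_seed = 7)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  tab3 <- generate_cohort(spec, master_seed = 8)
  expect_false(identical(as.data.frame(tab), as.data.frame(tab3)))
  expect_identical(names(tab3), names(tab))

  expect_error(generate_cohort(list()), "empty")
})
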