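test_that("sequences are built per subject x condition x block in trial order", {
  df <- make_trial_df(lat_is = c(100, 150, 300, 310, NA, -50, 280),
                      fp = c(400, 900, 1400, 1900, 400, 900, 1400))
  tab <- label_states3(trial_table(df), 170)
  seqs <- build_sequences(tab, "three")
  expect_length(seqs, 1)
  expect_identical(seqs[[1]]$states, c("e", "e", "v", "v", "f", "e", "v"))

  df2 <- df; df2$subject_id <- "S2"
  tab2 <- label_states3(trial_table(rbind(df, df2)), 170)
  seqs2 <- build_sequences(tab2, "three")
  expect_length(seqs2, 2)  # never concatenated across subjects

  expect_error(build_sequences(tab, "four"), "state4")
})

test_that("the MLE transition matrix reproduces the worked sequence", {
  # the sequence e-e-v-v-f-e-v has 6 transitions
  tm <- fit_transition_matrix(list(c("e", "e", "v", "v", "f", "e", "v")),
                              states = c("e", "v", "f"))
  expect_equal(unname(tm$probs["e", ]), c(1 / 3, 2 / 3, 0))
  expect_equal(unname(tm$probs["v", ]), c(0, 1 / 2, 1 / 2))
  expect_equal(unname(tm$probs["f", ]), c(1, 0, 0))
  expect_equal(unname(tm$n_row), c(3, 2, 1))
  expect_true(all(abs(rowSums(tm$probs) - 1) < 1e-12))
  # CIs bracket the estimates
  ok <- !is.na(tm$probs)
  expect_true(all(tm$ci_low[ok] <= tm$probs[ok] + 1e-12))
  expect_true(all(tm$ci_high[ok] >= tm$probs[ok] - 1e-12))
})

test_that("unvisited rows are NA and transitions never cross sequences", {
  tm <- fit_transition_matrix(list(c("v", "v", "v")), states = c("e", "v", "f"))
  expect_equal(unname(tm$probs["v", "v"]), 1)
  expect_true(all(is.na(tm$probs["e", ])))
  expect_true(all(is.na(tm$probs["f", ])))

  tm2 <- fit_transition_matrix(list(c("e", "v"), c("v", "e")),
                               states = c("e", "v", "f"))
  expect_equal(unname(tm2$counts["e", "v"]), 1)
  expect_equal(unname(tm2$counts["v", "e"]), 1)
  expect_equal(unname(tm2$counts["v", "v"]), 0)  # no cross-sequence pair
  expect_error(fit_transition_matrix(list()), "empty")
})

test_that("pair counting matches the brute-force oracle on fuzzed sequence sets", {
  set.seed(7)
  states <- c("e", "v", "f")
  for (rep in 1:100) {
    n_seq <- sample(1:5, 1)
    seq_list <- lapply(seq_len(n_seq), function(i)
      sample(states, sample(2:40, 1), replace = TRUE))
    tm <- fit_transition_matrix(seq_list, states = states)
    expect_identical(tm$counts, oracle_pair_counts(seq_list, states))
  }
})

test_that("the alphabets yield 9 and 16 possible transitions", {
  p <- default_params("CONT", "NONE", "explicit", n_trials = 400, seed = 7,
                      latency_profile = "well_separated")
  tab <- label_states3(generate_session(p, "S1"))
  tab <- assign_modes(tab, 2000)  # everything early is first; enough for shape
  tm3 <- fit_transition_matrix(build_sequences(tab, "three"))
  tm4 <- fit_transition_matrix(build_sequences(tab, "four"))
  expect_equal(length(tm3$probs), 9)
  expect_equal(length(tm4$probs), 16)
})

test_that("the Markov property test accepts first-order and rejects second-order chains", {
  set.seed(7)
  # i.i.d. (zeroth-order, hence first-order) sequence
  iid <- sample(c("e", "v", "f"), 10000, replace = TRUE)
  res <- verify_markov_property(iid)
  expect_true(res$passed)
  expect_gt(res$p_value, 0.05)

  # second-order chain: next is e with prob 0.9 iff the previous two match
  s <- character(10000)
  s[1:2] <- c("e", "v")
  for (i in 3:10000) {
    p_e <- if (s[i - 1] == s[i - 2]) 0.9 else 0.1
    s[i] <- sample(c("e", "v", "f"), 1, prob = c(p_e, (1 - p_e) / 2, (1 - p_e) / 2))
  }
  res2 <- verify_markov_property(s)
  expect_false(res2$passed)
  expect_lt(res2$p_value, 1e-6)

  expect_error(verify_markov_property(sample(c("e", "v"), 10, replace = TRUE)),
               "too short")
})

test_that("row uniformity follows the closed-form chi-square", {
  r1 <- row_uniformity_test(c(10, 10, 10))
  expect_equal(r1$chi2, 0)
  expect_equal(r1$df, 2)
  expect_equal(r1$p_value, 1)

  r2 <- row_uniformity_test(c(30, 10, 20))
  expect_equal(r2$chi2, 10)
  expect_equal(r2$p_value, pchisq(10, 2, lower.tail = FALSE))
  expect_equal(r2$p_value, 0.006738, tolerance = 1e-4)

  expect_error(row_uniformity_test(c(0, 0, 0)), "zero row total")
})

test_that("probability comparisons build the Bonferroni-adjusted difference CI", {
  same <- compare_probabilities(0.5, 100, 0.5, 100, alpha = 0.01)
  expect_false(same$significant)

  big <- compare_probabilities(0.9, 200, 0.1, 200, alpha = 0.01, m_comparisons = 1)
  expect_equal(big$se, 0.03, tolerance = 1e-9)
  expect_equal(big$ci_low, 0.8 - qnorm(0.995) * 0.03, tolerance = 1e-9)
  expect_equal(big$ci_low, 0.723, tolerance = 1e-3)
  expect_equal(big$ci_high, 0.877, tolerance = 1e-3)
  expect_true(big$significant)

  # three planned comparisons at family alpha 0.01: per-comparison level 1 - 0.01/3
  bonf <- compare_probabilities(0.6, 100, 0.5, 100, alpha = 0.01, m_comparisons = 3)
  expect_equal(bonf$level, 1 - 0.01 / 3)
  expect_error(compare_probabilities(0.5, 0, 0.5, 10), "positive")
})

test_that("the subject screen excludes non-Markov subjects before pooling", {
  set.seed(7)
  P <- matrix(c(0.6, 0.3, 0.1,
                0.2, 0.6, 0.2,
                0.3, 0.3, 0.4), 3, byrow = TRUE,
              dimnames = list(c("e", "v", "f"), c("e", "v", "f")))
  good <- lapply(1:3, function(i) {
    structure(list(subject_id = paste0("G", i), condition = "implicit",
                   block = 1L, states = simulate_chain(P, 600),
                   alphabet = c("e", "v", "f")), class = "state_sequence")
  })
  # a strongly second-order subject
  s <- character(600); s[1:2] <- c("e", "v")
  for (i in 3:600) {
    p_e <- if (s[i - 1] == s[i - 2]) 0.95 else 0.05
    s[i] <- sample(c("e", "v", "f"), 1, prob = c(p_e, (1 - p_e) / 2, (1 - p_e) / 2))
  }
  bad <- structure(list(subject_id = "BAD", condition = "implicit", block = 1L,
                        states = s, alphabet = c("e", "v", "f")),
                   class = "state_sequence")
  fit <- pooled_transition_fit(c(good, list(bad)))
  expect_true("BAD" %in% fit$excluded)
  # the screen runs at alpha 0.05, so a first-order subject may occasionally
  # be a false positive; the strongly second-order one must always go
  expect_lte(length(fit$excluded), 2)
  expect_true(all(abs(fit$matrix$probs - P) < 0.1))
})
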