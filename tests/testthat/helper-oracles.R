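# Independent oracles used to check the package implementations. These are
# deliberately naive (loops, dense grids) and share no code with R/.

# Dense-grid crossing of the two weighted component densities: leftmost grid
# cell where component-1 dominance flips to component 2.
oracle_cut_grid <- function(fit, step = 0.01) {
  g <- seq(fit$mu1, fit$mu2, by = step)
  d <- fit$lambda1 * dnorm(g, fit$mu1, fit$sigma1) -
    fit$lambda2 * dnorm(g, fit$mu2, fit$sigma2)
  i <- which(d[-length(d)] >= 0 & d[-1] < 0)
  if (!length(i)) return(NA_real_)
  (g[i[1]] + g[i[1] + 1]) / 2
}

# Same objective as detect_cutoff, written independently.
oracle_breakpoint <- function(latencies, range, grid_ms = 1) {
  xg <- seq(range[1], range[2], by = grid_ms)
  yg <- sapply(xg, function(t) sum(latencies <= t))
  sses <- sapply(xg, function(b) {
    fit <- lm(yg ~ xg + pmax(xg - b, 0))
    sum(residuals(fit)^2)
  })
  xg[which.min(sses)]
}

# Brute-force pair counting within sequences (never across boundaries).
oracle_pair_counts <- function(seq_list, states) {
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(states, states))
  for (s in seq_list) {
    if (length(s) < 2) next
    for (i in 1:(length(s) - 1)) {
      counts[s[i], s[i + 1]] <- counts[s[i], s[i + 1]] + 1L
    }
  }
  counts
}

# Double-loop ECDF supremum distance.
oracle_ks_d <- function(x1, x2) {
  d <- 0
  for (t in c(x1, x2)) {
    d <- max(d, abs(mean(x1 <= t) - mean(x2 <= t)))
  }
  d
}

# Plain Markov chain simulator.
simulate_chain <- function(P, n, states = rownames(P), init = NULL) {
  s <- character(n)
  s[1] <- if (is.null(init)) sample(states, 1) else init
  for (i in seq_len(n - 1)) {
    s[i + 1] <- sample(states, 1, prob = P[s[i], ])
  }
  s
}

# A small hand-built valid trial data.frame (one subject, one block).
make_trial_df <- function(lat_is = c(150, -800, NA, 300, 171),
                          fp = c(400, 900, 1400, 1900, 400),
                          condition = "implicit") {
  n <- length(lat_is)
  data.frame(
    subject_id = "S1", group = "CONT", medication = "NONE",
    condition = condition, block = 1L, trial_index = seq_len(n),
    side = rep(c("left", "right"), length.out = n),
    fp_ms = fp,
    cue_ms = if (condition == "explicit") fp else NA_real_,
    lat_ws_ms = lat_is + fp, lat_is_ms = lat_is,
    state3 = NA_character_, state4 = NA_character_,
    stringsAsFactors = FALSE
  )
}

# Wrap a plain state vector as a minimal one-block sequence list.
as_seq <- function(states, id = "S1") {
  list(structure(list(subject_id = id, condition = "implicit", block = 1L,
                      states = states,
                      alphabet = sort(unique(states))),
                 class = "state_sequence"))
}

# Trapezoid integral (independent of the package internal).
trapezoid <- function(grid, values) {
  sum(diff(grid) * (values[-1] + values[-length(values)]) / 2)
}
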