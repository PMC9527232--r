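#' Build per-block trial-state sequences
#'
#' Each subject x condition x block yields one ordered sequence of trial
#' states; transitions never span subjects or blocks. The three-state
#' alphabet is `{e, v, f}` (early / visually-guided / failed), the
#' four-state alphabet `{first, second, v, f}` splits early saccades into
#' premature and anticipatory modes.
#'
#' @param table A labelled [trial_table()].
#' @param alphabet `"three"` (uses `state3`) or `"four"` (uses `state4`).
#' @return A list of `state_sequence` objects, each with fields
#'   `subject_id`, `condition`, `block`, `states`.
#' @export
build_sequences <- function(table, alphabet = c("three", "four")) {
  alphabet <- match.arg(alphabet)
  stopifnot(inherits(table, "trial_table"))
  col <- if (alphabet == "three") "state3" else "state4"
  if (anyNA(table[[col]])) {
    stop(sprintf("%s labels are missing; run the %s stage first", col,
                 if (col == "state3") "classification" else "mode-assignment"))
  }
  d <- as.data.frame(table)
  d <- d[order(d$subject_id, d$condition, d$block, d$trial_index), ]
  keys <- unique(d[, c("subject_id", "condition", "block")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- d$subject_id == keys$subject_id[i] &
      d$condition == keys$condition[i] & d$block == keys$block[i]
    structure(list(subject_id = keys$subject_id[i],
                   condition = keys$condition[i],
                   block = keys$block[i],
                   states = d[[col]][sel],
                   alphabet = if (alphabet == "three") STATES3 else STATES4),
              class = "state_sequence")
  })
}

# Harvest (previous, current, next) triplets and adjacent pairs from one or
# several sequences, never crossing sequence boundaries.
sequence_pairs <- function(seqs) {
  if (inherits(seqs, "state_sequence")) seqs <- list(seqs)
  froms <- character(); tos <- character()
  for (s in seqs) {
    st <- if (is.list(s)) s$states else s
    n <- length(st)
    if (n >= 2) {
      froms <- c(froms, st[-n])
      tos <- c(tos, st[-1])
    }
  }
  list(from = froms, to = tos)
}

sequence_triplets <- function(seqs) {
  if (inherits(seqs, "state_sequence")) seqs <- list(seqs)
  prevs <- character(); mids <- character(); nexts <- character()
  for (s in seqs) {
    st <- if (is.list(s)) s$states else s
    n <- length(st)
    if (n >= 3) {
      prevs <- c(prevs, st[1:(n - 2)])
      mids <- c(mids, st[2:(n - 1)])
      nexts <- c(nexts, st[3:n])
    }
  }
  list(prev = prevs, mid = mids, nxt = nexts)
}

#' Test the first-order Markov property
#'
#' For each state `s`, positions where the current state equals `s` are
#' stratified and the contingency table of (previous state) x (next state)
#' is tested for independence by Pearson chi-square: under a first-order
#' chain the next state is conditionally independent of the previous one
#' given the present. Statistics and degrees of freedom are summed over
#' strata; strata whose table collapses below 2x2 (a state never or almost
#' never visited) are skipped, with the degrees of freedom adjusted
#' accordingly.
#'
#' @param seqs A `state_sequence`, plain character vector, or list of
#'   either (pooled).
#' @param alpha Significance level (default 0.05, the conventional screen
#'   level for this test).
#' @param min_length Minimum total length (default 50).
#' @return An object of class `markov_property_result` with `statistic`,
#'   `df`, `p_value`, `passed` (`TRUE` when `p > alpha`).
#' @export
verify_markov_property <- function(seqs, alpha = 0.05, min_length = 50) {
  if (is.character(seqs)) seqs <- list(seqs)
  if (inherits(seqs, "state_sequence")) seqs <- list(seqs)
  total_len <- sum(vapply(seqs, function(s)
    length(if (is.list(s)) s$states else s), numeric(1)))
  if (total_len < min_length) {
    stop(sprintf("sequence too short for the Markov property test (%d < %d)",
                 total_len, min_length))
  }
  tri <- sequence_triplets(seqs)
  if (!length(tri$mid)) stop("no triplets available")
  stat <- 0; df <- 0
  for (s in unique(tri$mid)) {
    sel <- tri$mid == s
    tab <- table(tri$prev[sel], tri$nxt[sel])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) next
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- stat + sum((tab - expected)^2 / expected)
    df <- df + (nrow(tab) - 1) * (ncol(tab) - 1)
  }
  if (df == 0) stop("no testable stratum (all states visited too rarely)")
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 alpha = alpha, passed = p > alpha),
            class = "markov_property_result")
}

#' @export
print.markov_property_result <- function(x, ...) {
  cat(sprintf("Markov property test: chi2 = %.3f, df = %d, p = %.4g -> %s at alpha = %g\n",
              x$statistic, x$df, x$p_value,
              if (x$passed) "consistent with first-order" else "rejected",
              x$alpha))
  invisible(x)
}

#' Maximum-likelihood transition matrix with cellwise confidence intervals
#'
#' Counts within-sequence adjacent state pairs over all sequences (never
#' crossing subject or block boundaries), estimates transition
#' probabilities as row-normalised counts, and attaches per-cell intervals.
#' Rows for never-visited origin states are NA, not zero.
#'
#' @param seqs List of `state_sequence` objects (or character vectors).
#' @param states Ordered state alphabet; inferred from the first sequence's
#'   alphabet (or observed states) when NULL.
#' @param ci_level Confidence level for per-cell intervals (default 0.99).
#' @param ci_method `"wald"` (default): `p ± z sqrt(p(1-p)/n_row)` clipped
#'   to the unit interval; `"wilson"` for the Wilson score interval.
#' @return An object of class `transition_matrix` with `states`, `counts`,
#'   `probs`, `ci_low`, `ci_high`, `n_row`.
#' @export
fit_transition_matrix <- function(seqs, states = NULL, ci_level = 0.99,
                                  ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  if (is.character(seqs)) seqs <- list(seqs)
  if (inherits(seqs, "state_sequence")) seqs <- list(seqs)
  if (!length(seqs)) stop("empty sequence set")
  if (is.null(states)) {
    first <- seqs[[1]]
    states <- if (is.list(first) && !is.null(first$alphabet)) first$alphabet
              else sort(unique(unlist(lapply(seqs, function(s)
                if (is.list(s)) s$states else s))))
  }
  pr <- sequence_pairs(seqs)
  bad <- setdiff(unique(c(pr$from, pr$to)), states)
  if (length(bad)) stop("states outside the alphabet: ", paste(bad, collapse = ", "))
  counts <- table(factor(pr$from, levels = states),
                  factor(pr$to, levels = states))
  counts <- matrix(as.integer(counts), nrow = length(states),
                   dimnames = list(states, states))
  n_row <- rowSums(counts)
  probs <- counts / ifelse(n_row == 0, NA_real_, n_row)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  if (ci_method == "wald") {
    se <- sqrt(probs * (1 - probs) / n_row)
    ci_low <- pmax(probs - z * se, 0)
    ci_high <- pmin(probs + z * se, 1)
  } else {
    denom <- 1 + z^2 / n_row
    center <- (probs + z^2 / (2 * n_row)) / denom
    half <- z * sqrt(probs * (1 - probs) / n_row + z^2 / (4 * n_row^2)) / denom
    ci_low <- pmax(center - half, 0)
    ci_high <- pmin(center + half, 1)
  }
  structure(list(states = states, counts = counts, probs = probs,
                 ci_low = ci_low, ci_high = ci_high, n_row = n_row,
                 ci_level = ci_level, ci_method = ci_method),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Transition matrix (%d states; %s %g%% CIs)\n",
              length(x$states), x$ci_method, 100 * x$ci_level))
  print(round(x$probs, 3))
  cat("row totals:", paste(sprintf("%s=%d", x$states, x$n_row), collapse = ", "), "\n")
  invisible(x)
}

#' Chi-square test of row uniformity
#'
#' Tests whether the transitions out of one state are uniformly distributed
#' over the destinations (Pearson chi-square against equal expected counts,
#' df = k - 1).
#'
#' @param counts Non-negative integer vector of transition counts out of
#'   one state.
#' @return A list with `chi2`, `df`, `p_value`, `n`.
#' @export
row_uniformity_test <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("zero row total")
  k <- length(counts)
  expected <- n / k
  chi2 <- sum((counts - expected)^2 / expected)
  df <- k - 1
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE), n = n)
}

#' Compare two transition probabilities via the CI of their difference
#'
#' Builds the confidence interval of `p1 - p2` at level
#' `1 - alpha / m_comparisons` (Bonferroni across `m_comparisons` planned
#' comparisons) with standard error
#' `sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`; the difference is significant when
#' the interval excludes zero. This is the Schenker-Gentleman style
#' difference interval, which is less conservative than requiring the two
#' individual intervals not to overlap.
#'
#' @param p1,n1 First estimated probability and its row sample size.
#' @param p2,n2 Second estimated probability and its row sample size.
#' @param alpha Family significance level (default 0.01).
#' @param m_comparisons Number of planned comparisons (default 1).
#' @return A list with `diff`, `se`, `ci_low`, `ci_high`, `level`,
#'   `significant`.
#' @export
compare_probabilities <- function(p1, n1, p2, n2, alpha = 0.01,
                                  m_comparisons = 1) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, alpha > 0, alpha < 1,
            m_comparisons >= 1)
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  level <- 1 - alpha / m_comparisons
  z <- stats::qnorm(1 - (alpha / m_comparisons) / 2)
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  d <- p1 - p2
  ci <- c(d - z * se, d + z * se)
  list(diff = d, se = se, ci_low = ci[1], ci_high = ci[2], level = level,
       significant = (ci[1] > 0 || ci[2] < 0))
}

#' Screen subjects by the Markov property and fit a pooled matrix
#'
#' Applies [verify_markov_property()] per subject (pooling that subject's
#' block sequences) and fits the pooled transition matrix over the subjects
#' that pass, mirroring the convention of removing subjects whose sequences
#' are inconsistent with a first-order chain before pooling.
#'
#' @param seqs List of `state_sequence` objects.
#' @param screen_alpha Level of the per-subject screen (default 0.05).
#' @param ci_level,ci_method Passed to [fit_transition_matrix()].
#' @param min_length Minimum per-subject length to attempt the screen;
#'   shorter subjects are kept (too little data to reject).
#' @return A list with `matrix` (a `transition_matrix`), `excluded`
#'   (subject ids), `screen` (per-subject test results).
#' @export
pooled_transition_fit <- function(seqs, screen_alpha = 0.05, ci_level = 0.99,
                                  ci_method = "wald", min_length = 50) {
  subj <- vapply(seqs, function(s) s$subject_id, character(1))
  screen <- list(); excluded <- character()
  for (id in unique(subj)) {
    sub_seqs <- seqs[subj == id]
    res <- tryCatch(verify_markov_property(sub_seqs, alpha = screen_alpha,
                                           min_length = min_length),
                    error = function(e) NULL)
    screen[[id]] <- res
    if (!is.null(res) && !res$passed) excluded <- c(excluded, id)
  }
  kept <- seqs[!(subj %in% excluded)]
  if (!length(kept)) stop("all subjects excluded by the Markov screen")
  list(matrix = fit_transition_matrix(kept, ci_level = ci_level,
                                      ci_method = ci_method),
       excluded = excluded, screen = screen)
}
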