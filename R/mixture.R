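#' Fit a two-component Gaussian mixture by EM
#'
#' Decomposes a latency sample (WS clock) into a short-latency premature
#' component and a longer anticipatory component. The algorithm is standard
#' EM for a two-component univariate normal mixture: initial means at the
#' 25th/75th sample percentiles, both standard deviations at the sample sd,
#' weights 1/2; additional restarts perturb the initial means by up to ±10%
#' of the inter-initial-mean spread (seeded, additive so the whole fit is
#' shift-equivariant). Component standard deviations are floored at 1 ms to
#' keep the likelihood bounded on duplicated latencies. The best restart by
#' final log-likelihood wins, and components are returned ordered by mean.
#'
#' @param latencies Numeric latencies in ms.
#' @param tol Relative log-likelihood change for convergence (default 1e-8).
#' @param max_iter Maximum iterations per restart (default 1000).
#' @param restarts Number of restarts (default 5).
#' @param seed Seed for restart jitter.
#' @param min_n Minimum sample size (default 30).
#' @param sd_floor Lower bound on component sds in ms (default 1).
#'
#' @return An object of class `mixture_fit` with elements `lambda1`,
#'   `lambda2`, `mu1`, `mu2`, `sigma1`, `sigma2` (ordered so `mu1 < mu2`),
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `n`, and `cut_ms`
#'   (NA until [gaussian_intersection_cut()] is applied).
#' @export
fit_em <- function(latencies, tol = 1e-8, max_iter = 1000, restarts = 5,
                   seed = 7L, min_n = 30, sd_floor = 1) {
  x <- latencies[!is.na(latencies)]
  n <- length(x)
  if (n < min_n) stop(sprintf("sample too small for a mixture fit (n = %d < %d)", n, min_n))
  if (stats::sd(x) == 0) stop("zero-variance input: all latencies identical")

  mu_init <- as.numeric(stats::quantile(x, c(0.25, 0.75)))
  spread <- diff(mu_init)
  sd_init <- max(stats::sd(x), sd_floor)
  set.seed(seed)
  jitters <- matrix(stats::runif(2 * restarts, -0.1, 0.1) * spread,
                    ncol = 2)
  jitters[1, ] <- 0  # first restart uses the plain quantile initialisation

  best <- NULL
  n_degenerate <- 0L
  for (r in seq_len(restarts)) {
    fit <- em_once(x, mu_init + jitters[r, ], c(sd_init, sd_init),
                   c(0.5, 0.5), tol, max_iter, sd_floor)
    if (fit$degenerate) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    stop("all EM restarts degenerate (a component collapsed onto the sd floor)")
  }
  ord <- order(best$mu)
  structure(list(
    lambda1 = best$lambda[ord[1]], lambda2 = best$lambda[ord[2]],
    mu1 = best$mu[ord[1]], mu2 = best$mu[ord[2]],
    sigma1 = best$sigma[ord[1]], sigma2 = best$sigma[ord[2]],
    loglik = best$loglik, loglik_trace = best$trace,
    n_iter = best$n_iter, converged = best$converged,
    n = n, n_degenerate_restarts = n_degenerate,
    cut_ms = NA_real_
  ), class = "mixture_fit")
}

# One EM run. Returns parameters plus the per-iteration log-likelihood
# trace; flags degeneracy when a component collapses (sd on the floor with
# vanishing weight).
em_once <- function(x, mu, sigma, lambda, tol, max_iter, sd_floor) {
  n <- length(x)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d1 <- lambda[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- lambda[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    g <- d1 / tot
    lambda <- c(mean(g), 1 - mean(g))
    sw1 <- sum(g); sw2 <- n - sw1
    if (sw1 < 1e-10 || sw2 < 1e-10) {
      return(list(degenerate = TRUE))
    }
    mu <- c(sum(g * x) / sw1, sum((1 - g) * x) / sw2)
    sigma <- c(sqrt(sum(g * (x - mu[1])^2) / sw1),
               sqrt(sum((1 - g) * (x - mu[2])^2) / sw2))
    sigma <- pmax(sigma, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  degenerate <- (min(lambda) < 1e-4 && any(sigma <= sd_floor))
  list(mu = mu, sigma = sigma, lambda = lambda, loglik = trace[length(trace)],
       trace = trace, n_iter = length(trace), converged = converged,
       degenerate = degenerate)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component Gaussian mixture fit\n")
  cat(sprintf("  component 1: lambda %.3f, mu %.1f ms, sigma %.1f ms\n",
              x$lambda1, x$mu1, x$sigma1))
  cat(sprintf("  component 2: lambda %.3f, mu %.1f ms, sigma %.1f ms\n",
              x$lambda2, x$mu2, x$sigma2))
  cat(sprintf("  loglik %.2f after %d iteration(s)%s, n = %d\n", x$loglik,
              x$n_iter, if (x$converged) "" else " (not converged)", x$n))
  if (!is.na(x$cut_ms)) cat(sprintf("  density-crossing cut: %.2f ms\n", x$cut_ms))
  invisible(x)
}

#' Latency cut at the crossing of the two weighted component densities
#'
#' Solves `lambda1 * phi(x; mu1, sigma1) = lambda2 * phi(x; mu2, sigma2)`
#' (a quadratic in `x` after taking logs; linear when the variances are
#' equal) and returns the root in `(mu1, mu2)` at which dominance flips from
#' the first to the second component moving rightward.
#'
#' @param fit A `mixture_fit` (or any list with the six parameter fields and
#'   `mu1 < mu2`).
#' @return The cut latency in ms. With equal weights and equal variances
#'   this is exactly the midpoint of the means.
#' @export
gaussian_intersection_cut <- function(fit) {
  l1 <- fit$lambda1; l2 <- fit$lambda2
  m1 <- fit$mu1; m2 <- fit$mu2
  s1 <- fit$sigma1; s2 <- fit$sigma2
  stopifnot(m1 < m2, s1 > 0, s2 > 0, l1 > 0, l2 > 0)
  # log l1 - log s1 - (x-m1)^2/(2 s1^2) = log l2 - log s2 - (x-m2)^2/(2 s2^2)
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log((l1 * s2) / (l2 * s1))
  if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) stop("no crossing: identical components")
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("no crossing between the component means")
    roots <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
  }
  inside <- roots[roots > m1 & roots < m2]
  if (!length(inside)) stop("no crossing between the component means")
  dens <- function(x) l1 * stats::dnorm(x, m1, s1) - l2 * stats::dnorm(x, m2, s2)
  # keep the root where component 1 dominates on the left and 2 on the right
  eps <- (m2 - m1) * 1e-6
  flip <- vapply(inside, function(r) dens(r - eps) > 0 && dens(r + eps) < 0,
                 logical(1))
  if (any(flip)) inside[flip][1] else inside[1]
}

#' Assign first/second mode labels to early saccades
#'
#' Every `e` trial is labelled `first` if its WS-clock latency is at or
#' below the cut for its duration, `second` otherwise (ties go to the first
#' mode, a deterministic convention); `v` and `f` labels are copied through
#' to `state4`.
#'
#' @param table A labelled [trial_table()] (`state3` set).
#' @param cuts Named numeric vector mapping duration (ms, as character or
#'   numeric names `"400"`, `"900"`, ...) to a WS-clock cut latency. A
#'   single unnamed value is applied to every duration (pooled-fit
#'   fallback).
#' @return The table with `state4` filled.
#' @export
assign_modes <- function(table, cuts) {
  stopifnot(inherits(table, "trial_table"))
  if (anyNA(table$state3)) stop("state3 must be labelled first")
  durations <- sort(unique(table$fp_ms[table$state3 == "e"]))
  if (length(cuts) == 1 && is.null(names(cuts))) {
    cuts <- stats::setNames(rep(cuts, length(durations)), durations)
  }
  missing_cut <- setdiff(as.character(durations), names(cuts))
  if (length(missing_cut)) {
    stop("missing cut for duration(s): ", paste(missing_cut, collapse = ", "))
  }
  state4 <- table$state3
  is_e <- table$state3 == "e"
  cut_for <- unname(cuts[as.character(table$fp_ms[is_e])])
  state4[is_e] <- ifelse(table$lat_ws_ms[is_e] <= cut_for, "first", "second")
  table$state4 <- state4
  latent <- attr(table, "latent_states")
  out <- trial_table(as.data.frame(table), provenance = attr(table, "provenance"))
  attr(out, "latent_states") <- latent
  out
}

#' Mixing proportions of first and second mode responses
#'
#' For each group x condition (medication pooled by default, split with
#' `split_medication = TRUE`) and each duration, the proportion of early
#' saccades falling in each mode: count of first (or second) mode responses
#' over total first + second responses. Cells with no early saccades yield
#' NA proportions rather than an error.
#'
#' @param table A [trial_table()] with `state4` assigned.
#' @param split_medication Keep ON/OFF patient cells separate.
#' @return A data.frame of class `mixing_table` with columns `group`,
#'   `condition` (and `medication` if split), `fp_ms`, `proportion_first`,
#'   `proportion_second`, `n`.
#' @export
mixing_proportions <- function(table, split_medication = FALSE) {
  stopifnot(inherits(table, "trial_table"))
  if (anyNA(table$state4)) stop("state4 must be assigned first")
  d <- as.data.frame(table)
  key <- if (split_medication) {
    paste(d$group, d$medication, d$condition, sep = "|")
  } else {
    paste(d$group, d$condition, sep = "|")
  }
  rows <- list()
  for (cell in unique(key)) {
    dc <- d[key == cell, ]
    parts <- strsplit(cell, "|", fixed = TRUE)[[1]]
    for (dur in FP_VALUES) {
      s4 <- dc$state4[dc$fp_ms == dur & dc$state4 %in% c("first", "second")]
      n <- length(s4)
      rows[[length(rows) + 1L]] <- data.frame(
        group = parts[1],
        medication = if (split_medication) parts[2] else "pooled",
        condition = parts[length(parts)],
        fp_ms = dur,
        proportion_first = if (n) mean(s4 == "first") else NA_real_,
        proportion_second = if (n) mean(s4 == "second") else NA_real_,
        n = n, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mixing_table", "data.frame")
  out
}

#' Per-duration mixture fits with density-crossing cuts
#'
#' Fits the two-component mixture to the WS-clock latencies of early
#' saccades separately for each duration within a group x condition cell.
#' Cells with fewer than `min_n` early saccades fall back to a fit pooled
#' across durations (flagged `pooled = TRUE`), whose cut is reused for the
#' missing durations. If the density-crossing cut does not exist for a fit,
#' the midpoint of the component means is used and flagged.
#'
#' @param latencies_by_duration Named list mapping duration to WS-clock
#'   latency vectors.
#' @inheritParams fit_em
#' @return A list with elements `fits` (per-duration `mixture_fit` or NULL),
#'   `cuts` (named vector of WS-clock cuts), and `flags` (per-duration
#'   character notes).
#' @export
fit_mixture_cuts <- function(latencies_by_duration, tol = 1e-8,
                             max_iter = 1000, restarts = 5, seed = 7L,
                             min_n = 30, sd_floor = 1) {
  durations <- names(latencies_by_duration)
  pooled <- unlist(latencies_by_duration, use.names = FALSE)
  pooled_fit <- NULL
  fits <- stats::setNames(vector("list", length(durations)), durations)
  cuts <- stats::setNames(rep(NA_real_, length(durations)), durations)
  flags <- stats::setNames(rep("", length(durations)), durations)
  cut_of <- function(fit) {
    tryCatch(gaussian_intersection_cut(fit),
             error = function(e) structure((fit$mu1 + fit$mu2) / 2,
                                           midpoint = TRUE))
  }
  for (dur in durations) {
    x <- latencies_by_duration[[dur]]
    if (length(x) >= min_n && stats::sd(x) > 0) {
      fit <- fit_em(x, tol, max_iter, restarts, seed, min_n, sd_floor)
      cut <- cut_of(fit)
      fits[[dur]] <- fit
      cuts[dur] <- as.numeric(cut)
      if (isTRUE(attr(cut, "midpoint"))) flags[dur] <- "midpoint fallback (no crossing)"
    } else {
      if (is.null(pooled_fit)) {
        if (length(pooled) < min_n) stop("too few early saccades even pooled")
        pooled_fit <- fit_em(pooled, tol, max_iter, restarts, seed, min_n, sd_floor)
      }
      cut <- cut_of(pooled_fit)
      fits[[dur]] <- pooled_fit
      cuts[dur] <- as.numeric(cut)
      flags[dur] <- paste0("pooled fit (n = ", length(x), " < ", min_n, ")",
                           if (isTRUE(attr(cut, "midpoint"))) "; midpoint fallback")
    }
    fits[[dur]]$cut_ms <- cuts[dur]
  }
  list(fits = fits, cuts = cuts, flags = flags)
}
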