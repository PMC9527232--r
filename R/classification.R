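#' Detect saccades in a gaze-position trace
#'
#' Velocity is estimated by central differences after a 5-sample moving
#' average smooth, and a saccade onset is recorded at the first sample of
#' each episode during which absolute velocity stays at or above the
#' threshold.
#'
#' @param trace Numeric vector of gaze positions (degrees), uniformly
#'   sampled.
#' @param sample_rate_hz Sampling rate in Hz (default 1000).
#' @param threshold_deg_s Velocity threshold in deg/s (default 30).
#' @param smooth_window Moving-average window in samples (odd; default 5).
#' @return Numeric vector of onset times in ms (possibly empty).
#' @export
detect_saccades <- function(trace, sample_rate_hz = 1000,
                            threshold_deg_s = 30, smooth_window = 5) {
  stopifnot(is.numeric(trace), threshold_deg_s > 0, sample_rate_hz > 0,
            smooth_window >= 1, smooth_window %% 2 == 1)
  if (length(trace) < smooth_window + 2) {
    stop("trace shorter than the smoothing window")
  }
  sm <- stats::filter(trace, rep(1 / smooth_window, smooth_window), sides = 2)
  sm <- as.numeric(sm)
  # pad the filter's NA edges with the nearest smoothed value
  first_ok <- which(!is.na(sm))[1]
  last_ok <- max(which(!is.na(sm)))
  sm[seq_len(first_ok - 1)] <- sm[first_ok]
  if (last_ok < length(sm)) sm[(last_ok + 1):length(sm)] <- sm[last_ok]
  dt <- 1 / sample_rate_hz
  n <- length(sm)
  vel <- c(NA, (sm[3:n] - sm[1:(n - 2)]) / (2 * dt), NA)
  supra <- !is.na(vel) & abs(vel) >= threshold_deg_s
  onsets <- which(supra & !c(FALSE, supra[-n]))
  (onsets - 1) * 1000 * dt
}

#' Cut-off detection result
#'
#' @param cutoff_ms Cut-off latency on the IS clock.
#' @param method `"breakpoint"` if detected from the data, `"fixed"` if the
#'   configured default was used (fallback or by request).
#' @param sse Residual sum of squares of the two-segment fit (NA for fixed).
#' @param n Sample size used.
#' @param reason Optional note on why a fallback was taken.
#' @return An object of class `cutoff_result`.
#' @export
cutoff_result <- function(cutoff_ms, method = c("breakpoint", "fixed"),
                          sse = NA_real_, n = 0L, reason = NULL) {
  method <- match.arg(method)
  structure(list(cutoff_ms = cutoff_ms, method = method, sse = sse,
                 n = as.integer(n), reason = reason),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Cut-off: %.1f ms (%s%s), n = %d\n", x$cutoff_ms, x$method,
              if (!is.null(x$reason)) paste0("; ", x$reason) else "", x$n))
  invisible(x)
}

#' Detect the early/visual latency cut-off
#'
#' Fits a continuous two-segment piecewise-linear model to the empirical
#' cumulative count curve of IS-clock latencies (cumulative count evaluated
#' on a uniform latency grid across the search window) by least squares over
#' a grid of candidate breakpoints, and returns the breakpoint with minimal
#' residual — the "abrupt slope change" where the
#' dense visually-guided mass takes over from the sparse early mass. Ties go
#' to the smaller breakpoint.
#'
#' Degenerate inputs (fewer than 50 latencies, or a breakpoint with slope
#' contrast below `min_slope_ratio`, as in a unimodal visual-only sample)
#' yield a fixed-cut fallback flagged in the result.
#'
#' @param latencies_is Numeric IS-clock latencies in ms.
#' @param range Length-2 numeric search interval for the breakpoint (ms).
#' @param grid_ms Grid step in ms (default 1).
#' @param fixed_cutoff_ms Fallback cut-off (default 170).
#' @param min_slope_ratio Minimum right/left slope ratio for a detection to
#'   count (default 3).
#' @return A [cutoff_result()].
#' @export
detect_cutoff <- function(latencies_is, range = c(0, 300), grid_ms = 1,
                          fixed_cutoff_ms = 170, min_slope_ratio = 3) {
  latencies_is <- latencies_is[!is.na(latencies_is)]
  n <- length(latencies_is)
  if (n < 50) {
    return(cutoff_result(fixed_cutoff_ms, "fixed", n = n,
                         reason = "fewer than 50 latencies"))
  }
  stopifnot(length(range) == 2, range[1] < range[2], grid_ms > 0)
  if (range[1] < min(latencies_is) || range[2] > max(latencies_is)) {
    return(cutoff_result(fixed_cutoff_ms, "fixed", n = n,
                         reason = "search range outside observed support"))
  }
  # cumulative count evaluated on a uniform latency grid, so every
  # millisecond of the curve carries equal weight in the fit (a per-point
  # fit would be dominated by the dense visually-guided mass)
  xg <- seq(range[1], range[2], by = grid_ms)
  yg <- findInterval(xg, sort(latencies_is))
  best <- NULL
  for (b in xg) {
    hinge <- pmax(xg - b, 0)
    fit <- stats::lm.fit(cbind(1, xg, hinge), yg)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(b = b, sse = sse,
                   slope_left = fit$coefficients[2],
                   slope_right = fit$coefficients[2] + fit$coefficients[3])
    }
  }
  ratio <- best$slope_right / best$slope_left
  if (!is.finite(ratio) && best$slope_left <= 0 && best$slope_right > 0) {
    ratio <- Inf  # flat-then-rising counts as maximal contrast
  }
  if (!is.finite(ratio) || ratio < min_slope_ratio) {
    return(cutoff_result(fixed_cutoff_ms, "fixed", sse = best$sse, n = n,
                         reason = sprintf("low breakpoint contrast (slope ratio %.2f)",
                                          ratio)))
  }
  cutoff_result(best$b, "breakpoint", sse = best$sse, n = n)
}

#' Label trials as early, visual or failed
#'
#' `state3` is `e` if the IS-clock latency is at or below the cut-off
#' (including negative latencies, i.e. saccades during the foreperiod), `v`
#' if above it, and `f` if no latency was recorded. Saccades slower than
#' `max_visual_latency_ms` are implausible as visually guided responses and
#' are relabelled `f` (their latencies are removed so the labelled table
#' still satisfies the state/latency invariant). Idempotent.
#'
#' @param table A [trial_table()].
#' @param cutoff_ms Cut-off latency in ms on the IS clock (default 170).
#' @param max_visual_latency_ms Upper plausibility bound (default 1000).
#' @return The labelled [trial_table()].
#' @export
label_states3 <- function(table, cutoff_ms = 170, max_visual_latency_ms = 1000) {
  stopifnot(inherits(table, "trial_table"))
  lat <- table$lat_is_ms
  too_slow <- !is.na(lat) & lat > max_visual_latency_ms
  table$lat_is_ms[too_slow] <- NA_real_
  table$lat_ws_ms[too_slow] <- NA_real_
  lat <- table$lat_is_ms
  table$state3 <- ifelse(is.na(lat), "f", ifelse(lat <= cutoff_ms, "e", "v"))
  latent <- attr(table, "latent_states")
  out <- trial_table(as.data.frame(table), provenance = attr(table, "provenance"))
  attr(out, "latent_states") <- latent
  out
}

#' Response-type percentages by study cell
#'
#' Computes, for each group x medication x condition cell, the mean and
#' standard error across subjects of the per-subject percentages of failed,
#' visually-guided and early trials, plus the total trial count per category.
#' Percentages are computed within subject first, so subjects with different
#' trial counts carry equal weight; the standard error uses the n-1 sample
#' standard deviation across subjects.
#'
#' @param table A labelled [trial_table()] (`state3` set).
#' @return A data.frame of class `percent_table` with one row per cell and
#'   columns `<type>_pct`, `<type>_se`, `<type>_n` for failed/visual/early,
#'   plus `n_subjects`.
#' @export
response_percentages <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  if (anyNA(table$state3)) stop("state3 must be labelled first")
  cells <- split(as.data.frame(table),
                 paste(table$group, table$medication, table$condition, sep = "_"),
                 drop = TRUE)
  rows <- lapply(names(cells), function(cell) {
    d <- cells[[cell]]
    per_subj <- t(vapply(split(d$state3, d$subject_id), function(s) {
      c(failed = mean(s == "f"), visual = mean(s == "v"),
        early = mean(s == "e")) * 100
    }, numeric(3)))
    if (nrow(per_subj) == 0) stop("cell with zero subjects: ", cell)
    se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    data.frame(
      cell = cell,
      group = d$group[1], medication = d$medication[1], condition = d$condition[1],
      n_subjects = nrow(per_subj),
      failed_pct = mean(per_subj[, "failed"]), failed_se = se(per_subj[, "failed"]),
      failed_n = sum(d$state3 == "f"),
      visual_pct = mean(per_subj[, "visual"]), visual_se = se(per_subj[, "visual"]),
      visual_n = sum(d$state3 == "v"),
      early_pct = mean(per_subj[, "early"]), early_se = se(per_subj[, "early"]),
      early_n = sum(d$state3 == "e"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("percent_table", "data.frame")
  out
}

#' @export
print.percent_table <- function(x, ...) {
  cat("Response-type percentages (mean ± se across subjects)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-22s failed %5.1f ± %4.1f%% (n=%d)  visual %5.1f ± %4.1f%% (n=%d)  early %5.1f ± %4.1f%% (n=%d)\n",
                x$cell[i], x$failed_pct[i], x$failed_se[i], x$failed_n[i],
                x$visual_pct[i], x$visual_se[i], x$visual_n[i],
                x$early_pct[i], x$early_se[i], x$early_n[i]))
  }
  invisible(x)
}
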