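#' Gaussian kernel density of a latency sample
#'
#' The density is the exact mean of Gaussian kernels centred at each
#' latency (no FFT binning), evaluated on a uniform grid spanning the data
#' plus six bandwidths on each side, so the trapezoid integral of the
#' result is 1 to within 1e-6. The bandwidth is the kernel standard
#' deviation.
#'
#' @param latencies Numeric latencies in ms (at least one).
#' @param bandwidth_ms Kernel sd in ms (default 40).
#' @param grid_step_ms Grid step in ms (default 1).
#' @return An object of class `kernel_density` with `grid`, `values`,
#'   `bandwidth_ms`, `grid_step_ms`, `n`.
#' @export
kernel_density <- function(latencies, bandwidth_ms = 40, grid_step_ms = 1) {
  x <- latencies[!is.na(latencies)]
  if (!length(x)) stop("empty latency sample")
  stopifnot(bandwidth_ms > 0, grid_step_ms > 0)
  lo <- floor((min(x) - 6 * bandwidth_ms) / grid_step_ms) * grid_step_ms
  hi <- ceiling((max(x) + 6 * bandwidth_ms) / grid_step_ms) * grid_step_ms
  grid <- seq(lo, hi, by = grid_step_ms)
  # chunk the grid to keep the (grid x n) kernel matrix small
  values <- numeric(length(grid))
  chunk <- max(1L, floor(5e6 / length(x)))
  for (start in seq(1L, length(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(grid))
    values[idx] <- colMeans(matrix(
      stats::dnorm(rep(x, times = length(idx)),
                   mean = rep(grid[idx], each = length(x)),
                   sd = bandwidth_ms),
      nrow = length(x)))
  }
  structure(list(grid = grid, values = values, bandwidth_ms = bandwidth_ms,
                 grid_step_ms = grid_step_ms, n = length(x)),
            class = "kernel_density")
}

#' @export
print.kernel_density <- function(x, ...) {
  cat(sprintf("Kernel density: n = %d, bandwidth %g ms, grid [%g, %g] by %g ms\n",
              x$n, x$bandwidth_ms, min(x$grid), max(x$grid), x$grid_step_ms))
  invisible(x)
}

# Trapezoid integral of a gridded function.
trapezoid <- function(grid, values) {
  sum(diff(grid) * (values[-1] + values[-length(values)]) / 2)
}

#' Pointwise difference of two kernel densities
#'
#' The two grids are unioned (linear interpolation, zero outside each
#' density's own grid — negligible mass lives there by construction) and
#' the difference `a - b` is returned. Densities estimated with different
#' bandwidths are not comparable and are rejected.
#'
#' @param a,b `kernel_density` objects with equal bandwidths and grid steps.
#' @return A list with `grid`, `difference`, `bandwidth_ms`.
#' @export
density_difference <- function(a, b) {
  stopifnot(inherits(a, "kernel_density"), inherits(b, "kernel_density"))
  if (a$bandwidth_ms != b$bandwidth_ms) {
    stop("bandwidth mismatch: ", a$bandwidth_ms, " vs ", b$bandwidth_ms)
  }
  step <- min(a$grid_step_ms, b$grid_step_ms)
  grid <- seq(min(a$grid[1], b$grid[1]), max(max(a$grid), max(b$grid)),
              by = step)
  interp <- function(d) {
    out <- stats::approx(d$grid, d$values, xout = grid, rule = 1)$y
    out[is.na(out)] <- 0
    out
  }
  list(grid = grid, difference = interp(a) - interp(b),
       bandwidth_ms = a$bandwidth_ms)
}

#' Two-sample Kolmogorov-Smirnov Z test
#'
#' Computes `D = sup |ECDF1 - ECDF2|`, the Z statistic
#' `D * sqrt(n1 n2 / (n1 + n2))`, and the p-value from the asymptotic
#' Kolmogorov distribution (the convention behind a reported "Z test");
#' `exact = TRUE` switches to the exact small-sample distribution.
#'
#' @param x1,x2 Numeric samples with at least 2 observations each.
#' @param exact Use the exact null distribution of D (default FALSE).
#' @return An object of class `ks_result` with `d_statistic`,
#'   `z_statistic`, `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(x1, x2, exact = FALSE) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 observations")
  pts <- sort(unique(c(x1, x2)))
  f1 <- findInterval(pts, sort(x1)) / n1
  f2 <- findInterval(pts, sort(x2)) / n2
  d <- max(abs(f1 - f2))
  z <- d * sqrt(n1 * n2 / (n1 + n2))
  p <- if (exact) {
    1 - stats::psmirnov(d, sizes = c(n1, n2), two.sided = TRUE)
  } else {
    kolmogorov_sf(z)
  }
  structure(list(d_statistic = d, z_statistic = z, p_value = p,
                 n1 = n1, n2 = n2, exact = exact),
            class = "ks_result")
}

# Asymptotic Kolmogorov survival function Q(z) = 2 sum (-1)^{k-1} e^{-2k^2z^2}.
kolmogorov_sf <- function(z) {
  if (z <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * z^2))
  min(max(p, 0), 1)
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Kolmogorov-Smirnov: D = %.4f, Z = %.3f, p = %.4g (n1 = %d, n2 = %d%s)\n",
              x$d_statistic, x$z_statistic, x$p_value, x$n1, x$n2,
              if (x$exact) ", exact" else ""))
  invisible(x)
}

#' Ordinary least-squares slope summary
#'
#' Simple regression of latency on duration with the summaries conventional
#' for slope comparisons: the standardised slope `beta_std = b * sd(x) /
#' sd(y)`, its t statistic, the model F (`= t^2` for a single predictor),
#' and `r^2`.
#'
#' @param x Durations in ms (not constant, at least 3 points).
#' @param y Latencies in ms.
#' @return An object of class `slope_summary` with `slope`, `beta_std`,
#'   `t`, `F`, `r2`, `n`.
#' @export
ols_slope <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("constant x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  tval <- unname(sm$coefficients[2, "t value"])
  structure(list(slope = slope,
                 beta_std = slope * stats::sd(x) / stats::sd(y),
                 t = tval, F = tval^2, r2 = sm$r.squared, n = n),
            class = "slope_summary")
}

#' @export
print.slope_summary <- function(x, ...) {
  cat(sprintf("OLS slope: b = %.4f (beta = %.3f), t = %.3f, F = %.3f, r2 = %.3f, n = %d\n",
              x$slope, x$beta_std, x$t, x$F, x$r2, x$n))
  invisible(x)
}
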