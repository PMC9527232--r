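#' Analysis configuration
#'
#' Bundles every tunable the pipeline consumes: the early/visual latency
#' cut-off on the imperative-stimulus (IS) clock, the significance level used
#' throughout, the kernel bandwidth for latency densities, EM settings for the
#' two-component mixture fits, and screening/CI conventions for the Markov
#' stage.
#'
#' @param cutoff_ms Early/visual latency cut-off in ms on the IS clock.
#'   A saccade with latency less than or equal to this value counts as early.
#' @param alpha Significance level applied to all tests.
#' @param kernel_bandwidth_ms Gaussian kernel standard deviation (ms) for
#'   latency density estimation.
#' @param em_tol Relative log-likelihood change below which EM stops.
#' @param em_max_iter Maximum EM iterations per restart.
#' @param em_restarts Number of EM restarts (first uses quantile
#'   initialisation, the rest jitter the initial means).
#' @param seed Master seed; every stochastic stage derives its randomness
#'   from it.
#' @param min_sample_per_fit Minimum number of early saccades required for a
#'   per-duration mixture fit; smaller cells fall back to a pooled fit.
#' @param max_visual_latency_ms Saccades with IS-clock latency above this are
#'   relabelled failed (implausibly slow "visual" responses).
#' @param markov_screen_alpha Level for the per-subject Markov-property
#'   screen; failing subjects are excluded from pooled transition fits.
#' @param ci_level Confidence level for per-cell transition-probability
#'   intervals.
#' @param grid_step_ms Grid step (ms) for density evaluation.
#' @param min_markov_length Minimum pooled sequence length for the
#'   Markov-property test.
#'
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(cutoff_ms = 170,
                            alpha = 0.01,
                            kernel_bandwidth_ms = 40,
                            em_tol = 1e-8,
                            em_max_iter = 1000,
                            em_restarts = 5,
                            seed = 7L,
                            min_sample_per_fit = 30,
                            max_visual_latency_ms = 1000,
                            markov_screen_alpha = 0.05,
                            ci_level = 0.99,
                            grid_step_ms = 1,
                            min_markov_length = 50) {
  stopifnot(is.numeric(cutoff_ms), length(cutoff_ms) == 1, cutoff_ms > 0)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  stopifnot(kernel_bandwidth_ms > 0, em_tol > 0, em_max_iter >= 1,
            em_restarts >= 1, min_sample_per_fit >= 2,
            ci_level > 0, ci_level < 1, grid_step_ms > 0)
  structure(list(
    cutoff_ms = cutoff_ms,
    alpha = alpha,
    kernel_bandwidth_ms = kernel_bandwidth_ms,
    em_tol = em_tol,
    em_max_iter = em_max_iter,
    em_restarts = em_restarts,
    seed = as.integer(seed),
    min_sample_per_fit = min_sample_per_fit,
    max_visual_latency_ms = max_visual_latency_ms,
    markov_screen_alpha = markov_screen_alpha,
    ci_level = ci_level,
    grid_step_ms = grid_step_ms,
    min_markov_length = min_markov_length
  ), class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' The file is a flat key-value mapping mirroring the arguments of
#' [analysis_config()]; keys absent from the file keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must be a key-value mapping")
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Write an analysis configuration to a YAML file
#'
#' @param config An `analysis_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  cut-off: %g ms (IS clock)   alpha: %g\n", x$cutoff_ms, x$alpha))
  cat(sprintf("  kernel bandwidth: %g ms   grid step: %g ms\n",
              x$kernel_bandwidth_ms, x$grid_step_ms))
  cat(sprintf("  EM: tol %g, max %d iter, %d restarts, min n %d\n",
              x$em_tol, x$em_max_iter, x$em_restarts, x$min_sample_per_fit))
  cat(sprintf("  Markov: screen alpha %g, CI level %g\n",
              x$markov_screen_alpha, x$ci_level))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
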