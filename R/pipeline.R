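#' Run the full analysis pipeline
#'
#' Orchestrates classification -> mixture -> Markov -> distributions on a
#' trial table (provided or generated), writing every stage artifact plus a
#' JSON run manifest into `out_dir`:
#'
#' * `labeled.tsv` — the table with `state3`/`state4` labels
#' * `percentages.tsv` — response-type percentages per study cell
#' * `mixing.tsv` — first/second mode mixing proportions per duration
#' * `fits.json` — per-cell mixture fits, cuts and flags
#' * `transitions3.json`, `transitions4.json` — pooled transition matrices
#'   with CIs, per group x medication x condition (4-state on explicit
#'   data only unless `four_state_all = TRUE`)
#' * `ks.tsv` — implicit-vs-explicit KS Z grid per duration and group
#' * `density_diff.tsv` — explicit-minus-implicit early-latency density
#'   differences per group
#' * `manifest.json` — config snapshot, seeds, input hash, output paths
#'
#' @param config An [analysis_config()].
#' @param input A [trial_table()], or NULL to generate one from
#'   `generator_spec`.
#' @param generator_spec A cohort spec for [generate_cohort()]; defaults to
#'   the six-cell study layout (18 controls, 20 patients ON and OFF, both
#'   conditions) when `input` is NULL.
#' @param out_dir Output directory (created if needed).
#' @param auto_cutoff Detect the early/visual cut-off from the data
#'   ([detect_cutoff()]); by default the configured fixed cut-off is used.
#' @param four_state_all Run the 4-state analysis on all conditions rather
#'   than only the explicit one.
#' @return A `run_manifest` object (invisibly readable from
#'   `manifest.json`).
#' @export
run_full_analysis <- function(config = analysis_config(), input = NULL,
                              generator_spec = NULL, out_dir = "results",
                              auto_cutoff = FALSE, four_state_all = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  on_fail <- function(e, stage) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  run <- function(stage_name, expr) {
    tryCatch(expr, error = function(e) on_fail(e, stage_name))
  }

  table <- run("input", {
    if (is.null(input)) {
      spec <- if (is.null(generator_spec)) default_cohort_spec(config$seed) else generator_spec
      generate_cohort(spec, master_seed = config$seed)
    } else {
      stopifnot(inherits(input, "trial_table"))
      input
    }
  })
  input_hash <- unname(tools::md5sum(write_trials(table, file.path(out_dir, "input.tsv"))))

  # -- classification ------------------------------------------------------
  labeled <- run("classification", {
    cut <- if (auto_cutoff) {
      detect_cutoff(table$lat_is_ms, fixed_cutoff_ms = config$cutoff_ms)
    } else {
      cutoff_result(config$cutoff_ms, "fixed", n = sum(!is.na(table$lat_is_ms)))
    }
    list(cut = cut,
         table = label_states3(table, cut$cutoff_ms, config$max_visual_latency_ms))
  })
  cutoff_used <- labeled$cut
  table <- labeled$table
  percentages <- run("classification", response_percentages(table))
  write.table(as.data.frame(percentages), file.path(out_dir, "percentages.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # -- mixture -------------------------------------------------------------
  mixres <- run("mixture", {
    d <- as.data.frame(table)
    cells <- split(seq_len(nrow(d)), paste(d$group, d$condition, sep = "|"))
    fits <- list()
    state4 <- rep(NA_character_, nrow(d))
    for (cell in names(cells)) {
      idx <- cells[[cell]]
      early <- idx[d$state3[idx] == "e"]
      by_dur <- split(d$lat_ws_ms[early], d$fp_ms[early])
      res <- fit_mixture_cuts(by_dur, tol = config$em_tol,
                              max_iter = config$em_max_iter,
                              restarts = config$em_restarts,
                              seed = config$seed,
                              min_n = config$min_sample_per_fit)
      fits[[cell]] <- res
      sub <- assign_modes(subset_table(table, idx), res$cuts)
      state4[idx] <- sub$state4
    }
    table$state4 <- state4
    table <- trial_table(as.data.frame(table),
                         provenance = attr(table, "provenance"))
    list(fits = fits, table = table)
  })
  table <- mixres$table
  mixing <- run("mixture", mixing_proportions(table))
  write.table(as.data.frame(mixing), file.path(out_dir, "mixing.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_trials(table, file.path(out_dir, "labeled.tsv"))
  fits_json <- lapply(mixres$fits, function(res) list(
    cuts = as.list(res$cuts), flags = as.list(res$flags),
    fits = lapply(res$fits, function(f) f[c("lambda1", "lambda2", "mu1", "mu2",
                                            "sigma1", "sigma2", "loglik",
                                            "n_iter", "converged", "n", "cut_ms")])))
  jsonlite::write_json(fits_json, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- markov --------------------------------------------------------------
  markov_out <- run("markov", {
    d <- as.data.frame(table)
    cells <- split(seq_len(nrow(d)), paste(d$group, d$medication, d$condition, sep = "|"))
    res3 <- list(); res4 <- list(); skipped4 <- character()
    for (cell in names(cells)) {
      sub <- subset_table(table, cells[[cell]])
      seqs3 <- build_sequences(sub, "three")
      res3[[cell]] <- pooled_transition_fit(seqs3,
                                            screen_alpha = config$markov_screen_alpha,
                                            ci_level = config$ci_level,
                                            min_length = config$min_markov_length)
      is_explicit <- grepl("\\|explicit$", cell)
      if (is_explicit || four_state_all) {
        seqs4 <- build_sequences(sub, "four")
        res4[[cell]] <- pooled_transition_fit(seqs4,
                                              screen_alpha = config$markov_screen_alpha,
                                              ci_level = config$ci_level,
                                              min_length = config$min_markov_length)
      } else {
        skipped4 <- c(skipped4, cell)
      }
    }
    list(res3 = res3, res4 = res4, skipped4 = skipped4)
  })
  tm_json <- function(res) lapply(res, function(r) list(
    states = r$matrix$states, counts = r$matrix$counts,
    probs = r$matrix$probs, ci_low = r$matrix$ci_low,
    ci_high = r$matrix$ci_high, n_row = as.list(r$matrix$n_row),
    excluded_subjects = r$excluded))
  jsonlite::write_json(tm_json(markov_out$res3),
                       file.path(out_dir, "transitions3.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(c(tm_json(markov_out$res4),
                         list(skipped = markov_out$skipped4)),
                       file.path(out_dir, "transitions4.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- distributions -------------------------------------------------------
  dist_out <- run("distributions", {
    d <- as.data.frame(table)
    ks_rows <- list(); dd <- list()
    for (g in unique(d$group)) {
      for (dur in FP_VALUES) {
        imp <- d$lat_ws_ms[d$group == g & d$condition == "implicit" &
                             d$state3 == "e" & d$fp_ms == dur]
        expl <- d$lat_ws_ms[d$group == g & d$condition == "explicit" &
                              d$state3 == "e" & d$fp_ms == dur]
        if (length(imp) >= 2 && length(expl) >= 2) {
          ks <- ks_two_sample(imp, expl)
          ks_rows[[length(ks_rows) + 1L]] <- data.frame(
            group = g, fp_ms = dur, z = ks$z_statistic, d = ks$d_statistic,
            p_value = ks$p_value, n1 = ks$n1, n2 = ks$n2,
            significant = ks$p_value < config$alpha)
        }
      }
      imp_all <- d$lat_ws_ms[d$group == g & d$condition == "implicit" & d$state3 == "e"]
      exp_all <- d$lat_ws_ms[d$group == g & d$condition == "explicit" & d$state3 == "e"]
      if (length(imp_all) && length(exp_all)) {
        diff <- density_difference(
          kernel_density(exp_all, config$kernel_bandwidth_ms, config$grid_step_ms),
          kernel_density(imp_all, config$kernel_bandwidth_ms, config$grid_step_ms))
        dd[[g]] <- data.frame(group = g, grid_ms = diff$grid,
                              difference = diff$difference)
      }
    }
    list(ks = if (length(ks_rows)) do.call(rbind, ks_rows) else NULL,
         dd = if (length(dd)) do.call(rbind, dd) else NULL)
  })
  if (!is.null(dist_out$ks)) {
    write.table(dist_out$ks, file.path(out_dir, "ks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(dist_out$dd)) {
    write.table(dist_out$dd, file.path(out_dir, "density_diff.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("oculochain")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(config),
    seed = config$seed,
    input_hash = input_hash,
    cutoff = list(cutoff_ms = cutoff_used$cutoff_ms, method = cutoff_used$method,
                  reason = cutoff_used$reason),
    skipped_stages = if (length(markov_out$skipped4))
      sprintf("4-state analysis skipped for %s (implicit condition by default)",
              paste(markov_out$skipped4, collapse = ", ")) else character(),
    outputs = list(
      input = "input.tsv", labeled = "labeled.tsv",
      percentages = "percentages.tsv", mixing = "mixing.tsv",
      fits = "fits.json", transitions3 = "transitions3.json",
      transitions4 = "transitions4.json",
      ks = if (!is.null(dist_out$ks)) "ks.tsv" else NULL,
      density_diff = if (!is.null(dist_out$dd)) "density_diff.tsv" else NULL),
    out_dir = normalizePath(out_dir)
  ), class = "run_manifest")
  mjson <- manifest
  mjson$outputs <- Filter(Negate(is.null), mjson$outputs)
  jsonlite::write_json(unclass(mjson), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

# Default six-cell cohort: 18 controls and 20 patients (ON and OFF), both
# timing conditions, ~200 trials per session.
default_cohort_spec <- function(seed = 7L, latency_profile = "realistic",
                                n_trials = 200) {
  cells <- list(
    list("CONT", "NONE", "implicit", 18), list("CONT", "NONE", "explicit", 18),
    list("iPD", "ON", "implicit", 20), list("iPD", "ON", "explicit", 20),
    list("iPD", "OFF", "implicit", 20), list("iPD", "OFF", "explicit", 20))
  lapply(cells, function(cl) list(
    params = default_params(cl[[1]], cl[[2]], cl[[3]],
                            latency_profile = latency_profile,
                            n_trials = n_trials, seed = seed),
    n_subjects = cl[[4]]))
}

# Row subset preserving the trial_table class and latent attribute.
subset_table <- function(table, idx) {
  latent <- attr(table, "latent_states")
  out <- trial_table(as.data.frame(table)[idx, , drop = FALSE],
                     provenance = attr(table, "provenance"))
  if (!is.null(latent)) attr(out, "latent_states") <- latent[idx]
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest\n")
  cat(sprintf("  version %s, seed %d, %s\n", x$package_version, x$seed, x$timestamp))
  cat(sprintf("  cut-off: %g ms (%s)\n", x$cutoff$cutoff_ms, x$cutoff$method))
  cat("  outputs in", x$out_dir, ":\n")
  for (nm in names(x$outputs)) {
    if (!is.null(x$outputs[[nm]])) cat(sprintf("    %s: %s\n", nm, x$outputs[[nm]]))
  }
  if (length(x$skipped_stages)) cat("  skipped:", x$skipped_stages, "\n")
  invisible(x)
}

#' Render a human-readable report from a run manifest
#'
#' Reads the stage artifacts named by the manifest and writes a single
#' markdown document summarising the run: response-type percentages, mixing
#' proportions, KS grid, transition matrices, and any skipped stage.
#'
#' @param manifest A `run_manifest` (or path to a `manifest.json`).
#' @param path Output markdown path (default `report.md` in the run
#'   directory).
#' @return `path`, invisibly.
#' @export
make_report <- function(manifest, path = NULL) {
  if (is.character(manifest)) {
    m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    m$out_dir <- dirname(normalizePath(manifest))
    manifest <- m
  }
  out_dir <- manifest$out_dir
  if (is.null(path)) path <- file.path(out_dir, "report.md")
  need <- c("percentages", "mixing", "transitions3")
  for (nm in need) {
    f <- file.path(out_dir, manifest$outputs[[nm]])
    if (!file.exists(f)) stop("missing stage output: ", f)
  }
  lines <- c("# Analysis run report", "",
             sprintf("- package version: %s", manifest$package_version),
             sprintf("- seed: %s", manifest$seed),
             sprintf("- cut-off: %s ms (%s)", manifest$cutoff$cutoff_ms,
                     manifest$cutoff$method),
             "")
  tsv_section <- function(title, file) {
    f <- file.path(out_dir, file)
    if (is.null(file) || !file.exists(f)) return(character())
    d <- utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(v) round(v, 4))
    c(sprintf("## %s", title), "",
      paste("|", paste(names(d), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(d)), collapse = " | "), "|"),
      vapply(seq_len(nrow(d)), function(i)
        paste("|", paste(unlist(d[i, ]), collapse = " | "), "|"), character(1)),
      "")
  }
  lines <- c(lines,
             tsv_section("Response-type percentages", manifest$outputs$percentages),
             tsv_section("Mixing proportions", manifest$outputs$mixing),
             tsv_section("Kolmogorov-Smirnov grid", manifest$outputs$ks))
  tr3 <- jsonlite::read_json(file.path(out_dir, manifest$outputs$transitions3),
                             simplifyVector = TRUE)
  lines <- c(lines, "## 3-state transition matrices", "")
  for (cell in names(tr3)) {
    p <- round(as.matrix(tr3[[cell]]$probs), 3)
    lines <- c(lines, sprintf("### %s", cell), "", "```",
               utils::capture.output(print(p)), "```", "")
  }
  if (length(manifest$skipped_stages)) {
    lines <- c(lines, "## Skipped stages", "",
               paste("-", manifest$skipped_stages), "")
  }
  writeLines(lines, path)
  invisible(path)
}
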