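#' @importFrom stats approx coef cor dnorm lm pchisq pnorm qnorm quantile
#'   rnorm runif sd setNames
#' @importFrom utils read.table write.table
NULL

# Canonical column order of the trial TSV format.
TRIAL_COLUMNS <- c("subject_id", "group", "medication", "condition", "block",
                   "trial_index", "side", "fp_ms", "cue_ms", "lat_ws_ms",
                   "lat_is_ms", "state3", "state4")

FP_VALUES <- c(400, 900, 1400, 1900)
GROUPS <- c("CONT", "iPD")
MEDICATIONS <- c("ON", "OFF", "NONE")
CONDITIONS <- c("implicit", "explicit")
SIDES <- c("left", "right")
STATES3 <- c("e", "v", "f")
STATES4 <- c("first", "second", "v", "f")

# Tolerance for the two-clock identity lat_ws_ms = lat_is_ms + fp_ms.
CLOCK_TOL <- 1e-9

#' Construct a validated trial table
#'
#' A trial table holds one row per task trial. Latencies are recorded on two
#' clocks: `lat_ws_ms` counts from warning-stimulus (WS) offset and
#' `lat_is_ms` from imperative-stimulus (IS) onset, so
#' `lat_ws_ms = lat_is_ms + fp_ms` whenever a saccade was recorded (negative
#' `lat_is_ms` means the eye moved before the target appeared). Missing
#' latencies mean no scorable saccade. `state3` / `state4` are the
#' early/visual/failed and first/second-mode/visual/failed labels assigned by
#' the classification and mixture stages.
#'
#' @param df A data.frame with the columns listed in the package's trial TSV
#'   format (see [read_trials()]); extra columns are rejected.
#' @param provenance Free-text metadata (seed, generator parameters, file
#'   path) carried as an attribute.
#' @param skip_bad If `TRUE`, rows violating the trial invariants are dropped
#'   with a warning instead of failing the whole table.
#'
#' @return A data.frame of class `trial_table`.
#' @export
trial_table <- function(df, provenance = NULL, skip_bad = FALSE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), TRIAL_COLUMNS)
  if (length(extra)) {
    stop("schema error: unexpected columns: ", paste(extra, collapse = ", "))
  }
  df <- df[, TRIAL_COLUMNS, drop = FALSE]
  df$subject_id <- as.character(df$subject_id)
  for (col in c("block", "trial_index")) df[[col]] <- as.integer(df[[col]])
  for (col in c("fp_ms", "cue_ms", "lat_ws_ms", "lat_is_ms")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("group", "medication", "condition", "side", "state3", "state4")) {
    df[[col]] <- as.character(df[[col]])
  }

  problems <- validate_trial_rows(df)
  if (length(problems)) {
    bad_rows <- as.integer(sub(":.*$", "", problems))
    if (skip_bad) {
      warning(sprintf("dropping %d invalid row(s): %s",
                      length(unique(bad_rows)),
                      paste(utils::head(problems, 5), collapse = "; ")))
      df <- df[-unique(bad_rows), , drop = FALSE]
    } else {
      stop("validation error in row(s):\n  ",
           paste(utils::head(problems, 10), collapse = "\n  "),
           if (length(problems) > 10) sprintf("\n  ... and %d more", length(problems) - 10))
    }
  }

  key <- paste(df$subject_id, df$condition, df$block, df$trial_index)
  if (anyDuplicated(key)) {
    stop("validation error: duplicate (subject_id, condition, block, trial_index)")
  }
  # trial_index strictly increasing within subject x condition x block
  ord_bad <- unlist(lapply(
    split(seq_len(nrow(df)), paste(df$subject_id, df$condition, df$block)),
    function(idx) {
      ti <- df$trial_index[idx]
      if (any(diff(ti) <= 0)) idx[which(diff(ti) <= 0) + 1L] else integer()
    }))
  if (length(ord_bad)) {
    stop("validation error: trial_index not strictly increasing at row(s) ",
         paste(sort(ord_bad), collapse = ", "))
  }

  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("trial_table", "data.frame"))
}

# Row-level invariant checks; returns "row: message" strings.
validate_trial_rows <- function(df) {
  n <- nrow(df)
  problems <- character()
  note <- function(rows, msg) {
    if (length(rows)) problems <<- c(problems, sprintf("%d: %s", rows, msg))
  }
  note(which(!(df$group %in% GROUPS)), "group must be CONT or iPD")
  note(which(!(df$medication %in% MEDICATIONS)), "medication must be ON, OFF or NONE")
  note(which(!(df$condition %in% CONDITIONS)), "condition must be implicit or explicit")
  note(which(!(df$side %in% SIDES)), "side must be left or right")
  note(which(!(df$fp_ms %in% FP_VALUES)),
       "fp_ms must be one of 400, 900, 1400, 1900")
  # cue equals fp in explicit trials, absent in implicit trials
  exp_rows <- df$condition == "explicit"
  note(which(exp_rows & (is.na(df$cue_ms) | abs(df$cue_ms - df$fp_ms) > CLOCK_TOL)),
       "explicit trial must have cue_ms equal to fp_ms")
  note(which(!exp_rows & !is.na(df$cue_ms)),
       "implicit trial must not carry cue_ms")
  # latency presence is all-or-none and the two clocks must agree
  one_clock <- xor(is.na(df$lat_ws_ms), is.na(df$lat_is_ms))
  note(which(one_clock), "lat_ws_ms and lat_is_ms must be both present or both absent")
  both <- !is.na(df$lat_ws_ms) & !is.na(df$lat_is_ms)
  bad_clock <- both & abs(df$lat_ws_ms - df$lat_is_ms - df$fp_ms) > CLOCK_TOL
  note(which(bad_clock), "clock identity lat_ws_ms - lat_is_ms = fp_ms violated")
  # state labels, when present, must come from the right alphabet;
  # state3 = f exactly when no latency was recorded
  has3 <- !is.na(df$state3) & df$state3 != ""
  note(which(has3 & !(df$state3 %in% STATES3)), "state3 must be e, v or f")
  note(which(has3 & df$state3 == "f" & both), "state3 = f but a latency is recorded")
  note(which(has3 & df$state3 != "f" & !both), "state3 != f but no latency recorded")
  has4 <- !is.na(df$state4) & df$state4 != ""
  note(which(has4 & !(df$state4 %in% STATES4)),
       "state4 must be first, second, v or f")
  if (n == 0) return(character())
  problems[order(as.integer(sub(":.*$", "", problems)))]
}

#' Read a trial table from a delimited file
#'
#' The canonical on-disk format is a TSV with a header naming the thirteen
#' trial columns in fixed order; empty fields encode missing values (the
#' medication level "NA" is spelled `NONE` in files precisely so that the
#' empty string can be the only missing-value token).
#'
#' @param path Path to a TSV (or CSV, see `dialect`) trial file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param skip_bad Drop invalid rows with a warning instead of failing; by
#'   default any invalid row fails the whole load, because silently losing
#'   trials corrupts the downstream sequence analyses.
#'
#' @return A validated [trial_table()].
#' @export
read_trials <- function(path, dialect = c("tsv", "csv"), skip_bad = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = "",
                           check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("block", "trial_index", "fp_ms", "cue_ms", "lat_ws_ms", "lat_is_ms")) {
    vals <- raw[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric %s in row(s) %s", col,
                   paste(bad, collapse = ", ")))
    }
    raw[[col]] <- num
  }
  trial_table(raw, provenance = paste0("file:", path), skip_bad = skip_bad)
}

#' Write a trial table to a delimited file
#'
#' Columns are written in the canonical order with missing values as empty
#' fields, so `read_trials(write_trials(x))` round-trips exactly (up to float
#' formatting at 1e-9).
#'
#' @param table A [trial_table()].
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(table, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "trial_table"))
  sep <- if (dialect == "tsv") "\t" else ","
  out <- as.data.frame(table)[, TRIAL_COLUMNS, drop = FALSE]
  for (col in c("fp_ms", "cue_ms", "lat_ws_ms", "lat_is_ms")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA, format(out[[col]], digits = 15,
                                                       scientific = FALSE, trim = TRUE))
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Trial table: %d trials, %d subject(s)\n",
              nrow(x), length(unique(x$subject_id))))
  cells <- table(paste(x$group, x$medication, x$condition, sep = "_"))
  for (nm in names(cells)) cat(sprintf("  %s: %d trials\n", nm, cells[[nm]]))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("  provenance:", paste(prov, collapse = " "), "\n")
  invisible(x)
}
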