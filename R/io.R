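#' Write a dataset to CSV with JSON metadata
#'
#' The CSV has columns `case_index, te, tr, me, mr, match`; a companion
#' JSON file (`<file>.json`) records the scenario, clamps, size, seed and
#' package version, enough to regenerate the CSV byte-exactly. Output is
#' UTF-8, comma-separated, LF line endings.
#'
#' @param d An `"er_dataset"`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_dataset <- function(d, file) {
  write_csv_lf(as.data.frame(d), file)
  sc <- attr(d, "scenario")
  meta <- list(scenario = sc, clamps = as.list(attr(d, "clamps")),
               n = nrow(d), seed = attr(d, "seed"),
               package_version = package_version_string())
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param file CSV path; the companion `<file>.json` metadata is read if
#'   present.
#' @return An `"er_dataset"`.
#' @export
read_dataset <- function(file) {
  d <- tryCatch(
    utils::read.csv(file, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("malformed dataset CSV '", file, "': ",
                             conditionMessage(e))
  )
  need <- c("case_index", "te", "tr", "me", "mr", "match")
  if (!all(need %in% names(d))) {
    stop("dataset CSV '", file, "' is missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  d$case_index <- as.integer(d$case_index)
  bad <- which(d$match != er_match_state(d$me, d$mr))
  if (length(bad)) {
    stop("dataset CSV '", file, "': match column inconsistent with me/mr ",
         "at line ", bad[1] + 1L)
  }
  metafile <- paste0(file, ".json")
  sc <- NULL
  seed <- NA_integer_
  if (file.exists(metafile)) {
    meta <- jsonlite::read_json(metafile, simplifyVector = TRUE)
    sc <- as_scenario(meta$scenario)
    seed <- as.integer(meta$seed)
  }
  structure(d, scenario = sc, seed = seed,
            clamps = if (!is.null(sc)) {
              c(R = sc$r_true, AcEM = sc$acem, AcRM = sc$acrm)
            },
            class = c("er_dataset", "data.frame"))
}

#' Write a posterior trajectory to CSV
#'
#' Columns `trial, case_index, outcome, p_none, p_medium, p_strong`;
#' probabilities with 6 decimal places.
#'
#' @param fit An `"er_fit"`, or an `"er_ensemble"` (one block per trial).
#' @param file Output CSV path.
#' @param trial Trial number written to the `trial` column for a single
#'   fit (default 1).
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(fit, file, trial = 1L) {
  df <- trajectory_frame(fit, trial)
  write_csv_lf(df, file)
  invisible(file)
}

trajectory_frame <- function(fit, trial = 1L) {
  if (inherits(fit, "er_ensemble")) {
    n_trials <- dim(fit$trajectories)[3]
    blocks <- lapply(seq_len(n_trials), function(t) {
      p <- fit$trajectories[, , t, drop = FALSE][, , 1]
      data.frame(trial = t, case_index = seq_len(nrow(p)),
                 outcome = NA_character_,
                 p_none = sprintf("%.6f", p[, "none"]),
                 p_medium = sprintf("%.6f", p[, "medium"]),
                 p_strong = sprintf("%.6f", p[, "strong"]),
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, blocks))
  }
  p <- fit$posterior
  data.frame(trial = as.integer(trial),
             case_index = seq_len(nrow(p)),
             outcome = fit$outcomes,
             p_none = sprintf("%.6f", p[, "none"]),
             p_medium = sprintf("%.6f", p[, "medium"]),
             p_strong = sprintf("%.6f", p[, "strong"]),
             stringsAsFactors = FALSE)
}

#' Write a required-sample-size table to CSV
#'
#' Rows are accuracy levels, columns the true strength states. Each cell
#' carries the integer required N in `required_<state>` and the censored
#' rendering (`">1000"`) in `display_<state>`; censored cells leave the
#' numeric column empty.
#'
#' @param pt An `"er_power_table"`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_power_table <- function(pt, file) {
  m <- pt$required_n
  df <- data.frame(accuracy = rownames(m), stringsAsFactors = FALSE)
  for (s in colnames(m)) {
    req <- rep(NA_integer_, nrow(m))
    fin <- is.finite(m[, s])
    req[fin] <- as.integer(m[fin, s])
    df[[paste0("required_", s)]] <- req
    df[[paste0("display_", s)]] <- format_required_n(m[, s], pt$n_max)
  }
  write_csv_lf(df, file)
  invisible(file)
}

#' Write a run record
#'
#' A JSON document echoing the configuration, the derived per-trial seeds
#' and the package version: everything needed to regenerate a run's
#' outputs byte-exactly (the timestamp is informational).
#'
#' @param config Named list of configuration values.
#' @param trial_seeds Integer vector of per-trial seeds.
#' @param file Output JSON path.
#' @return `file`, invisibly.
#' @export
write_run_record <- function(config, trial_seeds, file) {
  rec <- list(config = config, trial_seeds = trial_seeds,
              package_version = package_version_string(),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rec, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

package_version_string <- function() {
  as.character(utils::packageVersion("bnpower"))
}

# Deterministic CSV writer: UTF-8, comma-separated, '.' decimal, LF line
# endings, no quoting of plain strings.
write_csv_lf <- function(df, file) {
  con <- file(file, open = "wb")
  on.exit(close(con))
  cols <- lapply(df, function(col) {
    s <- as.character(col)
    s[is.na(col)] <- ""          # censored / absent cells stay empty
    s
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  if (nrow(df) == 0L) lines <- lines[1]
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(file)
}
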