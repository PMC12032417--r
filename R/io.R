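REQUIRED_COLUMNS <- c("pid", "day", part_columns(), "wear_h", "age", "sex", "bmi")

#' Read a participant-day CSV
#'
#' Long format, one row per participant-day; required columns are `pid`,
#' `day`, the five `<part>_min` minute columns, `wear_h`, and baseline
#' `age`, `sex`, `bmi`. Outcome columns and optional `walk_detected` /
#' `n_ratings` are carried through.
#'
#' @param path CSV path (UTF-8, header required).
#' @return Validated participant-day data frame.
#' @export
read_behavior_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_behavior_data(df)
}

#' Validate a participant-day table
#'
#' Checks the column contract, uniqueness of (pid, day), and
#' non-negativity of minute columns. Returns the data invisibly unchanged
#' on success; errors describe the first offending row.
#'
#' @param df Participant-day data frame.
#' @export
validate_behavior_data <- function(df) {
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("malformed table, missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df[c("pid", "day")]) > 0) {
    d <- df[duplicated(df[c("pid", "day")]), c("pid", "day")][1, ]
    stop(sprintf("duplicate participant-day: pid %s day %s", d$pid, d$day))
  }
  for (cl in part_columns()) {
    if (any(df[[cl]] < 0, na.rm = TRUE)) {
      stop(sprintf("negative minutes in column %s (row %d)",
                   cl, which(df[[cl]] < 0)[1]))
    }
  }
  df
}

#' Apply day-level validity filters and the minimum-days rule
#'
#' Drops days failing any filter -- wear time below `min_wear_h` hours, no
#' sleep recorded (`sleep_min <= 0`), no walking period detected, or (when
#' `min_ratings` is set) too few affect ratings -- then drops participants
#' left with fewer than `min_days` valid days. Every removed day gets one
#' exclusion record with a reason code, so that
#' `nrow(retained) + nrow(exclusions) == nrow(input)`.
#'
#' @param df Participant-day table (see [validate_behavior_data()]).
#' @param min_wear_h Minimum daily wear time in hours (default 20).
#' @param min_days Minimum valid days per participant (default 3).
#' @param require_sleep Require `sleep_min > 0` (default TRUE).
#' @param require_walk Require `walk_detected` when the column is present.
#' @param min_ratings Optional minimum `n_ratings` per day (sensitivity
#'   analysis; default `NULL` = off).
#' @return List: `data` (retained days), `exclusions` (data frame with
#'   `pid`, `day`, `reason`).
#' @export
filter_days <- function(df, min_wear_h = 20, min_days = 3,
                        require_sleep = TRUE, require_walk = TRUE,
                        min_ratings = NULL) {
  stopifnot(min_wear_h > 0, min_days >= 1)
  df <- validate_behavior_data(df)
  reason <- rep(NA_character_, nrow(df))
  mark <- function(bad, code) ifelse(is.na(reason) & bad, code, reason)
  reason <- mark(df$wear_h < min_wear_h, "wear_below_min")
  if (require_sleep) reason <- mark(df$sleep_min <= 0, "no_sleep_recorded")
  if (require_walk && "walk_detected" %in% names(df)) {
    reason <- mark(!df$walk_detected, "no_walking_detected")
  }
  if (!is.null(min_ratings) && "n_ratings" %in% names(df)) {
    reason <- mark(df$n_ratings < min_ratings, "too_few_ratings")
  }
  keep <- is.na(reason)
  valid_n <- table(df$pid[keep])
  few <- names(valid_n)[valid_n < min_days]
  reason[keep & df$pid %in% few] <- "participant_below_min_days"
  keep <- is.na(reason)
  list(data = df[keep, , drop = FALSE],
       exclusions = data.frame(pid = df$pid[!keep], day = df$day[!keep],
                               reason = reason[!keep]))
}

#' Align predictors with next-day outcomes
#'
#' For prospective analyses: each day's composition is paired with the
#' following calendar day's outcome value; days without an adjacent next
#' day (the participant's last day, and days before an index gap such as a
#' weekend break) are dropped. The outcome column is overwritten in place,
#' so downstream lag construction ("previous day's outcome") remains
#' correct relative to the outcome's own day.
#'
#' @param df Participant-day table.
#' @param outcome Outcome column name.
#' @return The table with prospective outcome alignment.
#' @export
shift_outcome_next_day <- function(df, outcome) {
  if (!outcome %in% names(df)) stop(sprintf("no column '%s'", outcome))
  df <- df[order(df$pid, df$day), ]
  nxt <- c(df[[outcome]][-1], NA)
  adjacent <- c(df$pid[-1] == df$pid[-nrow(df)] & diff(df$day) == 1, FALSE)
  df[[outcome]] <- ifelse(adjacent, nxt, NA)
  df[adjacent, , drop = FALSE]
}

#' Pipeline run configuration
#'
#' @param outcomes Outcome columns to analyse.
#' @param report_pivots Parts whose first pivot coordinate is reported.
#' @param timings `"concurrent"` (same-day) and/or `"prospective"`
#'   (next-day) outcome alignment.
#' @param min_wear_h,min_days,min_ratings Day filters (see [filter_days()]).
#' @param chains,iter,warmup,seed MCMC settings.
#' @param sub_minutes Substitution duration grid.
#' @param matrix_minutes Duration of the pairwise matrix view.
#' @export
run_config <- function(outcomes = c("valence", "energetic_arousal",
                                    "calmness", "working_memory"),
                       report_pivots = c("mvpa", "sedentary"),
                       timings = "concurrent",
                       min_wear_h = 20, min_days = 3, min_ratings = NULL,
                       chains = 4, iter = 2000, warmup = 1000, seed = 1,
                       sub_minutes = 1:60, matrix_minutes = 30) {
  if (length(outcomes) == 0) stop("outcome list must be non-empty")
  stopifnot(all(timings %in% c("concurrent", "prospective")))
  list(outcomes = outcomes, report_pivots = report_pivots, timings = timings,
       min_wear_h = min_wear_h, min_days = min_days, min_ratings = min_ratings,
       chains = chains, iter = iter, warmup = warmup, seed = seed,
       sub_minutes = sub_minutes, matrix_minutes = matrix_minutes)
}

#' Run the full analysis pipeline on a participant-day table
#'
#' Filters days, decomposes compositions, and for every outcome x timing
#' fits the multilevel model, summarizes coefficients in each requested
#' pivot basis, and computes the substitution grid relative to the sample
#' reference composition. When `out_dir` is given, writes per-model
#' coefficient tables, the long substitution grids, the pairwise matrix
#' views, a diagnostics summary, the exclusion log, and a JSON run
#' manifest. A fit failing the convergence gates is flagged (and warned
#' about), never silently accepted.
#'
#' @param df Participant-day table.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for CSV/JSON reports.
#' @return List: `reference` composition, `exclusions`, `diagnostics`
#'   summary, and per-model `fits` (each with `summary`, `grid`,
#'   `matrices`, `fit`).
#' @export
run_analysis <- function(df, config = run_config(), out_dir = NULL) {
  filt <- filter_days(df, min_wear_h = config$min_wear_h,
                      min_days = config$min_days,
                      min_ratings = config$min_ratings)
  message(sprintf("[filter] retained %d of %d days (%d excluded)",
                  nrow(filt$data), nrow(df), nrow(filt$exclusions)))
  base <- reference_composition(filt$data)
  orders <- lapply(config$report_pivots, pivot_order)
  fit_order <- orders[[1]]
  results <- list()
  diag_rows <- list()
  for (timing in config$timings) {
    for (outcome in config$outcomes) {
      dat <- filt$data
      if (timing == "prospective") dat <- shift_outcome_next_day(dat, outcome)
      dec <- decompose(dat, order = fit_order)
      spec <- model_spec(outcome, order = fit_order,
                         chains = config$chains, iter = config$iter,
                         warmup = config$warmup, seed = config$seed)
      design <- build_design(dec, spec)
      t0 <- Sys.time()
      fit <- fit_mlcoda(design, spec)
      message(sprintf("[fit] %s/%s: n=%d rows, %d participants, %.1fs, converged=%s",
                      outcome, timing, length(design$y), max(design$g),
                      as.numeric(Sys.time() - t0, units = "secs"),
                      fit$diagnostics$converged))
      summ <- summarize_fit(fit, report_orders = orders)
      grid <- substitution_grid(fit, base, minutes = config$sub_minutes)
      mats <- lapply(setNames(c("between", "within"), c("between", "within")),
                     function(lv) substitution_matrix(grid,
                                                      config$matrix_minutes, lv))
      key <- paste(outcome, timing, sep = "_")
      results[[key]] <- list(outcome = outcome, timing = timing,
                             summary = summ, grid = grid, matrices = mats,
                             fit = fit)
      diag_rows[[key]] <- data.frame(model = key,
                                     max_rhat = max(fit$diagnostics$table$rhat),
                                     min_ess = min(fit$diagnostics$table$ess),
                                     converged = fit$diagnostics$converged)
    }
  }
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL
  out <- list(reference = base, exclusions = filt$exclusions,
              diagnostics = diagnostics, fits = results)
  if (!is.null(out_dir)) write_reports(out, config, out_dir)
  out
}

write_reports <- function(res, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(res$exclusions, "exclusions.csv")
  wcsv(res$diagnostics, "diagnostics.csv")
  for (key in names(res$fits)) {
    f <- res$fits[[key]]
    wcsv(f$summary, sprintf("coefficients_%s.csv", key))
    wcsv(f$grid, sprintf("substitution_grid_%s.csv", key))
    for (lv in names(f$matrices)) {
      m <- as.data.frame(f$matrices[[lv]])
      m <- cbind(up = rownames(m), m)
      wcsv(m, sprintf("substitution_matrix_%dmin_%s_%s.csv",
                      config$matrix_minutes, lv, key))
    }
  }
  manifest <- list(
    seed = config$seed, outcomes = config$outcomes,
    timings = config$timings, chains = config$chains, iter = config$iter,
    warmup = config$warmup,
    reference_composition = as.list(res$reference),
    converged = all(res$diagnostics$converged),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("coda24")))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
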