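#' Columns holding part minutes in a participant-day table
#'
#' The long data contract: one row per participant-day with columns
#' `pid`, `day`, `<part>_min` for each behavior, `wear_h`, `walk_detected`,
#' outcome columns, and baseline covariates `age`, `sex`, `bmi`.
#'
#' @param parts Part labels.
#' @return Column names of the minute columns.
#' @export
part_columns <- function(parts = BEHAVIOR_PARTS) paste0(parts, "_min")

#' Extract the composition matrix from a participant-day table
#'
#' @param data Participant-day data frame.
#' @param parts Part labels.
#' @return Numeric matrix, one closed-or-raw composition per row, columns
#'   named by `parts`.
#' @export
composition_matrix <- function(data, parts = BEHAVIOR_PARTS) {
  cols <- part_columns(parts)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing part columns: ", paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(data[cols])
  colnames(m) <- parts
  m
}

#' A person's average 24-hour composition
#'
#' The geometric center of the person's day compositions: the compositional
#' mean whose ilr image is the arithmetic mean of the day ilr vectors, so
#' that within-person deviations are mean-zero in ilr space by construction.
#'
#' @param days Matrix of the person's day compositions (rows).
#' @param total Closure total in minutes.
#' @export
person_mean_composition <- function(days, total = DAY_MINUTES) {
  geometric_center(days, total = total)
}

#' Between/within-person decomposition in ilr coordinates
#'
#' Splits each participant-day composition into the participant's average
#' 24-h composition (between-person level) and the day's mean-centered
#' deviation from it (within-person level), both expressed as ilr pivot
#' coordinates. The split is exact: for every row,
#' `between + within == ilr(day composition)`, and each participant's
#' within vectors average to zero.
#'
#' Days are always closed to `total` before transformation. All of a
#' participant's valid days contribute to the compositional mean, including
#' days whose outcome is missing (those are dropped later, at the design
#' stage, not here).
#'
#' @param data Participant-day data frame (see [part_columns()]).
#' @param order Pivot order used for the coordinates.
#' @param parts Part labels.
#' @param total Closure total in minutes.
#' @return `data` with added columns `bilr1..bilr(D-1)` (between, constant
#'   within participant) and `wilr1..wilr(D-1)` (within). The pivot order
#'   is stored in attribute `"order"`, part labels in `"parts"`.
#' @export
decompose <- function(data, order = pivot_order("mvpa"),
                      parts = BEHAVIOR_PARTS, total = DAY_MINUTES) {
  if (!all(c("pid", "day") %in% names(data))) stop("need pid and day columns")
  if (anyDuplicated(data[c("pid", "day")]) > 0) {
    stop("duplicate participant-day rows")
  }
  comp <- tryCatch(
    close_composition(composition_matrix(data, parts), total = total),
    error = function(e) {
      stop("invalid composition in participant-day table: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  z <- ilr_pivot(comp, order)
  pid <- as.character(data$pid)
  between <- apply(z, 2, function(col) ave(col, pid, FUN = mean))
  between <- matrix(between, nrow = nrow(z))
  within <- z - between
  D1 <- ncol(z)
  bcols <- paste0("bilr", seq_len(D1))
  wcols <- paste0("wilr", seq_len(D1))
  out <- data
  out[bcols] <- as.data.frame(between)
  out[wcols] <- as.data.frame(within)
  attr(out, "order") <- order
  attr(out, "parts") <- parts
  attr(out, "total") <- total
  out
}

#' Sample reference composition for substitution analyses
#'
#' The geometric center of the participants' mean compositions, each person
#' weighted equally ("the mean composition among included participants").
#' Set `pooled = TRUE` to weight by days instead (center of all days).
#'
#' @param data Participant-day data frame.
#' @param parts Part labels.
#' @param total Closure total in minutes.
#' @param pooled Pool all days instead of averaging person means.
#' @export
reference_composition <- function(data, parts = BEHAVIOR_PARTS,
                                  total = DAY_MINUTES, pooled = FALSE) {
  comp <- close_composition(composition_matrix(data, parts), total = total)
  if (pooled) return(geometric_center(comp, total = total))
  pid <- as.character(data$pid)
  centers <- t(vapply(split.data.frame(comp, pid),
                      function(m) geometric_center(m, total = total),
                      numeric(length(parts))))
  geometric_center(centers, total = total)
}
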