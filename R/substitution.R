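#' Reallocate minutes between two behaviors
#'
#' Moves `minutes` from `from_part` to `to_part`, all other parts and the
#' total unchanged. Errors if the donor part would be left with no time.
#'
#' @param base Named numeric composition (minutes).
#' @param to_part,from_part Distinct part labels.
#' @param minutes Minutes to move (>= 0).
#' @return The reallocated composition.
#' @examples
#' base <- close_composition(c(sleep = 477, sedentary = 630,
#'                             standing = 167.4, lpa = 69, mvpa = 81))
#' reallocate(base, "mvpa", "sedentary", 30)
#' @export
reallocate <- function(base, to_part, from_part, minutes) {
  stopifnot(is.numeric(minutes), length(minutes) == 1, minutes >= 0)
  if (identical(to_part, from_part)) stop("to_part and from_part must differ")
  if (!all(c(to_part, from_part) %in% names(base))) {
    stop("unknown part label in reallocation")
  }
  if (base[from_part] <= minutes) {
    stop(sprintf("infeasible reallocation: '%s' has %.1f min, cannot remove %.1f",
                 from_part, base[from_part], minutes))
  }
  out <- base
  out[to_part] <- out[to_part] + minutes
  out[from_part] <- out[from_part] - minutes
  out
}

#' Posterior estimate for one time reallocation
#'
#' Expected change in the outcome when `minutes` move from `from_part` to
#' `to_part`, relative to the reference composition `base`. Per posterior
#' draw the change is `beta_level . (ilr(reallocated) - ilr(base))`, with
#' `beta_level` the between- or within-person compositional coefficients;
#' covariates and random effects cancel in the difference. At the within
#' level the reference day is an average day (zero within-deviation), so
#' the reallocated day's deviation is exactly the ilr difference.
#'
#' @param fit A `mlcoda_fit`.
#' @param base Reference composition (e.g. [reference_composition()]).
#' @param to_part,from_part Part labels.
#' @param minutes Minutes to move.
#' @param level `"between"` or `"within"`.
#' @param prob Credible-interval mass.
#' @return One-row data frame: `level`, `to`, `from`, `minutes`, `mean`,
#'   `lower`, `upper`, `significant`, `feasible`.
#' @export
substitution_estimate <- function(fit, base, to_part, from_part, minutes,
                                  level = c("within", "between"),
                                  prob = 0.95) {
  level <- match.arg(level)
  feasible <- base[from_part] > minutes
  if (!feasible) {
    return(data.frame(level = level, to = to_part, from = from_part,
                      minutes = minutes, mean = NA_real_, lower = NA_real_,
                      upper = NA_real_, significant = NA, feasible = FALSE))
  }
  if (minutes == 0) {
    return(data.frame(level = level, to = to_part, from = from_part,
                      minutes = 0, mean = 0, lower = 0, upper = 0,
                      significant = FALSE, feasible = TRUE))
  }
  dz <- ilr_pivot(reallocate(base, to_part, from_part, minutes), fit$order) -
    ilr_pivot(base, fit$order)
  dy <- as.numeric(coef_draws(fit, level) %*% as.numeric(dz))
  s <- summarize_draws_vec(dy, prob)
  data.frame(level = level, to = to_part, from = from_part, minutes = minutes,
             mean = s["mean"], lower = s["lower"], upper = s["upper"],
             significant = s["lower"] > 0 | s["upper"] < 0, feasible = TRUE,
             row.names = NULL)
}

#' Full pairwise substitution grid
#'
#' All ordered behavior pairs, both levels, over a grid of durations
#' (default 1-60 min). Because the ilr transform is non-linear in minutes,
#' the grid covers both directions explicitly: the "add 30 min to A from B"
#' and "add 30 min to B from A" cells are distinct estimates, which
#' together trace the "adding to" and "deducting from" curves.
#' Infeasible cells (donor part exhausted) are flagged, not dropped.
#'
#' @param fit A `mlcoda_fit`.
#' @param base Reference composition.
#' @param minutes Duration grid (default `1:60`).
#' @param levels Levels to compute.
#' @param prob Credible-interval mass.
#' @return Long data frame of substitution estimates.
#' @export
substitution_grid <- function(fit, base, minutes = 1:60,
                              levels = c("between", "within"), prob = 0.95) {
  if (length(minutes) == 0) stop("empty duration grid")
  parts <- names(base)
  pairs <- expand.grid(to = parts, from = parts, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$to != pairs$from, ]
  rows <- vector("list", length(levels) * nrow(pairs) * length(minutes))
  i <- 0
  for (lv in levels) {
    bdraws <- coef_draws(fit, lv)
    zbase <- as.numeric(ilr_pivot(base, fit$order))
    for (r in seq_len(nrow(pairs))) {
      for (m in minutes) {
        i <- i + 1
        to <- pairs$to[r]; from <- pairs$from[r]
        if (base[from] <= m) {
          rows[[i]] <- data.frame(level = lv, to = to, from = from,
                                  minutes = m, mean = NA_real_,
                                  lower = NA_real_, upper = NA_real_,
                                  significant = NA, feasible = FALSE)
          next
        }
        dz <- as.numeric(ilr_pivot(reallocate(base, to, from, m),
                                   fit$order)) - zbase
        dy <- as.numeric(bdraws %*% dz)
        s <- summarize_draws_vec(dy, prob)
        rows[[i]] <- data.frame(level = lv, to = to, from = from, minutes = m,
                                mean = s["mean"], lower = s["lower"],
                                upper = s["upper"],
                                significant = s["lower"] > 0 | s["upper"] < 0,
                                feasible = TRUE, row.names = NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise matrix view of a substitution grid at one duration
#'
#' Reshapes the long grid into the conventional reallocation matrix:
#' rows are the behavior gaining time, columns the behavior losing it,
#' cells the posterior mean difference (diagonal `NA`).
#'
#' @param grid Output of [substitution_grid()].
#' @param minutes Duration to display (default 30).
#' @param level Level to display.
#' @param parts Row/column order.
#' @export
substitution_matrix <- function(grid, minutes = 30, level = "within",
                                parts = BEHAVIOR_PARTS) {
  g <- grid[grid$minutes == minutes & grid$level == level, ]
  if (nrow(g) == 0) stop("no grid cells at that duration/level")
  m <- matrix(NA_real_, length(parts), length(parts),
              dimnames = list(up = parts, down = parts))
  for (r in seq_len(nrow(g))) m[g$to[r], g$from[r]] <- g$mean[r]
  m
}
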