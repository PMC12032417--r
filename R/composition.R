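#' coda24: multilevel compositional analysis of 24-hour physical behavior
#'
#' Core workflow: [close_composition()] and [ilr_pivot()] for simplex
#' geometry, [decompose()] for the between/within-person split,
#' [fit_mlcoda()] for the Bayesian multilevel model, and
#' [substitution_grid()] for posterior time-reallocation estimates.
#'
#' @importFrom stats rnorm rgamma rbinom runif sd var ave quantile qnorm
#'   setNames complete.cases update
#' @importFrom utils read.csv write.csv packageVersion
#' @keywords internal
"_PACKAGE"

#' Default behavior labels of the 24-hour composition
#'
#' Sleep period, sedentary time, standing, light physical activity, and
#' moderate-to-vigorous physical activity, in canonical order.
#' @export
BEHAVIOR_PARTS <- c("sleep", "sedentary", "standing", "lpa", "mvpa")

#' Minutes in a full day
#' @export
DAY_MINUTES <- 1440

as_part_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(colnames(x))) stop("composition matrix must have column names")
    return(x)
  }
  if (is.null(names(x))) stop("composition vector must be named")
  matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
}

restore_shape <- function(m, like) {
  if (is.matrix(like)) m else m[1, ]
}

#' Close a vector of part minutes to a fixed daily total
#'
#' Rescales strictly positive parts so they sum to `total` (the closure
#' operation of Aitchison geometry). Zero or negative parts are an error:
#' the day-level inclusion rules of the intended data (e.g. sleep > 0 min)
#' make all five behaviors positive, so zeros indicate an upstream problem.
#' For degenerate synthetic rows, [offset_zero_parts()] can be applied first.
#'
#' @param x Named numeric vector of part minutes, or a matrix with one
#'   composition per row and part labels as column names.
#' @param total Positive total to close to, in minutes (default 1440).
#' @return Closed composition(s), same shape as `x`, summing to `total`.
#' @examples
#' close_composition(c(sleep = 477, sedentary = 630, standing = 167.4,
#'                     lpa = 69, mvpa = 81))
#' @export
close_composition <- function(x, total = DAY_MINUTES) {
  stopifnot(is.numeric(total), length(total) == 1, total > 0)
  m <- as_part_matrix(x)
  if (ncol(m) < 2) stop("a composition needs at least 2 parts")
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    lab <- colnames(m)[bad[1, "col"]]
    stop(sprintf("part '%s' is not strictly positive (row %d); %s",
                 lab, bad[1, "row"],
                 "apply offset_zero_parts() first if zeros are expected"))
  }
  out <- m * (total / rowSums(m))
  restore_shape(out, x)
}

#' Replace zero parts by a small offset before closure
#'
#' Utility for degenerate rows (e.g. a simulated day with 0 recorded minutes
#' in a behavior). Adds nothing when all parts are positive; otherwise sets
#' zero parts to `offset` minutes. Off by default in the pipeline.
#'
#' @param x Named numeric vector or row matrix of part minutes (non-negative).
#' @param offset Minutes to assign to zero parts (default 0.5).
#' @export
offset_zero_parts <- function(x, offset = 0.5) {
  stopifnot(offset > 0)
  m <- as_part_matrix(x)
  if (any(m < 0)) stop("parts must be non-negative")
  m[m == 0] <- offset
  restore_shape(m, x)
}

#' Construct a pivot ordering of composition parts
#'
#' A pivot order puts one part first; the first ilr pivot coordinate then
#' contrasts that part against the geometric mean of all remaining parts.
#' Remaining parts follow in canonical order (the order of `parts`), which
#' fixes coordinates 2..D-1; the first coordinate does not depend on it.
#'
#' @param first Label of the pivot part.
#' @param parts Character vector of all part labels in canonical order.
#' @return Character vector: a permutation of `parts` with `first` first.
#' @examples
#' pivot_order("mvpa")
#' pivot_order("sedentary")
#' @export
pivot_order <- function(first, parts = BEHAVIOR_PARTS) {
  if (!first %in% parts) stop(sprintf("unknown part '%s'", first))
  c(first, setdiff(parts, first))
}

check_order <- function(order, labels) {
  if (!setequal(order, labels) || length(order) != length(labels) ||
      anyDuplicated(order) > 0) {
    stop("pivot order must be a permutation of the composition's part labels")
  }
}

#' Contrast matrix of the pivot-coordinate ilr basis
#'
#' Returns the D x (D-1) matrix `V` with orthonormal, zero-sum columns such
#' that `z = t(V) %*% log(x)` gives the pivot coordinates
#' `z_k = sqrt((D-k)/(D-k+1)) * log(x_(k) / gmean(x_(k+1..D)))` for parts
#' taken in `order`. Rows of `V` are indexed by `labels` (the data's column
#' order), so the same matrix applies directly to unpermuted compositions.
#'
#' @param order Pivot order (permutation of `labels`).
#' @param labels Part labels in data column order.
#' @export
pivot_basis <- function(order, labels = order) {
  check_order(order, labels)
  D <- length(order)
  V <- matrix(0, D, D - 1, dimnames = list(order, NULL))
  for (k in seq_len(D - 1)) {
    r <- D - k
    a <- sqrt(r / (r + 1))
    V[k, k] <- a
    V[(k + 1):D, k] <- -a / r
  }
  V[labels, , drop = FALSE]
}

#' Isometric log-ratio pivot coordinates
#'
#' Maps D-part compositions to (D-1)-dimensional real vectors. The first
#' coordinate is proportional to the log-ratio of the pivot part to the
#' geometric mean of the remaining parts; e.g. under `pivot_order("mvpa")`
#' it is read as "MVPA relative to the remaining behaviors". The map is
#' scale invariant, so closure before or after does not change the result.
#'
#' @param x Named numeric vector, or matrix of compositions (rows).
#' @param order Pivot order; defaults to the parts in data order.
#' @return Numeric vector of length D-1, or a matrix with D-1 columns
#'   (`z1`, `z2`, ...), with attribute `"order"` recording the pivot order.
#' @examples
#' x <- close_composition(c(sleep = 477, sedentary = 630, standing = 167.4,
#'                          lpa = 69, mvpa = 81))
#' ilr_pivot(x, pivot_order("mvpa"))
#' @export
ilr_pivot <- function(x, order = NULL) {
  m <- as_part_matrix(x)
  labels <- colnames(m)
  if (is.null(order)) order <- labels
  check_order(order, labels)
  if (any(m <= 0)) stop("all parts must be strictly positive")
  V <- pivot_basis(order, labels)
  z <- log(m) %*% V
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  out <- restore_shape(z, x)
  attr(out, "order") <- order
  out
}

#' Inverse ilr transform back to a closed composition
#'
#' Reverses [ilr_pivot()]: `x = close(exp(V %*% z))`. The zero vector maps
#' to the uniform composition.
#'
#' @param z Numeric vector of length D-1, or matrix with D-1 columns.
#' @param order Pivot order used to build the coordinates; defaults to the
#'   `"order"` attribute of `z`.
#' @param labels Part labels in the output column order (default: canonical
#'   order implied by `order`, i.e. `sort`-free data order is unknown, so
#'   the order itself is used unless `labels` is given).
#' @param total Closure total in minutes.
#' @export
ilr_inverse <- function(z, order = attr(z, "order"), labels = NULL,
                        total = DAY_MINUTES) {
  if (is.null(order)) stop("pivot order is required (attribute or argument)")
  if (is.null(labels)) labels <- order
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  if (!all(is.finite(zm))) stop("ilr coordinates must be finite")
  if (ncol(zm) != length(order) - 1) stop("length(z) must equal D - 1")
  V <- pivot_basis(order, labels)
  x <- exp(zm %*% t(V))
  colnames(x) <- labels
  out <- close_composition(x, total = total)
  restore_shape(out, z)
}

#' Orthogonal rotation between two pivot bases
#'
#' Pivot bases for different orderings of the same parts are related by an
#' orthogonal (D-1) x (D-1) matrix `Q = t(V_new) %*% V_old`, so coordinates
#' (and, by equivariance, regression coefficients on those coordinates)
#' transform linearly: `z_new = Q %*% z_old`, `beta_new = Q %*% beta_old`.
#'
#' @param from,to Pivot orders (permutations of the same labels).
#' @return The orthogonal matrix `Q`.
#' @export
rotation_matrix <- function(from, to) {
  check_order(to, from)
  labels <- from
  crossprod(pivot_basis(to, labels), pivot_basis(from, labels))
}

#' Re-express ilr coordinates in another pivot basis
#'
#' Equivalent to `ilr_pivot(ilr_inverse(z), new_order)` but computed as the
#' linear map of [rotation_matrix()], which is what allows posterior
#' coefficient draws from one fit to be reported in several bases.
#'
#' @param z ilr vector or matrix with an `"order"` attribute (or `from`).
#' @param new_order Target pivot order.
#' @param from Source pivot order; defaults to `attr(z, "order")`.
#' @export
rotate_basis <- function(z, new_order, from = attr(z, "order")) {
  if (is.null(from)) stop("source pivot order is required")
  Q <- rotation_matrix(from, new_order)
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  out <- zm %*% t(Q)
  colnames(out) <- paste0("z", seq_len(ncol(out)))
  out <- restore_shape(out, z)
  attr(out, "order") <- new_order
  out
}

#' Geometric center of a set of compositions
#'
#' The closed per-part geometric mean -- the compositional mean of Aitchison
#' geometry, identical to mapping to ilr space, averaging arithmetically,
#' and mapping back. Used both for a person's average 24-h composition and
#' for the sample reference composition of substitution analyses.
#'
#' @param x Matrix of compositions (one per row, labelled columns).
#' @param total Closure total in minutes.
#' @return A single named composition summing to `total`.
#' @export
geometric_center <- function(x, total = DAY_MINUTES) {
  m <- as_part_matrix(x)
  if (nrow(m) == 0) stop("need at least one composition")
  if (any(m <= 0)) stop("all parts must be strictly positive")
  g <- exp(colMeans(log(m)))
  close_composition(g, total = total)
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between clr (equivalently ilr) images; the metric
#' under which [ilr_pivot()] is an isometry.
#'
#' @param x,y Named numeric compositions over the same parts.
#' @export
aitchison_distance <- function(x, y) {
  stopifnot(setequal(names(x), names(y)))
  lx <- log(x)
  ly <- log(y[names(x)])
  cx <- lx - mean(lx)
  cy <- ly - mean(ly)
  sqrt(sum((cx - cy)^2))
}
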