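# Independent oracles, written before the implementations they check.

# Pivot-coordinate formula evaluated directly, scalar loop, geometric means
# via products: z_k = sqrt((D-k)/(D-k+1)) * ln( x_(k) / gm(x_(k+1..D)) ).
# Shares no code path with ilr_pivot()'s contrast-matrix route.
oracle_ilr <- function(x, order) {
  xo <- x[order]
  D <- length(xo)
  z <- numeric(D - 1)
  for (k in seq_len(D - 1)) {
    rest <- xo[(k + 1):D]
    gm <- prod(rest)^(1 / length(rest))
    z[k] <- sqrt((D - k) / (D - k + 1)) * log(xo[k] / gm)
  }
  z
}

# Random strictly-positive compositions closed to 1440, log-normal parts.
random_compositions <- function(n, parts = BEHAVIOR_PARTS, sd = 0.6) {
  m <- matrix(exp(rnorm(n * length(parts), 0, sd)), n,
              dimnames = list(NULL, parts))
  close_composition(m)
}

table1_mean_minutes <- c(sleep = 477, sedentary = 630, standing = 167.4,
                         lpa = 69, mvpa = 81)

small_fixture_path <- function() {
  system.file("extdata", "ema_days_synthetic_small.csv", package = "coda24")
}
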