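# Small fits are expensive relative to the rest of the suite; memoize the
# ones shared across test files.
.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, force(expr), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

# Filtered + decomposed small fixture (MVPA-first basis).
fixture_decomposed <- function() {
  cached("fixture_dec", {
    d <- read_behavior_csv(small_fixture_path())
    decompose(filter_days(d)$data)
  })
}

# A quick real fit on the fixture for tests that need genuine draws but not
# tight posteriors.
fixture_fit_quick <- function() {
  cached("fixture_fit_quick", {
    dec <- fixture_decomposed()
    spec <- model_spec("valence", chains = 2, iter = 700, warmup = 300,
                       seed = 11)
    suppressWarnings(fit_mlcoda(build_design(dec, spec), spec))
  })
}

# Minimal hand-constructed fit object with known coefficients: a posterior
# of `ndraws` identical (or supplied) draws, for exact substitution algebra.
fake_fit <- function(beta_b, beta_w, order = pivot_order("mvpa"),
                     covariates = c("age", "sex"), intercept = 60,
                     gamma = rep(0.5, length(covariates))) {
  D1 <- length(order) - 1
  stopifnot(length(beta_b) == D1, length(beta_w) == D1)
  bcols <- paste0("bilr", seq_len(D1))
  wcols <- paste0("wilr", seq_len(D1))
  x_colnames <- c("(Intercept)", bcols, wcols, covariates)
  draws <- matrix(c(intercept, beta_b, beta_w, gamma), nrow = 1,
                  dimnames = list(NULL, x_colnames))
  structure(list(draws = draws, order = order, D1 = D1, bcols = bcols,
                 wcols = wcols, covariates = covariates,
                 x_colnames = x_colnames),
            class = "mlcoda_fit")
}
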