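#' Specification of the Bayesian multilevel compositional model
#'
#' Describes one model: a daily Gaussian outcome regressed on between- and
#' within-person ilr pivot coordinates plus covariates, with a random
#' intercept and correlated random within-composition slopes by participant.
#'
#' Priors are weakly informative and scaled by the outcome SD:
#' Normal(0, `beta_scale` * sd(y)) on regression coefficients (intercept
#' centered at mean(y)), half-Student-t(3, 0, `sigma_scale` * sd(y)) on the
#' residual SD, and a Wishart(I, K+1) prior on the random-effect precision
#' matrix (K = 1 + D-1 correlated effects).
#'
#' @param outcome Name of the outcome column.
#' @param order Pivot order used for fitting.
#' @param covariates Covariate columns; `"lag"` is the previous-day outcome,
#'   computed by [build_design()].
#' @param chains,iter,warmup MCMC settings (post-warmup draws per chain =
#'   `iter - warmup`).
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param ranef Include the random intercept + within-slope structure
#'   (disable only for the fixed-effects limit used in checks).
#' @param beta_scale,sigma_scale Prior scale multipliers.
#' @return An object of class `mlcoda_spec`.
#' @export
model_spec <- function(outcome, order = pivot_order("mvpa"),
                       covariates = c("age", "sex", "bmi", "wear_h", "lag"),
                       chains = 4, iter = 2000, warmup = 1000, seed = 1,
                       ranef = TRUE, beta_scale = 10, sigma_scale = 2.5) {
  stopifnot(iter > warmup, chains >= 1, warmup >= 0)
  structure(list(outcome = outcome, order = order, covariates = covariates,
                 chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 ranef = isTRUE(ranef), beta_scale = beta_scale,
                 sigma_scale = sigma_scale),
            class = "mlcoda_spec")
}

code_sex <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  tolower(as.character(x)) %in% c("male", "m", "1")  + 0
}

#' Build the model-input table from decomposed data
#'
#' One row per usable participant-day: the outcome, between/within ilr
#' coordinates, and covariates. The `lag` covariate is the outcome on the
#' participant's previous calendar day; rows without an adjacent previous
#' day (each participant's first day, and days after an index gap) are
#' dropped, as are rows with any missing field. Continuous covariates are
#' mean-centered; `sex` is coded male = 1. Centering shifts only the
#' intercept, not compositional coefficients or substitution differences.
#'
#' @param decomposed Output of [decompose()].
#' @param spec A [model_spec()].
#' @return List of class `mlcoda_design`: `X` (fixed-effect matrix),
#'   `Zw` (within-ilr columns for the random slopes), `y`, `g` (participant
#'   index), `pid` levels, plus the pivot order and column bookkeeping.
#' @export
build_design <- function(decomposed, spec) {
  order <- attr(decomposed, "order")
  if (is.null(order)) stop("run decompose() first")
  if (!identical(order, spec$order)) {
    decomposed <- decompose(decomposed[setdiff(names(decomposed),
                              grep("^[bw]ilr", names(decomposed), value = TRUE))],
                            order = spec$order,
                            parts = attr(decomposed, "parts"),
                            total = attr(decomposed, "total"))
    order <- spec$order
  }
  if (!spec$outcome %in% names(decomposed)) {
    stop(sprintf("outcome '%s' not found in data", spec$outcome))
  }
  D1 <- length(order) - 1
  df <- decomposed[order(decomposed$pid, decomposed$day), ]
  use_lag <- "lag" %in% spec$covariates
  if (use_lag) {
    prev <- c(NA, df[[spec$outcome]][-nrow(df)])
    adjacent <- c(FALSE, diff(df$day) == 1 &
                    df$pid[-1] == df$pid[-nrow(df)])
    df$lag <- ifelse(adjacent, prev, NA)
  }
  covs <- spec$covariates
  missing_covs <- setdiff(setdiff(covs, "lag"), names(df))
  if (length(missing_covs) > 0) {
    stop("missing covariate columns: ", paste(missing_covs, collapse = ", "))
  }
  bcols <- paste0("bilr", seq_len(D1))
  wcols <- paste0("wilr", seq_len(D1))
  keep <- complete.cases(df[c(spec$outcome, bcols, wcols, covs)])
  df <- df[keep, , drop = FALSE]
  if (length(unique(df$pid)) < 2) stop("need at least 2 participants")

  cov_mat <- matrix(0, nrow(df), length(covs),
                    dimnames = list(NULL, covs))
  for (cv in covs) {
    v <- if (cv == "sex") code_sex(df[[cv]]) else as.numeric(df[[cv]])
    if (cv != "sex") v <- v - mean(v)
    cov_mat[, cv] <- v
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(df[bcols]), as.matrix(df[wcols]), cov_mat)
  g <- match(df$pid, unique(df$pid))
  structure(list(X = X, Zw = as.matrix(df[wcols]), y = as.numeric(df[[spec$outcome]]),
                 g = g, pid = unique(df$pid), data = df,
                 order = order, D1 = D1,
                 bcols = bcols, wcols = wcols, covariates = covs),
            class = "mlcoda_design")
}

jags_model_string <- function(ranef) {
  if (ranef) "
model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i,], beta) + u[g[i],1] + inprod(Zw[i,], u[g[i],2:K])
    y[i] ~ dnorm(mu[i], tau_res)
  }
  # scaled inverse-Wishart: per-component half-t scales xi[k] around a
  # Wishart-correlated core, so intercept and slope SDs on very different
  # scales are not pooled toward a common magnitude
  for (j in 1:J) {
    u_raw[j,1:K] ~ dmnorm(zero[1:K], Omega[1:K,1:K])
    for (k in 1:K) { u[j,k] <- xi[k] * u_raw[j,k] }
  }
  Omega[1:K,1:K] ~ dwish(R[1:K,1:K], K + 1)
  Sigma_raw[1:K,1:K] <- inverse(Omega[1:K,1:K])
  for (k in 1:K) {
    xi[k] ~ dt(0, prec_s, 3) T(0,)
    sd_u[k] <- xi[k] * sqrt(Sigma_raw[k,k])
    for (l in 1:K) { Sigma_u[k,l] <- xi[k] * xi[l] * Sigma_raw[k,l] }
  }
  for (p in 1:P) { beta[p] ~ dnorm(mu_b[p], prec_b) }
  sigma ~ dt(0, prec_s, 3) T(0,)
  tau_res <- pow(sigma, -2)
}" else "
model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i,], beta)
    y[i] ~ dnorm(mu[i], tau_res)
  }
  for (p in 1:P) { beta[p] ~ dnorm(mu_b[p], prec_b) }
  sigma ~ dt(0, prec_s, 3) T(0,)
  tau_res <- pow(sigma, -2)
}"
}

#' Fit the multilevel compositional model by Gibbs sampling
#'
#' Runs JAGS on the design from [build_design()] and returns posterior
#' draws with convergence diagnostics. Non-convergence is not an error:
#' the fit is returned with `diagnostics$converged == FALSE` and a warning.
#'
#' @param design A `mlcoda_design`.
#' @param spec The matching [model_spec()].
#' @param quiet Suppress JAGS progress output.
#' @return Object of class `mlcoda_fit`: `draws` (matrix, one named column
#'   per parameter, `chains * (iter - warmup)` rows), `samples` (the
#'   underlying `coda::mcmc.list`), `diagnostics` (per-parameter split-Rhat
#'   and bulk ESS plus the overall `converged` flag), the spec, and design
#'   bookkeeping.
#' @export
fit_mlcoda <- function(design, spec, quiet = TRUE) {
  stopifnot(inherits(design, "mlcoda_design"), inherits(spec, "mlcoda_spec"))
  y <- design$y
  X <- design$X
  P <- ncol(X)
  sdy <- sd(y)
  if (!is.finite(sdy) || sdy <= 0) sdy <- 1
  mu_b <- numeric(P)
  mu_b[1] <- mean(y)
  dat <- list(N = length(y), P = P, X = X, y = y,
              mu_b = mu_b, prec_b = 1 / (spec$beta_scale * sdy)^2,
              prec_s = 1 / (spec$sigma_scale * sdy)^2)
  monitor <- c("beta", "sigma")
  if (spec$ranef) {
    K <- 1 + design$D1
    dat <- c(dat, list(J = max(design$g), K = K, g = design$g,
                       Zw = design$Zw, zero = rep(0, K), R = diag(K)))
    monitor <- c(monitor, "sd_u", "Sigma_u")
  }
  inits <- lapply(seq_len(spec$chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = spec$seed + c)
  })
  # block samplers for the linear-model conditionals; essential for mixing
  # of between-person coefficients against the random intercept
  rjags::load.module("glm", quiet = TRUE)
  adapt <- min(500L, max(100L, spec$warmup %/% 2L))
  jm <- rjags::jags.model(textConnection(jags_model_string(spec$ranef)),
                          data = dat, n.chains = spec$chains,
                          n.adapt = adapt, inits = inits, quiet = quiet)
  burn <- max(0L, spec$warmup - adapt)
  if (burn > 0) update(jm, burn, progress.bar = "none")
  samples <- rjags::coda.samples(jm, monitor, n.iter = spec$iter - spec$warmup,
                                 progress.bar = "none")
  samples <- rename_parameters(samples, design, spec)
  # the convergence gate covers population-level parameters (regression
  # coefficients and the residual SD); group-level SD diagnostics are
  # reported alongside but do not gate
  pop_pars <- c(colnames(design$X), "sigma")
  diag <- mcmc_diagnostics(samples, pop_pars)
  if (spec$ranef) {
    extra <- mcmc_diagnostics(samples,
                              paste0("sd_u[", seq_len(1 + design$D1), "]"))
    diag$group_table <- extra$table
  }
  if (!diag$converged) {
    warning(sprintf(
      "fit for '%s' did not meet convergence gates (max Rhat %.3f, min ESS %.0f)",
      spec$outcome, max(diag$table$rhat), min(diag$table$ess)))
  }
  draws <- as.matrix(samples)
  structure(list(draws = draws, samples = samples, diagnostics = diag,
                 spec = spec, order = design$order, D1 = design$D1,
                 bcols = design$bcols, wcols = design$wcols,
                 covariates = design$covariates,
                 x_colnames = colnames(design$X)),
            class = "mlcoda_fit")
}

# Map raw JAGS node names (beta[1], ...) to design column names.
rename_parameters <- function(samples, design, spec) {
  nm <- colnames(samples[[1]])
  new <- nm
  betas <- grep("^beta\\[", nm)
  idx <- as.integer(sub("^beta\\[(\\d+)\\]$", "\\1", nm[betas]))
  new[betas] <- colnames(design$X)[idx]
  as.mcmc.list(lapply(samples, function(ch) {
    colnames(ch) <- new
    ch
  }))
}

#' @importFrom coda as.mcmc.list as.mcmc mcmc effectiveSize
NULL

split_chain_matrix <- function(samples, par) {
  m <- sapply(samples, function(ch) as.numeric(ch[, par]))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(samples))
  n <- nrow(m) %/% 2
  cbind(m[seq_len(n), , drop = FALSE],
        m[(nrow(m) - n + 1):nrow(m), , drop = FALSE])
}

#' Split-chain potential scale reduction factor (Rhat)
#'
#' Each chain is split in half and the classic between/within variance
#' ratio is computed over the split chains, so within-chain trends are
#' detected even with few chains.
#'
#' @param samples A `coda::mcmc.list`.
#' @param par Parameter (column) name.
#' @export
rhat_split <- function(samples, par) {
  m <- split_chain_matrix(samples, par)
  n <- nrow(m)
  W <- mean(apply(m, 2, var))
  B <- n * var(colMeans(m))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bulk effective sample size
#'
#' Draws are rank-normalized (pooled ranks mapped through the normal
#' quantile function), chains are split in half, and per-split-chain
#' effective sizes from [coda::effectiveSize()] are summed -- a bulk-ESS
#' measure robust to heavy tails, paired with [rhat_split()] for the
#' cross-chain check.
#'
#' @inheritParams rhat_split
#' @export
ess_bulk <- function(samples, par) {
  m <- split_chain_matrix(samples, par)
  r <- matrix(rank(m, ties.method = "average"), nrow = nrow(m))
  z <- qnorm((r - 3 / 8) / (length(m) + 1 / 4))
  sum(apply(z, 2, function(col) coda::effectiveSize(coda::mcmc(col))))
}

#' Convergence diagnostics over monitored parameters
#'
#' @param samples A `coda::mcmc.list`.
#' @param pars Parameters to gate on (default: all columns).
#' @param rhat_max,ess_min Convergence gates (defaults 1.05 and 400).
#' @return List: `table` (per-parameter rhat/ess) and `converged`.
#' @export
mcmc_diagnostics <- function(samples, pars = NULL,
                             rhat_max = 1.05, ess_min = 400) {
  if (is.null(pars)) pars <- colnames(samples[[1]])
  pars <- intersect(pars, colnames(samples[[1]]))
  tab <- data.frame(
    parameter = pars,
    rhat = vapply(pars, function(p) rhat_split(samples, p), numeric(1)),
    ess = vapply(pars, function(p) ess_bulk(samples, p), numeric(1)),
    row.names = NULL)
  list(table = tab,
       converged = all(tab$rhat < rhat_max) && all(tab$ess > ess_min),
       rhat_max = rhat_max, ess_min = ess_min)
}

#' Extract compositional coefficient draws
#'
#' @param fit A `mlcoda_fit`.
#' @param level `"between"` or `"within"`.
#' @param order Optional pivot order to rotate the draws into (via the
#'   orthogonal map of [rotation_matrix()]).
#' @return Matrix of draws, one column per ilr coordinate.
#' @export
coef_draws <- function(fit, level = c("between", "within"), order = NULL) {
  level <- match.arg(level)
  cols <- if (level == "between") fit$bcols else fit$wcols
  b <- fit$draws[, cols, drop = FALSE]
  if (!is.null(order) && !identical(order, fit$order)) {
    b <- b %*% t(rotation_matrix(fit$order, order))
    colnames(b) <- cols
  }
  b
}

summarize_draws_vec <- function(x, prob = 0.95) {
  a <- (1 - prob) / 2
  q <- quantile(x, c(a, 1 - a), names = FALSE)
  c(mean = mean(x), lower = q[1], upper = q[2])
}

#' Summarize a fit, optionally in several pivot bases
#'
#' Produces a coefficient table (posterior mean, 95% equal-tailed credible
#' interval, significance flag = interval excludes zero) for the
#' compositional coefficients in each requested pivot order -- alternate
#' orders are obtained by rotating the coefficient draws, not by refitting
#' -- plus covariate and variance parameters in the fitted basis.
#'
#' @param fit A `mlcoda_fit`.
#' @param report_orders List of pivot orders (default: the fitted order).
#' @param prob Credible-interval mass.
#' @return Data frame with columns `parameter`, `level`, `pivot`,
#'   `coordinate`, `mean`, `lower`, `upper`, `significant`.
#' @export
summarize_fit <- function(fit, report_orders = list(fit$order), prob = 0.95) {
  rows <- list()
  for (ord in report_orders) {
    check_order(ord, fit$order)
    for (level in c("between", "within")) {
      b <- coef_draws(fit, level, ord)
      for (k in seq_len(ncol(b))) {
        s <- summarize_draws_vec(b[, k], prob)
        rows[[length(rows) + 1]] <- data.frame(
          parameter = sprintf("%s_%s_z%d", substr(level, 1, 1), ord[1], k),
          level = level, pivot = ord[1], coordinate = k,
          mean = s["mean"], lower = s["lower"], upper = s["upper"])
      }
    }
  }
  other <- c("(Intercept)", fit$covariates, "sigma",
             grep("^sd_u", colnames(fit$draws), value = TRUE))
  other <- intersect(other, colnames(fit$draws))
  for (p in other) {
    s <- summarize_draws_vec(fit$draws[, p], prob)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = p, level = "model", pivot = NA_character_,
      coordinate = NA_integer_,
      mean = s["mean"], lower = s["lower"], upper = s["upper"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- out$lower > 0 | out$upper < 0
  out
}

#' Population-level linear predictor for given coordinates
#'
#' Per-draw expected outcome at supplied between/within ilr coordinates
#' and covariate values, with random effects at zero (an average person on
#' an average day). Used by the substitution machinery and its tests.
#'
#' @param fit A `mlcoda_fit`.
#' @param bilr,wilr Numeric vectors of length D-1 (fitted basis).
#' @param covariate_values Named numeric values for the covariate columns
#'   (default all zero, i.e. at the centered means).
#' @return Numeric vector, one value per posterior draw.
#' @export
posterior_linpred <- function(fit, bilr, wilr, covariate_values = NULL) {
  x <- setNames(numeric(length(fit$x_colnames)), fit$x_colnames)
  x["(Intercept)"] <- 1
  x[fit$bcols] <- bilr
  x[fit$wcols] <- wilr
  if (!is.null(covariate_values)) {
    x[names(covariate_values)] <- covariate_values
  }
  as.numeric(fit$draws[, fit$x_colnames, drop = FALSE] %*% x)
}
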