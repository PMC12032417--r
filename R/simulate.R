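#' Calibrated generator constants
#'
#' Frozen calibration of the synthetic-data generator: per-part log-scale
#' SDs at the between- and within-person levels (chosen so day-level part
#' SDs in hours approximate the targets 1.1, 1.1, 0.84, 0.31, 0.42 for
#' sleep, sedentary, standing, LPA, MVPA), and per-outcome random-intercept
#' and residual SDs (chosen so marginal outcome SDs approximate 12.2, 12.0,
#' 12.8, 9.0 under a lag-1 coefficient of 0.2). Produced once by
#' `analysis/00_calibrate_generator.R` and frozen here.
#'
#' @keywords internal
CODA24_CAL <- list(
  log_sd_between = c(sleep = 0.1363, sedentary = 0.1040, standing = 0.2505,
                     lpa = 0.1992, mvpa = 0.2346),
  log_sd_within = c(sleep = 0.1113, sedentary = 0.0849, standing = 0.2045,
                    lpa = 0.1627, mvpa = 0.1916),
  center_correction = c(sleep = 0.9621, sedentary = 0.9686,
                        standing = 0.9256, lpa = 0.9333, mvpa = 0.9327),
  outcome_noise = list(
    valence = c(tau0 = 7.42, sigma = 7.62),
    energetic_arousal = c(tau0 = 7.25, sigma = 7.35),
    calmness = c(tau0 = 7.89, sigma = 8.09),
    working_memory = c(tau0 = 5.45, sigma = 5.65))
)

#' Default per-outcome generating effects
#'
#' Compositional effect sizes (first pivot coordinate, MVPA-first basis)
#' at realistic scales for daily affect/cognition outcomes on 0-100
#' scales; remaining coordinates default to zero. Modify elements of the
#' returned list to change generating truths (e.g. for recovery studies).
#' @export
default_outcome_config <- function() {
  mk <- function(mean, sd, bw1, ww1) {
    list(mean = mean, sd = sd,
         beta_b = c(bw1, 0, 0, 0), beta_w = c(ww1, 0, 0, 0),
         gamma = c(age = -0.05, sex = 1.0, bmi = -0.1, wear_h = 0.3),
         lag = 0.2, tau0 = NA_real_, tau_w = c(1, 0.5, 0.5, 0.5),
         sigma = NA_real_)
  }
  out <- list(
    valence = mk(65.69, 12.2, -2.27, 2.49),
    energetic_arousal = mk(56.25, 12.0, -3.24, 3.65),
    calmness = mk(60.87, 12.8, -3.93, -0.14),
    working_memory = mk(88.55, 9.0, -3.51, 0.19))
  for (nm in names(out)) {
    out[[nm]]$tau0 <- CODA24_CAL$outcome_noise[[nm]][["tau0"]]
    out[[nm]]$sigma <- CODA24_CAL$outcome_noise[[nm]][["sigma"]]
  }
  out
}

clr_projector <- function(D) diag(D) - matrix(1 / D, D, D)

#' ilr covariance implied by independent log-part scales
#'
#' Maps per-part log-scale SDs to the covariance of pivot coordinates:
#' independent log-normal parts are centered (clr) and projected onto the
#' pivot basis. Used to build the generator's between/within covariances
#' from interpretable per-behavior spreads.
#'
#' @param log_sd Named per-part log-scale SDs.
#' @param order Pivot order of the target coordinates.
#' @export
ilr_cov_from_log_sd <- function(log_sd, order = names(log_sd)) {
  labels <- names(log_sd)
  G <- clr_projector(length(labels))
  S_clr <- G %*% diag(log_sd^2) %*% t(G)
  V <- pivot_basis(order, labels)
  t(V) %*% S_clr %*% V
}

#' Configuration of the synthetic participant-day generator
#'
#' Defaults emulate a workweek ambulatory-assessment study of working
#' adults: 199 participants wearing a thigh accelerometer over ~3 weeks of
#' working days (weekends are break days, appearing as day-index gaps),
#' with daily 5-part behavior compositions, daily affect and working-memory
#' outcomes, and day-level validity conditions (wear time, sleep detection,
#' walking detection).
#'
#' @param n_participants Number of participants.
#' @param days_mean,days_sd,days_range Monitored days per participant:
#'   rounded normal draw truncated to `days_range`. The default mean is the
#'   planned ~3 working weeks; after day-level exclusions the analyzed days
#'   per participant average ~11.8 (range 3-22).
#' @param calendar `"workweek"` lays monitored days on a Monday-Friday
#'   calendar so weekend gaps break lag chains; `"consecutive"` numbers
#'   days 1..n without gaps.
#' @param part_means_h Target mean hours/day per behavior.
#' @param center_correction Frozen multiplicative calibration of the
#'   generator's compositional center, cancelling the small closure/Jensen
#'   bias so realized arithmetic part means hit `part_means_h`.
#' @param log_sd_between,log_sd_within Per-part log-scale SDs feeding
#'   [ilr_cov_from_log_sd()].
#' @param outcomes Per-outcome generating parameters (see
#'   `default_outcome_config()`); coordinates refer to `order`.
#' @param order Pivot basis in which effects are expressed.
#' @param nonwear_mean_h,nonwear_sd_h Daily non-wear draw (gamma), wear
#'   time = 24 h minus it.
#' @param p_sleep_zero,p_no_walk Rates of invalid days (no sleep detected /
#'   no walking period).
#' @param missing_outcome_rate Per-day, per-outcome missingness rate.
#' @param age_mean,age_sd,bmi_mean,bmi_sd,p_female Baseline covariates.
#' @param total Closure total, minutes.
#' @param seed Integer seed (`NULL` = leave RNG state alone).
#' @export
generator_config <- function(n_participants = 199,
                             days_mean = 15.9, days_sd = 3.2,
                             days_range = c(3, 22),
                             calendar = c("workweek", "consecutive"),
                             part_means_h = c(sleep = 7.95, sedentary = 10.5,
                                              standing = 2.79, lpa = 1.15,
                                              mvpa = 1.35),
                             center_correction = CODA24_CAL$center_correction,
                             log_sd_between = CODA24_CAL$log_sd_between,
                             log_sd_within = CODA24_CAL$log_sd_within,
                             outcomes = default_outcome_config(),
                             order = pivot_order("mvpa"),
                             nonwear_mean_h = 3.3, nonwear_sd_h = 1.1,
                             p_sleep_zero = 0.004, p_no_walk = 0.004,
                             missing_outcome_rate = 0.05,
                             age_mean = 35.84, age_sd = 10.7,
                             bmi_mean = 23.97, bmi_sd = 3.3,
                             p_female = 0.553,
                             total = DAY_MINUTES, seed = NULL) {
  cfg <- list(n_participants = n_participants, days_mean = days_mean,
              days_sd = days_sd, days_range = days_range,
              calendar = match.arg(calendar),
              part_means_h = part_means_h,
              center_correction = center_correction,
              sigma_between = ilr_cov_from_log_sd(log_sd_between, order),
              sigma_within = ilr_cov_from_log_sd(log_sd_within, order),
              outcomes = outcomes, order = order,
              nonwear_mean_h = nonwear_mean_h, nonwear_sd_h = nonwear_sd_h,
              p_sleep_zero = p_sleep_zero, p_no_walk = p_no_walk,
              missing_outcome_rate = missing_outcome_rate,
              age_mean = age_mean, age_sd = age_sd,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd, p_female = p_female,
              total = total, seed = seed)
  ev <- eigen(cfg$sigma_between, symmetric = TRUE, only.values = TRUE)$values
  ew <- eigen(cfg$sigma_within, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("between-person ilr covariance must be positive-definite")
  # zero within-covariance (identical days per person) is a valid degenerate case
  if (min(ew) < -1e-12) stop("within-person ilr covariance must be positive semi-definite")
  stopifnot(all(part_means_h > 0),
            missing_outcome_rate >= 0, missing_outcome_rate <= 1)
  class(cfg) <- "coda24_config"
  cfg
}

rmvn <- function(n, mu, Sigma) {
  if (all(Sigma == 0)) {
    return(matrix(mu, n, length(mu), byrow = TRUE))
  }
  L <- chol(Sigma)
  m <- matrix(rnorm(n * length(mu)), n) %*% L
  sweep(m, 2, mu, "+")
}

draw_days_per_person <- function(n, mean, sd, range) {
  out <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      d <- round(rnorm(1, mean, sd))
      if (d >= range[1] && d <= range[2]) break
    }
    out[i] <- d
  }
  out
}

# Working-day calendar indices: 5-day blocks separated by 2-day weekend gaps.
workday_indices <- function(n_days) {
  d <- seq_len(n_days)
  d + 2L * ((d - 1L) %/% 5L)
}

#' Generate a synthetic participant-day dataset
#'
#' Samples the generative counterpart of the fitted model: person-level
#' compositional means in ilr space from MVN(mu_B, Sigma_B), day deviations
#' from MVN(0, Sigma_W), compositions through the inverse ilr transform,
#' and outcomes sequentially through the linear predictor (compositional
#' effects + covariates + random intercept and within-slopes + lag-1
#' carry-over + Gaussian noise). Day indices follow a working-week
#' calendar, so weekend gaps break lag chains as in the emulated design.
#'
#' @param config A [generator_config()].
#' @return List: `data` (participant-day data frame in the long CSV
#'   contract), `truth` (the generating parameter values, for recovery
#'   scoring).
#' @export
simulate_emia <- function(config = generator_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  parts <- names(config$part_means_h)
  D1 <- length(parts) - 1
  mean_comp <- close_composition(
    config$part_means_h * 60 * config$center_correction[parts],
    total = config$total)
  mu_b <- as.numeric(ilr_pivot(mean_comp, config$order))

  np <- config$n_participants
  pid <- sprintf("P%03d", seq_len(np))
  age <- rnorm(np, config$age_mean, config$age_sd)
  sex <- ifelse(runif(np) < config$p_female, "female", "male")
  bmi <- rnorm(np, config$bmi_mean, config$bmi_sd)
  ndays <- draw_days_per_person(np, config$days_mean, config$days_sd,
                                config$days_range)
  zB <- rmvn(np, mu_b, config$sigma_between)

  rows <- vector("list", np)
  for (i in seq_len(np)) {
    nd <- ndays[i]
    zW <- rmvn(nd, rep(0, D1), config$sigma_within)
    comp <- ilr_inverse(zB[rep(i, nd), , drop = FALSE] + zW,
                        order = config$order, labels = config$order,
                        total = config$total)[, parts, drop = FALSE]
    nonwear <- rgamma(nd, shape = (config$nonwear_mean_h / config$nonwear_sd_h)^2,
                      scale = config$nonwear_sd_h^2 / config$nonwear_mean_h)
    wear_h <- 24 - pmin(pmax(nonwear, 0.3), 13)
    df <- data.frame(pid = pid[i],
                     day = if (config$calendar == "workweek")
                       workday_indices(nd) else seq_len(nd))
    df[part_columns(parts)] <- as.data.frame(comp)
    df$wear_h <- wear_h
    df$walk_detected <- runif(nd) >= config$p_no_walk
    df$n_ratings <- pmin(6L, stats::rbinom(nd, 6L, 0.73))
    df$zW <- I(zW)
    df$zBc <- I(zB[rep(i, nd), , drop = FALSE] -
                  matrix(mu_b, nd, D1, byrow = TRUE))
    rows[[i]] <- df
  }
  data <- do.call(rbind, rows)
  data$age <- age[match(data$pid, pid)]
  data$sex <- sex[match(data$pid, pid)]
  data$bmi <- bmi[match(data$pid, pid)]

  cov_c <- cbind(age = data$age - config$age_mean,
                 sex = code_sex(data$sex) - (1 - config$p_female),
                 bmi = data$bmi - config$bmi_mean,
                 wear_h = data$wear_h - (24 - config$nonwear_mean_h))
  adjacent <- c(FALSE, diff(data$day) == 1 &
                  data$pid[-1] == data$pid[-nrow(data)])

  truth <- list(order = config$order, mu_b = mu_b,
                sigma_between = config$sigma_between,
                sigma_within = config$sigma_within, outcomes = list())
  for (nm in names(config$outcomes)) {
    oc <- config$outcomes[[nm]]
    u0 <- rnorm(np, 0, oc$tau0)
    uW <- rmvn(np, rep(0, D1), diag(oc$tau_w^2, D1))
    gi <- match(data$pid, pid)
    eta <- as.numeric(data$zBc %*% oc$beta_b) +
      as.numeric(data$zW %*% oc$beta_w) +
      as.numeric(cov_c[, names(oc$gamma)] %*% oc$gamma) +
      u0[gi] + rowSums(data$zW * uW[gi, , drop = FALSE])
    y <- numeric(nrow(data))
    for (r in seq_len(nrow(data))) {
      if (adjacent[r]) {
        y[r] <- oc$mean + eta[r] + oc$lag * (y[r - 1] - oc$mean) +
          rnorm(1, 0, oc$sigma)
      } else {
        y[r] <- oc$mean + eta[r] / (1 - oc$lag) +
          rnorm(1, 0, oc$sigma / sqrt(1 - oc$lag^2))
      }
    }
    if (config$missing_outcome_rate > 0) {
      y[runif(length(y)) < config$missing_outcome_rate] <- NA
    }
    data[[nm]] <- y
    truth$outcomes[[nm]] <- oc
  }
  if (config$p_sleep_zero > 0) {
    z <- runif(nrow(data)) < config$p_sleep_zero
    data$sleep_min[z] <- 0
  }
  data$zW <- NULL
  data$zBc <- NULL
  rownames(data) <- NULL
  list(data = data, truth = truth)
}

#' Parameter-recovery and calibration experiment
#'
#' Repeatedly generates data from a known configuration, runs the full
#' pipeline (day filters, decomposition, design, fit), and scores the
#' compositional coefficients against the generating truth: mean bias,
#' RMSE, 95% credible-interval coverage, and the rate at which intervals
#' exclude zero (the significance rate -- for null coordinates this is the
#' empirical false-positive rate). Non-convergent replicates are counted
#' and excluded from coverage.
#'
#' @param config A [generator_config()].
#' @param replicates Number of replicates.
#' @param fit_spec A [model_spec()] naming the outcome to fit; its seed is
#'   advanced per replicate.
#' @param outcome Outcome to score (default: `fit_spec$outcome`).
#' @return Data frame, one row per compositional coefficient: `parameter`,
#'   `true`, `mean_estimate`, `bias`, `rmse`, `coverage`, `sig_rate`,
#'   `n_used`, `n_nonconverged`.
#' @export
recovery_experiment <- function(config, replicates, fit_spec,
                                outcome = fit_spec$outcome) {
  stopifnot(replicates >= 1)
  oc <- config$outcomes[[outcome]]
  if (is.null(oc)) stop(sprintf("outcome '%s' not in generator config", outcome))
  true_vals <- c(setNames(oc$beta_b, paste0("bilr", seq_along(oc$beta_b))),
                 setNames(oc$beta_w, paste0("wilr", seq_along(oc$beta_w))))
  est <- low <- upp <- matrix(NA_real_, replicates, length(true_vals),
                              dimnames = list(NULL, names(true_vals)))
  converged <- logical(replicates)
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- (if (is.null(config$seed)) 0L else config$seed) + r
    sim <- simulate_emia(cfg)
    filt <- filter_days(sim$data)
    dec <- decompose(filt$data, order = fit_spec$order)
    spec_r <- fit_spec
    spec_r$seed <- fit_spec$seed + 1000L * r
    fit <- suppressWarnings(fit_mlcoda(build_design(dec, spec_r), spec_r))
    converged[r] <- fit$diagnostics$converged
    for (p in names(true_vals)) {
      s <- summarize_draws_vec(fit$draws[, p])
      est[r, p] <- s["mean"]; low[r, p] <- s["lower"]; upp[r, p] <- s["upper"]
    }
  }
  use <- which(converged)
  if (length(use) == 0) use <- seq_len(replicates)  # degenerate; all counted
  out <- data.frame(
    parameter = names(true_vals), true = as.numeric(true_vals),
    mean_estimate = colMeans(est[use, , drop = FALSE]),
    bias = colMeans(est[use, , drop = FALSE]) - as.numeric(true_vals),
    rmse = sqrt(colMeans(sweep(est[use, , drop = FALSE], 2, true_vals)^2)),
    coverage = colMeans(low[use, , drop = FALSE] <=
                          matrix(true_vals, length(use), length(true_vals),
                                 byrow = TRUE) &
                        upp[use, , drop = FALSE] >=
                          matrix(true_vals, length(use), length(true_vals),
                                 byrow = TRUE)),
    sig_rate = colMeans(low[use, , drop = FALSE] > 0 |
                          upp[use, , drop = FALSE] < 0),
    n_used = length(use),
    n_nonconverged = sum(!converged), row.names = NULL)
  out
}
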