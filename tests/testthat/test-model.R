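# A small complete dataset with consecutive days for design checks.
design_data <- function(n_pid = 3, n_days = 4, seed = 9) {
  cfg <- generator_config(n_participants = n_pid, days_mean = n_days,
                          days_sd = 0.01, days_range = c(n_days, n_days),
                          calendar = "consecutive", nonwear_mean_h = 2,
                          nonwear_sd_h = 0.3, p_sleep_zero = 0, p_no_walk = 0,
                          missing_outcome_rate = 0, seed = seed)
  simulate_emia(cfg)$data
}

test_that("the design drops first days, keeps lag-complete rows, and has the documented columns", {
  dat <- design_data(3, 4)
  dec <- decompose(dat)
  spec <- model_spec("valence", chains = 2, iter = 200, warmup = 100)
  des <- build_design(dec, spec)
  # 3 persons x (4 - 1) days: the first day has no previous-day outcome
  expect_equal(length(des$y), 3 * (4 - 1))
  # 1 intercept + 2(D-1) compositional + covariates
  expect_equal(ncol(des$X), 1 + 2 * 4 + length(spec$covariates))
  expect_equal(colnames(des$X),
               c("(Intercept)", paste0("bilr", 1:4), paste0("wilr", 1:4),
                 "age", "sex", "bmi", "wear_h", "lag"))
  # lag really is the previous day's outcome
  d2 <- des$data
  expect_equal(d2$lag,
               dat$valence[match(paste(d2$pid, d2$day - 1),
                                 paste(dat$pid, dat$day))])
  # continuous covariates are centered, sex is an indicator
  expect_equal(mean(des$X[, "age"]), 0, tolerance = 1e-12)
  expect_true(all(des$X[, "sex"] %in% c(0, 1)))
})

test_that("rows with a missing outcome are dropped but still inform the person mean", {
  dat <- design_data(3, 5)
  dat$valence[7] <- NA
  dec <- decompose(dat)
  spec <- model_spec("valence", chains = 2, iter = 200, warmup = 100)
  des <- build_design(dec, spec)
  # the NA day and the day after it (whose lag is NA) are both unusable
  expect_equal(length(des$y), 3 * 4 - 2)
  # between coordinates still reflect all 5 days
  dec_b <- decompose(dat[!is.na(dat$valence), ])
  expect_false(isTRUE(all.equal(
    dec$bilr1[dec$pid == dec$pid[7]][1],
    dec_b$bilr1[dec_b$pid == dec$pid[7]][1])))

  expect_error(build_design(dec, model_spec("happiness")), "not found")
})

test_that("equal-tailed interval summaries come from the right quantiles", {
  s <- coda24:::summarize_draws_vec(c(1, 2, 3))
  expect_equal(unname(s["mean"]), 2)
  expect_equal(unname(s["lower"]), unname(quantile(c(1, 2, 3), 0.025)))
  expect_equal(unname(s["upper"]), unname(quantile(c(1, 2, 3), 0.975)))
})

test_that("with random effects off and flat priors the posterior matches OLS", {
  dat <- design_data(8, 6, seed = 21)
  dec <- decompose(dat)
  spec <- model_spec("valence", chains = 2, iter = 1600, warmup = 400,
                     seed = 5, ranef = FALSE, beta_scale = 1e4)
  des <- build_design(dec, spec)
  fit <- suppressWarnings(fit_mlcoda(des, spec))
  ols <- lm(des$y ~ des$X - 1)
  for (j in seq_len(ncol(des$X))) {
    draws <- fit$draws[, colnames(des$X)[j]]
    mcse <- sd(draws) / sqrt(coda24::ess_bulk(fit$samples, colnames(des$X)[j]))
    expect_lt(abs(mean(draws) - unname(coef(ols)[j])), 3 * mcse + 1e-8)
  }
})

test_that("fitting is deterministic given the seed", {
  dec <- fixture_decomposed()
  spec <- model_spec("valence", chains = 2, iter = 400, warmup = 200, seed = 77)
  des <- build_design(dec, spec)
  f1 <- suppressWarnings(fit_mlcoda(des, spec))
  f2 <- suppressWarnings(fit_mlcoda(des, spec))
  expect_identical(f1$draws, f2$draws)
})

test_that("predictions do not depend on the pivot basis used to fit", {
  dat <- design_data(6, 5, seed = 33)
  mv <- model_spec("valence", order = pivot_order("mvpa"))
  sb <- model_spec("valence", order = pivot_order("sedentary"))
  des_mv <- build_design(decompose(dat, mv$order), mv)
  des_sb <- build_design(decompose(dat, sb$order), sb)
  # the two designs are an exact orthogonal reparameterization ...
  Q <- rotation_matrix(mv$order, sb$order)
  expect_equal(des_sb$X[, des_sb$bcols],
               des_mv$X[, des_mv$bcols] %*% t(Q), ignore_attr = TRUE)
  # ... so least-squares fitted values (the flat-prior, no-ranef limit of
  # the model) are identical
  expect_equal(fitted(lm(des_mv$y ~ des_mv$X - 1)),
               fitted(lm(des_sb$y ~ des_sb$X - 1)), tolerance = 1e-9)
})

test_that("summaries in a rotated basis agree with an independent refit", {
  dec <- fixture_decomposed()
  sb_order <- pivot_order("sedentary")
  spec_mv <- model_spec("valence", chains = 2, iter = 1200, warmup = 400,
                        seed = 3)
  fit_mv <- suppressWarnings(fit_mlcoda(build_design(dec, spec_mv), spec_mv))
  spec_sb <- model_spec("valence", order = sb_order, chains = 2, iter = 1200,
                        warmup = 400, seed = 4)
  dec_sb <- decompose(filter_days(read_behavior_csv(small_fixture_path()))$data,
                      order = sb_order)
  fit_sb <- suppressWarnings(fit_mlcoda(build_design(dec_sb, spec_sb), spec_sb))

  rotated <- summarize_fit(fit_mv, report_orders = list(sb_order))
  refit <- summarize_fit(fit_sb, report_orders = list(sb_order))
  for (lv in c("between", "within")) {
    r1 <- rotated[rotated$level == lv & rotated$coordinate == 1, ]
    r2 <- refit[refit$level == lv & refit$coordinate == 1, ]
    psd <- sd(coef_draws(fit_sb, lv)[, 1])
    expect_lt(abs(r1$mean - r2$mean), 0.5 * psd)
  }
  # reporting in the fitted order is the identity
  same <- summarize_fit(fit_mv, report_orders = list(fit_mv$order))
  direct <- coda24:::summarize_draws_vec(fit_mv$draws[, "wilr1"])
  expect_equal(same$mean[same$level == "within" & same$coordinate == 1],
               unname(direct["mean"]))
})

test_that("convergence diagnostics flag an obviously unconverged sampler", {
  # two 'chains' stuck at different values
  ch <- coda::mcmc.list(coda::mcmc(matrix(rnorm(100, 0), 100, 1,
                                          dimnames = list(NULL, "p"))),
                        coda::mcmc(matrix(rnorm(100, 50), 100, 1,
                                          dimnames = list(NULL, "p"))))
  expect_gt(rhat_split(ch, "p"), 1.5)
  d <- mcmc_diagnostics(ch)
  expect_false(d$converged)
})
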