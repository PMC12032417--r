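base30 <- close_composition(table1_mean_minutes)

test_that("reallocation moves minutes between exactly two parts", {
  out <- reallocate(base30, "mvpa", "sedentary", 30)
  expect_equal(out[["mvpa"]], base30[["mvpa"]] + 30)
  expect_equal(out[["sedentary"]], base30[["sedentary"]] - 30)
  expect_equal(out[c("sleep", "standing", "lpa")],
               base30[c("sleep", "standing", "lpa")])
  expect_equal(sum(out), sum(base30))

  expect_equal(reallocate(base30, "mvpa", "sedentary", 0), base30)
  expect_error(reallocate(base30, "mvpa", "sedentary",
                          base30[["sedentary"]] + 1), "infeasible")
  expect_error(reallocate(base30, "mvpa", "mvpa", 10), "differ")
})

test_that("a single-draw posterior reproduces hand-computed differences", {
  bw <- c(2.49, -0.8, 0.3, 1.1)
  bb <- c(-2.27, 0.5, -0.4, 0.9)
  fit <- fake_fit(beta_b = bb, beta_w = bw)
  dz <- as.numeric(ilr_pivot(reallocate(base30, "mvpa", "sedentary", 30),
                             fit$order) - ilr_pivot(base30, fit$order))
  est_w <- substitution_estimate(fit, base30, "mvpa", "sedentary", 30, "within")
  expect_equal(est_w$mean, sum(bw * dz), tolerance = 1e-12)
  est_b <- substitution_estimate(fit, base30, "mvpa", "sedentary", 30, "between")
  expect_equal(est_b$mean, sum(bb * dz), tolerance = 1e-12)

  # two-prediction oracle: predict at reallocated and at base, subtract;
  # covariates held at a common arbitrary value cancel exactly
  covs <- c(age = 4.2, sex = 1)
  z_new <- as.numeric(ilr_pivot(reallocate(base30, "mvpa", "sedentary", 30),
                                fit$order))
  z_base <- as.numeric(ilr_pivot(base30, fit$order))
  oracle <- posterior_linpred(fit, bilr = z_base, wilr = z_new - z_base,
                              covariate_values = covs) -
    posterior_linpred(fit, bilr = z_base, wilr = rep(0, 4),
                      covariate_values = covs)
  expect_equal(est_w$mean, oracle, tolerance = 1e-12)
})

test_that("zero-minute reallocations give an exactly-zero degenerate estimate", {
  fit <- fake_fit(beta_b = rnorm(4), beta_w = rnorm(4))
  est <- substitution_estimate(fit, base30, "mvpa", "sleep", 0, "within")
  expect_identical(c(est$mean, est$lower, est$upper), c(0, 0, 0))
  expect_false(est$significant)
})

test_that("adding and deducting the same minutes are different estimates", {
  fit <- fake_fit(beta_b = c(1, 0, 0, 0), beta_w = c(2.49, 0, 0, 0))
  up <- substitution_estimate(fit, base30, "mvpa", "sedentary", 30, "within")
  down <- substitution_estimate(fit, base30, "sedentary", "mvpa", 30, "within")
  # the ilr difference is non-linear in minutes, so these are not mirror images
  expect_gt(abs(up$mean + down$mean), 1e-6)
})

test_that("ilr differences do not chain through an intermediate behavior", {
  ord <- pivot_order("mvpa")
  dz <- function(to, from) {
    as.numeric(ilr_pivot(reallocate(base30, to, from, 30), ord) -
                 ilr_pivot(base30, ord))
  }
  direct <- dz("mvpa", "sedentary")
  chained <- dz("standing", "sedentary") + dz("mvpa", "standing")
  expect_gt(max(abs(direct - chained)), 1e-6)
})

test_that("the grid covers all ordered pairs, flags infeasible cells, and is monotone per draw", {
  fit <- fake_fit(beta_b = c(-1, 0.3, 0.2, -0.5), beta_w = c(2, -0.4, 0.1, 0.3))
  g <- substitution_grid(fit, base30, minutes = c(10, 30, 60))
  expect_equal(nrow(g), 2 * 20 * 3)           # levels x ordered pairs x durations
  expect_true(all(g$feasible))

  # a base with a small LPA part makes 60-minute LPA-donor cells infeasible
  tight <- close_composition(c(sleep = 480, sedentary = 660, standing = 200,
                               lpa = 50, mvpa = 50))
  g2 <- substitution_grid(fit, tight, minutes = c(30, 60))
  infeas <- g2[!g2$feasible, ]
  expect_true(all(infeas$from %in% c("lpa", "mvpa") & infeas$minutes == 60))
  expect_true(all(is.na(infeas$mean)))
  expect_error(substitution_grid(fit, base30, minutes = numeric(0)), "empty")

  # with a single draw, |effect| grows with duration along every feasible pair
  g3 <- substitution_grid(fit, base30, minutes = 1:60, levels = "within")
  for (key in unique(paste(g3$to, g3$from))) {
    eff <- g3$mean[paste(g3$to, g3$from) == key]
    expect_true(all(diff(abs(eff)) > -1e-12))
  }
})

test_that("per-draw estimates equal prediction differences on a real posterior", {
  fit <- fixture_fit_quick()
  base <- reference_composition(fixture_decomposed())
  z_base <- as.numeric(ilr_pivot(base, fit$order))
  for (pair in list(c("mvpa", "sedentary"), c("sleep", "standing"),
                    c("lpa", "sleep"))) {
    dz <- as.numeric(ilr_pivot(reallocate(base, pair[1], pair[2], 30),
                               fit$order)) - z_base
    draws_direct <- as.numeric(coef_draws(fit, "within") %*% dz)
    draws_oracle <- posterior_linpred(fit, z_base, dz) -
      posterior_linpred(fit, z_base, rep(0, 4))
    expect_lt(max(abs(draws_direct - draws_oracle)), 1e-10)
    est <- substitution_estimate(fit, base, pair[1], pair[2], 30, "within")
    expect_equal(est$mean, mean(draws_oracle), tolerance = 1e-12)
    expect_equal(est$significant, est$lower > 0 | est$upper < 0)
  }
})

test_that("the matrix view mirrors gainers in rows and donors in columns", {
  fit <- fake_fit(beta_b = c(1, 0, 0, 0), beta_w = c(2, 0, 0, 0))
  g <- substitution_grid(fit, base30, minutes = 30)
  m <- substitution_matrix(g, 30, "within")
  expect_equal(dim(m), c(5, 5))
  expect_true(all(is.na(diag(m))))
  est <- substitution_estimate(fit, base30, "mvpa", "sedentary", 30, "within")
  expect_equal(m["mvpa", "sedentary"], est$mean)
})
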