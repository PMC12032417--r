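test_that("closure rescales proportionally and preserves the stated total", {
  x <- table1_mean_minutes  # sums to 1424.4
  cl <- close_composition(x)
  expect_equal(sum(cl), 1440)
  expect_equal(cl, x * (1440 / 1424.4))

  already <- c(a = 700, b = 500, c = 240)
  expect_equal(close_composition(already), already)

  expect_equal(unname(close_composition(setNames(rep(1, 5), BEHAVIOR_PARTS))),
               rep(288, 5))

  # idempotent
  expect_equal(close_composition(cl), cl)
})

test_that("closure rejects non-positive parts, naming the offender", {
  x <- c(sleep = 400, sedentary = 0, standing = 100, lpa = 50, mvpa = 30)
  expect_error(close_composition(x), "sedentary")
  expect_error(close_composition(c(a = -1, b = 2)), "'a'")
  # the offset utility repairs zeros, then closure succeeds
  expect_silent(close_composition(offset_zero_parts(x)))
  expect_equal(offset_zero_parts(x, 0.5)[["sedentary"]], 0.5)
})

test_that("pivot coordinates match the independent formula oracle", {
  set.seed(101)
  comps <- random_compositions(1000)
  orders <- list(pivot_order("mvpa"), pivot_order("sedentary"),
                 BEHAVIOR_PARTS)
  for (ord in orders) {
    z <- ilr_pivot(comps, ord)
    zo <- t(apply(comps, 1, oracle_ilr, order = ord))
    expect_lt(max(abs(z - zo)), 1e-10)
  }
})

test_that("pivot coordinates have the stated closed forms and symmetries", {
  # uniform composition maps to the origin
  u <- setNames(rep(288, 5), BEHAVIOR_PARTS)
  expect_equal(unname(as.numeric(ilr_pivot(u))), rep(0, 4))

  # D = 2 closed form
  t_min <- 500
  z <- ilr_pivot(c(awake = t_min, asleep = 1440 - t_min))
  expect_equal(as.numeric(z), sqrt(1 / 2) * log(t_min / (1440 - t_min)))

  # scale invariance
  x <- table1_mean_minutes
  expect_equal(as.numeric(ilr_pivot(x, pivot_order("mvpa"))),
               as.numeric(ilr_pivot(close_composition(x), pivot_order("mvpa"))),
               tolerance = 1e-12)
  expect_equal(as.numeric(ilr_pivot(x * 3.7, pivot_order("mvpa"))),
               as.numeric(ilr_pivot(x, pivot_order("mvpa"))), tolerance = 1e-12)

  # first coordinate ignores the ordering of the remaining parts
  rest <- setdiff(BEHAVIOR_PARTS, "mvpa")
  z1 <- sapply(1:10, function(i) {
    set.seed(i)
    ilr_pivot(x, c("mvpa", sample(rest)))[1]
  })
  expect_equal(diff(range(z1)), 0)

  # label mismatch is an error
  expect_error(ilr_pivot(x, c("mvpa", "sleep", "sedentary", "standing", "nap")),
               "permutation")
})

test_that("ilr round-trips exactly and the inverse is monotone in the pivot part", {
  set.seed(202)
  comps <- random_compositions(1000)
  ord <- pivot_order("mvpa")
  z <- ilr_pivot(comps, ord)
  back <- ilr_inverse(z, order = ord, labels = BEHAVIOR_PARTS)
  expect_lt(max(abs(back - comps)), 1e-10)
  expect_lt(max(abs(ilr_pivot(back, ord) - z)), 1e-10)

  # zero vector -> uniform
  expect_equal(unname(ilr_inverse(rep(0, 4), order = ord)), rep(288, 4 + 1))

  # raising z1 alone strictly raises the MVPA minutes
  z0 <- as.numeric(ilr_pivot(close_composition(table1_mean_minutes), ord))
  grid <- seq(-1, 1, length.out = 21)
  mv <- sapply(grid, function(g) {
    ilr_inverse(z0 + c(g, 0, 0, 0), order = ord)[["mvpa"]]
  })
  expect_true(all(diff(mv) > 0))

  expect_error(ilr_inverse(c(NA, 0, 0, 0), order = ord), "finite")
})

test_that("basis rotation is orthogonal and agrees with the composition route", {
  mv <- pivot_order("mvpa")
  sb <- pivot_order("sedentary")
  Q <- rotation_matrix(mv, sb)
  expect_equal(Q %*% t(Q), diag(4), tolerance = 1e-12)

  set.seed(303)
  z <- matrix(rnorm(100 * 4), 100)
  attr(z, "order") <- mv
  zr <- rotate_basis(z, sb)
  # oracle route: back to the simplex, forward in the new basis
  zo <- ilr_pivot(ilr_inverse(z, order = mv, labels = BEHAVIOR_PARTS), sb)
  expect_lt(max(abs(zr - zo)), 1e-10)
  # identity and involution
  expect_equal(unclass(rotate_basis(zr, mv)), unclass(z)[, ],
               tolerance = 1e-10, ignore_attr = TRUE)
  zi <- rotate_basis(z, mv)
  expect_equal(unclass(zi)[, ], unclass(z)[, ], ignore_attr = TRUE)
})

test_that("ilr is an isometry of Aitchison geometry", {
  set.seed(404)
  a <- random_compositions(200)
  b <- random_compositions(200)
  za <- ilr_pivot(a, pivot_order("mvpa"))
  zb <- ilr_pivot(b, pivot_order("mvpa"))
  d_ilr <- sqrt(rowSums((za - zb)^2))
  d_ait <- sapply(seq_len(nrow(a)), function(i) {
    aitchison_distance(a[i, ], b[i, ])
  })
  expect_lt(max(abs(d_ilr - d_ait)), 1e-9)
})

test_that("the geometric center matches the mean-in-ilr-space route", {
  x <- close_composition(table1_mean_minutes)
  expect_equal(geometric_center(matrix(x, 1, dimnames = list(NULL, names(x)))),
               x)
  two <- rbind(x, x)
  expect_equal(geometric_center(two), x)

  set.seed(505)
  comps <- random_compositions(50)
  ord <- pivot_order("mvpa")
  via_ilr <- ilr_inverse(colMeans(ilr_pivot(comps, ord)), order = ord,
                         labels = BEHAVIOR_PARTS)
  expect_equal(geometric_center(comps), via_ilr[names(geometric_center(comps))],
               tolerance = 1e-10)
  expect_error(geometric_center(comps[0, , drop = FALSE]), "at least one")
})
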