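test_that("initialization stays in bounds, is seeded, and is uniform in mean", {
  cfg <- cbo_config(n = 1000, dims = 3, lower = c(-2, 0, 10),
                    upper = c(2, 1, 20), max_iters = 1, seed = 4)
  pop <- cbo_initialize(cfg)
  expect_true(all(sweep(pop$positions, 2, cfg$lower, ">=")))
  expect_true(all(sweep(pop$positions, 2, cfg$upper, "<=")))
  expect_identical(pop$positions, cbo_initialize(cfg)$positions)
  expect_true(all(pop$velocities == 0))

  # CLT band: sample mean of U(a,b) within 3 SE of the midpoint
  big <- cbo_config(n = 10000, dims = 2, lower = -5, upper = 5,
                    max_iters = 1, seed = 9)
  pos <- cbo_initialize(big)$positions
  se <- sqrt(10^2 / 12 / 10000)
  expect_true(all(abs(colMeans(pos) - 0) < 3 * se))

  expect_error(cbo_config(n = 5, dims = 1, lower = 0, upper = 1), "even")
})

test_that("masses are inverse-fitness normalized", {
  expect_equal(cbo_masses(c(1, 1)), c(0.5, 0.5))
  expect_equal(cbo_masses(c(1, 2, 4)), c(4, 2, 1) / 7)
  for (s in 1:10) {
    f <- withr::with_seed(s, runif(8, 0.1, 10))
    expect_equal(sum(cbo_masses(f)), 1)
  }
  expect_error(cbo_masses(c(1, -2)), "positive|> 0")
})

test_that("collision laws reduce to the elastic and plastic limits", {
  pop2 <- function(x, fit, m) {
    structure(list(positions = matrix(x, ncol = 1),
                   velocities = matrix(0, length(x), 1),
                   fitnesses = fit, masses = m),
              class = "cbo_population")
  }
  # equal masses, eps = 1: full elastic transfer (moving stops, stationary
  # takes v); with rand pinned at 1 the new positions expose the velocities
  p <- pop2(c(0, 2), c(1, 2), c(0.5, 0.5))
  out <- cbo_collide(p, 1, -10, 10, rand = matrix(1, 2, 1))
  v <- 0 - 2
  expect_equal(out[1, 1], 0 + v)     # stationary gains v
  expect_equal(out[2, 1], 0 + 0)     # moving stops at partner position

  # equal masses, eps = 0: both halves share v/2
  out0 <- cbo_collide(p, 0, -10, 10, rand = matrix(1, 2, 1))
  expect_equal(out0[1, 1], 0 + v / 2)
  expect_equal(out0[2, 1], 0 + v / 2)

  # hand-evaluated n = 2 example: masses (0.6, 0.4), x = (0, 1), eps = 0.5
  ph <- pop2(c(0, 1), c(1, 1.5), c(0.6, 0.4))
  outh <- cbo_collide(ph, 0.5, -10, 10, rand = matrix(1, 2, 1))
  expect_equal(outh[1, 1], -0.6)
  expect_equal(outh[2, 1], -0.1)

  # unsorted population violates the contract
  bad <- pop2(c(0, 1), c(2, 1), c(0.4, 0.6))
  expect_error(cbo_collide(bad, 0.5, -10, 10), "sorted")
})

test_that("optimize tracks a non-increasing best and finds boundary optima", {
  sphere <- function(x) 1 + sum(x^2)
  cfg <- cbo_config(n = 20, dims = 2, lower = -5, upper = 5,
                    max_iters = 100, seed = 2)
  res <- cbo_optimize(sphere, cfg, lower_bound = 1)
  expect_true(all(diff(res$history) <= 0))
  expect_lt(res$best_fitness, 1 + 1e-3)

  # identical config => identical result
  res2 <- cbo_optimize(sphere, cfg, lower_bound = 1)
  expect_identical(res$best_position, res2$best_position)
  expect_identical(res$history, res2$history)

  # minimum at a box endpoint stays reachable under clipping; the oracle is
  # a fine grid search
  q <- function(x) (x - 7)^2 + 0.5
  cfgb <- cbo_config(n = 10, dims = 1, lower = 0, upper = 5,
                     max_iters = 200, seed = 6)
  resb <- cbo_optimize(q, cfgb, lower_bound = 0)
  grid <- seq(0, 5, by = 1e-4)
  expect_lt(abs(resb$best_position - grid[which.min(q(grid))]), 1e-3)

  # non-finite objective values are reported, not swallowed
  expect_error(
    cbo_optimize(function(x) NaN,
                 cbo_config(n = 4, dims = 1, lower = 0, upper = 1,
                            max_iters = 2, seed = 1)),
    "non-finite"
  )
})

test_that("rank positivization handles objectives without a known lower bound", {
  shifted <- function(x) sum(x^2) - 50   # negative near the origin
  cfg <- cbo_config(n = 16, dims = 2, lower = -5, upper = 5,
                    max_iters = 80, seed = 3)
  res <- cbo_optimize(shifted, cfg)
  expect_lt(res$best_fitness, -49.5)
})

test_that("plastic collisions contract a single pair on average", {
  gaps <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      x <- matrix(c(0, 3), 2, 1)
      for (i in 1:5) {
        pop <- structure(list(positions = x, velocities = matrix(0, 2, 1),
                              fitnesses = c(1, 2), masses = cbo_masses(c(1, 2))),
                         class = "cbo_population")
        x <- cbo_collide(pop, 0, -10, 10)
        x <- matrix(sort(x), 2, 1)
      }
      abs(x[2, 1] - x[1, 1])
    })
  }, numeric(1))
  expect_lt(mean(gaps), 3)
})

test_that("tidy and glance expose the convergence history", {
  cfg <- cbo_config(n = 6, dims = 1, lower = -1, upper = 1,
                    max_iters = 10, seed = 1)
  res <- cbo_optimize(function(x) 1 + x^2, cfg, lower_bound = 1)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 10)
  expect_equal(glance(res)$n_bodies, 6)
})
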