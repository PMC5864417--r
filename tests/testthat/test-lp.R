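# The internal bounded-variable simplex, validated against brute-force
# vertex enumeration.

test_that("simplex agrees with vertex enumeration on random bounded LPs", {
  set.seed(101)
  for (trial in 1:40) {
    n <- sample(4:8, 1); m <- sample(2:3, 1)
    A <- matrix(sample(c(-2, -1, 0, 0, 1, 1, 3), m * n, TRUE), m, n)
    lb <- round(runif(n, -3, 0), 2); ub <- lb + round(runif(n, 0.5, 6), 2)
    x0 <- lb + runif(n) * (ub - lb)
    b <- as.vector(A %*% x0)
    obj <- round(runif(n, -2, 2), 2)
    got <- nitrox:::lp_solve(obj, A, b, lb, ub, maximize = TRUE)
    want <- enumerate_lp(obj, A, b, lb, ub)
    expect_equal(got$status, "optimal")
    expect_equal(got$value, want$value, tolerance = 1e-7)
  }
})

test_that("simplex detects infeasibility and honours equality-fixed fluxes", {
  r <- nitrox:::lp_solve(c(1, 1), matrix(c(1, 1), 1, 2), 10,
                         c(0, 0), c(1, 1))
  expect_equal(r$status, "infeasible")
  # variable fixed by lb == ub is respected
  r2 <- nitrox:::lp_solve(c(1, 0), matrix(c(1, -1), 1, 2), 0,
                          c(0, 2), c(5, 2))
  expect_equal(r2$x, c(2, 2))
})

test_that("warm-started solves equal cold solves under changed bounds", {
  set.seed(202)
  n <- 12; m <- 6
  A <- matrix(sample(c(-1, 0, 0, 1, 2), m * n, TRUE), m, n)
  lb <- rep(0, n); ub <- runif(n, 1, 8)
  b <- as.vector(A %*% (runif(n) * 0.5))
  obj <- runif(n)
  cold0 <- nitrox:::lp_solve(obj, A, b, lb, ub)
  expect_equal(cold0$status, "optimal")
  for (i in 1:20) {
    ub2 <- ub * runif(n, 0.6, 1.4)
    warm <- nitrox:::lp_solve(obj, A, b, lb, ub2, warm = cold0$warm)
    cold <- nitrox:::lp_solve(obj, A, b, lb, ub2)
    expect_equal(warm$status, cold$status)
    expect_equal(warm$value, cold$value, tolerance = 1e-7)
  }
})

test_that("redundant equality rows are tolerated", {
  A <- rbind(c(1, -1), c(2, -2))          # second row redundant
  r <- nitrox:::lp_solve(c(1, 0), A, c(0, 0), c(0, 0), c(3, 3))
  expect_equal(r$status, "optimal")
  expect_equal(r$value, 3)
})
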