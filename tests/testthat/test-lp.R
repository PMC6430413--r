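# The built-in simplex against independent oracles.

test_that("lp_solve matches the vertex-enumeration oracle on random FBA-style LPs", {
  for (seed in 1:25) {
    g <- random_small_network_lp(seed)
    res <- lp_solve(g$obj, g$S, rep("=", nrow(g$S)), numeric(nrow(g$S)),
                    lb = g$lb, ub = g$ub)
    expect_equal(res$status, "optimal", info = paste("seed", seed))
    oracle <- fba_vertex_oracle(g$S, g$lb, g$ub, g$obj)
    expect_equal(res$objval, oracle, tolerance = 1e-7,
                 info = paste("seed", seed))
  }
})

test_that("lp_solve handles the three inequality senses and infeasibility", {
  # max x + y, x + y <= 4, x >= 1, y = 2 -> x = 2, y = 2
  A <- rbind(c(1, 1), c(1, 0), c(0, 1))
  res <- lp_solve(c(1, 1), A, c("<=", ">=", "="), c(4, 1, 2),
                  lb = c(0, 0), ub = c(10, 10))
  expect_equal(res$objval, 4, tolerance = 1e-9)
  expect_equal(unname(res$x), c(2, 2), tolerance = 1e-9)
  # contradictory rows
  res2 <- lp_solve(c(1), matrix(c(1, 1), 2, 1), c("<=", ">="), c(1, 2),
                   lb = 0, ub = 10)
  expect_equal(res2$status, "infeasible")
  # unbounded
  res3 <- lp_solve(c(1), matrix(1, 1, 1), "<=" , 100, lb = 0, ub = Inf)
  expect_equal(res3$objval, 100)
  res4 <- lp_solve(c(1), matrix(0, 1, 1), "<=", 1, lb = 0, ub = Inf)
  expect_equal(res4$status, "unbounded")
})

test_that("presolve agrees with the unreduced solve on randomly fixed problems", {
  for (seed in 26:35) {
    g <- random_small_network_lp(seed)
    n <- ncol(g$S)
    lb <- g$lb; ub <- g$ub
    j <- sample(n, 1)
    lb[j] <- ub[j] <- 0 # force a fixed variable into the presolve path
    res <- lp_solve(g$obj, g$S, rep("=", nrow(g$S)), numeric(nrow(g$S)),
                    lb = lb, ub = ub)
    oracle <- fba_vertex_oracle(g$S, lb, ub, g$obj)
    expect_equal(res$objval, oracle, tolerance = 1e-7,
                 info = paste("seed", seed))
  }
})

test_that("solutions satisfy constraints to tight tolerance", {
  g <- random_small_network_lp(7)
  res <- lp_solve(g$obj, g$S, rep("=", nrow(g$S)), numeric(nrow(g$S)),
                  lb = g$lb, ub = g$ub)
  expect_lt(max(abs(g$S %*% res$x)), 1e-9)
  expect_true(all(res$x >= g$lb - 1e-9 & res$x <= g$ub + 1e-9))
})
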