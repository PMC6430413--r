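# Phenotype procedures: sweeps, onsets, ratios, correlation machinery.

test_that("overflow_onset on constructed sweeps: none, step, and flagged cases", {
  mk <- function(v) {
    structure(list(swept_id = "EX_s_e", grid = seq_along(v),
                   status = rep("optimal", length(v)),
                   mu_star = rep(0.1, length(v)),
                   exchange_fluxes = matrix(v, 1,
                     dimnames = list("EX_p_e", NULL)),
                   expression_fluxes = matrix(0, 0, length(v)),
                   secretion = list()),
              class = "acetome_sweep")
  }
  expect_true(is.na(overflow_onset(mk(c(0, 0, 0, 0)), "EX_p_e")))
  expect_equal(overflow_onset(mk(c(0, 0, 1, 2)), "EX_p_e"), 3)
  expect_error(overflow_onset(mk(c(0, 1)), "EX_nope_e"), "unknown")
  # secretion decreasing after onset is flagged, not hidden
  expect_warning(on <- overflow_onset(mk(c(0, 2, 0.5, 0.5)), "EX_p_e"),
                 "violated")
  expect_true(isTRUE(attr(on, "flagged")))
})

test_that("secretion_ratio returns the ratio or an undefined marker", {
  sol <- structure(list(status = "optimal",
                        fluxes = c(EX_a_e = 2, EX_b_e = 2, EX_c_e = 0)),
                   class = "acetome_me_solution")
  expect_equal(secretion_ratio(sol, "EX_a_e", "EX_b_e"), 1)
  expect_true(is.na(secretion_ratio(sol, "EX_a_e", "EX_c_e")))
  expect_error(secretion_ratio(sol, "EX_a_e", "EX_zz_e"), "unknown")
})

test_that("aggregate_by_category is a partition homomorphism", {
  fl <- c(g1 = 1, g2 = 2, g3 = 3)
  w <- c(g1 = 10, g2 = 10, g3 = 1)
  one <- aggregate_by_category(fl, c(g1 = "A", g2 = "A", g3 = "A"), w)
  expect_equal(unname(one[["A"]]), sum(fl * w))
  two <- aggregate_by_category(fl, c(g1 = "A", g2 = "B", g3 = "B"), w)
  expect_equal(sum(two), sum(one)) # refinement preserves the grand total
  # unmapped genes land in "uncategorized"; negative flux errors
  part <- aggregate_by_category(fl, c(g1 = "A"), w)
  expect_equal(unname(part[["uncategorized"]]), 2 * 10 + 3 * 1)
  expect_error(aggregate_by_category(c(g1 = -1), c(g1 = "A"), w),
               "negative")
  nrm <- aggregate_by_category(fl, c(g1 = "A", g2 = "B", g3 = "B"), w,
                               normalize = "max")
  expect_equal(max(nrm), 1)
})

test_that("expression_growth_corr: determinism, perfect correlation, exclusions", {
  mu <- c(0.05, 0.1, 0.18, 0.24, 0.3, 0.33)
  E <- rbind(linear = 2 * mu,
             noisy = 2 * mu * exp(c(0.05, -0.03, 0.04, -0.02, 0.01, -0.04)),
             flat = rep(1, 6))
  r1 <- expression_growth_corr(E, mu = mu, n_perm = 200, seed = 11)
  r2 <- expression_growth_corr(E, mu = mu, n_perm = 200, seed = 11)
  expect_identical(r1$table, r2$table)
  expect_equal(r1$table$r[1], 1, tolerance = 1e-12)
  expect_equal(r1$table$p_perm[1], 1 / 201, tolerance = 1e-12)
  expect_true(is.na(r1$table$r[3])) # constant vector: undefined r
  expect_equal(r1$n_genes_defined, 2L)
  expect_error(expression_growth_corr(E[, 1:3], mu = mu[1:3]),
               "at least 4")
})

test_that("exact permutation p-values equal the exhaustive oracle", {
  set.seed(42)
  mu <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  E <- rbind(a = mu + rnorm(5, 0, 0.05),
             b = rnorm(5),
             c = rev(mu) + rnorm(5, 0, 0.1))
  res <- expression_growth_corr(E, mu = mu, exact = TRUE)
  expect_equal(res$n_perm, 120L)
  for (g in 1:3)
    expect_equal(res$table$p_perm[g],
                 perm_exhaustive_oracle(E[g, ], mu),
                 tolerance = 1e-12, info = rownames(E)[g])
})

test_that("correlate_vs_substrate contracts", {
  sw <- structure(list(
    swept_id = "EX_s_e", grid = 1:5, status = rep("optimal", 5),
    mu_star = c(0.1, 0.18, 0.24, 0.28, 0.3),
    exchange_fluxes = matrix(-(1:5), 1, dimnames = list("EX_s_e", NULL)),
    expression_fluxes = rbind(gA = (1:5) * 0.01,
                              gB = c(0.1, 0.2, 0.25, 0.28, 0.3)),
    secretion = list()), class = "acetome_sweep")
  r <- correlate_vs_substrate(sw, "gA")
  expect_equal(unname(r["r_substrate"]), 1, tolerance = 1e-12)
  expect_error(correlate_vs_substrate(sw, character()), "empty")
  expect_error(correlate_vs_substrate(sw, "ghost"), "unknown")
})

test_that("metal_sweep warns when the metal feeds no modification", {
  toy <- toy_bundle()
  prob <- toy_problem_on(co = 6)
  expect_warning(
    ms <- metal_sweep(toy, "EX_mg2_e", c(1e-5, 1e-4), prob = prob),
    "no modification")
  expect_equal(nrow(ms$activity), 0L)
})

test_that("uptake_sweep records failed points without aborting", {
  toy <- toy_bundle()
  # grid must be strictly increasing and non-negative
  expect_error(uptake_sweep(toy, "EX_co_e", c(2, 1)), "increasing")
  expect_error(uptake_sweep(toy, "EX_co_e", c(-1, 2)), "magnitudes")
  expect_error(uptake_sweep(toy, "EX_nope_e", c(1, 2),
                            prob = toy_problem()), "unknown")
})
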