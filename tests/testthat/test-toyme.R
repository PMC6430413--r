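# Synthetic toy acetogen: stated-world checks.

test_that("the generated model passes check_balances with zero violations", {
  toy <- toy_bundle()
  expect_equal(nrow(check_balances(toy$network)), 0L)
})

test_that("generation is deterministic: same seed gives byte-identical files", {
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_network(build_toy_acetogen(toy_config(seed = 7))$network, f1)
  write_network(build_toy_acetogen(toy_config(seed = 7))$network, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("WLP row reduction yields the 4-CO acetate net balance", {
  # 3 CODH4 + FDML + MTHFR5 + METR + CODH_ACS + ACKL + 2 RNF + ATPS +
  # 2 ATPM + ACt telescopes to 4 co + 2 h2o -> ac + h + 2 co2
  S <- stoichiometric_matrix(toy_bundle()$network)
  w <- setNames(numeric(ncol(S)), colnames(S))
  w[c("CODH4", "FDML", "MTHFR5", "METR", "CODH_ACS", "ACKL", "RNF",
      "ATPS4r", "ATPM", "ACt")] <- c(3, 1, 1, 1, 1, 1, 2, 1, 2, 1)
  net_change <- as.numeric(S %*% w)
  names(net_change) <- rownames(S)
  expected <- c(co_c = -4, h2o_c = -2, ac_e = 1, h_e = 1, co2_c = 2)
  for (m in names(expected))
    expect_equal(net_change[[m]], expected[[m]], tolerance = 1e-12,
                 info = m)
  expect_equal(sum(abs(net_change)) , sum(abs(expected)), tolerance = 1e-9)
})

test_that("the ethanol route telescopes to the 6-CO net balance", {
  S <- stoichiometric_matrix(toy_bundle()$network)
  w <- setNames(numeric(ncol(S)), colnames(S))
  w[c("CODH4", "FDML", "MTHFR5", "METR", "CODH_ACS", "ACKL", "AOR_CL",
      "ALCD2x", "RNF", "ATPS4r", "ATPM", "ETOHt")] <-
    c(5, 1, 1, 1, 1, 1, 1, 1, 3, 1.5, 2.5, 1)
  net_change <- as.numeric(S %*% w)
  names(net_change) <- rownames(S)
  expected <- c(co_c = -6, h2o_c = -3, etoh_e = 1, co2_c = 4)
  for (m in names(expected))
    expect_equal(net_change[[m]], expected[[m]], tolerance = 1e-12,
                 info = m)
  expect_equal(sum(abs(net_change)), sum(abs(expected)), tolerance = 1e-9)
})

test_that("the model is ME-feasible at mu = 0.01 on every configured substrate", {
  expect_true(feasible(toy_problem_on(co = 20), 0.01))
  expect_true(feasible(toy_problem_on(fru = 10), 0.01))
  expect_true(feasible(toy_problem_on(h2 = 40), 0.01))
})

test_that("config handles: glycerol loop removal and the nickel contradiction", {
  expect_error(toy_config(include_nickel = FALSE,
                          retain_ni_modifications = TRUE),
               "contradiction")
  noloop <- build_toy_acetogen(toy_config(include_glycerol_loop = FALSE))
  expect_false(any(c("GLYCt", "GLYCDx", "DHAK", "CLPNS140") %in%
                   names(noloop$network$reactions)))
  expect_equal(nrow(check_balances(noloop$network)), 0L)
  # lipid demand falls back to phosphatidylglycerol; the model still grows
  prob <- assemble(noloop$network, noloop$annex, noloop$params)
  prob <- me_set_bounds(prob, "EX_co_e", 0, 0)
  prob <- me_set_bounds(prob, "EX_h2_e", 0, 0)
  prob <- me_set_bounds(prob, "EX_fru_e", -5, 0)
  expect_true(feasible(prob, 0.01))
  # and glycerol can never be secreted (no exchange at all)
  expect_false("EX_glyc_e" %in% prob$col_ids)
})

test_that("synthetic expression datasets honor noise, seeds and labels", {
  toy <- toy_bundle()
  prob <- toy_problem_on(fru = 10)
  sw <- uptake_sweep(toy, "EX_fru_e", c(1, 2, 3, 4, 5), prob = prob)
  d0 <- synth_expression_dataset(sw, noise_sd = 0, n_null_genes = 5,
                                 seed = 3)
  # zero noise reproduces the true fluxes exactly
  genes <- rownames(sw$expression_fluxes)
  expect_equal(d0$expression[genes, ], sw$expression_fluxes,
               tolerance = 1e-12, ignore_attr = TRUE)
  d1 <- synth_expression_dataset(sw, noise_sd = 0.1, n_null_genes = 5,
                                 seed = 3)
  d2 <- synth_expression_dataset(sw, noise_sd = 0.1, n_null_genes = 5,
                                 seed = 3)
  expect_identical(d1, d2)
  expect_error(synth_expression_dataset(sw, noise_sd = -1), "noise_sd")
  expect_true(all(d1$truth$is_null[grepl("^null", d1$truth$gene)]))
  expect_false(any(d1$truth$growth_linked & d1$truth$is_null))
})
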