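# Shared fixtures: the toy bundle and assembled ME problems are built
# once per test run and cached.

.cache <- new.env(parent = emptyenv())

toy_bundle <- function() {
  if (is.null(.cache$toy)) .cache$toy <- build_toy_acetogen(toy_config())
  .cache$toy
}

toy_problem <- function() {
  if (is.null(.cache$prob)) {
    toy <- toy_bundle()
    .cache$prob <- assemble(toy$network, toy$annex, toy$params)
  }
  .cache$prob
}

# close all carbon sources, then open the named ones
toy_problem_on <- function(co = NULL, fru = NULL, h2 = NULL) {
  p <- toy_problem()
  p <- me_set_bounds(p, "EX_co_e", if (is.null(co)) 0 else -co, 0)
  p <- me_set_bounds(p, "EX_fru_e", if (is.null(fru)) 0 else -fru, 0)
  p <- me_set_bounds(p, "EX_h2_e", if (is.null(h2)) 0 else -h2, 0)
  if (!is.null(h2)) p <- me_set_bounds(p, "EX_co2_e", -1000, 1000)
  p
}

# a 4-reaction transport chain: A_e -> A_c -> B_c -> B_e
chain_network <- function(uptake = 10) {
  mets <- list(
    metabolite("A_e", formula = c(C = 1), compartment = "e"),
    metabolite("A_c", formula = c(C = 1), compartment = "c"),
    metabolite("B_c", formula = c(C = 1), compartment = "c"),
    metabolite("B_e", formula = c(C = 1), compartment = "e"))
  rxns <- list(
    reaction("EX_A_e", c(A_e = -1), lower_bound = -uptake, upper_bound = 0),
    reaction("At", c(A_e = -1, A_c = 1), lower_bound = -1000),
    reaction("conv", c(A_c = -1, B_c = 1)),
    reaction("Bt", c(B_c = -1, B_e = 1)),
    reaction("EX_B_e", c(B_e = -1), lower_bound = 0, upper_bound = 1000))
  network(mets, rxns, objective_id = "EX_B_e", id = "chain")
}
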