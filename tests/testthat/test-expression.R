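# E-matrix builders: coupling coefficients, cofactor delivery, dummy
# catalyst, carrier coupling, and the affine/balance invariants.

params_default <- coupling_params()

test_that("gene/TU/complex constructors enforce invariants", {
  expect_error(gene_spec("g", "mRNA", c(A = 10, C = 10, G = 10, U = 10)),
               "protein_aa_composition")
  expect_error(gene_spec("g", "rRNA", c(A = 10),
                         protein_aa_composition = c(aa_c = 3)), "mRNA")
  expect_error(gene_spec("g", "mRNA", c(A = 30),
                         protein_aa_composition = c(aa_c = 0)),
               "zero-length")
  expect_error(tu_spec("t", character()), "no genes")
  expect_error(modification_spec("ni2_c", 0), ">= 1")
  expect_error(modification_spec("cobalt2_c", 1, "hyp_nickel"), "nickel")
  expect_error(modification_spec("ni2_c", 1, "isc_suf_fes"),
               "iron-sulfur")
  expect_error(complex_spec("c", c(g = 0)), ">= 1")
  # stable TU may not contain mRNA genes
  toy <- toy_bundle()
  ann <- toy$annex
  ann$transcription_units$TU_stable$gene_ids <-
    c("rrn", "trn", "codh4")
  expect_error(validate_annex(ann), "stable")
})

test_that("transcription coefficients follow mu * L / (3600 k_rnap)", {
  g <- gene_spec("g1", "mRNA", c(A = 225, C = 225, G = 225, U = 225),
                 protein_aa_composition = c(aa_c = 280))
  tu <- tu_spec("tu1", "g1")
  rx <- build_transcription(tu, list(g1 = g), params_default)[[1]]
  # L = 900 nt, k_rnap = 55 nt/s: at mu = 0.2 the RNAP usage is
  # 0.2 * 900 / (3600 * 55) ~ 9.09e-4
  b <- rx$stoich_b[["CPLX_rnap"]]
  expect_equal(-b * 0.2, 0.2 * 900 / (3600 * 55), tolerance = 1e-12)
  # NTP consumption matches composition; ppi and one water bookkeeping
  expect_equal(rx$stoich_a[["atp_c"]], -225)
  expect_equal(rx$stoich_a[["ppi_c"]], 900)
  expect_equal(rx$stoich_a[["h2o_c"]], -1)
  expect_equal(rx$stoich_a[[rna_species("g1")]], 1)
})

test_that("stable TUs emit no degradation; operons co-produce member RNAs", {
  toy <- toy_bundle()
  genes <- annex_all_genes(toy$annex)
  stable <- build_transcription(toy$annex$transcription_units$TU_stable,
                                genes, params_default)
  expect_length(stable, 1L) # transcription only, no DEG_*
  op <- build_transcription(toy$annex$transcription_units$TU_aor,
                            genes, params_default)
  tx <- op[[1]]
  expect_equal(tx$stoich_a[[rna_species("aor")]], 1)
  expect_equal(tx$stoich_a[[rna_species("alcd")]], 1)
  degs <- vapply(op[-1], `[[`, "", "id")
  expect_setequal(degs, c("DEG_aor", "DEG_alcd"))
  # missing gene reference errors
  expect_error(build_transcription(tu_spec("x", "ghost"), genes),
               "ghost")
})

test_that("translation costs 4 ATP-equivalents per residue with machinery couplings", {
  g <- gene_spec("g2", "mRNA", toy_nt_composition(960),
                 protein_aa_composition = c(aa_c = 300))
  rx <- build_translation(g, params_default)[[1]]
  expect_equal(rx$stoich_a[["aa_c"]], -300)
  expect_equal(rx$stoich_a[["atp_c"]], -1200)
  # ribosome usage mu * L / (3600 k_rib): 0.2*300/43200 ~ 1.389e-3
  expect_equal(-rx$stoich_b[[params_default$ribosome_complex_id]] * 0.2,
               0.2 * 300 / (3600 * 12), tolerance = 1e-12)
  # mRNA usage (mu + kdeg) / k_tl
  mrna_use <- rx$stoich_a[[rna_species("g2")]] +
    0.2 * rx$stoich_b[[rna_species("g2")]]
  expect_equal(-mrna_use, (0.2 + params_default$kdeg_mrna) / 300,
               tolerance = 1e-12)
  # 26-aa dummy: 26 aa-equivalents and 104 ATP-equivalents
  dummy <- toy_bundle()$annex$dummy_protein_gene
  rxd <- build_translation(dummy, params_default)[[1]]
  expect_equal(rxd$stoich_a[["aa_c"]], -26)
  expect_equal(rxd$stoich_a[["atp_c"]], -104)
})

test_that("doubling gene length doubles NTP cost and RNAP coupling, not mRNA usage", {
  mk <- function(L_aa) gene_spec("g", "mRNA", toy_nt_composition(3 * L_aa),
                                 protein_aa_composition = c(aa_c = L_aa))
  g1 <- mk(200); g2 <- mk(400)
  t1 <- build_transcription(tu_spec("t", "g"), list(g = g1))[[1]]
  t2 <- build_transcription(tu_spec("t", "g"), list(g = g2))[[1]]
  expect_equal(sum(t2$stoich_a[c("atp_c", "ctp_c", "gtp_c", "utp_c")]),
               2 * sum(t1$stoich_a[c("atp_c", "ctp_c", "gtp_c", "utp_c")]))
  expect_equal(t2$stoich_b[["CPLX_rnap"]], 2 * t1$stoich_b[["CPLX_rnap"]])
  l1 <- build_translation(g1)[[1]]; l2 <- build_translation(g2)[[1]]
  expect_equal(l2$stoich_b[[rna_species("g")]],
               l1$stoich_b[[rna_species("g")]]) # per-translation mRNA usage
})

test_that("translocation uses the ceiling ATP rule", {
  mk <- function(L) gene_spec("m", "mRNA", toy_nt_composition(3 * L),
                              protein_aa_composition = c(aa_c = L))
  r250 <- build_translocation(mk(250))[[1]]
  expect_equal(r250$stoich_a[["atp_c"]], -10)
  r26 <- build_translocation(mk(26))[[1]]
  expect_equal(r26$stoich_a[["atp_c"]], -2) # ceil(26/25)
  expect_equal(r26$stoich_a[[protein_mem_species("m")]], 1)
})

test_that("complex assembly consumes subunits and routes cofactors by delivery", {
  toy <- toy_bundle()
  ann <- toy$annex
  # unmodified monomer/dimer: only protein consumption
  rx <- build_complex_assembly(ann$complexes$CPLX_mthfr5, ann)[[1]]
  expect_equal(rx$stoich_a[[protein_species("mthfr5")]], -2)
  expect_equal(rx$stoich_a[["CPLX_mthfr5"]], 1)
  expect_false(any(grepl("ni2|fe2|cobalt", names(rx$stoich_a))))
  # direct delivery consumes the cofactor metabolite 1:1
  rm <- build_complex_assembly(ann$complexes$CPLX_metr, ann)[[1]]
  expect_equal(rm$stoich_a[["cobalt2_c"]], -1)
  # hyp_nickel: CODH_ACS consumes 2 loaded-carrier units, releasing Hyp
  ra <- build_complex_assembly(ann$complexes$CPLX_codhacs, ann)[[1]]
  expect_equal(ra$stoich_a[["CPLX_hyp_ni"]], -2)
  expect_equal(ra$stoich_a[["CPLX_hyp"]], 2)
  # loading reaction consumes ni2_c 1:1, so net Ni per CODH_ACS is 2
  loads <- build_cofactor_loading(ann)
  hyp <- loads[[which(vapply(loads, `[[`, "", "id") == "HYPLOAD")]]
  expect_equal(hyp$stoich_a[["ni2_c"]], -1)
  # isc_suf_fes: 4 Fe + 4 sulfur-donor units per cluster on the carrier
  fes <- loads[[which(vapply(loads, `[[`, "", "id") == "FESLOAD")]]
  expect_equal(fes$stoich_a[["fe2_c"]], -4)
  expect_equal(fes$stoich_a[["h2s_c"]], -4)
  # membrane complexes consume translocated subunit species
  rr <- build_complex_assembly(ann$complexes$CPLX_rnf, ann)[[1]]
  expect_true(protein_mem_species("rnf") %in% names(rr$stoich_a))
})

test_that("add_unmodeled_protein computes the mass-coupling ratio", {
  ann <- toy_bundle()$annex
  expect_equal(add_unmodeled_protein(ann, 0)$unmodeled_constraint$ratio, 0)
  expect_equal(add_unmodeled_protein(ann, 0.35)$unmodeled_constraint$ratio,
               0.35 / 0.65, tolerance = 1e-12)
  expect_equal(add_unmodeled_protein(ann, 0.5)$unmodeled_constraint$ratio, 1)
  expect_error(add_unmodeled_protein(ann, 1), "f < 1")
})

test_that("add_dummy_catalyst assigns soluble/membrane dummies to orphans only", {
  toy <- toy_bundle()
  net <- toy$network
  # the builder already ran the pass: an orphan transporter got the
  # membrane dummy, an orphan cytosolic reaction the soluble dummy
  expect_equal(net$reactions$COt$enzyme_complex_id, "CPLX_dummy_mem")
  expect_equal(net$reactions$AMPSYN$enzyme_complex_id, "CPLX_dummy")
  # named enzymes are untouched
  expect_equal(net$reactions$CODH4$enzyme_complex_id, "CPLX_codh4")
  # pseudo-reactions stay enzyme-free
  expect_null(net$reactions$EX_co_e$enzyme_complex_id)
  expect_null(net$reactions$ATPM$enzyme_complex_id)
  # a network with all reactions assigned is unchanged
  again <- add_dummy_catalyst(net, toy$annex)
  expect_identical(again$network$reactions$COt$enzyme_complex_id,
                   "CPLX_dummy_mem")
})

test_that("carrier coupling validates redox pairs and registers keff", {
  toy <- toy_bundle()
  expect_error(
    add_carrier_coupling(toy$network, toy$annex,
                         carriers = list(bad = list(complex = "CPLX_fdx",
                                                    reduced = "nope_c",
                                                    oxidized = "fd_ox_c"))),
    "nope_c")
  ann <- add_carrier_coupling(toy$network, toy$annex)
  expect_equal(ann$carriers$ferredoxin$keff, 25)
})

test_that("every emitted expression reaction is elementally balanced (a-part)", {
  # pseudo-formula assignment must close every constant (chemical) part
  # of the emitted reactions; mu-proportional parts are dilution terms
  toy <- toy_bundle()
  net <- toy$network
  reg <- species_registry(net, toy$annex, toy$params)
  # assemble a validation network: species become pseudo-metabolites
  mets <- net$metabolites
  for (sp in reg) {
    id <- paste0(sp$id, "_c")
    mets[[id]] <- metabolite(id, formula = sp$formula,
                             charge = sp$charge,
                             compartment = "c")
  }
  rxs <- list()
  genes <- annex_all_genes(toy$annex)
  for (tu in toy$annex$transcription_units)
    rxs <- c(rxs, build_transcription(tu, genes, toy$params))
  for (g in Filter(function(g) g$rna_type == "mRNA", genes))
    rxs <- c(rxs, build_translation(g, toy$params))
  for (gid in toy$annex$translocated_protein_ids)
    rxs <- c(rxs, build_translocation(genes[[gid]], toy$params))
  for (cx in toy$annex$complexes)
    rxs <- c(rxs, build_complex_assembly(cx, toy$annex, toy$params))
  rxs <- c(rxs, build_cofactor_loading(toy$annex, toy$params))
  conv <- lapply(rxs, function(rx) {
    st <- rx$stoich_a
    names(st) <- ifelse(names(st) %in% names(net$metabolites),
                        names(st), paste0(names(st), "_c"))
    reaction(rx$id, st, lower_bound = 0)
  })
  vnet <- network(unname(mets), conv, objective_id = conv[[1]]$id)
  bal <- check_balances(vnet)
  expect_equal(nrow(bal), 0L, info = paste(utils::head(bal$reaction, 5),
                                           collapse = ", "))
})

test_that("all mu-dependence is affine (linearity of instantiated coefficients)", {
  prob <- toy_problem()
  lp0 <- instantiate(prob, 0)
  lp1 <- instantiate(prob, 0.1)
  lp2 <- instantiate(prob, 0.2)
  expect_equal(lp2$A - lp1$A, lp1$A - lp0$A, tolerance = 1e-12)
  expect_equal(lp2$rhs - lp1$rhs, lp1$rhs - lp0$rhs, tolerance = 1e-12)
  expect_equal(lp2$lb - lp1$lb, lp1$lb - lp0$lb, tolerance = 1e-12)
})
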