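# E-matrix reaction builders. Every builder emits `me_reaction` objects
# whose mu-independent part (stoich_a) is exactly elementally balanced
# after pseudo-formula assignment; mu-proportional parts (stoich_b) are
# dilution/usage couplings and are exempt from balancing by definition
# (the diluted catalyst mass is accounted on the biomass-dilution row).

.NT_NTP <- c(A = "atp_c", C = "ctp_c", G = "gtp_c", U = "utp_c")
.NT_NMP <- c(A = "amp_c", C = "cmp_c", G = "gmp_c", U = "ump_c")

met_formula <- function(net, id) {
  m <- net$metabolites[[id]]
  if (is.null(m)) stop("unknown metabolite '", id, "'")
  m$formula
}

# pseudo-formula of an RNA chain: sum of NMP residues minus one water per
# phosphodiester bond
rna_formula <- function(net, nt_composition) {
  f <- numeric()
  for (nt in names(nt_composition))
    f <- formula_add(f, formula_scale(met_formula(net, .NT_NMP[[nt]]),
                                      nt_composition[[nt]]))
  formula_add(f, formula_scale(met_formula(net, "h2o_c"),
                               -(sum(nt_composition) - 1)))
}

rna_charge <- function(net, nt_composition) {
  sum(vapply(names(nt_composition), function(nt)
    net$metabolites[[.NT_NMP[[nt]]]]$charge * nt_composition[[nt]], 0))
}

protein_formula <- function(net, aa_composition) {
  f <- numeric()
  for (aa in names(aa_composition))
    f <- formula_add(f, formula_scale(met_formula(net, aa),
                                      aa_composition[[aa]]))
  formula_add(f, formula_scale(met_formula(net, "h2o_c"),
                               -(sum(aa_composition) - 1)))
}

protein_charge <- function(net, aa_composition) {
  sum(vapply(names(aa_composition), function(aa)
    net$metabolites[[aa]]$charge * aa_composition[[aa]], 0))
}

#' Build the macromolecule species registry
#'
#' Derives every macromolecular species implied by an annex: one RNA
#' species per gene, protein (and membrane-protein) species for mRNA
#' genes, the complexes, and loaded cofactor-carrier intermediates.
#' Pseudo-formulas are monomer sums minus one water per bond, so all
#' emitted reactions close elementally; molecular weights (g/mmol) derive
#' from the formulas. mRNA species carry the degradation rate
#' `params$kdeg_mrna`; stable RNA, proteins and complexes have kdeg 0.
#'
#' @param net metabolic network providing monomer formulas.
#' @param annex an `acetome_annex`.
#' @param params [coupling_params()].
#' @return named list of species records (`id`, `kind`, `mw`, `kdeg`,
#'   `formula`, `charge`).
#' @export
species_registry <- function(net, annex, params = coupling_params()) {
  reg <- list()
  add <- function(id, kind, formula, kdeg = 0, charge = 0) {
    mw <- formula_mw(formula)
    if (mw <= 0) mw <- 1e-6 # pseudo-species of unknown mass
    reg[[id]] <<- list(id = id, kind = kind, mw = mw, kdeg = kdeg,
                       formula = formula, charge = charge)
  }
  all_genes <- c(annex$genes,
                 setNames(list(annex$unmodeled_protein_gene,
                               annex$dummy_protein_gene),
                          c(annex$unmodeled_protein_gene$id,
                            annex$dummy_protein_gene$id)))
  stable_ids <- unlist(lapply(Filter(function(tu) tu$stable,
                                     annex$transcription_units),
                              `[[`, "gene_ids"))
  for (g in all_genes) {
    fr <- rna_formula(net, g$nt_composition)
    qr <- rna_charge(net, g$nt_composition)
    kdeg <- if (g$rna_type == "mRNA" && !(g$id %in% stable_ids))
      params$kdeg_mrna else 0
    add(rna_species(g$id), "RNA", fr, kdeg = kdeg, charge = qr)
    if (g$rna_type == "mRNA") {
      if (kdeg > 0) add(mrna_used_species(g$id), "RNA", fr, charge = qr)
      fp <- protein_formula(net, g$protein_aa_composition)
      qp <- protein_charge(net, g$protein_aa_composition)
      add(protein_species(g$id), "protein", fp, charge = qp)
      if (g$id %in% annex$translocated_protein_ids)
        add(protein_mem_species(g$id), "protein", fp, charge = qp)
    }
  }
  for (cx in annex$complexes) {
    f <- numeric()
    qc <- 0
    for (gid in names(cx$subunit_stoichiometry)) {
      g <- all_genes[[gid]]
      n <- cx$subunit_stoichiometry[[gid]]
      if (g$rna_type == "mRNA") {
        sub_f <- protein_formula(net, g$protein_aa_composition)
        qc <- qc + n * protein_charge(net, g$protein_aa_composition)
      } else {
        sub_f <- rna_formula(net, g$nt_composition)
        qc <- qc + n * rna_charge(net, g$nt_composition)
      }
      f <- formula_add(f, formula_scale(sub_f, n))
    }
    for (mod in cx$modifications) {
      cf <- cofactor_net_formula(net, mod)
      f <- formula_add(f, formula_scale(cf, mod$count))
      qc <- qc + mod$count * cofactor_net_charge(net, mod)
    }
    add(cx$id, "complex", f, charge = qc)
  }
  # loaded-carrier intermediates
  mods <- unlist(lapply(annex$complexes, `[[`, "modifications"),
                 recursive = FALSE)
  deliveries <- vapply(mods, `[[`, "", "delivery")
  if (any(deliveries == "hyp_nickel")) {
    hyp <- annex$machinery$hyp_machinery
    if (is.null(hyp) || is.null(reg[[hyp]]))
      stop("hyp_nickel modifications need machinery$hyp_machinery")
    add(paste0(hyp, "_ni"), "intermediate",
        formula_add(reg[[hyp]]$formula, met_formula(net, "ni2_c")),
        charge = reg[[hyp]]$charge + net$metabolites[["ni2_c"]]$charge)
  }
  if (any(deliveries == "isc_suf_fes")) {
    carrier <- annex$machinery$fes_carrier_gene
    if (is.null(carrier))
      stop("isc_suf_fes modifications need machinery$fes_carrier_gene")
    add(paste0(protein_species(carrier), "_fes"), "intermediate",
        formula_add(reg[[protein_species(carrier)]]$formula,
                    c(Fe = 4, S = 4)),
        charge = reg[[protein_species(carrier)]]$charge)
  }
  reg
}

# net elemental/charge contribution of a modification to the holo-complex
cofactor_net_formula <- function(net, mod) {
  if (mod$delivery == "isc_suf_fes") return(c(Fe = 4, S = 4))
  met_formula(net, mod$cofactor_metabolite_id)
}
cofactor_net_charge <- function(net, mod) {
  if (mod$delivery == "isc_suf_fes") return(0) # 4 Fe2+ + 4 S2- cluster
  net$metabolites[[mod$cofactor_metabolite_id]]$charge
}

#' Build transcription (and mRNA degradation) reactions for one TU
#'
#' The transcription reaction consumes NTPs over the summed member
#' nucleotide composition (each incorporated NTP costs two phosphate-bond
#' equivalents: pyrophosphate is released and hydrolyzed downstream),
#' produces every member RNA species, and uses RNA polymerase with the
#' growth-coupled coefficient mu * L_nt / (3600 * k_rnap). For non-stable
#' units one degradation reaction per member mRNA converts the
#' translation-coupled degraded-mRNA pool back to NMPs.
#'
#' @param tu a [tu_spec()].
#' @param genes named list of [gene_spec()] covering the TU.
#' @param params [coupling_params()].
#' @return list of `me_reaction`.
#' @export
build_transcription <- function(tu, genes, params = coupling_params()) {
  miss <- setdiff(tu$gene_ids, names(genes))
  if (length(miss))
    stop("TU '", tu$id, "' references missing gene(s): ",
         paste(miss, collapse = ", "))
  memb <- genes[tu$gene_ids]
  a <- numeric(); b <- numeric()
  L_tot <- 0
  for (g in memb) {
    L <- g$length_nt
    L_tot <- L_tot + L
    for (nt in names(g$nt_composition))
      a <- acc(a, .NT_NTP[[nt]], -g$nt_composition[[nt]])
    a <- acc(a, "h2o_c", -1)         # one water per chain initiation
    a <- acc(a, rna_species(g$id), 1)
    a <- acc(a, "ppi_c", L)
    a <- acc(a, "h_c", L)
  }
  rnap <- params$rnap_complex_id
  if (!is.null(rnap)) b <- acc(b, rnap, -L_tot / (3600 * params$k_rnap))
  out <- list(me_reaction(paste0("TX_", tu$id), "transcription", a, b))
  if (!tu$stable && params$kdeg_mrna > 0) {
    for (g in memb) {
      if (g$rna_type != "mRNA") next
      da <- numeric()
      da <- acc(da, mrna_used_species(g$id), -1)
      da <- acc(da, "h2o_c", -(g$length_nt - 1))
      for (nt in names(g$nt_composition))
        da <- acc(da, .NT_NMP[[nt]], g$nt_composition[[nt]])
      out[[length(out) + 1L]] <-
        me_reaction(paste0("DEG_", g$id), "degradation", da)
    }
  }
  out
}

#' Build the translation reaction for an mRNA gene
#'
#' Consumes amino acids per the protein composition and 4 ATP-equivalents
#' per residue (2 for tRNA charging, 2 GTP-as-ATP for elongation),
#' produces the protein species. Couplings: ribosome usage
#' mu * L_aa / (3600 * k_rib); mRNA usage (mu + kdeg) / k_tl, of which the
#' kdeg / k_tl part is routed to the degraded-mRNA pool; pooled
#' charged-tRNA usage mu * L_aa / (3600 * keff_trna).
#'
#' @param gene a [gene_spec()] with `rna_type == "mRNA"`.
#' @param params [coupling_params()].
#' @param stable treat the mRNA as non-degrading (kdeg 0).
#' @return list with one `me_reaction`.
#' @export
build_translation <- function(gene, params = coupling_params(),
                              stable = FALSE) {
  if (gene$rna_type != "mRNA")
    stop("gene '", gene$id, "' is not protein-coding")
  L <- gene$protein_length_aa
  kdeg <- if (stable) 0 else params$kdeg_mrna
  a <- numeric(); b <- numeric()
  for (aa in names(gene$protein_aa_composition))
    a <- acc(a, aa, -gene$protein_aa_composition[[aa]])
  natp <- params$atp_per_aa * L
  a <- acc(a, "atp_c", -natp)
  # net water: nATP hydrolyses consume water, L-1 peptide bonds release it
  a <- acc(a, "h2o_c", -(natp - (L - 1)))
  a <- acc(a, "adp_c", natp)
  a <- acc(a, "pi_c", natp)
  a <- acc(a, "h_c", natp)
  a <- acc(a, protein_species(gene$id), 1)
  a <- acc(a, rna_species(gene$id), -kdeg / params$k_tl)
  b <- acc(b, rna_species(gene$id), -1 / params$k_tl)
  if (kdeg > 0) a <- acc(a, mrna_used_species(gene$id), kdeg / params$k_tl)
  if (!is.null(params$ribosome_complex_id))
    b <- acc(b, params$ribosome_complex_id, -L / (3600 * params$k_rib))
  if (!is.null(params$trna_complex_id))
    b <- acc(b, params$trna_complex_id, -L / (3600 * params$keff_trna))
  list(me_reaction(paste0("TL_", gene$id), "translation", a, b))
}

#' Build the membrane-translocation reaction for a protein
#'
#' Converts the cytosolic protein species into its membrane-localized
#' form at a cost of one ATP-equivalent per started 25-residue segment
#' (ceiling rule), with translocase usage coupling.
#'
#' @param gene a protein-coding [gene_spec()] flagged for translocation.
#' @param params [coupling_params()].
#' @return list with one `me_reaction`.
#' @export
build_translocation <- function(gene, params = coupling_params()) {
  if (gene$rna_type != "mRNA")
    stop("gene '", gene$id, "' has no protein to translocate")
  L <- gene$protein_length_aa
  k <- ceiling(L / params$transloc_aa_per_atp)
  a <- numeric(); b <- numeric()
  a <- acc(a, protein_species(gene$id), -1)
  a <- acc(a, protein_mem_species(gene$id), 1)
  a <- acc(a, "atp_c", -k)
  a <- acc(a, "h2o_c", -k)
  a <- acc(a, "adp_c", k)
  a <- acc(a, "pi_c", k)
  a <- acc(a, "h_c", k)
  if (!is.null(params$translocase_complex_id))
    b <- acc(b, params$translocase_complex_id,
             -1 / (3600 * params$keff_translocase))
  list(me_reaction(paste0("TLOC_", gene$id), "translocation", a, b))
}

#' Build complex formation (and cofactor delivery) reactions
#'
#' The formation reaction consumes subunit species per stoichiometry
#' (membrane complexes consume translocated subunit species) and the
#' cofactors demanded by each modification:
#' * `direct` - the cofactor metabolite, `count` per complex;
#' * `hyp_nickel` - a Hyp-loaded nickel intermediate (the shared loading
#'   reaction consumes `ni2_c` and is catalyzed by the Hyp machinery);
#' * `isc_suf_fes` - a carrier-bound Fe-S cluster (the shared loading
#'   reaction consumes 4 `fe2_c` + 4 sulfur-donor units on the NifU-like
#'   carrier, SufBC-catalyzed with IscS usage; the transfer into the
#'   target is ErpA-catalyzed).
#'
#' Shared loading reactions are emitted once per annex by
#' [build_cofactor_loading()].
#'
#' @param cx a [complex_spec()].
#' @param annex the enclosing `acetome_annex`.
#' @param params [coupling_params()].
#' @return list with one `me_reaction`.
#' @export
build_complex_assembly <- function(cx, annex, params = coupling_params()) {
  all_genes <- annex_all_genes(annex)
  a <- numeric(); b <- numeric()
  a <- acc(a, cx$id, 1)
  for (gid in names(cx$subunit_stoichiometry)) {
    g <- all_genes[[gid]]
    if (is.null(g))
      stop("complex '", cx$id, "': unknown subunit gene '", gid, "'")
    n <- cx$subunit_stoichiometry[[gid]]
    sp <- if (g$rna_type != "mRNA") rna_species(gid)
    else if (cx$membrane && gid %in% annex$translocated_protein_ids)
      protein_mem_species(gid)
    else protein_species(gid)
    a <- acc(a, sp, -n)
  }
  for (mod in cx$modifications) {
    if (mod$delivery == "direct") {
      a <- acc(a, mod$cofactor_metabolite_id, -mod$count)
    } else if (mod$delivery == "hyp_nickel") {
      hyp <- annex$machinery$hyp_machinery
      a <- acc(a, paste0(hyp, "_ni"), -mod$count)
      a <- acc(a, hyp, mod$count)       # carrier is released
    } else { # isc_suf_fes
      carrier <- protein_species(annex$machinery$fes_carrier_gene)
      a <- acc(a, paste0(carrier, "_fes"), -mod$count)
      a <- acc(a, carrier, mod$count)
      if (!is.null(annex$machinery$fes_transfer))
        b <- acc(b, annex$machinery$fes_transfer,
                 -mod$count / (3600 * params$keff_default))
    }
  }
  list(me_reaction(paste0("FORM_", cx$id), "complex_formation", a, b))
}

#' Build shared cofactor-loading reactions for an annex
#'
#' Emits (at most once each) the Hyp nickel-loading reaction and the
#' NifU-carrier Fe-S assembly reaction used by [build_complex_assembly()].
#'
#' @param annex an `acetome_annex`.
#' @param params [coupling_params()].
#' @return list of `me_reaction` (possibly empty).
#' @export
build_cofactor_loading <- function(annex, params = coupling_params()) {
  mods <- unlist(lapply(annex$complexes, `[[`, "modifications"),
                 recursive = FALSE)
  deliveries <- vapply(mods, `[[`, "", "delivery")
  out <- list()
  if (any(deliveries == "hyp_nickel")) {
    hyp <- annex$machinery$hyp_machinery
    a <- numeric(); b <- numeric()
    a <- acc(a, hyp, -1)
    a <- acc(a, "ni2_c", -1)
    a <- acc(a, paste0(hyp, "_ni"), 1)
    b <- acc(b, hyp, -1 / (3600 * params$keff_default)) # self-catalysis
    out[[length(out) + 1L]] <- me_reaction("HYPLOAD", "cofactor_loading", a, b)
  }
  if (any(deliveries == "isc_suf_fes")) {
    carrier <- protein_species(annex$machinery$fes_carrier_gene)
    a <- numeric(); b <- numeric()
    a <- acc(a, carrier, -1)
    a <- acc(a, "fe2_c", -4)
    a <- acc(a, "h2s_c", -4)
    a <- acc(a, "h_c", 8)
    a <- acc(a, paste0(carrier, "_fes"), 1)
    for (role in c("fes_catalyst", "fes_sulfur")) {
      cxid <- annex$machinery[[role]]
      if (!is.null(cxid))
        b <- acc(b, cxid, -1 / (3600 * params$keff_default))
    }
    out[[length(out) + 1L]] <- me_reaction("FESLOAD", "cofactor_loading", a, b)
  }
  out
}

annex_all_genes <- function(annex) {
  c(annex$genes,
    setNames(list(annex$unmodeled_protein_gene, annex$dummy_protein_gene),
             c(annex$unmodeled_protein_gene$id,
               annex$dummy_protein_gene$id)))
}

#' Pin the unmodeled-protein mass fraction
#'
#' Returns the constraint specification enforcing
#' (unmodeled protein mass) = f / (1 - f) * (modeled protein mass)
#' at any solution, and records it on the annex.
#'
#' @param annex an `acetome_annex`.
#' @param f unmodeled proteome mass fraction, `0 <= f < 1` (0.35 in the
#'   reference parameterization).
#' @return the annex with `$unmodeled_constraint` set
#'   (`list(f, ratio = f/(1-f))`).
#' @export
add_unmodeled_protein <- function(annex, f = 0.35) {
  if (!is.numeric(f) || f < 0 || f >= 1)
    stop("unmodeled fraction must satisfy 0 <= f < 1")
  annex$unmodeled_constraint <- list(f = f, ratio = f / (1 - f))
  annex
}

#' Assign the dummy catalyst to orphan reactions
#'
#' Every internal enzyme-requiring reaction without an
#' `enzyme_complex_id` is assigned the soluble 26-aa dummy complex;
#' transport reactions (stoichiometry spanning both compartments) get the
#' membrane dummy. Exchange, demand, biomass and maintenance
#' pseudo-reactions are exempt.
#'
#' @param net an `acetome_network`.
#' @param annex an `acetome_annex` whose machinery names `dummy` and
#'   `dummy_mem` complexes.
#' @return list with the modified `network` and the (unchanged) `annex`.
#' @export
add_dummy_catalyst <- function(net, annex) {
  dummy <- annex$machinery$dummy
  dummy_mem <- annex$machinery$dummy_mem
  if (is.null(dummy) || is.null(dummy_mem))
    stop("annex machinery must name 'dummy' and 'dummy_mem' complexes")
  for (i in seq_along(net$reactions)) {
    r <- net$reactions[[i]]
    if (is_pseudo(r$id) || !is.null(r$enzyme_complex_id)) next
    comps <- vapply(net$metabolites[names(r$stoichiometry)],
                    `[[`, "", "compartment")
    is_transport <- length(unique(comps)) > 1L
    net$reactions[[i]]$enzyme_complex_id <-
      if (is_transport) dummy_mem else dummy
    net$reactions[[i]]$keff <- r$keff
  }
  list(network = net, annex = annex)
}

#' Couple carrier-protein expression to reducing flux
#'
#' Ferredoxin and thioredoxin are proteins; without coupling they would
#' carry flux without ever being synthesized. Every metabolic reaction
#' producing the reduced form of a registered carrier acquires a usage
#' coupling of mu / (3600 * keff) on the carrier complex per unit flux,
#' forcing carrier expression whenever reducing flux is nonzero.
#'
#' @param net an `acetome_network` (for validation of the redox pairs).
#' @param annex an `acetome_annex`.
#' @param carriers named list, each element
#'   `list(complex = <complex id>, reduced = <met id>, oxidized = <met id>,
#'   keff = <1/s>)`; defaults to the annex's carriers.
#' @return the annex with `$carriers` set.
#' @export
add_carrier_coupling <- function(net, annex, carriers = annex$carriers) {
  for (nm in names(carriers)) {
    cr <- carriers[[nm]]
    for (fld in c("reduced", "oxidized"))
      if (!cr[[fld]] %in% names(net$metabolites))
        stop("carrier '", nm, "': missing redox-pair metabolite '",
             cr[[fld]], "'")
    if (!cr$complex %in% names(annex$complexes))
      stop("carrier '", nm, "': unknown complex '", cr$complex, "'")
    if (is.null(cr$keff)) carriers[[nm]]$keff <- 25
  }
  annex$carriers <- carriers
  annex
}
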