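# ---------------------------------------------------------------------------
# E-matrix data model: genes, transcription units, complexes, cofactor
# modifications, and the expression annex bundling them. Reactions emitted
# by the builders carry growth-rate-affine stoichiometric coefficients
# (value = a + b*mu), the ME-model coupling mechanism.
# ---------------------------------------------------------------------------

#' Create a gene specification
#'
#' @param id gene id.
#' @param rna_type `"mRNA"`, `"rRNA"` or `"tRNA"`.
#' @param nt_composition named counts over `c("A","C","G","U")`.
#' @param protein_aa_composition named counts, amino-acid metabolite id ->
#'   count; required iff `rna_type == "mRNA"`.
#' @return object of class `acetome_gene`.
#' @export
gene_spec <- function(id, rna_type = c("mRNA", "rRNA", "tRNA"),
                      nt_composition, protein_aa_composition = NULL) {
  rna_type <- match.arg(rna_type)
  nt_composition <- unlist(nt_composition)
  if (!all(names(nt_composition) %in% c("A", "C", "G", "U")))
    stop("gene '", id, "': nt_composition keys must be A/C/G/U")
  if (any(nt_composition < 0)) stop("gene '", id, "': negative nt counts")
  length_nt <- sum(nt_composition)
  if (length_nt <= 0) stop("gene '", id, "': empty transcript")
  if (rna_type == "mRNA") {
    if (is.null(protein_aa_composition))
      stop("gene '", id, "': mRNA gene needs protein_aa_composition")
    protein_aa_composition <- unlist(protein_aa_composition)
    if (sum(protein_aa_composition) <= 0)
      stop("gene '", id, "': zero-length protein")
  } else if (!is.null(protein_aa_composition)) {
    stop("gene '", id, "': only mRNA genes encode protein")
  }
  structure(list(id = id, rna_type = rna_type,
                 nt_composition = nt_composition,
                 length_nt = length_nt,
                 protein_aa_composition = protein_aa_composition,
                 protein_length_aa =
                   if (is.null(protein_aa_composition)) NULL
                   else sum(protein_aa_composition)),
            class = "acetome_gene")
}

#' Create a transcription unit specification
#'
#' @param id TU id.
#' @param gene_ids member gene ids, 5' to 3'.
#' @param terminator `"rho_dependent"` or `"rho_independent"` (metadata
#'   only; terminators carry no coefficients).
#' @param stable `TRUE` only for all-rRNA/tRNA units; stable RNA is not
#'   degraded.
#' @return object of class `acetome_tu`.
#' @export
tu_spec <- function(id, gene_ids,
                    terminator = c("rho_dependent", "rho_independent"),
                    stable = FALSE) {
  terminator <- match.arg(terminator)
  if (length(gene_ids) == 0L) stop("TU '", id, "' has no genes")
  structure(list(id = id, gene_ids = gene_ids, terminator = terminator,
                 stable = isTRUE(stable)),
            class = "acetome_tu")
}

#' Create a cofactor modification specification
#'
#' @param cofactor_metabolite_id cytosolic cofactor metabolite (e.g.
#'   `"ni2_c"`, `"4fe4s_c"`, `"cobalt2_c"`).
#' @param count clusters/ions per complex, >= 1.
#' @param delivery `"direct"` (cofactor consumed 1:1), `"hyp_nickel"`
#'   (nickel loaded onto a carrier by the Hyp machinery), or
#'   `"isc_suf_fes"` (Fe-S cluster built on the NifU-like carrier with
#'   IscS sulfur donation and SufBC catalysis, transferred by ErpA).
#' @return object of class `acetome_modification`.
#' @export
modification_spec <- function(cofactor_metabolite_id, count = 1L,
                              delivery = c("direct", "hyp_nickel",
                                           "isc_suf_fes")) {
  delivery <- match.arg(delivery)
  if (count < 1) stop("modification count must be >= 1")
  if (delivery == "hyp_nickel" && !grepl("^ni2?_", cofactor_metabolite_id))
    stop("hyp_nickel delivery is only for nickel")
  if (delivery == "isc_suf_fes" && !grepl("fe", cofactor_metabolite_id))
    stop("isc_suf_fes delivery is only for iron-sulfur clusters")
  structure(list(cofactor_metabolite_id = cofactor_metabolite_id,
                 count = as.integer(count), delivery = delivery),
            class = "acetome_modification")
}

#' Create a protein-complex specification
#'
#' @param id complex id (conventionally `CPLX_*`).
#' @param subunit_stoichiometry named integer vector, gene id -> copies
#'   (>= 1). rRNA/tRNA gene ids are allowed as subunits (ribosome, tRNA
#'   pool).
#' @param modifications list of [modification_spec()].
#' @param membrane membrane-bound complex; protein subunits must then be
#'   translocated.
#' @return object of class `acetome_complex`.
#' @export
complex_spec <- function(id, subunit_stoichiometry, modifications = list(),
                         membrane = FALSE) {
  subunit_stoichiometry <- unlist(subunit_stoichiometry)
  if (any(subunit_stoichiometry < 1))
    stop("complex '", id, "': subunit counts must be >= 1")
  structure(list(id = id, subunit_stoichiometry = subunit_stoichiometry,
                 modifications = modifications, membrane = isTRUE(membrane)),
            class = "acetome_complex")
}

#' Assemble an expression annex
#'
#' Bundles the E-side entities: genes, transcription units, complexes,
#' translocation flags, carrier-protein couplings, machinery roles, and
#' the unmodeled/dummy protein genes.
#'
#' @param genes list of [gene_spec()].
#' @param transcription_units list of [tu_spec()].
#' @param complexes list of [complex_spec()].
#' @param translocated_protein_ids gene ids of membrane/secreted proteins.
#' @param unmodeled_protein_gene [gene_spec()] for the unmodeled-proteome
#'   stand-in (its mass is pinned to the modeled proteome by the
#'   unmodeled fraction `f`).
#' @param dummy_protein_gene [gene_spec()] for the generic catalyst; must
#'   be 26 amino acids long.
#' @param machinery named list of machinery roles: `rnap`, `ribosome`,
#'   `translocase`, `trna` (complex ids), optional `hyp_machinery`,
#'   `fes_carrier_gene`, `fes_sulfur`, `fes_catalyst`, `fes_transfer`,
#'   `dummy`, `dummy_mem`.
#' @param carriers named list of carrier couplings, each
#'   `list(complex, reduced, oxidized)` (see [add_carrier_coupling()]).
#' @return object of class `acetome_annex`.
#' @export
expression_annex <- function(genes, transcription_units, complexes,
                             translocated_protein_ids = character(),
                             unmodeled_protein_gene,
                             dummy_protein_gene,
                             machinery = list(), carriers = list()) {
  gene_ids <- vapply(genes, `[[`, "", "id")
  names(genes) <- gene_ids
  names(transcription_units) <-
    vapply(transcription_units, `[[`, "", "id")
  names(complexes) <- vapply(complexes, `[[`, "", "id")
  if (!inherits(unmodeled_protein_gene, "acetome_gene"))
    stop("unmodeled_protein_gene must be a gene_spec")
  if (!inherits(dummy_protein_gene, "acetome_gene"))
    stop("dummy_protein_gene must be a gene_spec")
  if (dummy_protein_gene$protein_length_aa != 26L)
    stop("the dummy catalyst protein must be 26 amino acids long")
  ann <- structure(list(genes = genes,
                        transcription_units = transcription_units,
                        complexes = complexes,
                        translocated_protein_ids = translocated_protein_ids,
                        unmodeled_protein_gene = unmodeled_protein_gene,
                        dummy_protein_gene = dummy_protein_gene,
                        dummy_protein_length_aa = 26L,
                        machinery = machinery, carriers = carriers),
                   class = "acetome_annex")
  validate_annex(ann)
  ann
}

#' Validate expression-annex invariants
#'
#' @param annex an `acetome_annex`.
#' @return the annex, invisibly.
#' @export
validate_annex <- function(annex) {
  gene_ids <- c(names(annex$genes), annex$unmodeled_protein_gene$id,
                annex$dummy_protein_gene$id)
  for (tu in annex$transcription_units) {
    miss <- setdiff(tu$gene_ids, gene_ids)
    if (length(miss))
      stop("TU '", tu$id, "' references unknown gene(s): ",
           paste(miss, collapse = ", "))
    if (tu$stable) {
      types <- vapply(annex$genes[tu$gene_ids], `[[`, "", "rna_type")
      if (any(types == "mRNA"))
        stop("TU '", tu$id, "' is stable but contains mRNA genes")
    }
  }
  in_tu <- unlist(lapply(annex$transcription_units, `[[`, "gene_ids"))
  orphan <- setdiff(names(annex$genes), in_tu)
  if (length(orphan))
    stop("gene(s) not covered by any transcription unit: ",
         paste(orphan, collapse = ", "))
  for (cx in annex$complexes) {
    miss <- setdiff(names(cx$subunit_stoichiometry), gene_ids)
    if (length(miss))
      stop("complex '", cx$id, "' references unknown gene(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(annex)
}

# species-id helpers (flat namespace shared with metabolite ids)
rna_species <- function(gene_id) paste0("RNA_", gene_id)
protein_species <- function(gene_id) paste0("protein_", gene_id)
protein_mem_species <- function(gene_id) paste0("protein_", gene_id, "_mem")
mrna_used_species <- function(gene_id) paste0("mRNAdeg_", gene_id)

# an me_reaction: growth-rate-affine stoichiometry (a + b*mu per row key)
me_reaction <- function(id, kind, stoich_a = numeric(),
                        stoich_b = numeric(), lb = c(0, 0),
                        ub = c(Inf, 0)) {
  structure(list(id = id, kind = kind, stoich_a = stoich_a,
                 stoich_b = stoich_b, lb = lb, ub = ub),
            class = "acetome_me_reaction")
}

# merge affine coefficients into a named vector
acc <- function(vec, key, val) {
  if (key %in% names(vec)) vec[[key]] <- vec[[key]] + val else vec[[key]] <- val
  vec
}
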