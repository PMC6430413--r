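#' Coupling parameters for ME-model assembly and solution
#'
#' Defaults follow the reference parameterization where stated (enzyme
#' turnover `keff_default` 25/s, unmodeled proteome fraction 0.35) and
#' conventional bacterial values elsewhere (RNA polymerase 55 nt/s,
#' ribosome 12 aa/s, 300 translation initiations per mRNA per hour, mRNA
#' degradation 8.3/h, i.e. a ~5 min half-life). GAM/NGAM default to
#' 45 mmol ATP/gDW and 0.45 mmol ATP/gDW/h. All coefficients are kept in
#' per-hour units.
#'
#' @param keff_default enzyme turnover (1/s) where a reaction does not
#'   override it.
#' @param k_rnap RNA polymerase elongation rate (nt/s).
#' @param k_rib ribosome elongation rate (aa/s).
#' @param k_tl translation initiations per mRNA per hour.
#' @param kdeg_mrna mRNA degradation rate (1/h).
#' @param keff_trna,keff_translocase turnover for the pooled charged-tRNA
#'   species and the translocase (1/s).
#' @param atp_per_aa ATP-equivalents per translated residue (charging +
#'   elongation).
#' @param transloc_aa_per_atp residues per ATP during translocation
#'   (ceiling rule).
#' @param unmodeled_fraction unmodeled proteome mass fraction `f`.
#' @param gam growth-associated maintenance (mmol ATP/gDW).
#' @param ngam non-growth-associated maintenance (mmol ATP/gDW/h).
#' @param mu_min,mu_max bisection bracket (1/h). `mu_min` is the minimum
#'   resolvable growth rate: below ~1e-3/h the growth-coupled usage
#'   coefficients (of order mu/(3600 keff)) fall under the LP
#'   feasibility tolerance, so feasibility verdicts there are
#'   meaningless and infeasibility at `mu_min` is reported as
#'   `no_growth` (mu* = 0).
#' @param mu_tol bisection width tolerance (1/h).
#' @param max_iter bisection iteration cap.
#' @param biomass_demands named mass fractions (g/gDW) drained as fixed
#'   demands per unit growth; the remaining mass is filled by protein
#'   (and machinery RNA).
#' @param membrane_constraint enforce the bilayer capacity constraint.
#' @param membrane_gamma g membrane protein allowed per g lipid.
#' @param lipid_metabolite metabolite id whose demand carries the lipid
#'   mass (cardiolipin in the toy).
#' @param rnap_complex_id,ribosome_complex_id,trna_complex_id,translocase_complex_id
#'   machinery complex ids (NULL disables that coupling).
#' @return object of class `acetome_params`.
#' @export
coupling_params <- function(keff_default = 25, k_rnap = 55, k_rib = 12,
                            k_tl = 300, kdeg_mrna = 8.3,
                            keff_trna = 25, keff_translocase = 25,
                            atp_per_aa = 4, transloc_aa_per_atp = 25,
                            unmodeled_fraction = 0.35,
                            gam = 45, ngam = 0.45,
                            mu_min = 1e-3, mu_max = 2,
                            mu_tol = 1e-6, max_iter = 60L,
                            biomass_demands = c(dna_c = 0.03,
                                                murein_c = 0.04,
                                                clpn_c = 0.08,
                                                other_c = 0.14),
                            membrane_constraint = TRUE,
                            membrane_gamma = 2,
                            lipid_metabolite = "clpn_c",
                            rnap_complex_id = "CPLX_rnap",
                            ribosome_complex_id = "CPLX_ribosome",
                            trna_complex_id = "CPLX_trna",
                            translocase_complex_id = "CPLX_translocase") {
  stopifnot(keff_default > 0, k_rnap > 0, k_rib > 0, k_tl > 0,
            kdeg_mrna >= 0, unmodeled_fraction >= 0,
            unmodeled_fraction < 1, mu_min < mu_max, mu_tol > 0,
            gam >= 0, ngam >= 0)
  structure(list(keff_default = keff_default, k_rnap = k_rnap,
                 k_rib = k_rib, k_tl = k_tl, kdeg_mrna = kdeg_mrna,
                 keff_trna = keff_trna,
                 keff_translocase = keff_translocase,
                 atp_per_aa = atp_per_aa,
                 transloc_aa_per_atp = transloc_aa_per_atp,
                 unmodeled_fraction = unmodeled_fraction,
                 gam = gam, ngam = ngam, mu_min = mu_min,
                 mu_max = mu_max, mu_tol = mu_tol,
                 max_iter = as.integer(max_iter),
                 biomass_demands = biomass_demands,
                 membrane_constraint = isTRUE(membrane_constraint),
                 membrane_gamma = membrane_gamma,
                 lipid_metabolite = lipid_metabolite,
                 rnap_complex_id = rnap_complex_id,
                 ribosome_complex_id = ribosome_complex_id,
                 trna_complex_id = trna_complex_id,
                 translocase_complex_id = translocase_complex_id),
            class = "acetome_params")
}
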