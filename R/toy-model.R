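# ---------------------------------------------------------------------------
# Synthetic toy acetogen: a CO / CO2+H2 / fructose-fed network with
# Wood-Ljungdahl carbon fixation, acetate and ethanol branches, a
# glycerol/cardiolipin byproduct loop, nickel/cobalt/Fe-S-requiring
# enzymes, and a minimal expression machinery. The reference reaction
# table below is the single source of truth; its net balances are
#   4 CO + 2 H2O -> acetate + 2 CO2      (acetate route)
#   6 CO + 3 H2O -> ethanol + 4 CO2      (ethanol route)
# and every reaction is exactly elementally and charge balanced.
#
# Lumped pathway steps (methyl branch, glycolysis halves, anabolism
# lumps) carry pathway-equivalent keff values well below the 25/s
# single-enzyme default: one lumped reaction stands for several enzymes,
# so its effective turnover per unit of catalyst mass is lower. These
# values place the proteome-limited knee of the growth curve inside the
# 0-30 mmol/gDW/h uptake window.
# ---------------------------------------------------------------------------

#' Configuration for the toy acetogen generator
#'
#' @param substrates subset of `c("co", "co2_h2", "fructose")`; uptake
#'   exchanges of unconfigured substrates are closed.
#' @param include_glycerol_loop include cardiolipin synthesis with its
#'   glycerol byproduct, recycle (GLYCDx/DHAK) and secretion (GLYCt)
#'   reactions; when `FALSE` the lipid demand falls on
#'   phosphatidylglycerol directly.
#' @param include_nickel include the nickel exchange and the Hyp-delivered
#'   nickel modifications on CODH4, CODH_ACS and HYD2.
#' @param retain_ni_modifications keep Ni modifications even without the
#'   nickel supply; combined with `include_nickel = FALSE` this is a
#'   contradiction and errors.
#' @param n_filler_genes number of inert protein-coding genes.
#' @param seed integer seed controlling the (deterministic) generated
#'   gene compositions.
#' @return object of class `acetome_toy_config`.
#' @export
toy_config <- function(substrates = c("co", "co2_h2", "fructose"),
                       include_glycerol_loop = TRUE,
                       include_nickel = TRUE,
                       retain_ni_modifications = include_nickel,
                       n_filler_genes = 4L, seed = 1L) {
  substrates <- match.arg(substrates, several.ok = TRUE)
  if (length(substrates) == 0L) stop("at least one substrate is required")
  if (!include_nickel && retain_ni_modifications)
    stop("contradiction: nickel-free model cannot retain Ni modifications")
  structure(list(substrates = substrates,
                 include_glycerol_loop = isTRUE(include_glycerol_loop),
                 include_nickel = isTRUE(include_nickel),
                 n_filler_genes = as.integer(n_filler_genes),
                 seed = as.integer(seed)),
            class = "acetome_toy_config")
}

# real small-molecule formulas (BiGG conventions); pseudo-species are
# derived below so that every reaction closes by construction
toy_base_formulas <- function() {
  list(
    co = list(c(C = 1, O = 1), 0), co2 = list(c(C = 1, O = 2), 0),
    h2 = list(c(H = 2), 0), h2o = list(c(H = 2, O = 1), 0),
    h = list(c(H = 1), 1), pi = list(c(H = 1, O = 4, P = 1), -2),
    ppi = list(c(H = 1, O = 7, P = 2), -3),
    atp = list(c(C = 10, H = 12, N = 5, O = 13, P = 3), -4),
    adp = list(c(C = 10, H = 12, N = 5, O = 10, P = 2), -3),
    amp = list(c(C = 10, H = 12, N = 5, O = 7, P = 1), -2),
    gtp = list(c(C = 10, H = 12, N = 5, O = 14, P = 3), -4),
    gmp = list(c(C = 10, H = 12, N = 5, O = 8, P = 1), -2),
    utp = list(c(C = 9, H = 11, N = 2, O = 15, P = 3), -4),
    ump = list(c(C = 9, H = 11, N = 2, O = 9, P = 1), -2),
    ctp = list(c(C = 9, H = 12, N = 3, O = 14, P = 3), -4),
    cmp = list(c(C = 9, H = 12, N = 3, O = 8, P = 1), -2),
    nad = list(c(C = 21, H = 26, N = 7, O = 14, P = 2), -1),
    nadh = list(c(C = 21, H = 27, N = 7, O = 14, P = 2), -2),
    nadp = list(c(C = 21, H = 25, N = 7, O = 17, P = 3), -3),
    nadph = list(c(C = 21, H = 26, N = 7, O = 17, P = 3), -4),
    coa = list(c(C = 21, H = 32, N = 7, O = 16, P = 3, S = 1), -4),
    accoa = list(c(C = 23, H = 34, N = 7, O = 17, P = 3, S = 1), -4),
    pyr = list(c(C = 3, H = 3, O = 3), -1),
    fru = list(c(C = 6, H = 12, O = 6), 0),
    ac = list(c(C = 2, H = 3, O = 2), -1),
    etoh = list(c(C = 2, H = 6, O = 1), 0),
    acald = list(c(C = 2, H = 4, O = 1), 0),
    glyc = list(c(C = 3, H = 8, O = 3), 0),
    dha = list(c(C = 3, H = 6, O = 3), 0),
    dhap = list(c(C = 3, H = 5, O = 6, P = 1), -2),
    nh4 = list(c(N = 1, H = 4), 1),
    ni2 = list(c(Ni = 1), 2), cobalt2 = list(c(Co = 1), 2),
    mg2 = list(c(Mg = 1), 2), fe2 = list(c(Fe = 1), 2),
    h2s = list(c(H = 2, S = 1), 0),
    `4fe4s` = list(c(Fe = 4, S = 4), 0),
    fd_ox = list(c(Fd = 1), 0), fd_red = list(c(Fd = 1), -2),
    thf = list(c(Thf = 1), 0), mlthf = list(c(Thf = 1, C = 1), 0),
    mthf5 = list(c(Thf = 1, C = 1, H = 2), 0),
    cfesp = list(c(Cfe = 1), 0),
    mecfesp = list(c(Cfe = 1, C = 1, H = 2), 0),
    trd_ox = list(c(Trd = 1), 0), trd_red = list(c(Trd = 1, H = 2), 0))
}

# derived pseudo-species (lipids, biomass constituents): formula :=
# reactant sum minus byproduct sum of the defining reaction
toy_derived_formulas <- function(bf) {
  f <- function(id) bf[[id]][[1]]
  q <- function(id) bf[[id]][[2]]
  der <- list()
  # PGSYN: dhap + 4 accoa + 6 nadph + 2 nadh + 8 h ->
  #        pg + 4 coa + 6 nadp + 2 nad + 3 h2o
  der$pg <- list(formula_add(f("dhap"),
                             formula_scale(f("accoa"), 4),
                             formula_scale(f("nadph"), 6),
                             formula_scale(f("nadh"), 2),
                             formula_scale(f("h"), 8),
                             formula_scale(f("coa"), -4),
                             formula_scale(f("nadp"), -6),
                             formula_scale(f("nad"), -2),
                             formula_scale(f("h2o"), -3)),
                 q("dhap") + 4 * q("accoa") + 6 * q("nadph") +
                   2 * q("nadh") + 8 - 4 * q("coa") - 6 * q("nadp") -
                   2 * q("nad"))
  # CLPNS140: 2 pg -> clpn + glyc
  der$clpn <- list(formula_add(formula_scale(der$pg[[1]], 2),
                               formula_scale(f("glyc"), -1)),
                   2 * der$pg[[2]] - q("glyc"))
  # Electron bookkeeping rule (see the methods vignette): every anabolic
  # lump consumes exactly one NAD(P)H pair per pyruvate and two per
  # acetyl-CoA it draws, so biomass formation is redox-neutral against
  # sugar substrates and strands no reducing power when the WLP sink is
  # unavailable.
  # AASYN: 2 pyr + nh4 + nadh + nadph + atp + h ->
  #        aa + co2 + nad + nadp + adp + pi
  der$aa <- list(formula_add(formula_scale(f("pyr"), 2), f("nh4"),
                             f("nadh"), f("nadph"), f("atp"), f("h"),
                             formula_scale(f("co2"), -1),
                             formula_scale(f("nad"), -1),
                             formula_scale(f("nadp"), -1),
                             formula_scale(f("adp"), -1),
                             formula_scale(f("pi"), -1)),
                 2 * q("pyr") + q("nh4") + q("nadh") + q("nadph") +
                   q("atp") + 1 - q("co2") - q("nad") - q("nadp") -
                   q("adp") - q("pi"))
  # DNASYN: atp + gtp + ctp + utp + 4 trd_red + 4 nad ->
  #         dna + 4 ppi + 4 trd_ox + 4 nadh + 2 h2o + 4 h
  # (the 2'-reduction draws thioredoxin, recharged from NADPH; the
  # abstraction is returned as NADH so the lump stays redox-neutral)
  der$dna <- list(formula_add(f("atp"), f("gtp"), f("ctp"), f("utp"),
                              formula_scale(f("trd_red"), 4),
                              formula_scale(f("nad"), 4),
                              formula_scale(f("ppi"), -4),
                              formula_scale(f("trd_ox"), -4),
                              formula_scale(f("nadh"), -4),
                              formula_scale(f("h2o"), -2),
                              formula_scale(f("h"), -4)),
                  q("atp") + q("gtp") + q("ctp") + q("utp") +
                    4 * q("nad") - 4 * q("ppi") - 4 * q("nadh") - 4)
  # MURSYN: 2 aa + 2 pyr + 2 nadh + 2 atp + nh4 + 3 h ->
  #         murein + 2 nad + 2 adp + 2 pi
  der$murein <- list(formula_add(formula_scale(der$aa[[1]], 2),
                                 formula_scale(f("pyr"), 2),
                                 formula_scale(f("nadh"), 2),
                                 formula_scale(f("atp"), 2), f("nh4"),
                                 formula_scale(f("h"), 3),
                                 formula_scale(f("nad"), -2),
                                 formula_scale(f("adp"), -2),
                                 formula_scale(f("pi"), -2)),
                     2 * der$aa[[2]] + 2 * q("pyr") + 2 * q("nadh") +
                       2 * q("atp") + q("nh4") + 3 - 2 * q("nad") -
                       2 * q("adp") - 2 * q("pi"))
  # OTHSYN: 2 pyr + atp + 2 nadh + 2 h -> other + adp + pi + 2 nad + h2o
  der$other <- list(formula_add(formula_scale(f("pyr"), 2), f("atp"),
                                formula_scale(f("nadh"), 2),
                                formula_scale(f("h"), 2),
                                formula_scale(f("adp"), -1),
                                formula_scale(f("pi"), -1),
                                formula_scale(f("nad"), -2),
                                formula_scale(f("h2o"), -1)),
                    2 * q("pyr") + q("atp") + 2 * q("nadh") + 2 -
                      q("adp") - q("pi") - 2 * q("nad"))
  der
}


# Solve the nucleotide-lump stoichiometry exactly: precursors are the
# (already redox-neutral) amino-acid skeleton, CO2, NH4, Pi, water and
# protons; the 6x6 element/charge system has a unique solution, and
# carrying no redox pair keeps the lump electron-neutral. ATP hydrolysis
# (ring assembly + activation) is added on top as a balanced unit.
toy_nmp_lump <- function(nmp_id, natp) {
  bf <- toy_base_formulas()
  der <- toy_derived_formulas(bf)
  els <- c("C", "H", "N", "O", "P")
  colv <- function(fo, q) c(vapply(els, function(e)
    if (e %in% names(fo)) fo[[e]] else 0, 0), q)
  basis <- cbind(aa = colv(der$aa[[1]], der$aa[[2]]),
                 co2 = colv(bf$co2[[1]], bf$co2[[2]]),
                 nh4 = colv(bf$nh4[[1]], bf$nh4[[2]]),
                 pi = colv(bf$pi[[1]], bf$pi[[2]]),
                 h2o = colv(bf$h2o[[1]], bf$h2o[[2]]),
                 h = colv(bf$h[[1]], bf$h[[2]]))
  tgt <- colv(bf[[nmp_id]][[1]], bf[[nmp_id]][[2]])
  u <- solve(basis, tgt)
  st <- c(-u[["aa"]], -u[["co2"]], -u[["nh4"]], -u[["pi"]] + natp,
          -u[["h2o"]] - natp, -u[["h"]] + natp, -natp, natp, 1)
  names(st) <- c("aa_c", "co2_c", "nh4_c", "pi_c", "h2o_c", "h_c",
                 "atp_c", "adp_c", paste0(nmp_id, "_c"))
  st[abs(st) > 1e-9]
}

#' The immutable toy reaction table
#'
#' Returns the reference stoichiometry of the toy acetogen: every
#' internal reaction, transport and exchange, with bounds, enzyme
#' assignments and pathway-equivalent keff values. The table is constant
#' (configuration only adjusts exchange bounds and drops the glycerol
#' loop or nickel chemistry).
#'
#' @return named list of reaction descriptors
#'   (`stoich`, `lb`, `ub`, `enzyme`, `keff`, `group`).
#' @export
reference_stoichiometry <- function() {
  R <- function(stoich, lb = 0, ub = 1000, enzyme = NULL, keff = 25,
                group = "core")
    list(stoich = unlist(stoich), lb = lb, ub = ub, enzyme = enzyme,
         keff = keff, group = group)
  list(
    # --- Wood-Ljungdahl pathway and energy conservation ---
    CODH4 = R(c(co_c = -1, h2o_c = -1, fd_ox_c = -1, co2_c = 1,
                fd_red_c = 1, h_c = 2), lb = -1000,
              enzyme = "CPLX_codh4", keff = 8, group = "wlp"),
    FDML = R(c(co2_c = -1, fd_red_c = -1, nadh_c = -1, h_c = -3,
               thf_c = -1, mlthf_c = 1, fd_ox_c = 1, nad_c = 1,
               h2o_c = 2), enzyme = "CPLX_fdml", keff = 1, group = "wlp"),
    MTHFR5 = R(c(mlthf_c = -1, nadh_c = -1, h_c = -1, mthf5_c = 1,
                 nad_c = 1), enzyme = "CPLX_mthfr5", keff = 1.5,
               group = "wlp"),
    METR = R(c(mthf5_c = -1, cfesp_c = -1, mecfesp_c = 1, thf_c = 1),
             enzyme = "CPLX_metr", keff = 1, group = "wlp"),
    CODH_ACS = R(c(mecfesp_c = -1, co_c = -1, coa_c = -1, accoa_c = 1,
                   cfesp_c = 1), enzyme = "CPLX_codhacs", keff = 1,
                 group = "wlp"),
    ACKL = R(c(accoa_c = -1, adp_c = -1, pi_c = -1, ac_c = 1, atp_c = 1,
               coa_c = 1), enzyme = "CPLX_ackl", keff = 5),
    AOR_CL = R(c(ac_c = -1, fd_red_c = -1, h_c = -3, acald_c = 1,
                 fd_ox_c = 1, h2o_c = 1), enzyme = "CPLX_aor", keff = 6),
    ALCD2x = R(c(acald_c = -1, nadh_c = -1, h_c = -1, etoh_c = 1,
                 nad_c = 1), enzyme = "CPLX_alcd", keff = 6),
    RNF = R(c(fd_red_c = -1, nad_c = -1, h_c = -3, fd_ox_c = 1,
              nadh_c = 1, h_e = 2), lb = -1000, enzyme = "CPLX_rnf",
            keff = 1.5),
    ATPS4r = R(c(adp_c = -1, pi_c = -1, h_e = -4, atp_c = 1, h2o_c = 1,
                 h_c = 3), lb = -1000, enzyme = "CPLX_atps", keff = 2),
    HYDFDN2r = R(c(h2_c = -2, fd_ox_c = -1, nad_c = -1, fd_red_c = 1,
                   nadh_c = 1, h_c = 3), enzyme = "CPLX_hydfdn",
                 keff = 3),
    HYD2 = R(c(h2_c = -1, fd_ox_c = -1, fd_red_c = 1, h_c = 2),
             lb = -1000, enzyme = "CPLX_hyd2", keff = 3),
    FRNDPR2r = R(c(fd_red_c = -1, nadh_c = -1, nadp_c = -2, h_c = -1,
                   fd_ox_c = 1, nad_c = 1, nadph_c = 2), lb = -1000,
                 enzyme = "CPLX_nfn", keff = 3),
    PFOR = R(c(pyr_c = -1, coa_c = -1, fd_ox_c = -1, accoa_c = 1,
               co2_c = 1, fd_red_c = 1, h_c = 1), lb = -1000,
             enzyme = "CPLX_pfor", keff = 2),
    # --- glycolysis (lumped halves) ---
    FBAL = R(c(fru_c = -1, atp_c = -2, dhap_c = 2, adp_c = 2, h_c = 2),
             enzyme = "CPLX_fbal", keff = 3),
    GAPDL = R(c(dhap_c = -1, nad_c = -1, adp_c = -2, pi_c = -1,
                pyr_c = 1, nadh_c = 1, atp_c = 2, h2o_c = 1),
              lb = -1000, enzyme = "CPLX_gapdl", keff = 2.5),
    # --- lipid branch with glycerol byproduct loop ---
    PGSYN = R(c(dhap_c = -1, accoa_c = -4, nadph_c = -6, nadh_c = -2,
                h_c = -8, pg_c = 1, coa_c = 4, nadp_c = 6, nad_c = 2,
                h2o_c = 3), enzyme = "CPLX_pgsyn", keff = 2,
              group = "lipid"),
    CLPNS140 = R(c(pg_c = -2, clpn_c = 1, glyc_c = 1),
                 enzyme = "CPLX_clpns", keff = 2, group = "lipid"),
    GLYCDx = R(c(glyc_c = -1, nad_c = -1, dha_c = 1, nadh_c = 1,
                 h_c = 1), enzyme = "CPLX_glycdx", keff = 0.5,
               group = "glyloop"),
    DHAK = R(c(dha_c = -1, atp_c = -1, dhap_c = 1, adp_c = 1, h_c = 1),
             enzyme = "CPLX_dhak", keff = 0.5, group = "glyloop"),
    GLYCt = R(c(glyc_c = -1, glyc_e = 1), enzyme = "CPLX_glyct",
              keff = 5, group = "glyloop"),
    # --- anabolism lumps ---
    AASYN = R(c(pyr_c = -2, nh4_c = -1, nadh_c = -1, nadph_c = -1,
                atp_c = -1, h_c = -1, aa_c = 1, co2_c = 1, nad_c = 1,
                nadp_c = 1, adp_c = 1, pi_c = 1),
              enzyme = "CPLX_aasyn", keff = 2),
    # ring assembly and PRPP activation cost ~8 (purine) / ~5
    # (pyrimidine) ATP per nucleotide, keeping RNA realistically more
    # expensive per gram than protein
    AMPSYN = R(toy_nmp_lump("amp", 8)),
    GMPSYN = R(toy_nmp_lump("gmp", 8)),
    UMPSYN = R(toy_nmp_lump("ump", 5)),
    CMPSYN = R(toy_nmp_lump("cmp", 5)),
    ADK = R(c(amp_c = -1, atp_c = -1, adp_c = 2), lb = -1000),
    GMPK2 = R(c(gmp_c = -1, atp_c = -2, gtp_c = 1, adp_c = 2)),
    UMPK2 = R(c(ump_c = -1, atp_c = -2, utp_c = 1, adp_c = 2)),
    CMPK2 = R(c(cmp_c = -1, atp_c = -2, ctp_c = 1, adp_c = 2)),
    DNASYN = R(c(atp_c = -1, gtp_c = -1, ctp_c = -1, utp_c = -1,
                 trd_red_c = -4, nad_c = -4, dna_c = 1, ppi_c = 4,
                 trd_ox_c = 4, nadh_c = 4, h2o_c = 2, h_c = 4)),
    MURSYN = R(c(aa_c = -2, pyr_c = -2, nadh_c = -2, atp_c = -2,
                 nh4_c = -1, h_c = -3, murein_c = 1, nad_c = 2,
                 adp_c = 2, pi_c = 2)),
    OTHSYN = R(c(pyr_c = -2, atp_c = -1, nadh_c = -2, h_c = -2,
                 other_c = 1, adp_c = 1, pi_c = 1, nad_c = 2,
                 h2o_c = 1)),
    TRXR = R(c(trd_ox_c = -1, nadph_c = -1, h_c = -1, trd_red_c = 1,
               nadp_c = 1)),
    PPA = R(c(ppi_c = -1, h2o_c = -1, pi_c = 2, h_c = 1)),
    ATPM = R(c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
             lb = 0.45),
    # --- transports (orphans get the membrane dummy catalyst) ---
    COt = R(c(co_e = -1, co_c = 1), lb = -1000),
    CO2t = R(c(co2_e = -1, co2_c = 1), lb = -1000),
    H2t = R(c(h2_e = -1, h2_c = 1), lb = -1000),
    H2Ot = R(c(h2o_e = -1, h2o_c = 1), lb = -1000),
    FRUt = R(c(fru_e = -1, fru_c = 1)),
    ACt = R(c(ac_c = -1, h_c = -1, ac_e = 1, h_e = 1)),
    ETOHt = R(c(etoh_c = -1, etoh_e = 1)),
    NH4t = R(c(nh4_e = -1, nh4_c = 1)),
    PIt = R(c(pi_e = -1, pi_c = 1)),
    H2St = R(c(h2s_e = -1, h2s_c = 1)),
    NIt = R(c(ni2_e = -1, ni2_c = 1)),
    COBALTt = R(c(cobalt2_e = -1, cobalt2_c = 1)),
    MGt = R(c(mg2_e = -1, mg2_c = 1)),
    FE2t = R(c(fe2_e = -1, fe2_c = 1)),
    # --- exchanges (negative flux = uptake) ---
    EX_co_e = R(c(co_e = -1), lb = -1000, ub = 0),
    EX_co2_e = R(c(co2_e = -1), lb = 0, ub = 1000),
    EX_h2_e = R(c(h2_e = -1), lb = -1000, ub = 0),
    EX_h2o_e = R(c(h2o_e = -1), lb = -1000, ub = 1000),
    EX_h_e = R(c(h_e = -1), lb = -1000, ub = 1000),
    EX_fru_e = R(c(fru_e = -1), lb = -1000, ub = 0),
    EX_ac_e = R(c(ac_e = -1), lb = 0, ub = 1000),
    EX_etoh_e = R(c(etoh_e = -1), lb = 0, ub = 1000),
    EX_glyc_e = R(c(glyc_e = -1), lb = 0, ub = 1000),
    EX_nh4_e = R(c(nh4_e = -1), lb = -1000, ub = 0),
    EX_pi_e = R(c(pi_e = -1), lb = -1000, ub = 0),
    EX_h2s_e = R(c(h2s_e = -1), lb = -1000, ub = 0),
    EX_ni2_e = R(c(ni2_e = -1), lb = -1000, ub = 0),
    EX_cobalt2_e = R(c(cobalt2_e = -1), lb = -1000, ub = 0),
    EX_mg2_e = R(c(mg2_e = -1), lb = -1000, ub = 0),
    EX_fe2_e = R(c(fe2_e = -1), lb = -1000, ub = 0))
}

# gene table: id, protein length (aa), transcript length 3*L+60 nt;
# machinery and RNA genes carry explicit lengths
toy_gene_table <- function() {
  c(codh4 = 550, fdml = 500, mthfr5 = 480, metr = 700, codhacs = 750,
    ackl = 400, aor = 350, alcd = 340, rnf = 450, atps = 500,
    hydfdn = 520, hyd2 = 430, nfn = 460, pfor = 580, fbal = 380,
    gapdl = 390, pgsyn = 300, clpns = 310, glycdx = 370, dhak = 360,
    glyct = 250, aasyn = 420, secy = 440, rnap = 1100, rprot = 250,
    fdx = 90, trx = 110, nifu = 140, iscs = 400, sufbc = 470,
    erpa = 120, hyp = 230)
}

toy_nt_composition <- function(L_nt) {
  base <- L_nt %/% 4
  c(A = base + (L_nt - 4 * base), C = base, G = base, U = base)
}

toy_gene <- function(id, L_aa) {
  gene_spec(id, "mRNA", toy_nt_composition(3 * L_aa + 60),
            protein_aa_composition = c(aa_c = L_aa))
}

#' Generate the toy acetogen model
#'
#' Builds the metabolic network and the expression annex from the
#' reference table according to the configuration, runs the dummy-catalyst
#' assignment and carrier-coupling passes, and pins the unmodeled-protein
#' fraction at the parameter default. Deterministic for a fixed config.
#'
#' @param cfg a [toy_config()].
#' @param params [coupling_params()] used for the unmodeled fraction.
#' @return list with `network`, `annex`, `params` (possibly adjusted,
#'   e.g. lipid target without the glycerol loop) and `config`.
#' @export
build_toy_acetogen <- function(cfg = toy_config(),
                               params = coupling_params()) {
  stopifnot(inherits(cfg, "acetome_toy_config"))
  bf <- toy_base_formulas()
  der <- toy_derived_formulas(bf)

  mets <- list()
  addm <- function(base, comp, formula, charge) {
    id <- paste0(base, "_", comp)
    mets[[id]] <<- metabolite(id, name = base, formula = formula,
                              charge = charge, compartment = comp)
  }
  ext <- c("co", "co2", "h2", "h2o", "h", "fru", "ac", "etoh", "glyc",
           "nh4", "pi", "h2s", "ni2", "cobalt2", "mg2", "fe2")
  for (nm in names(bf)) {
    addm(nm, "c", bf[[nm]][[1]], bf[[nm]][[2]])
    if (nm %in% ext) addm(nm, "e", bf[[nm]][[1]], bf[[nm]][[2]])
  }
  for (nm in names(der)) addm(nm, "c", der[[nm]][[1]], der[[nm]][[2]])

  tbl <- reference_stoichiometry()
  if (!cfg$include_glycerol_loop) {
    tbl <- tbl[setdiff(names(tbl),
                       c("CLPNS140", "GLYCDx", "DHAK", "GLYCt",
                         "EX_glyc_e"))]
    mets <- mets[setdiff(names(mets),
                         c("glyc_c", "glyc_e", "dha_c", "clpn_c"))]
    params$biomass_demands <-
      c(params$biomass_demands[setdiff(names(params$biomass_demands),
                                       "clpn_c")], pg_c = 0.08)
    params$lipid_metabolite <- "pg_c"
  }
  if (!cfg$include_nickel) {
    tbl <- tbl[setdiff(names(tbl), c("NIt", "EX_ni2_e"))]
    mets <- mets[setdiff(names(mets), c("ni2_c", "ni2_e"))]
  }
  # close uptake of unconfigured substrates
  if (!"co" %in% cfg$substrates) tbl$EX_co_e$lb <- 0
  if (!"co2_h2" %in% cfg$substrates) tbl$EX_h2_e$lb <- 0
  else tbl$EX_co2_e$lb <- -1000
  if (!"fructose" %in% cfg$substrates) tbl$EX_fru_e$lb <- 0

  # --- M-side biomass objective consistent with the zero-cost ME limit:
  # protein-dominant macromolecular fill (infinite-chain approximation),
  # same fixed demands, same GAM ---
  mw_aa <- formula_mw(der$aa[[1]])
  mw_h2o <- formula_mw(bf$h2o[[1]])
  fill <- 1 - sum(params$biomass_demands)
  na <- fill / (mw_aa - mw_h2o)
  natp <- params$gam + 4 * na
  bm <- c(aa_c = -na, atp_c = -natp, h2o_c = -(natp - na),
          adp_c = natp, pi_c = natp, h_c = natp)
  for (met in names(params$biomass_demands)) {
    mw <- formula_mw(mets[[met]]$formula)
    bm[[met]] <- -params$biomass_demands[[met]] / mw
  }
  tbl$BIOMASS <- list(stoich = bm, lb = 0, ub = 1000, enzyme = NULL,
                      keff = 25, group = "biomass")

  rxns <- lapply(names(tbl), function(id) {
    r <- tbl[[id]]
    reaction(id, r$stoich, lower_bound = r$lb, upper_bound = r$ub,
             enzyme_complex_id = r$enzyme, keff = r$keff)
  })
  net <- network(unname(mets), rxns, objective_id = "BIOMASS",
                 id = "toy_acetogen")

  # --- expression annex ---
  gt <- toy_gene_table()
  genes <- lapply(names(gt), function(g) toy_gene(g, gt[[g]]))
  names(genes) <- names(gt)
  genes$rrn <- gene_spec("rrn", "rRNA", toy_nt_composition(1500))
  genes$trn <- gene_spec("trn", "tRNA", toy_nt_composition(80))
  set.seed(cfg$seed)
  filler_ids <- character()
  if (cfg$n_filler_genes > 0) {
    filler_len <- 200 + 10 * sample.int(20, cfg$n_filler_genes,
                                        replace = TRUE)
    filler_ids <- sprintf("filler%02d", seq_len(cfg$n_filler_genes))
    for (i in seq_along(filler_ids))
      genes[[filler_ids[i]]] <- toy_gene(filler_ids[i], filler_len[i])
  }

  tus <- list(
    tu_spec("TU_wlp", c("codh4", "fdml", "mthfr5", "metr", "codhacs"),
            "rho_dependent"),
    tu_spec("TU_ack", "ackl", "rho_independent"),
    tu_spec("TU_aor", c("aor", "alcd"), "rho_dependent"),
    tu_spec("TU_energy", c("rnf", "atps"), "rho_dependent"),
    tu_spec("TU_hyd", c("hydfdn", "hyd2", "nfn"), "rho_dependent"),
    tu_spec("TU_glycolysis", c("fbal", "gapdl", "pfor"), "rho_dependent"),
    tu_spec("TU_lipid", c("pgsyn", "clpns"), "rho_independent"),
    tu_spec("TU_glyloop", c("glycdx", "dhak", "glyct"), "rho_dependent"),
    tu_spec("TU_ana", "aasyn", "rho_independent"),
    tu_spec("TU_sec", "secy", "rho_dependent"),
    tu_spec("TU_rnap", "rnap", "rho_dependent"),
    tu_spec("TU_rprot", "rprot", "rho_dependent"),
    tu_spec("TU_carrier", c("fdx", "trx"), "rho_independent"),
    tu_spec("TU_fes", c("nifu", "iscs", "sufbc", "erpa"), "rho_dependent"),
    tu_spec("TU_hyp", "hyp", "rho_dependent"),
    tu_spec("TU_stable", c("rrn", "trn"), "rho_independent",
            stable = TRUE))
  for (fid in filler_ids)
    tus[[length(tus) + 1L]] <- tu_spec(paste0("TU_", fid), fid,
                                       "rho_dependent")

  ni_mod <- function(n) if (cfg$include_nickel)
    list(modification_spec("ni2_c", n, "hyp_nickel")) else list()
  fes <- function(n = 1) list(modification_spec("4fe4s_c", n,
                                                "isc_suf_fes"))
  cxs <- list(
    complex_spec("CPLX_codh4", c(codh4 = 2),
                 c(ni_mod(1), fes(1))),
    complex_spec("CPLX_fdml", c(fdml = 2), fes(1)),
    complex_spec("CPLX_mthfr5", c(mthfr5 = 2)),
    complex_spec("CPLX_metr", c(metr = 2),
                 list(modification_spec("cobalt2_c", 1, "direct"))),
    complex_spec("CPLX_codhacs", c(codhacs = 2),
                 c(ni_mod(2), fes(1))),
    complex_spec("CPLX_ackl", c(ackl = 1)),
    complex_spec("CPLX_aor", c(aor = 1), fes(1)),
    complex_spec("CPLX_alcd", c(alcd = 1)),
    complex_spec("CPLX_rnf", c(rnf = 2), fes(1), membrane = TRUE),
    complex_spec("CPLX_atps", c(atps = 2), membrane = TRUE),
    complex_spec("CPLX_hydfdn", c(hydfdn = 2), fes(1)),
    complex_spec("CPLX_hyd2", c(hyd2 = 1), ni_mod(1)),
    complex_spec("CPLX_nfn", c(nfn = 2), fes(1)),
    complex_spec("CPLX_pfor", c(pfor = 2), fes(1)),
    complex_spec("CPLX_fbal", c(fbal = 1)),
    complex_spec("CPLX_gapdl", c(gapdl = 1)),
    complex_spec("CPLX_pgsyn", c(pgsyn = 1)),
    complex_spec("CPLX_aasyn", c(aasyn = 2)),
    complex_spec("CPLX_rnap", c(rnap = 1)),
    complex_spec("CPLX_ribosome", c(rprot = 20, rrn = 1),
                 list(modification_spec("mg2_c", 1, "direct"))),
    complex_spec("CPLX_trna", c(trn = 1),
                 list(modification_spec("mg2_c", 1, "direct"))),
    complex_spec("CPLX_translocase", c(secy = 1), membrane = TRUE),
    complex_spec("CPLX_fdx", c(fdx = 1), fes(1)),
    complex_spec("CPLX_trx", c(trx = 1)),
    complex_spec("CPLX_iscs", c(iscs = 1)),
    complex_spec("CPLX_sufbc", c(sufbc = 2)),
    complex_spec("CPLX_erpa", c(erpa = 1)),
    complex_spec("CPLX_hyp", c(hyp = 1)))
  if (cfg$include_glycerol_loop) {
    cxs <- c(cxs, list(
      complex_spec("CPLX_clpns", c(clpns = 1)),
      complex_spec("CPLX_glycdx", c(glycdx = 1)),
      complex_spec("CPLX_dhak", c(dhak = 1)),
      complex_spec("CPLX_glyct", c(glyct = 1), membrane = TRUE)))
  }
  dummy_gene <- toy_gene("dummy", 26)
  cxs <- c(cxs, list(
    complex_spec("CPLX_dummy", c(dummy = 1)),
    complex_spec("CPLX_dummy_mem", c(dummy = 1), membrane = TRUE)))

  annex <- expression_annex(
    genes = genes, transcription_units = tus, complexes = cxs,
    translocated_protein_ids = c("rnf", "atps", "glyct", "secy", "dummy"),
    unmodeled_protein_gene = toy_gene("unmod", 250),
    dummy_protein_gene = dummy_gene,
    machinery = list(rnap = "CPLX_rnap", ribosome = "CPLX_ribosome",
                     trna = "CPLX_trna", translocase = "CPLX_translocase",
                     hyp_machinery = "CPLX_hyp", fes_carrier_gene = "nifu",
                     fes_sulfur = "CPLX_iscs", fes_catalyst = "CPLX_sufbc",
                     fes_transfer = "CPLX_erpa", dummy = "CPLX_dummy",
                     dummy_mem = "CPLX_dummy_mem"))
  if (!cfg$include_glycerol_loop)
    annex$translocated_protein_ids <-
      setdiff(annex$translocated_protein_ids, "glyct")
  annex <- add_carrier_coupling(
    net, annex,
    carriers = list(
      ferredoxin = list(complex = "CPLX_fdx", reduced = "fd_red_c",
                        oxidized = "fd_ox_c", keff = 25),
      thioredoxin = list(complex = "CPLX_trx", reduced = "trd_red_c",
                         oxidized = "trd_ox_c", keff = 25)))
  annex <- add_unmodeled_protein(annex, params$unmodeled_fraction)
  withdummy <- add_dummy_catalyst(net, annex)

  list(network = withdummy$network, annex = withdummy$annex,
       params = params, config = cfg)
}
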