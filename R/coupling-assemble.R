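# ME-problem assembly: metabolism + expression with mu-affine
# coefficients. The result is a growth-rate-parametric LP in triplet form
# (every coefficient, bound and right-hand side is a + b*mu).

#' Assemble a metabolism-and-expression problem
#'
#' Combines the metabolic network (minus its biomass objective reaction,
#' which the expression machinery replaces) with the E-matrix reactions
#' of the annex into a single growth-rate-parametric LP:
#'
#' * steady-state rows for every metabolite and macromolecule species;
#' * enzyme-usage coupling: each catalyzed flux consumes its complex at
#'   mu / (3600 * keff) per unit flux (catalyzed reversible reactions are
#'   split into forward/reverse columns);
#' * carrier coupling on reactions reducing ferredoxin/thioredoxin;
#' * the biomass-dilution row fixing total macromolecule mass production
#'   to mu x 1 g/gDW, with fixed demands (DNA, murein, lipid, other) and
#'   the floating protein/RNA fill;
#' * the unmodeled-protein ratio row, mass_unmodeled =
#'   f/(1-f) * mass_modeled;
#' * ATP maintenance with lower bound ngam + gam * mu;
#' * optionally a membrane capacity row limiting membrane-protein mass to
#'   gamma x lipid mass flux.
#'
#' @param net an `acetome_network`.
#' @param annex an `acetome_annex`.
#' @param params [coupling_params()].
#' @return object of class `acetome_me_problem`.
#' @export
assemble <- function(net, annex, params = coupling_params()) {
  validate_network(net)
  validate_annex(annex)
  reg <- species_registry(net, annex, params)

  # cross-validation: every enzyme resolves
  enz <- unlist(lapply(net$reactions, `[[`, "enzyme_complex_id"))
  bad <- setdiff(unique(enz), names(reg))
  if (length(bad))
    stop("unresolved enzyme complex id(s): ", paste(bad, collapse = ", "))

  cols <- list()   # id -> list(kind, lb=c(a,b), ub=c(a,b))
  tri <- vector("list", 8192L); trn <- 0L
  add_col <- function(id, kind, lb = c(0, 0), ub = c(Inf, 0)) {
    if (!is.null(cols[[id]])) stop("duplicate column id '", id, "'")
    cols[[id]] <<- list(kind = kind, lb = lb, ub = ub)
  }
  add_trip <- function(row, col, a = 0, b = 0) {
    trn <<- trn + 1L
    tri[[trn]] <<- list(row = row, col = col, a = a, b = b)
  }

  all_genes <- annex_all_genes(annex)
  stable_ids <- unlist(lapply(Filter(function(tu) tu$stable,
                                     annex$transcription_units),
                              `[[`, "gene_ids"))
  mrna_genes <- Filter(function(g) g$rna_type == "mRNA", all_genes)

  f <- if (!is.null(annex$unmodeled_constraint))
    annex$unmodeled_constraint$f else params$unmodeled_fraction
  ratio <- f / (1 - f)
  unmod_id <- annex$unmodeled_protein_gene$id

  emit <- function(rx) {
    add_col(rx$id, "expression", rx$lb, rx$ub)
    for (k in names(rx$stoich_a)) add_trip(k, rx$id, a = rx$stoich_a[[k]])
    for (k in names(rx$stoich_b)) add_trip(k, rx$id, b = rx$stoich_b[[k]])
  }

  # --- expression reactions ---
  # Macromolecule mass accounting on the biomass-dilution row: protein at
  # translation, mRNA via its dilution coupling at translation, stable
  # RNA at its incorporation into a complex (ribosome, tRNA pool).
  # Surplus RNA of either kind decays back to NMPs without biomass
  # credit, so protein is the unique biomass filler (the composition is
  # regulated, not cost-optimal; see the methods vignette).
  gene_tu <- character()
  for (tu in annex$transcription_units) {
    for (rx in build_transcription(tu, all_genes, params)) emit(rx)
    for (gid in tu$gene_ids) gene_tu[gid] <- tu$id
    for (gid in tu$gene_ids) {
      g <- all_genes[[gid]]
      if (g$rna_type == "mRNA") next
      # stable-RNA surplus decay to NMPs
      id <- paste0("SURP_", gid)
      add_col(id, "excess")
      add_trip(rna_species(gid), id, a = -1)
      add_trip("h2o_c", id, a = -(g$length_nt - 1))
      for (nt in names(g$nt_composition))
        add_trip(.NT_NMP[[nt]], id, a = g$nt_composition[[nt]])
    }
  }
  # unmodeled/dummy genes need transcription too: synthetic single-gene TUs
  for (gid in c(unmod_id, annex$dummy_protein_gene$id)) {
    if (gid %in% names(gene_tu)) next
    tu <- tu_spec(paste0("TU_", gid), gid, "rho_dependent", stable = FALSE)
    for (rx in build_transcription(tu, all_genes, params)) emit(rx)
    gene_tu[gid] <- tu$id
  }
  for (g in mrna_genes) {
    for (rx in build_translation(g, params)) emit(rx)
    sp <- reg[[protein_species(g$id)]]
    add_trip("biomass_dilution", paste0("TL_", g$id), a = sp$mw)
    rk <- reg[[rna_species(g$id)]]
    add_trip("biomass_dilution", paste0("TL_", g$id),
             b = rk$mw / params$k_tl)
    # surplus mRNA decay: operon members share one transcription flux,
    # so each mRNA needs an independent decay route (to NMPs when the
    # degradation machinery exists, else a plain sink)
    surp <- paste0("SURP_", g$id)
    add_col(surp, "excess")
    add_trip(rna_species(g$id), surp, a = -1)
    if (rk$kdeg > 0) add_trip(mrna_used_species(g$id), surp, a = 1)
    # unmodeled-protein mass ratio row
    if (ratio > 0 || g$id == unmod_id)
      add_trip("unmodeled_ratio", paste0("TL_", g$id),
               a = if (g$id == unmod_id) sp$mw else -ratio * sp$mw)
    if (g$id %in% annex$translocated_protein_ids)
      for (rx in build_translocation(g, params)) emit(rx)
  }
  rna_complexes <- character()
  for (cx in annex$complexes) {
    for (rx in build_complex_assembly(cx, annex, params)) emit(rx)
    rna_mass <- 0
    for (gid in names(cx$subunit_stoichiometry)) {
      if (all_genes[[gid]]$rna_type != "mRNA")
        rna_mass <- rna_mass + cx$subunit_stoichiometry[[gid]] *
          reg[[rna_species(gid)]]$mw
    }
    if (rna_mass > 0) {
      add_trip("biomass_dilution", paste0("FORM_", cx$id), a = rna_mass)
      rna_complexes <- c(rna_complexes, cx$id)
    }
  }
  for (rx in build_cofactor_loading(annex, params)) emit(rx)

  # --- excess (overproduction) sinks ---
  # proteins and RNA-free complexes may be overproduced (diluted away);
  # RNA-carrying complexes are sized exactly by catalytic need so that
  # excess RNA cannot masquerade as biomass filler
  for (sp in reg) {
    if (sp$kind == "protein" ||
        (sp$kind == "complex" && !sp$id %in% rna_complexes)) {
      id <- paste0("EXS_", sp$id)
      add_col(id, "excess")
      add_trip(sp$id, id, a = -1)
    }
  }

  # --- metabolic columns ---
  membrane_cx <- names(Filter(function(cx) cx$membrane, annex$complexes))
  if (!is.null(annex$machinery$dummy_mem))
    membrane_cx <- c(membrane_cx, annex$machinery$dummy_mem)
  lipid_demand_col <- paste0("DM_", params$lipid_metabolite)
  rxn_map <- list()

  couple_col <- function(colid, stoich, cxid, keff) {
    add_trip(cxid, colid, b = -1 / (3600 * keff))
    if (params$membrane_constraint && cxid %in% membrane_cx)
      add_trip("membrane_capacity", colid,
               b = reg[[cxid]]$mw / (3600 * keff))
    for (cr in annex$carriers) {
      red <- stoich[names(stoich) == cr$reduced]
      if (length(red) && red[[1]] > 0)
        add_trip(cr$complex, colid, b = -1 / (3600 * cr$keff))
    }
  }

  for (r in net$reactions) {
    if (identical(r$id, net$objective_id)) next
    lb <- c(r$lower_bound, 0); ub <- c(r$upper_bound, 0)
    if (r$id == "ATPM") lb <- c(params$ngam, params$gam)
    if (is.null(r$enzyme_complex_id)) {
      add_col(r$id, "metabolic", lb, ub)
      for (k in names(r$stoichiometry))
        add_trip(k, r$id, a = r$stoichiometry[[k]])
      rxn_map[[r$id]] <- c(fwd = r$id, rev = NA_character_)
    } else {
      cxid <- r$enzyme_complex_id
      if (r$lower_bound < 0) { # split reversible catalyzed reaction
        fid <- r$id; rid <- paste0(r$id, "_REV")
        add_col(fid, "metabolic", c(0, 0), c(max(r$upper_bound, 0), 0))
        add_col(rid, "metabolic", c(0, 0), c(-r$lower_bound, 0))
        for (k in names(r$stoichiometry)) {
          add_trip(k, fid, a = r$stoichiometry[[k]])
          add_trip(k, rid, a = -r$stoichiometry[[k]])
        }
        couple_col(fid, r$stoichiometry, cxid, r$keff)
        couple_col(rid, -r$stoichiometry, cxid, r$keff)
        rxn_map[[r$id]] <- c(fwd = fid, rev = rid)
      } else {
        add_col(r$id, "metabolic", lb, ub)
        for (k in names(r$stoichiometry))
          add_trip(k, r$id, a = r$stoichiometry[[k]])
        couple_col(r$id, r$stoichiometry, cxid, r$keff)
        rxn_map[[r$id]] <- c(fwd = r$id, rev = NA_character_)
      }
    }
  }

  # --- fixed biomass demands ---
  for (met in names(params$biomass_demands)) {
    frac <- params$biomass_demands[[met]]
    if (frac <= 0) next
    if (!met %in% names(net$metabolites))
      stop("biomass demand metabolite '", met, "' missing from the network")
    mw <- formula_mw(net$metabolites[[met]]$formula)
    if (mw <= 0) stop("demand metabolite '", met, "' has zero mass")
    id <- paste0("DM_", met)
    add_col(id, "demand", c(0, frac / mw), c(0, frac / mw))
    add_trip(met, id, a = -1)
    add_trip("biomass_dilution", id, a = mw)
    if (params$membrane_constraint && met == params$lipid_metabolite)
      add_trip("membrane_capacity", id, a = -params$membrane_gamma * mw)
  }

  # --- rows ---
  rows <- list()
  for (mid in names(net$metabolites))
    rows[[mid]] <- list(sense = "=", rhs = c(0, 0), kind = "metabolite")
  for (sp in reg)
    rows[[sp$id]] <- list(sense = "=", rhs = c(0, 0), kind = "species")
  rows[["biomass_dilution"]] <- list(sense = "=", rhs = c(0, 1),
                                     kind = "constraint")
  rows[["unmodeled_ratio"]] <- list(sense = "=", rhs = c(0, 0),
                                    kind = "constraint")
  if (params$membrane_constraint &&
      params$lipid_metabolite %in% names(net$metabolites))
    rows[["membrane_capacity"]] <- list(sense = "<=", rhs = c(0, 0),
                                        kind = "constraint")

  # --- consolidate triplets ---
  tri <- tri[seq_len(trn)]
  rk <- vapply(tri, `[[`, "", "row")
  ck <- vapply(tri, `[[`, "", "col")
  bad_rows <- setdiff(unique(rk), names(rows))
  if (length(bad_rows))
    stop("assembly produced references to unknown row(s): ",
         paste(head(bad_rows, 8), collapse = ", "))
  trip <- data.frame(
    i = match(rk, names(rows)), j = match(ck, names(cols)),
    a = vapply(tri, `[[`, 0, "a"), b = vapply(tri, `[[`, 0, "b"))
  # collapse duplicates
  key <- paste(trip$i, trip$j)
  if (anyDuplicated(key)) {
    trip <- do.call(rbind, lapply(split(trip, key), function(d)
      data.frame(i = d$i[1], j = d$j[1], a = sum(d$a), b = sum(d$b))))
    rownames(trip) <- NULL
  }

  prob <- structure(list(
    col_ids = names(cols),
    col_kind = vapply(cols, `[[`, "", "kind"),
    lb_a = vapply(cols, function(x) x$lb[1], 0),
    lb_b = vapply(cols, function(x) x$lb[2], 0),
    ub_a = vapply(cols, function(x) x$ub[1], 0),
    ub_b = vapply(cols, function(x) x$ub[2], 0),
    row_ids = names(rows),
    row_sense = vapply(rows, `[[`, "", "sense"),
    rhs_a = vapply(rows, function(x) x$rhs[1], 0),
    rhs_b = vapply(rows, function(x) x$rhs[2], 0),
    trip = trip,
    gene_tu = gene_tu,
    rxn_map = rxn_map,
    registry = reg,
    unmodeled_gene = unmod_id,
    mrna_gene_ids = vapply(mrna_genes, `[[`, "", "id"),
    exchange_ids = names(Filter(function(r) is_exchange(r$id),
                                net$reactions)),
    params = params,
    signature = paste0(net$id, ":", length(cols), ":", length(rows))),
    class = "acetome_me_problem")
  validate_me_problem(prob)
  prob
}

validate_me_problem <- function(prob) {
  if (!"biomass_dilution" %in% prob$row_ids)
    stop("ME problem lacks the biomass-dilution row")
  used <- unique(prob$trip$j)
  unused <- setdiff(seq_along(prob$col_ids), used)
  if (length(unused))
    stop("variable(s) appear in no constraint: ",
         paste(head(prob$col_ids[unused], 8), collapse = ", "))
  invisible(prob)
}

#' @export
print.acetome_me_problem <- function(x, ...) {
  cat("<acetome_me_problem> ", length(x$col_ids), " variables, ",
      length(x$row_ids), " rows, ", nrow(x$trip),
      " mu-affine coefficients\n", sep = "")
  invisible(x)
}

#' Override bounds of an ME-problem column
#'
#' @param prob an `acetome_me_problem`.
#' @param id column (reaction) id.
#' @param lo,hi new constant bounds.
#' @return the modified problem.
#' @export
me_set_bounds <- function(prob, id, lo, hi) {
  j <- match(id, prob$col_ids)
  if (is.na(j)) stop("unknown ME-problem column '", id, "'")
  prob$lb_a[j] <- lo; prob$lb_b[j] <- 0
  prob$ub_a[j] <- hi; prob$ub_b[j] <- 0
  prob
}

#' Instantiate the ME problem at a fixed growth rate
#'
#' Evaluates every affine coefficient at `mu`, yielding an ordinary LP.
#' Re-instantiation at the same `mu` is bit-identical.
#'
#' @param prob an `acetome_me_problem`.
#' @param mu growth rate (1/h), >= 0.
#' @return list with `A` (dense), `sense`, `rhs`, `lb`, `ub`.
#' @export
instantiate <- function(prob, mu) {
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0)
    stop("mu must be a single non-negative number")
  nr <- length(prob$row_ids); nc <- length(prob$col_ids)
  A <- matrix(0, nr, nc, dimnames = list(prob$row_ids, prob$col_ids))
  A[cbind(prob$trip$i, prob$trip$j)] <- prob$trip$a + mu * prob$trip$b
  list(A = A,
       sense = unname(ifelse(prob$row_sense == "<=", "<=",
                             ifelse(prob$row_sense == ">=", ">=", "="))),
       rhs = unname(prob$rhs_a + mu * prob$rhs_b),
       lb = unname(prob$lb_a + mu * prob$lb_b),
       ub = unname(prob$ub_a + mu * prob$ub_b))
}
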