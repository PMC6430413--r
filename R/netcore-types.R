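#' @useDynLib acetome, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor pt runif setNames rnorm
#' @importFrom utils head modifyList
"_PACKAGE"

# ---------------------------------------------------------------------------
# Metabolic-network data model (the M side). Plain S3 lists, validated
# eagerly, in the style of small COBRA toolboxes: a network is a list of
# metabolites and reactions plus an objective reaction id.
# ---------------------------------------------------------------------------

#' Create a metabolite
#'
#' @param id metabolite id; must end in `"_c"` (cytosol) or `"_e"`
#'   (extracellular) matching `compartment`.
#' @param name human-readable name.
#' @param formula named integer vector of element counts (e.g.
#'   `c(C = 1, O = 2)`). Pseudo-elements are allowed for macromolecules.
#'   `NULL` marks a metabolite without a formula; [check_balances()] then
#'   reports reactions touching it as unbalanceable.
#' @param charge integer formal charge.
#' @param compartment `"c"` or `"e"`.
#' @return object of class `acetome_metabolite`.
#' @export
metabolite <- function(id, name = id, formula = NULL, charge = 0L,
                       compartment = c("c", "e")) {
  compartment <- match.arg(compartment)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!endsWith(id, paste0("_", compartment)))
    stop("metabolite id '", id, "' does not carry the '_", compartment,
         "' compartment suffix")
  if (!is.null(formula)) {
    formula <- unlist(formula)
    if (is.null(names(formula)) || any(!nzchar(names(formula))))
      stop("formula must be a named vector of element counts")
    if (any(formula < 0)) stop("formula counts must be >= 0")
    formula <- formula[formula != 0]
    storage.mode(formula) <- "double"
  }
  structure(list(id = id, name = name, formula = formula,
                 charge = as.numeric(charge), compartment = compartment),
            class = "acetome_metabolite")
}

#' Create a metabolic reaction
#'
#' Stoichiometry uses the COBRA sign convention: negative coefficients are
#' consumed, positive produced. Exchange reactions (ids starting `EX_`)
#' touch only extracellular metabolites; uptake is a negative flux, so
#' uptake limits are set as lower bounds.
#'
#' @param id reaction id.
#' @param stoichiometry named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound flux bounds in mmol/gDW/h.
#' @param enzyme_complex_id optional id of the catalyzing complex.
#' @param keff effective turnover rate in 1/s used for the enzyme-usage
#'   coupling (default 25, the acetogen-average turnover the ME model
#'   adopts for all enzymes).
#' @param name human-readable name.
#' @return object of class `acetome_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0,
                     upper_bound = 1000, enzyme_complex_id = NULL,
                     keff = 25, name = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoichiometry <- unlist(stoichiometry)
  if (length(stoichiometry) == 0L)
    stop("reaction '", id, "' has empty stoichiometry")
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("stoichiometry must be named by metabolite id")
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound > upper_bound")
  if (!is.null(enzyme_complex_id) && (!is.numeric(keff) || keff <= 0))
    stop("reaction '", id, "': keff must be > 0 when an enzyme is assigned")
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 enzyme_complex_id = enzyme_complex_id,
                 keff = as.numeric(keff)),
            class = "acetome_reaction")
}

#' Assemble and validate a metabolic network
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param objective_id id of the objective (biomass) reaction.
#' @param id model id string.
#' @return object of class `acetome_network`.
#' @export
network <- function(metabolites, reactions, objective_id, id = "model") {
  met_ids <- vapply(metabolites, `[[`, "", "id")
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  net <- structure(list(id = id, metabolites = metabolites,
                        reactions = reactions,
                        objective_id = objective_id),
                   class = "acetome_network")
  validate_network(net)
  net
}

#' Validate network invariants
#'
#' Checks that every stoichiometry key resolves to a metabolite, that the
#' objective id resolves to a reaction, and that exchange reactions touch
#' only extracellular metabolites.
#'
#' @param net an `acetome_network`.
#' @return the network, invisibly; errors on violation.
#' @export
validate_network <- function(net) {
  met_ids <- names(net$metabolites)
  dangling <- character()
  for (r in net$reactions) {
    miss <- setdiff(names(r$stoichiometry), met_ids)
    if (length(miss)) dangling <- c(dangling, paste0(r$id, ": ", miss))
    if (is_exchange(r$id)) {
      comps <- vapply(net$metabolites[names(r$stoichiometry)],
                      `[[`, "", "compartment")
      if (any(comps != "e"))
        stop("exchange reaction '", r$id,
             "' touches non-extracellular metabolites")
    }
  }
  if (length(dangling))
    stop("unknown metabolite reference(s): ",
         paste(dangling, collapse = "; "))
  if (!net$objective_id %in% names(net$reactions))
    stop("objective_id '", net$objective_id, "' is not a reaction")
  invisible(net)
}

# reaction-id classification conventions (documented in the vignette):
# EX_* exchange, DM_* demand, ids containing BIOMASS or named ATPM are
# pseudo-reactions exempt from elemental balancing
is_exchange <- function(id) startsWith(id, "EX_")
is_demand <- function(id) startsWith(id, "DM_")
is_pseudo <- function(id) {
  is_exchange(id) | is_demand(id) | grepl("BIOMASS", id, fixed = TRUE) |
    id == "ATPM"
}

#' @export
print.acetome_network <- function(x, ...) {
  cat("<acetome_network> ", x$id, ": ", length(x$metabolites),
      " metabolites, ", length(x$reactions), " reactions, objective '",
      x$objective_id, "'\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' @param net an `acetome_network`.
#' @return dense matrix, metabolites x reactions.
#' @export
stoichiometric_matrix <- function(net) {
  S <- matrix(0, length(net$metabolites), length(net$reactions),
              dimnames = list(names(net$metabolites), names(net$reactions)))
  for (r in net$reactions) S[names(r$stoichiometry), r$id] <- r$stoichiometry
  S
}
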