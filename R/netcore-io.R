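# Model file I/O. cobra-json is the canonical (read/write, bit-exact
# round-trip) format; SBML L3 FBC is a read-only subset covering species,
# reactions, bounds and the active objective.

format_formula <- function(formula) {
  if (is.null(formula) || length(formula) == 0L) return(NULL)
  els <- sort(names(formula))
  paste0(vapply(els, function(el) {
    k <- formula[[el]]
    if (abs(k - round(k)) < 1e-9) k <- as.integer(round(k))
    paste0(el, if (identical(k, 1L)) "" else format(k, scientific = FALSE))
  }, ""), collapse = "")
}

parse_formula <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(s)) return(NULL)
  m <- gregexpr("([A-Z][a-z]*)([0-9]*\\.?[0-9]*)", s)[[1]]
  parts <- regmatches(s, gregexpr("([A-Z][a-z]*)([0-9]*\\.?[0-9]*)", s))[[1]]
  if (sum(nchar(parts)) != nchar(s))
    stop("cannot parse chemical formula '", s, "'")
  out <- numeric()
  for (p in parts) {
    el <- sub("^([A-Z][a-z]*).*$", "\\1", p)
    num <- sub("^[A-Z][a-z]*", "", p)
    out[el] <- (if (el %in% names(out)) out[[el]] else 0) +
      (if (nzchar(num)) as.numeric(num) else 1)
  }
  out
}

#' Write a network as COBRA-style JSON
#'
#' Output is deterministic: two writes of the same network are
#' byte-identical, and `read_network()` of the output reproduces the
#' network field-by-field.
#'
#' @param net an `acetome_network` (validated before writing).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  validate_network(net)
  if (length(net$reactions) == 0L) stop("refusing to write an empty network")
  mets <- lapply(net$metabolites, function(m) {
    o <- list(id = m$id, name = m$name, compartment = m$compartment,
              charge = m$charge)
    f <- format_formula(m$formula)
    if (!is.null(f)) o$formula <- f
    o
  })
  rxns <- lapply(net$reactions, function(r) {
    o <- list(id = r$id, name = r$name,
              metabolites = as.list(r$stoichiometry),
              lower_bound = r$lower_bound, upper_bound = r$upper_bound,
              gene_reaction_rule = "",
              objective_coefficient =
                if (identical(r$id, net$objective_id)) 1 else 0)
    if (!is.null(r$enzyme_complex_id)) {
      o$annotation <- list(acetome_enzyme = r$enzyme_complex_id,
                           acetome_keff = r$keff)
    }
    o
  })
  doc <- list(id = net$id, version = "1",
              metabolites = unname(mets), reactions = unname(rxns),
              genes = list())
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n")
  invisible(path)
}

#' Read a metabolic network model
#'
#' @param path model file.
#' @param format `"cobra-json"` (canonical) or `"sbml-subset"` (read-only
#'   SBML Level 3 with the FBC package: species, reactions, flux bounds,
#'   active objective).
#' @return validated `acetome_network`.
#' @export
read_network <- function(path, format = c("cobra-json", "sbml-subset")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "cobra-json") read_network_json(path) else read_network_sbml(path)
}

read_network_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cobra-json parse failure in '", path, "': ",
                             conditionMessage(e)))
  for (f in c("metabolites", "reactions"))
    if (is.null(doc[[f]])) stop("cobra-json missing '", f, "' array")
  mets <- lapply(doc$metabolites, function(m) {
    metabolite(id = m$id, name = if (is.null(m$name)) m$id else m$name,
               formula = parse_formula(m$formula),
               charge = if (is.null(m$charge)) 0 else m$charge,
               compartment = m$compartment)
  })
  objective_id <- NULL
  rxns <- lapply(doc$reactions, function(r) {
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0)
      objective_id <<- r$id
    enz <- r$annotation$acetome_enzyme
    keff <- r$annotation$acetome_keff
    reaction(id = r$id, name = if (is.null(r$name)) r$id else r$name,
             stoichiometry = unlist(r$metabolites),
             lower_bound = r$lower_bound, upper_bound = r$upper_bound,
             enzyme_complex_id = enz,
             keff = if (is.null(keff)) 25 else keff)
  })
  if (is.null(objective_id))
    stop("cobra-json model has no reaction with objective_coefficient != 0")
  network(mets, rxns, objective_id,
          id = if (is.null(doc$id)) "model" else doc$id)
}

strip_sbml_prefix <- function(id, prefix) sub(paste0("^", prefix), "", id)

read_network_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  # flux-bound parameters
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- lapply(sp, function(x) {
    id <- strip_sbml_prefix(xml2::xml_attr(x, "id"), "M_")
    fchg <- xml2::xml_attr(x, "fbc:charge", ns = ns)
    form <- xml2::xml_attr(x, "fbc:chemicalFormula", ns = ns)
    metabolite(id = id, name = xml2::xml_attr(x, "name"),
               formula = parse_formula(form),
               charge = if (!is.na(fchg)) as.numeric(fchg) else 0,
               compartment = xml2::xml_attr(x, "compartment"))
  })
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx, function(x) {
    id <- strip_sbml_prefix(xml2::xml_attr(x, "id"), "R_")
    stoich <- numeric()
    for (sr in xml2::xml_find_all(x, "./s:listOfReactants/s:speciesReference", ns)) {
      met <- strip_sbml_prefix(xml2::xml_attr(sr, "species"), "M_")
      stoich[met] <- (if (met %in% names(stoich)) stoich[[met]] else 0) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(x, "./s:listOfProducts/s:speciesReference", ns)) {
      met <- strip_sbml_prefix(xml2::xml_attr(sr, "species"), "M_")
      stoich[met] <- (if (met %in% names(stoich)) stoich[[met]] else 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lbp <- xml2::xml_attr(x, "fbc:lowerFluxBound", ns = ns)
    ubp <- xml2::xml_attr(x, "fbc:upperFluxBound", ns = ns)
    reaction(id = id, name = xml2::xml_attr(x, "name"),
             stoichiometry = stoich,
             lower_bound = if (!is.na(lbp)) parval[[lbp]] else -1000,
             upper_bound = if (!is.na(ubp)) parval[[ubp]] else 1000)
  })
  objref <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (inherits(objref, "xml_missing"))
    stop("SBML model has no FBC objective")
  objective_id <- strip_sbml_prefix(
    xml2::xml_attr(objref, "fbc:reaction", ns = ns), "R_")
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id")
  network(mets, rxns, objective_id, id = if (is.na(mid)) "model" else mid)
}
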