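# Growth maximization: bisection over LP feasibility in mu.

#' Test feasibility of the ME problem at a growth rate
#'
#' @param prob an `acetome_me_problem`.
#' @param mu growth rate (1/h).
#' @return `TRUE`/`FALSE`. Solver failures are raised, never coerced to
#'   `FALSE`.
#' @export
feasible <- function(prob, mu) {
  lp <- instantiate(prob, mu)
  res <- lp_solve(numeric(ncol(lp$A)), lp$A, lp$sense, lp$rhs,
                  lb = lp$lb, ub = lp$ub, feasibility_only = TRUE)
  if (!res$status %in% c("optimal", "infeasible"))
    stop("LP solver returned '", res$status, "' at mu = ", mu)
  res$status == "optimal"
}

#' Maximize growth rate by bisection over LP feasibility
#'
#' Bisects feasibility of the growth-rate-parametric LP on
#' `[mu_min, mu_max]` down to width `mu_tol`. The predicate is
#' down-closed in mu (checked: a non-monotone observation raises an
#' error). The final solve at the optimum minimizes total expression flux
#' to select a parsimonious representative among alternate optima.
#'
#' @param prob an `acetome_me_problem`.
#' @param params [coupling_params()] supplying `mu_min`, `mu_max`,
#'   `mu_tol`, `max_iter`; defaults to the problem's own.
#' @return object of class `acetome_me_solution` with fields `status`
#'   (`"optimal"` or `"no_growth"`), `mu_star`, `fluxes` (net flux per
#'   original metabolic reaction), `expression_fluxes` (per-gene
#'   transcription flux), `translation_fluxes`, `complex_usage`
#'   (formation fluxes), `proteome_fractions`, `secretion` (positive
#'   exchange fluxes), `iterations`.
#' @export
maximize_growth <- function(prob, params = prob$params) {
  lo <- params$mu_min; hi <- params$mu_max
  if (!feasible(prob, lo)) {
    return(structure(list(status = "no_growth", mu_star = 0,
                          fluxes = numeric(), expression_fluxes = numeric(),
                          translation_fluxes = numeric(),
                          complex_usage = numeric(),
                          proteome_fractions = numeric(),
                          secretion = numeric(), iterations = 0L,
                          signature = prob$signature),
                     class = "acetome_me_solution"))
  }
  if (feasible(prob, hi))
    stop("mu_max = ", hi, " is still feasible: raise mu_max")
  it <- 0L
  while (hi - lo > params$mu_tol && it < params$max_iter) {
    mid <- (lo + hi) / 2
    if (feasible(prob, mid)) {
      if (mid < lo) stop("non-monotone feasibility observed in bisection")
      lo <- mid
    } else {
      if (mid > hi) stop("non-monotone feasibility observed in bisection")
      hi <- mid
    }
    it <- it + 1L
  }
  sol <- me_extract(prob, lo)
  sol$iterations <- it
  sol
}

# solve at fixed mu with the parsimonious objective and build the
# solution object. mu sits within mu_tol of the feasibility boundary, so
# the full optimizing solve can tip infeasible where the feasibility
# probe succeeded; back off by a few tolerance steps in that case.
me_extract <- function(prob, mu, mu_tol = prob$params$mu_tol) {
  obj <- as.numeric(prob$col_kind %in% c("expression", "excess"))
  res <- NULL
  for (off in c(0, 1, 10, 100, 1000) * mu_tol) {
    mu_try <- max(mu - off, 0)
    lp <- instantiate(prob, mu_try)
    res <- lp_solve(obj, lp$A, lp$sense, lp$rhs, lb = lp$lb, ub = lp$ub,
                    maximize = FALSE)
    if (res$status == "optimal") { mu <- mu_try; break }
    # last resort: accept a clean basic feasible point at this growth rate
    res2 <- lp_solve(numeric(ncol(lp$A)), lp$A, lp$sense, lp$rhs,
                     lb = lp$lb, ub = lp$ub, feasibility_only = TRUE)
    if (res2$status == "optimal" && !is.null(res2$viol) &&
        res2$viol <= 1e-4) { res <- res2; mu <- mu_try; break }
  }
  if (res$status != "optimal")
    stop("final LP at mu* unexpectedly ", res$status)
  x <- setNames(res$x, prob$col_ids)
  # net flux per original metabolic reaction
  fluxes <- vapply(prob$rxn_map, function(mp) {
    v <- x[[mp[["fwd"]]]]
    if (!is.na(mp[["rev"]])) v <- v - x[[mp[["rev"]]]]
    v
  }, 0)
  tx <- x[paste0("TX_", prob$gene_tu)]
  names(tx) <- names(prob$gene_tu)
  tl <- x[paste0("TL_", prob$mrna_gene_ids)]
  names(tl) <- prob$mrna_gene_ids
  form_ids <- grep("^FORM_", prob$col_ids, value = TRUE)
  usage <- setNames(x[form_ids], sub("^FORM_", "", form_ids))
  secr <- fluxes[intersect(names(fluxes), prob$exchange_ids)]
  secr <- secr[secr > 1e-9]
  sol <- structure(list(status = "optimal", mu_star = mu, fluxes = fluxes,
                        expression_fluxes = tx, translation_fluxes = tl,
                        complex_usage = usage,
                        proteome_fractions = numeric(),
                        secretion = secr, iterations = NA_integer_,
                        signature = prob$signature,
                        protein_mw = vapply(
                          prob$mrna_gene_ids,
                          function(g) prob$registry[[protein_species(g)]]$mw,
                          0)),
                   class = "acetome_me_solution")
  sol$proteome_fractions <- proteome_fractions(sol)
  sol
}

#' @export
print.acetome_me_solution <- function(x, ...) {
  cat("<acetome_me_solution> status=", x$status,
      " mu*=", format(x$mu_star, digits = 7), " /h", sep = "")
  if (length(x$secretion))
    cat("; secretion:",
        paste(names(x$secretion),
              format(x$secretion, digits = 4), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Proteome mass fractions of a solution
#'
#' Protein is not degraded, so synthesis fluxes are proportional to
#' steady-state amounts and mass fractions reduce to
#' mw_i * v_tl_i / sum_j mw_j * v_tl_j (all protein species, including
#' the unmodeled stand-in).
#'
#' @param sol an `acetome_me_solution`.
#' @param annex unused; accepted for interface symmetry.
#' @return named fractions summing to 1.
#' @export
proteome_fractions <- function(sol, annex = NULL) {
  if (sol$status != "optimal") stop("solution is not optimal")
  mass <- sol$protein_mw * sol$translation_fluxes[names(sol$protein_mw)]
  tot <- sum(mass)
  if (tot <= 0) stop("zero total protein synthesis: fractions undefined")
  mass / tot
}

#' Relative protein activity between two solutions
#'
#' Activity of a reaction under limitation is its flux relative to an
#' unlimited reference solved on the same problem:
#' `v_limited / v_reference`. Returns 0 when both fluxes are zero; a
#' limited flux exceeding a zero reference is an error.
#'
#' @param sol_limited,sol_reference solutions of the same ME problem
#'   differing only in (metal) bounds.
#' @param reaction_id metabolic reaction id.
#' @param tol flux magnitude treated as zero.
#' @return scalar activity.
#' @export
protein_activity <- function(sol_limited, sol_reference, reaction_id,
                             tol = 1e-9) {
  if (!identical(sol_limited$signature, sol_reference$signature))
    stop("solutions come from different ME problems")
  v_ref <- if (sol_reference$status == "optimal")
    sol_reference$fluxes[[reaction_id]] else 0
  v_lim <- if (sol_limited$status == "optimal" &&
               reaction_id %in% names(sol_limited$fluxes))
    sol_limited$fluxes[[reaction_id]] else 0
  if (abs(v_ref) < tol) {
    if (abs(v_lim) < tol) return(0)
    stop("reference flux is zero but limited flux is ", v_lim)
  }
  v_lim / v_ref
}
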