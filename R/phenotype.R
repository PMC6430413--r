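# Phenotype analyses: substrate-uptake sweeps, overflow onset, yield
# ratios, metal-limitation sweeps.

#' Sweep a substrate uptake bound
#'
#' For each grid value the named exchange's uptake is capped at that
#' magnitude (lower bound -g) and growth is maximized. Solver failures
#' are recorded as failed points; the sweep continues.
#'
#' @param bundle model bundle `list(network, annex, params)` as returned
#'   by [build_toy_acetogen()].
#' @param exchange_id exchange reaction to sweep.
#' @param grid increasing vector of uptake magnitudes (>= 0).
#' @param params [coupling_params()]; defaults to the bundle's.
#' @param prob optionally a pre-assembled `acetome_me_problem`.
#' @return object of class `acetome_sweep`: `swept_id`, `grid`, `status`,
#'   `mu_star`, `exchange_fluxes` (exchanges x points),
#'   `expression_fluxes` (genes x points), `secretion` (per point, list).
#' @export
uptake_sweep <- function(bundle, exchange_id, grid,
                         params = bundle$params, prob = NULL,
                         keep_solutions = FALSE) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  if (any(grid < 0)) stop("grid values are uptake magnitudes, >= 0")
  if (is.null(prob)) prob <- assemble(bundle$network, bundle$annex, params)
  if (!exchange_id %in% prob$col_ids)
    stop("unknown exchange '", exchange_id, "'")
  npt <- length(grid)
  mu <- rep(NA_real_, npt)
  status <- character(npt)
  ex_ids <- prob$exchange_ids
  exch <- matrix(NA_real_, length(ex_ids), npt,
                 dimnames = list(ex_ids, NULL))
  genes <- names(prob$gene_tu)
  expr <- matrix(NA_real_, length(genes), npt,
                 dimnames = list(genes, NULL))
  secretion <- vector("list", npt)
  solutions <- vector("list", npt)
  for (i in seq_len(npt)) {
    p_i <- me_set_bounds(prob, exchange_id, -grid[i], 0)
    sol <- tryCatch(maximize_growth(p_i, params),
                    error = function(e) e)
    if (inherits(sol, "error")) {
      status[i] <- paste0("failed: ", conditionMessage(sol))
      next
    }
    if (keep_solutions) solutions[[i]] <- sol
    status[i] <- sol$status
    mu[i] <- sol$mu_star
    if (sol$status == "optimal") {
      exch[, i] <- sol$fluxes[ex_ids]
      expr[, i] <- sol$expression_fluxes[genes]
      secretion[[i]] <- sol$secretion
    } else {
      mu[i] <- 0
      secretion[[i]] <- numeric()
    }
  }
  out <- list(swept_id = exchange_id, grid = grid, status = status,
              mu_star = mu, exchange_fluxes = exch,
              expression_fluxes = expr, secretion = secretion)
  if (keep_solutions) out$solutions <- solutions
  structure(out, class = "acetome_sweep")
}

#' @export
print.acetome_sweep <- function(x, ...) {
  cat("<acetome_sweep> ", x$swept_id, ": ", length(x$grid),
      " points, mu* in [", format(min(x$mu_star, na.rm = TRUE), digits = 4),
      ", ", format(max(x$mu_star, na.rm = TRUE), digits = 4), "]\n",
      sep = "")
  invisible(x)
}

secretion_at <- function(sweep, product_id) {
  if (!product_id %in% rownames(sweep$exchange_fluxes))
    stop("unknown product exchange '", product_id, "'")
  v <- sweep$exchange_fluxes[product_id, ]
  v[is.na(v)] <- 0
  v
}

#' Overflow onset of a secreted product along a sweep
#'
#' @param sweep an `acetome_sweep`.
#' @param product_id product exchange id.
#' @param threshold secretion level distinguishing real secretion from LP
#'   noise (1e-6 mmol/gDW/h).
#' @return smallest grid value with secretion above threshold, or `NA`
#'   if the product is never secreted. If secretion is nonzero before
#'   onset or decreases by more than the threshold after onset, the
#'   result carries attribute `flagged = TRUE` and a warning is issued
#'   (never hidden).
#' @export
overflow_onset <- function(sweep, product_id, threshold = 1e-6) {
  v <- secretion_at(sweep, product_id)
  idx <- which(v > threshold)
  if (length(idx) == 0L) return(NA_real_)
  onset <- sweep$grid[idx[1]]
  flagged <- FALSE
  if (idx[1] > 1 && any(v[seq_len(idx[1] - 1)] > threshold)) flagged <- TRUE
  after <- v[idx[1]:length(v)]
  if (any(diff(after) < -10 * threshold - 1e-9 * max(abs(after))))
    flagged <- TRUE
  if (flagged) {
    warning("overflow structure violated for ", product_id,
            ": secretion before onset or decreasing after onset")
    attr(onset, "flagged") <- TRUE
  }
  onset
}

#' Secretion-rate ratio of two products
#'
#' @param sol an `acetome_me_solution`.
#' @param num_id,den_id exchange ids (numerator, denominator).
#' @return ratio of secretion fluxes, or `NA` (undefined marker) when
#'   the denominator is below 1e-9.
#' @export
secretion_ratio <- function(sol, num_id, den_id) {
  getf <- function(id) {
    if (!id %in% names(sol$fluxes)) stop("unknown exchange '", id, "'")
    max(sol$fluxes[[id]], 0)
  }
  den <- getf(den_id)
  if (den <= 1e-9) return(NA_real_)
  getf(num_id) / den
}

#' Sweep a metal uptake cap
#'
#' Solves the uncapped problem as reference, then caps the metal uptake
#' at each grid value, recording growth, secretion, and protein activity
#' (flux relative to reference) for every reaction whose enzyme carries a
#' modification consuming the metal.
#'
#' @param bundle model bundle (see [uptake_sweep()]).
#' @param metal_exchange_id e.g. `"EX_ni2_e"`.
#' @param grid increasing uptake caps (absolute magnitudes; use
#'   fractions of the reference uptake for a relative axis).
#' @param params [coupling_params()].
#' @param prob optional pre-assembled problem.
#' @return `acetome_sweep` with extra fields `activity` (metal-dependent
#'   reactions x points), `reference` (the uncapped solution) and
#'   `reference_uptake` (its metal uptake magnitude).
#' @export
metal_sweep <- function(bundle, metal_exchange_id, grid,
                        params = bundle$params, prob = NULL) {
  if (is.null(prob)) prob <- assemble(bundle$network, bundle$annex, params)
  metal_met <- sub("^EX_", "", metal_exchange_id)
  dep_rxns <- metal_dependent_reactions(bundle, sub("_e$", "_c", metal_met))
  if (length(dep_rxns) == 0L)
    warning("metal '", metal_met, "' is consumed by no modification; ",
            "the sweep will be flat")
  ref <- maximize_growth(prob, params)
  ref_uptake <- if (ref$status == "optimal")
    abs(min(ref$fluxes[[metal_exchange_id]], 0)) else 0
  sweep <- uptake_sweep(bundle, metal_exchange_id, grid, params,
                        prob = prob, keep_solutions = TRUE)
  act <- matrix(NA_real_, length(dep_rxns), length(grid),
                dimnames = list(dep_rxns, NULL))
  for (i in seq_along(grid)) {
    sol <- sweep$solutions[[i]]
    if (is.null(sol)) next
    for (r in dep_rxns)
      act[r, i] <- tryCatch(protein_activity(sol, ref, r),
                            error = function(e) NA_real_)
  }
  sweep$activity <- act
  sweep$reference <- ref
  sweep$reference_uptake <- ref_uptake
  sweep
}

# reactions catalyzed by complexes carrying a modification that consumes
# the given cytosolic metal
metal_dependent_reactions <- function(bundle, metal_met_c) {
  dep_cx <- vapply(bundle$annex$complexes, function(cx)
    any(vapply(cx$modifications, function(m)
      identical(m$cofactor_metabolite_id, metal_met_c), TRUE)), TRUE)
  dep_cx <- names(dep_cx)[dep_cx]
  hits <- vapply(bundle$network$reactions, function(r)
    !is.null(r$enzyme_complex_id) && r$enzyme_complex_id %in% dep_cx, TRUE)
  names(hits)[hits]
}

#' Aggregate expression fluxes by functional category
#'
#' Category value = sum over member genes of flux x molecular weight
#' (mass-weighted transcription flux). Unmapped genes fall into
#' `"uncategorized"`.
#'
#' @param expression_fluxes named per-gene fluxes (>= 0).
#' @param categories named character vector, gene -> category.
#' @param weights named numeric, gene -> molecular weight (g/mmol).
#' @param normalize `"none"` (default), `"max"` (scale by the largest
#'   category), or `"sum"` (fractions of the total).
#' @return named numeric, category -> value.
#' @export
aggregate_by_category <- function(expression_fluxes, categories, weights,
                                  normalize = c("none", "max", "sum")) {
  normalize <- match.arg(normalize)
  if (any(expression_fluxes < 0, na.rm = TRUE))
    stop("negative expression flux")
  genes <- names(expression_fluxes)
  cat_of <- categories[genes]
  cat_of[is.na(cat_of)] <- "uncategorized"
  w <- weights[genes]
  if (anyNA(w)) stop("missing weight for gene(s): ",
                     paste(genes[is.na(w)], collapse = ", "))
  out <- tapply(expression_fluxes * w, cat_of, sum)
  out <- setNames(as.numeric(out), names(out))
  switch(normalize,
         none = out,
         max = if (max(out) > 0) out / max(out) else out,
         sum = if (sum(out) > 0) out / sum(out) else out)
}
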