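#' Flux balance analysis
#'
#' Maximizes the objective reaction subject to steady state (`S v = 0`)
#' and flux bounds. A network with all exchanges closed returns
#' `status = "optimal"` with objective 0 (zero growth is feasible when
#' there is no substrate), not infeasible.
#'
#' @param net an `acetome_network`.
#' @param extra_bounds named list of `c(lo, hi)` overrides per reaction id;
#'   must lie within the declared bounds.
#' @param objective_id reaction to maximize; defaults to the network's
#'   objective.
#' @return object of class `acetome_flux_solution`: list with `status`
#'   (`"optimal"`, `"infeasible"`, `"unbounded"`), `objective_value`, and
#'   `fluxes` (named vector; empty when infeasible).
#' @export
solve_fba <- function(net, extra_bounds = list(),
                      objective_id = net$objective_id) {
  validate_network(net)
  if (!objective_id %in% names(net$reactions))
    stop("objective '", objective_id, "' is not a reaction")
  S <- stoichiometric_matrix(net)
  lb <- vapply(net$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(net$reactions, `[[`, 0, "upper_bound")
  for (id in names(extra_bounds)) {
    if (!id %in% colnames(S)) stop("extra_bounds: unknown reaction '", id, "'")
    bo <- extra_bounds[[id]]
    if (length(bo) != 2L) stop("extra_bounds entries must be c(lo, hi)")
    if (bo[1] < lb[[id]] - 1e-9 || bo[2] > ub[[id]] + 1e-9)
      stop("extra_bounds for '", id, "' exceed declared bounds")
    lb[[id]] <- bo[1]; ub[[id]] <- bo[2]
  }
  obj <- setNames(numeric(ncol(S)), colnames(S))
  obj[[objective_id]] <- 1
  res <- lp_solve(obj, S, rep("=", nrow(S)), numeric(nrow(S)),
                  lb = lb, ub = ub, maximize = TRUE)
  status <- res$status
  fluxes <- if (status == "optimal") setNames(res$x, colnames(S)) else numeric()
  structure(list(status = status,
                 objective_value = if (status == "optimal") res$objval else NA_real_,
                 fluxes = fluxes),
            class = "acetome_flux_solution")
}

#' @export
print.acetome_flux_solution <- function(x, ...) {
  cat("<acetome_flux_solution> status=", x$status,
      " objective=", format(x$objective_value, digits = 6), "\n", sep = "")
  invisible(x)
}
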