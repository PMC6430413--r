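# Elemental and charge bookkeeping.

# standard atomic masses (g/mol) for molecular-weight computation;
# pseudo-elements absent from this table contribute zero mass
.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06, Fe = 55.845, Ni = 58.693,
                  Co = 58.933, Mg = 24.305, Se = 78.971, Zn = 65.38)

#' Molecular weight from a formula
#'
#' @param formula named vector of element counts.
#' @return weight in g/mmol (numerically, kDa). Unknown pseudo-elements
#'   count zero.
#' @export
formula_mw <- function(formula) {
  if (is.null(formula) || length(formula) == 0L) return(0)
  m <- .ATOMIC_MASS[names(formula)]
  m[is.na(m)] <- 0
  sum(m * formula) / 1000
}

# add/subtract formulas (named count vectors)
formula_add <- function(...) {
  fs <- list(...)
  out <- numeric()
  for (f in fs) {
    if (is.null(f)) next
    for (el in names(f)) out[el] <- (if (el %in% names(out)) out[[el]] else 0) + f[[el]]
  }
  out[abs(out) > 1e-12]
}
formula_scale <- function(f, k) {
  if (is.null(f)) return(NULL)
  f * k
}

#' Check elemental and charge balance of every reaction
#'
#' Exchange (`EX_*`), demand (`DM_*`), biomass and maintenance
#' pseudo-reactions are exempt. A metabolite without a formula makes each
#' reaction touching it explicitly "unbalanceable" rather than silently
#' passing.
#'
#' @param net an `acetome_network`.
#' @param tol residual below which a balance is considered exact.
#' @return data.frame with columns `reaction`, `quantity` (element name,
#'   `"charge"`, or `"unbalanceable"`), `residual`. Zero rows means the
#'   network is fully balanced.
#' @export
check_balances <- function(net, tol = 1e-9) {
  out <- list()
  for (r in net$reactions) {
    if (is_pseudo(r$id)) next
    mets <- net$metabolites[names(r$stoichiometry)]
    noform <- vapply(mets, function(m) is.null(m$formula), TRUE)
    if (any(noform)) {
      out[[length(out) + 1L]] <- data.frame(
        reaction = r$id, quantity = "unbalanceable",
        residual = NA_real_, stringsAsFactors = FALSE)
      next
    }
    bal <- numeric()
    chg <- 0
    for (i in seq_along(mets)) {
      k <- r$stoichiometry[[i]]
      bal <- formula_add(bal, formula_scale(mets[[i]]$formula, k))
      chg <- chg + k * mets[[i]]$charge
    }
    for (el in names(bal)) {
      if (abs(bal[[el]]) > tol)
        out[[length(out) + 1L]] <- data.frame(
          reaction = r$id, quantity = el, residual = bal[[el]],
          stringsAsFactors = FALSE)
    }
    if (abs(chg) > tol)
      out[[length(out) + 1L]] <- data.frame(
        reaction = r$id, quantity = "charge", residual = chg,
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(reaction = character(), quantity = character(),
                      residual = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
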