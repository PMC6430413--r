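#' Solve a dense linear program
#'
#' Thin R interface to the package's built-in two-phase simplex. Solves
#' \deqn{\max\ c'x \quad \mathrm{s.t.}\quad A x \;\{\le,=,\ge\}\; b,\quad
#' lb \le x \le ub.}
#'
#' The solver is dense and intended for the problem sizes this package
#' produces (a few hundred rows and columns). Feasibility and optimality
#' tolerances default to `1e-9`; all ME coefficients are kept in per-hour
#' units upstream so that the matrices stay reasonably conditioned.
#'
#' @param obj numeric objective coefficients (length `n`).
#' @param A dense constraint matrix (`m x n`).
#' @param sense character vector of `"<="`, `"="`, `">="` (length `m`).
#' @param rhs numeric right-hand sides.
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize maximize (`TRUE`, default) or minimize.
#' @param feasibility_only stop after phase 1; `x` is then any basic
#'   feasible point and `objval` is `0`.
#' @param tol pivot/optimality tolerance.
#' @param max_iter simplex iteration cap.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), `x` (named if `A` has column names), `objval`, `iter`.
#' @export
lp_solve <- function(obj, A, sense, rhs, lb = rep(0, ncol(A)),
                     ub = rep(Inf, ncol(A)), maximize = TRUE,
                     feasibility_only = FALSE, tol = 1e-9,
                     max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(sense) == m, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  sns <- match(sense, c("<=", "=", ">="))
  if (anyNA(sns)) stop("sense entries must be one of '<=', '=', '>='")

  # ---- presolve: fix forced variables, drop inert rows ----
  # ME instances carry large blocks of structurally dead columns (closed
  # exchanges cascade through cofactor-loading and usage-coupling rows);
  # eliminating them up front removes most degeneracy before the simplex
  # runs. Rules, iterated to fixpoint: (a) lb == ub fixes a variable;
  # (b) an equality row with one free variable left pins it; (c) a row
  # whose bound-implied min (or max) activity equals its rhs forces every
  # participating variable to the corresponding bound.
  ps <- lp_presolve(A, sns, as.numeric(rhs), as.numeric(lb),
                    as.numeric(ub))
  if (identical(ps$status, "infeasible")) {
    return(list(status = "infeasible", x = numeric(n), objval = NA_real_,
                iter = 0L))
  }
  x_full <- ps$x_fixed
  free <- which(!ps$fixed)
  rows <- which(!ps$drop_row)
  if (length(free) == 0L) {
    res <- list(status = "optimal", x = x_full,
                objval = sum(obj * x_full), iter = 0L)
  } else {
    A2 <- A[rows, free, drop = FALSE]
    rhs2 <- ps$rhs_adj[rows]
    res <- .lp_simplex_cpp(A2, as.integer(sns[rows] - 2L), rhs2,
                           as.numeric(obj[free]), ps$lb[free], ps$ub[free],
                           isTRUE(maximize), isTRUE(feasibility_only),
                           tol, as.integer(max_iter))
    if (res$status == "optimal") {
      x_full[free] <- res$x
      res$x <- x_full
      res$objval <- sum(obj * x_full)
    } else res$x <- numeric(n)
  }
  if (res$status == "maxiter")
    stop("LP solver hit the iteration limit (", max_iter, ")")
  if (res$status == "optimal") {
    # guard against a numerically unrepairable final basis: gross
    # constraint violations must not be reported as an optimum
    viol <- max(0, lb - res$x, res$x - ub)
    r <- as.numeric(A %*% res$x) - rhs
    viol <- max(viol, abs(r[sense == "="]),
                r[sense == "<="], -r[sense == ">="])
    if (!is.finite(viol)) viol <- Inf
    res$viol <- viol
    if (viol > 1e-4 && !feasibility_only) res$status <- "infeasible"
  }
  if (!is.null(colnames(A))) names(res$x) <- colnames(A)
  res
}

# Bound-propagation presolve (internal). Iterates three reductions to a
# fixpoint: variables with lb == ub are fixed; an equality row with a
# single remaining variable pins it; a row whose bound-implied minimum
# (maximum) activity equals its right-hand side forces every remaining
# variable onto the bound achieving it. Rows fully resolved are dropped
# (after a satisfaction check). Detects trivial infeasibility.
lp_presolve <- function(A, sns, rhs, lb, ub, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  fixed <- rep(FALSE, n)
  xf <- numeric(n)
  drop_row <- rep(FALSE, m)
  infeasible <- FALSE
  infeas_at <- NULL
  fix_var <- function(j, v) {
    xf[j] <<- v
    fixed[j] <<- TRUE
  }
  repeat {
    changed <- FALSE
    newfix <- which(!fixed & (ub - lb <= tol))
    if (length(newfix)) {
      for (j in newfix) fix_var(j, (lb[j] + ub[j]) / 2)
      changed <- TRUE
    }
    for (i in which(!drop_row)) {
      arow <- A[i, ]
      J <- which(!fixed & arow != 0)
      # adjusted rhs must reflect fixes made earlier in this same pass
      r <- rhs[i] - sum(arow[fixed] * xf[fixed])
      rt <- 1e-7 * (1 + abs(r))
      if (length(J) == 0L) {
        ok <- switch(sns[i], abs(r) >= -Inf && r >= -rt,  # <=
                     abs(r) <= rt,                         # =
                     r <= rt)                              # >=
        if (!ok) { infeasible <- TRUE; infeas_at <- c(i, 1); break }
        drop_row[i] <- TRUE
        changed <- TRUE
        next
      }
      if (sns[i] == 2L && length(J) == 1L) {
        j <- J
        v <- r / arow[j]
        if (v < lb[j] - 1e-6 || v > ub[j] + 1e-6) { infeasible <- TRUE; infeas_at <- c(i, 2); break }
        fix_var(j, min(max(v, lb[j]), ub[j]))
        drop_row[i] <- TRUE
        changed <- TRUE
        next
      }
      a <- arow[J]
      lo_at <- ifelse(a > 0, lb[J], ub[J])
      hi_at <- ifelse(a > 0, ub[J], lb[J])
      rowmin <- sum(a * lo_at)
      rowmax <- sum(a * hi_at)
      ft <- 1e-11 * (1 + abs(r))
      if (sns[i] != 3L && is.finite(rowmin) && rowmin > r + rt) {
        infeasible <- TRUE; infeas_at <- c(i, 3); break
      }
      if (sns[i] != 1L && is.finite(rowmax) && rowmax < r - rt) {
        infeasible <- TRUE; infeas_at <- c(i, 4); break
      }
      if (sns[i] != 3L && is.finite(rowmin) && rowmin >= r - ft) {
        for (k in seq_along(J)) fix_var(J[k], lo_at[k])
        drop_row[i] <- TRUE
        changed <- TRUE
        next
      }
      if (sns[i] != 1L && is.finite(rowmax) && rowmax <= r + ft) {
        for (k in seq_along(J)) fix_var(J[k], hi_at[k])
        drop_row[i] <- TRUE
        changed <- TRUE
        next
      }
      # redundant inequalities
      if (sns[i] == 1L && is.finite(rowmax) && rowmax <= r + ft) {
        drop_row[i] <- TRUE; changed <- TRUE; next
      }
      if (sns[i] == 3L && is.finite(rowmin) && rowmin >= r - ft) {
        drop_row[i] <- TRUE; changed <- TRUE; next
      }
    }
    if (infeasible || !changed) break
  }
  if (infeasible) return(list(status = "infeasible", at = infeas_at))
  radj <- rhs - as.numeric(A[, fixed, drop = FALSE] %*% xf[fixed])
  list(status = "ok", fixed = fixed, x_fixed = xf, drop_row = drop_row,
       rhs_adj = radj, lb = lb, ub = ub)
}
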