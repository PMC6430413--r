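# Independent oracles, deliberately implemented without reusing the
# package's solution paths.

# Vertex-enumeration oracle for max c'v s.t. S v = 0, l <= v <= u.
# Enumerates all choices of n - m variables fixed at a bound, solves the
# square system for the rest, keeps feasible vertices. Assumes rank(S)
# = m (guaranteed by the generators below retrying on deficiency).
fba_vertex_oracle <- function(S, lb, ub, obj) {
  m <- nrow(S); n <- ncol(S)
  best <- -Inf
  free_sets <- utils::combn(n, n - m, simplify = FALSE)
  for (F in free_sets) {
    B <- setdiff(seq_len(n), F)
    SB <- S[, B, drop = FALSE]
    if (abs(det(SB)) < 1e-10) next
    nf <- length(F)
    for (mask in 0:(2^nf - 1)) {
      vF <- numeric(nf)
      for (k in seq_len(nf))
        vF[k] <- if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0)
          ub[F[k]] else lb[F[k]]
      rhs <- -S[, F, drop = FALSE] %*% vF
      vB <- solve(SB, rhs)
      v <- numeric(n)
      v[F] <- vF; v[B] <- vB
      if (all(v >= lb - 1e-8) && all(v <= ub + 1e-8))
        best <- max(best, sum(obj * v))
    }
  }
  best
}

random_small_network_lp <- function(seed) {
  set.seed(seed)
  repeat {
    m <- sample(2:3, 1); n <- m + sample(2:3, 1)
    S <- matrix(sample(-2:2, m * n, replace = TRUE), m, n)
    if (qr(S)$rank < m) next
    lb <- round(runif(n, -5, 0), 1)
    ub <- round(runif(n, 0, 5), 1)
    obj <- round(runif(n, -1, 1), 2)
    # ensure the all-zero point is feasible so the LP is never infeasible
    return(list(S = S, lb = lb, ub = ub, obj = obj))
  }
}

# Multiresolution feasibility scan: an independent substitute for
# bisection. Scans mu upward on successively finer grids (factor-10
# refinement) until the step reaches tol; returns the largest feasible
# mu observed.
grid_scan_oracle <- function(prob, mu_min, mu_max, tol = 1e-6) {
  if (!feasible(prob, mu_min)) return(NA_real_)
  lo <- mu_min; hi <- mu_max
  step <- (mu_max - mu_min) / 8
  repeat {
    mus <- seq(lo, hi, by = step)
    feas <- vapply(mus, function(m) feasible(prob, m), TRUE)
    lo <- max(mus[feas])
    above <- mus[mus > lo]
    hi <- if (length(above)) min(above) else hi
    if (step <= tol) return(lo)
    step <- max(step / 10, tol / 2)
  }
}

# Exhaustive permutation p-value for |Pearson r| (own enumeration)
perm_exhaustive_oracle <- function(x, y) {
  permute_all <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in permute_all(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  r0 <- abs(cor(x, y))
  rs <- vapply(permute_all(seq_along(x)),
               function(p) abs(cor(x[p], y)), 0)
  mean(rs >= r0 - 1e-12)
}
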