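# Dense two-phase primal simplex with Bland's rule, used as the LP core of
# the flux solver. Written for the small stoichiometric models this package
# targets (tens of reactions): deterministic (fixed variable order, Bland
# anti-cycling), explicit infeasible/unbounded statuses.
#
# Standard form: minimize c'x subject to A x = b, x >= 0.

simplex_pivot <- function(T, basis, r, ent) {
  T[r, ] <- T[r, ] / T[r, ent]
  for (i in seq_len(nrow(T))) {
    if (i != r && abs(T[i, ent]) > 0) T[i, ] <- T[i, ] - T[i, ent] * T[r, ]
  }
  basis[r] <- ent
  list(T = T, basis = basis)
}

# T: (m+1) x (ncol+1) tableau, last row = reduced-cost row of the objective
# being minimized, last column = rhs. Returns list(T, basis, status).
simplex_iterate <- function(T, basis, n_cols, tol = 1e-9, max_iter = 10000) {
  m <- nrow(T) - 1
  for (it in seq_len(max_iter)) {
    red <- T[m + 1, seq_len(n_cols)]
    ent <- which(red < -tol)[1]          # Bland: smallest eligible index
    if (is.na(ent)) return(list(T = T, basis = basis, status = "optimal"))
    col <- T[seq_len(m), ent]
    pos <- which(col > tol)
    if (!length(pos)) return(list(T = T, basis = basis, status = "unbounded"))
    ratio <- T[pos, n_cols + 1] / col[pos]
    cand <- pos[ratio <= min(ratio) + 0]
    r <- cand[which.min(basis[cand])]    # Bland tie-break on leaving variable
    st <- simplex_pivot(T, basis, r, ent)
    T <- st$T; basis <- st$basis
  }
  list(T = T, basis = basis, status = "iteration_limit")
}

# minimize c'x s.t. A x = b, x >= 0.
# Returns list(x, value, status) with status optimal/infeasible/unbounded.
solve_lp_standard <- function(c_vec, A, b, tol = 1e-8) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  # phase 1: artificial variables with identity basis
  T <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  objrow <- c(-colSums(A), rep(0, m), -sum(b))
  T <- rbind(T, objrow)
  ph1 <- simplex_iterate(T, basis, n + m, tol = tol)
  if (ph1$status != "optimal" || -ph1$T[m + 1, n + m + 1] > 1e-6)
    return(list(x = NULL, value = NA_real_, status = "infeasible"))
  T <- ph1$T; basis <- ph1$basis
  # drive remaining artificials (basic at zero) out, or drop redundant rows
  drop_rows <- integer(0)
  for (r in which(basis > n)) {
    piv <- which(abs(T[r, seq_len(n)]) > tol)[1]
    if (is.na(piv)) drop_rows <- c(drop_rows, r)
    else { st <- simplex_pivot(T, basis, r, piv); T <- st$T; basis <- st$basis }
  }
  if (length(drop_rows)) {
    T <- T[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  m2 <- nrow(T) - 1
  T <- T[, c(seq_len(n), n + m + 1), drop = FALSE]  # drop artificial columns
  # phase 2: rebuild the reduced-cost row for the true objective
  cb <- c_vec[basis]
  T[m2 + 1, ] <- c(c_vec, 0) - drop(cb %*% T[seq_len(m2), , drop = FALSE])
  ph2 <- simplex_iterate(T, basis, n, tol = tol)
  if (ph2$status != "optimal")
    return(list(x = NULL, value = NA_real_, status = ph2$status))
  x <- numeric(n)
  x[ph2$basis] <- ph2$T[seq_len(m2), n + 1]
  list(x = x, value = sum(c_vec * x), status = "optimal")
}
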