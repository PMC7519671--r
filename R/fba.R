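# Linear programming layer for flux balance analysis.
#
# Flux variables are split as v = v+ - v- (both >= 0) so that bounds of
# either sign and the pFBA sum-of-absolute-fluxes objective are linear.
# Solved by the package's deterministic two-phase simplex (fixed variable
# order, Bland's rule), so repeated runs give identical flux vectors.

BIG_BOUND <- 1e6

# Solve: optimize obj'v  s.t.  S v = 0, lb <= v <= ub, v[fix] = fixval.
# direction "max"/"min"; obj may also be the string "total" for sum |v|.
# Fixed fluxes are imposed by clamping lb = ub = value before splitting.
lp_flux <- function(model, obj, direction = "max", fixed = numeric(0)) {
  S <- stoich_matrix(model)
  bnd <- reaction_bounds(model)
  lb <- pmax(bnd[, "lb"], -BIG_BOUND)
  ub <- pmin(bnd[, "ub"], BIG_BOUND)
  if (length(fixed)) {
    idx <- match(names(fixed), names(model$reactions))
    lb[idx] <- ub[idx] <- unname(fixed)
  }
  n <- ncol(S)
  up_p <- pmax(ub, 0)                 # upper bound on v+
  up_n <- pmax(-lb, 0)                # upper bound on v-
  keep_p <- which(up_p > 0)           # v+ identically 0 otherwise
  keep_n <- which(up_n > 0)
  np <- length(keep_p); nn <- length(keep_n)
  lo_p <- pmax(lb, 0)[keep_p]         # v+ >= lb where the range is positive
  lo_n <- pmax(-ub, 0)[keep_n]        # v- >= -ub where the range is negative
  n_surp <- sum(lo_p > 0) + sum(lo_n > 0)
  nv <- np + nn + np + nn + n_surp    # v+, v-, slacks, surpluses
  m_rows <- nrow(S) + np + nn + n_surp
  A <- matrix(0, m_rows, nv)
  b <- numeric(m_rows)
  A[seq_len(nrow(S)), seq_len(np)] <- S[, keep_p, drop = FALSE]
  A[seq_len(nrow(S)), np + seq_len(nn)] <- -S[, keep_n, drop = FALSE]
  r <- nrow(S)
  for (j in seq_len(np)) {            # v+_j + slack = up_p
    r <- r + 1; A[r, j] <- 1; A[r, np + nn + j] <- 1; b[r] <- up_p[keep_p[j]]
  }
  for (j in seq_len(nn)) {            # v-_j + slack = up_n
    r <- r + 1; A[r, np + j] <- 1; A[r, 2 * np + nn + j] <- 1
    b[r] <- up_n[keep_n[j]]
  }
  scol <- 2 * (np + nn)
  for (j in which(lo_p > 0)) {        # v+_j - surplus = lower bound
    r <- r + 1; scol <- scol + 1
    A[r, j] <- 1; A[r, scol] <- -1; b[r] <- lo_p[j]
  }
  for (j in which(lo_n > 0)) {
    r <- r + 1; scol <- scol + 1
    A[r, np + j] <- 1; A[r, scol] <- -1; b[r] <- lo_n[j]
  }
  cv <- numeric(nv)
  if (identical(obj, "total")) {
    cv[seq_len(np + nn)] <- 1
  } else {
    sgn <- if (direction == "max") -1 else 1
    cv[seq_len(np)] <- sgn * obj[keep_p]
    cv[np + seq_len(nn)] <- -sgn * obj[keep_n]
  }
  sol <- solve_lp_standard(cv, A, b)
  if (sol$status != "optimal") {
    return(list(value = NA_real_, flux = NULL,
                solved = if (sol$status == "infeasible") -1L else 0L))
  }
  v <- numeric(n)
  v[keep_p] <- sol$x[seq_len(np)]
  v[keep_n] <- v[keep_n] - sol$x[np + seq_len(nn)]
  names(v) <- names(model$reactions)
  value <- if (identical(obj, "total")) sol$value else sum(obj * v)
  list(value = value, flux = v, solved = 1L)
}

unit_obj <- function(model, rxn) {
  obj <- numeric(length(model$reactions))
  obj[match(rxn, names(model$reactions))] <- 1
  obj
}

#' Parsimonious flux balance analysis at a suboptimal growth fraction
#'
#' Three-stage solve: (1) maximize the growth objective to find the maximum
#' specific growth rate; (2) fix growth at `growth_fraction` of that maximum
#' and maximize flux through the production target (the tryptophan sink);
#' (3) fix both and minimize the total sum of absolute fluxes, returning the
#' parsimonious flux distribution.
#'
#' @param model a [stoich_model].
#' @param growth_fraction fraction of the maximum growth rate to retain,
#'   in (0, 1].
#' @return an object of class `flux_distribution`: named flux vector
#'   (mmol/gDW/h), the growth fraction, realized growth and target fluxes,
#'   and the total absolute flux.
#' @export
solve_pfba <- function(model, growth_fraction = 1) {
  stopifnot(inherits(model, "stoich_model"),
            growth_fraction > 0, growth_fraction <= 1)
  s1 <- lp_flux(model, unit_obj(model, model$objective), "max")
  if (s1$solved != 1)
    stop("infeasible model at stage: growth maximization (solver status ",
         s1$solved, ")")
  mu_max <- s1$value
  g <- growth_fraction * mu_max
  s2 <- lp_flux(model, unit_obj(model, model$target), "max",
                fixed = stats::setNames(g, model$objective))
  if (s2$solved != 1)
    stop("infeasible model at stage: target maximization (solver status ",
         s2$solved, ")")
  trp <- s2$value
  s3 <- lp_flux(model, "total",
                fixed = stats::setNames(c(g, trp),
                                        c(model$objective, model$target)))
  if (s3$solved != 1)
    stop("infeasible model at stage: flux minimization (solver status ",
         s3$solved, ")")
  v <- s3$flux
  v[abs(v) < 1e-9] <- 0
  structure(list(fluxes = v, growth_fraction = growth_fraction,
                 mu_max = mu_max, growth_flux = g, target_flux = trp,
                 total_flux = sum(abs(v))),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf(
    "pFBA flux distribution: growth fraction %.2f (growth %.4g, target %.4g, total |v| %.4g)\n",
    x$growth_fraction, x$growth_flux, x$target_flux, x$total_flux))
  invisible(x)
}

#' Scan pFBA solutions over suboptimal growth fractions
#'
#' Simulates growth at a grid of suboptimal growth rates with all remaining
#' flux capacity oriented toward the production target. The default grid is
#' 30--80\% of the maximum growth rate in 5\% steps (11 conditions).
#'
#' @param model a [stoich_model].
#' @param fractions numeric vector of growth fractions in (0, 1].
#' @return list of [solve_pfba] flux distributions, one per fraction.
#' @export
suboptimal_scan <- function(model, fractions = default_fraction_grid()) {
  stopifnot(length(fractions) >= 1, all(fractions > 0), all(fractions <= 1))
  lapply(fractions, function(f) {
    tryCatch(solve_pfba(model, f),
             error = function(e) stop("fraction ", f, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
}

#' @rdname suboptimal_scan
#' @export
default_fraction_grid <- function() seq(0.30, 0.80, by = 0.05)
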