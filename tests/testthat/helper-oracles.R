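# Independent oracles and fixture builders used across the suite.

# ---- model fixtures -------------------------------------------------------

# Random feasible stoichiometric model: a linear backbone (uptake ->
# M1 -> ... -> Mk) guaranteeing feasibility, plus random reversible cross
# reactions, with growth and trp sinks on distinct metabolites.
random_feasible_model <- function(n_extra = 8, n_mets = 6, seed = 1) {
  withr::with_seed(seed, {
    mets <- paste0("M", seq_len(n_mets))
    rxns <- list(list(id = "uptake", stoich = c(M1 = 1), lb = 0, ub = 10,
                      genes = "g_upt", pathway = "transport"))
    for (i in seq_len(n_mets - 1)) {
      st <- c(-1, 1)
      names(st) <- mets[c(i, i + 1)]
      rxns[[length(rxns) + 1]] <- list(
        id = paste0("chain", i), stoich = st, lb = 0, ub = 1000,
        genes = paste0("g_chain", i), pathway = "backbone")
    }
    for (j in seq_len(n_extra)) {
      pair <- sample(n_mets, 2)
      st <- c(-1, sample(c(1, 2), 1))
      names(st) <- mets[pair]
      rxns[[length(rxns) + 1]] <- list(
        id = paste0("x", j), stoich = st, lb = -5, ub = 5,
        genes = paste0("g_x", j), pathway = sample(c("ppp", "glycolysis"), 1))
    }
    rxns[[length(rxns) + 1]] <- list(id = "growth",
                                     stoich = stats::setNames(-1, mets[n_mets]),
                                     lb = 0, ub = 1000, genes = character(0),
                                     pathway = NA)
    rxns[[length(rxns) + 1]] <- list(id = "trp",
                                     stoich = stats::setNames(-1, mets[max(2, n_mets - 1)]),
                                     lb = 0, ub = 1000, genes = "g_trp",
                                     pathway = "shikimate")
    stoich_model(mets, rxns, "growth", "trp")
  })
}

check_mass_balance <- function(model, dist, tol = 1e-6) {
  max(abs(stoich_matrix(model) %*% dist$fluxes))  < tol
}

check_bounds <- function(model, dist, tol = 1e-6) {
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  all(dist$fluxes >= lb - tol) && all(dist$fluxes <= ub + tol)
}

# ---- scipy LP oracle ------------------------------------------------------

# Three-stage pFBA solved independently with scipy.optimize.linprog (HiGHS).
# Returns list(mu_max, trp_opt, total_abs_flux).
py_pfba_oracle <- function(model, fraction) {
  stopifnot(nzchar(Sys.which("python")))
  mj <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".json")
  write_model_json(model, mj)
  script <- tempfile(fileext = ".py")
  writeLines(sprintf('
import json, sys
import numpy as np
from scipy.optimize import linprog

model = json.load(open(%s))
frac = %.17g
rid = [r["id"] for r in model["reactions"]]
mets = model["metabolites"]
S = np.zeros((len(mets), len(rid)))
for j, r in enumerate(model["reactions"]):
    for m, c in r["stoich"].items():
        S[mets.index(m), j] = c
lb = np.array([r["lb"] for r in model["reactions"]], float)
ub = np.array([r["ub"] for r in model["reactions"]], float)
iobj = rid.index(model["objective"]); itar = rid.index(model["target"])

def solve(c, lo, hi):
    res = linprog(c, A_eq=S, b_eq=np.zeros(len(mets)),
                  bounds=list(zip(lo, hi)), method="highs")
    assert res.status == 0, res.message
    return res

c = np.zeros(len(rid)); c[iobj] = -1
mu = -solve(c, lb, ub).fun
lo, hi = lb.copy(), ub.copy()
lo[iobj] = hi[iobj] = frac * mu
c = np.zeros(len(rid)); c[itar] = -1
trp = -solve(c, lo, hi).fun
lo[itar] = hi[itar] = trp
# min sum |v| by splitting
n = len(rid)
S2 = np.hstack([S, -S])
bnd = ([(max(l, 0), max(h, 0)) for l, h in zip(lo, hi)]
       + [(max(-h, 0), max(-l, 0)) for l, h in zip(lo, hi)])
res = linprog(np.ones(2 * n), A_eq=S2, b_eq=np.zeros(len(mets)),
              bounds=bnd, method="highs")
assert res.status == 0, res.message
json.dump({"mu_max": mu, "trp_opt": trp, "total_abs_flux": res.fun},
          open(%s, "w"))
', deparse(mj), fraction, deparse(out)), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  jsonlite::read_json(out, simplifyVector = TRUE)
}

# ---- Fisher exact enumeration oracle --------------------------------------

# Two-sided exact p for table matrix(c(a,b,c,d),2): enumerate the full
# hypergeometric support at fixed margins, sum probabilities <= P(observed).
fisher_enum_oracle <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  supp <- max(0, r1 + c1 - n):min(r1, c1)
  lp <- lchoose(c1, supp) + lchoose(n - c1, r1 - supp) - lchoose(n, r1)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  p_obs <- p[match(a, supp)]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# ---- occupancy closed form ------------------------------------------------

# Expected unique genotypes among n*p correct colonies drawn uniformly over
# G equally likely genotypes.
coverage_closed_form <- function(G, n, p) G * (1 - (1 - 1 / G)^(n * p))
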