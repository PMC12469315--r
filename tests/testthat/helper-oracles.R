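# Brute-force oracles and toy model builders, independent of the package's
# Newton solver internals.  Oracles use plain bisection on the raw
# stoichiometry/constants tables.

toy_ML_model <- function(log_beta = 3, pKw = 13.78) {
  build_model(
    list(component("M", role = "metal"), component("L", role = "ligand"),
         component("H", role = "proton")),
    list(species_def("ML", c(M = 1, L = 1), log_beta)),
    pKw = pKw)
}

monoprotic_model <- function(logK = 10.28, pKw = 13.78) {
  build_model(
    list(component("L", role = "ligand"), component("H", role = "proton")),
    list(species_def("HL", c(L = 1, H = 1), logK)),
    pKw = pKw)
}

# plain bisection for a strictly increasing function g on [lo, hi]
bisect_root <- function(g, lo, hi, n_iter = 200L) {
  glo <- g(lo)
  ghi <- g(hi)
  stopifnot(glo <= 0, ghi >= 0)
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    if (g(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# free concentrations at fixed pH for models with 1 or 2 positive-total
# non-proton components, by (nested) bisection on log10 free concentration.
# Assumes nonnegative stoichiometry in the non-proton components.
oracle_free <- function(model, totals, pH) {
  totals <- totals[totals > 0]
  comps <- names(totals)
  stopifnot(length(comps) %in% 1:2)
  pro <- model$components$id[model$components$role == "proton"]
  other <- setdiff(colnames(model$stoich), c(comps, pro))
  keep <- rowSums(model$stoich[, other, drop = FALSE] != 0) == 0
  S <- model$stoich[keep, , drop = FALSE]
  lb <- model$species$log_beta[keep]
  conc_all <- function(lf) {   # lf: named log10 free over comps
    10^(lb - S[, pro] * pH + as.vector(S[, comps, drop = FALSE] %*% lf[comps]))
  }
  balance <- function(lf, j) sum(S[, j] * conc_all(lf)) + 10^lf[[j]] - totals[[j]]
  if (length(comps) == 1L) {
    j <- comps
    lf <- bisect_root(function(x) balance(setNames(x, j), j),
                      -40, log10(totals[[j]]))
    return(setNames(10^lf, j))
  }
  j1 <- comps[1]; j2 <- comps[2]
  inner <- function(x1) {
    bisect_root(function(x2) balance(setNames(c(x1, x2), comps), j2),
                -40, log10(totals[[j2]]))
  }
  lf1 <- bisect_root(function(x1)
    balance(setNames(c(x1, inner(x1)), comps), j1),
    -40, log10(totals[[j1]]), n_iter = 80L)
  setNames(10^c(lf1, inner(lf1)), comps)
}

# pH solving the full proton condition for a given total titratable
# acidity TH (mol/L), by bisection on pH with oracle_free inner solves
oracle_titration_pH <- function(model, totals, TH, lo = 0.5, hi = NULL) {
  pro <- model$components$id[model$components$role == "proton"]
  if (is.null(hi)) hi <- model$pKw - 0.5
  excess <- function(pH) {
    free <- oracle_free(model, totals, pH)
    other <- setdiff(colnames(model$stoich), c(names(free), pro))
    keep <- rowSums(model$stoich[, other, drop = FALSE] != 0) == 0
    S <- model$stoich[keep, , drop = FALSE]
    lb <- model$species$log_beta[keep]
    cc <- 10^(lb - S[, pro] * pH +
                as.vector(S[, names(free), drop = FALSE] %*% log10(free)))
    h <- 10^(-pH)
    sum(S[, pro] * cc) + h - 10^(-model$pKw) / h
  }
  # excess is decreasing in pH; bisect on the negated function
  bisect_root(function(pH) TH - excess(pH), lo, hi, n_iter = 120L)
}

# recompute component totals from a solution state (free + species)
recovered_totals <- function(model, state) {
  pro <- model$components$id[model$components$role == "proton"]
  comps <- setdiff(model$components$id, pro)
  vapply(comps, function(j)
    sum(model$stoich[, j] * state$species_conc) + state$free[[j]], numeric(1))
}
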