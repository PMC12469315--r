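# Mass-balance speciation: damped Newton-Raphson iteration on log10 free
# concentrations.  Two modes share one Newton core:
#   * fixed-pH   -- free [H+] known from the pH, proton balance not solved;
#   * full       -- proton treated as an unknown with a given total titratable
#                   acidity (may be negative in base excess); hydroxide enters
#                   as a pseudo-species with stoichiometry {H: -1} and
#                   log beta = -pKw.

# Newton core.  Su: species-by-unknown-component stoichiometry (free
# components are NOT rows; they enter as the 10^x self terms); lbu: effective
# log10 formation constants (fixed contributions folded in); Tu: totals for
# the unknown components.  x0: starting log10 free concentrations.
.newton_core <- function(Su, lbu, Tu, x0, tol = 1e-10, maxit = 200L) {
  ln10 <- log(10)
  nu <- length(Tu)
  Spos <- Su * (Su > 0)
  x <- pmin(pmax(x0, -300), 30)

  eval_state <- function(x) {
    logc <- if (nrow(Su)) pmin(lbu + as.vector(Su %*% x), 300) else numeric(0)
    cc <- 10^logc
    f <- 10^x
    tot <- as.vector(crossprod(Su, cc)) + f
    pos <- as.vector(crossprod(Spos, cc)) + f
    list(cc = cc, f = f, R = tot - Tu, scale = pmax(abs(Tu), pos, 1e-30))
  }

  st <- eval_state(x)
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    rel <- max(abs(st$R) / st$scale)
    if (rel <= tol) { converged <- TRUE; break }
    it <- it + 1L
    J <- ln10 * (crossprod(Su, Su * st$cc) + diag(st$f, nu))
    d <- tryCatch(solve(J, -st$R),
                  error = function(e) solve(J + diag(1e-12 * max(abs(diag(J))),
                                                     nu), -st$R))
    # clamp the step to at most 1 log10 unit per component
    m <- max(abs(d))
    if (m > 1) d <- d / m
    f0 <- sum((st$R / st$scale)^2)
    lam <- 1
    repeat {
      xn <- pmin(pmax(x + lam * d, -300), 30)
      stn <- eval_state(xn)
      if (sum((stn$R / st$scale)^2) < f0 || lam < 1e-8) break
      lam <- lam / 2
    }
    x <- xn
    st <- stn
  }
  list(x = x, cc = st$cc, converged = converged,
       residual_norm = max(abs(st$R) / st$scale), iterations = it)
}

# fixed-pH solve on the internal representation; returns NULL-safe state
.solve_fixed_pH <- function(model, totals, pH, x0 = NULL, tol = 1e-10,
                            maxit = 200L) {
  pro <- .proton_id(model)
  comps <- .nonproton_ids(model)
  tot <- setNames(numeric(length(comps)), comps)
  tot[names(totals)] <- as.numeric(totals)
  keep <- comps[tot[comps] > 0]
  drop <- setdiff(comps, keep)
  S <- model$stoich
  # species involving an absent component do not form
  sp_keep <- if (length(drop))
    rownames(S)[rowSums(S[, drop, drop = FALSE] != 0) == 0] else rownames(S)
  Su <- S[sp_keep, keep, drop = FALSE]
  lbu <- model$species$log_beta[match(sp_keep, model$species$name)] -
    S[sp_keep, pro] * pH
  if (is.null(x0)) x0 <- log10(tot[keep] / 2)
  res <- .newton_core(Su, lbu, tot[keep], x0, tol, maxit)

  free <- setNames(numeric(nrow(model$components)), model$components$id)
  free[keep] <- 10^res$x
  free[pro] <- 10^(-pH)
  conc <- setNames(numeric(nrow(S)), rownames(S))
  conc[sp_keep] <- res$cc
  list(free = free, species_conc = conc, converged = res$converged,
       residual_norm = res$residual_norm, x = res$x, keep = keep)
}

# full solve: proton total TH (mol/L, signed) is part of the unknown system.
# x0: named log10 free over c(keep, proton).
.solve_full <- function(model, totals, TH, x0 = NULL, tol = 1e-10,
                        maxit = 200L) {
  pro <- .proton_id(model)
  comps <- .nonproton_ids(model)
  tot <- setNames(numeric(length(comps)), comps)
  tot[names(totals)] <- as.numeric(totals)
  keep <- comps[tot[comps] > 0]
  drop <- setdiff(comps, keep)
  S <- model$stoich
  sp_keep <- if (length(drop))
    rownames(S)[rowSums(S[, drop, drop = FALSE] != 0) == 0] else rownames(S)
  unknowns <- c(keep, pro)
  Su <- rbind(S[sp_keep, unknowns, drop = FALSE],
              OH_ = setNames(as.numeric(unknowns == pro) * -1, unknowns))
  lbu <- c(model$species$log_beta[match(sp_keep, model$species$name)],
           -model$pKw)
  if (is.null(x0)) {
    h0 <- if (TH > 0) max(TH / 2, 1e-10) else 10^(-model$pKw) / max(-TH / 2, 1e-10)
    x0 <- c(log10(tot[keep] / 2), log10(h0))
  }
  res <- .newton_core(Su, lbu, c(tot[keep], TH), x0, tol, maxit)
  if (!res$converged) {
    # fallback: monotone bracketing on pH with inner fixed-pH solves
    g <- function(pH) .proton_excess_at(model, tot[keep], pH, tol) - TH
    lo <- 0.3; hi <- model$pKw - 0.3
    root <- tryCatch(stats::uniroot(g, c(lo, hi), tol = 1e-13)$root,
                     error = function(e) NA_real_)
    if (is.finite(root)) {
      st <- .solve_fixed_pH(model, tot[keep], root, tol = tol)
      x <- c(log10(pmax(st$free[keep], 1e-300)), -root)
      res <- .newton_core(Su, lbu, c(tot[keep], TH), x, tol, maxit)
    }
  }
  ncc <- length(res$cc)
  free <- setNames(numeric(nrow(model$components)), model$components$id)
  free[keep] <- 10^res$x[seq_along(keep)]
  free[pro] <- 10^res$x[length(res$x)]
  conc <- setNames(numeric(nrow(S)), rownames(S))
  conc[sp_keep] <- res$cc[-ncc]
  list(free = free, species_conc = conc, converged = res$converged,
       residual_norm = res$residual_norm, x = res$x, keep = keep)
}

# total titratable proton implied by a fixed-pH solve:
# sum_i sH_i c_i + [H] - Kw/[H]
.proton_excess_at <- function(model, totals, pH, tol = 1e-10, x0 = NULL) {
  st <- .solve_fixed_pH(model, totals, pH, x0 = x0, tol = tol)
  if (!st$converged)
    stop(sprintf("speciation solve did not converge at pH %.4f (residual %.3g)",
                 pH, st$residual_norm))
  pro <- .proton_id(model)
  h <- 10^(-pH)
  sum(model$stoich[, pro] * st$species_conc) + h - 10^(-model$pKw) / h
}

#' Solve the mass-balance speciation problem at fixed pH
#'
#' Finds the free concentrations of all non-proton components such that, for
#' every component, the analytical (total) concentration equals the
#' stoichiometry-weighted sum of all species concentrations.  The free
#' proton concentration is fixed by the pH (glass-electrode convention:
#' pH = -log10 of the proton *concentration*), and the proton mass balance
#' is not solved in this mode.
#'
#' Newton-Raphson iteration is performed on the logarithms of the free
#' concentrations with step clamping (1 log unit) and damped backtracking;
#' components with zero total, and species containing them, are excluded.
#'
#' @param model A [build_model()] / [bundled_model()] object.
#' @param totals Named numeric vector of analytical concentrations (mol/L)
#'   for non-proton components; omitted components default to 0.
#' @param pH Fixed pH, in (0, pKw).
#' @param free_init Optional warm start: named vector of free concentrations
#'   (mol/L) for the non-proton components, e.g. the `free` element of a
#'   previous solution.
#' @param tol Relative mass-balance tolerance (default 1e-10).
#' @param maxit Maximum Newton iterations (default 200).
#' @return An object of class `"solution_state"`: list with `pH`, `free`
#'   (named, all components), `species_conc` (named, mol/L), `converged`,
#'   `residual_norm`.
#' @examples
#' m <- bundled_model("Cu_Tyr")
#' s <- solve_speciation(m, c(Cu = 1e-3, Tyr = 2e-3), pH = 3)
#' sort(s$species_conc, decreasing = TRUE)[1:3]
#' @export
solve_speciation <- function(model, totals, pH, free_init = NULL,
                             tol = 1e-10, maxit = 200L) {
  stopifnot(inherits(model, "speciation_model"), is.numeric(totals),
            !is.null(names(totals)), length(pH) == 1L, is.finite(pH))
  if (pH <= 0 || pH >= model$pKw)
    stop(sprintf("pH must lie in (0, pKw = %.2f)", model$pKw))
  bad <- setdiff(names(totals), .nonproton_ids(model))
  if (length(bad))
    stop("totals name unknown non-proton component(s): ",
         paste(bad, collapse = ", "))
  if (any(totals < 0)) stop("totals must be nonnegative")
  if (all(totals <= 0)) stop("at least one component total must be positive")
  x0 <- NULL
  if (!is.null(free_init)) {
    keep <- .nonproton_ids(model)
    keep <- keep[keep %in% names(free_init)]
    fi <- free_init[keep]
    if (all(is.finite(fi)) && all(fi > 0)) x0 <- log10(fi)
  }
  st <- .solve_fixed_pH(model, totals, pH, x0 = x0, tol = tol, maxit = maxit)
  if (!st$converged)
    stop(sprintf("speciation solve did not converge at pH %.4f (relative residual %.3g after %d iterations)",
                 pH, st$residual_norm, maxit))
  structure(list(pH = pH, free = st$free, species_conc = st$species_conc,
                 converged = st$converged, residual_norm = st$residual_norm),
            class = "solution_state")
}

#' @export
print.solution_state <- function(x, ...) {
  cat(sprintf("solution state at pH %.3f (converged: %s, residual %.2e)\n",
              x$pH, x$converged, x$residual_norm))
  cat("free (mol/L):\n")
  print(signif(x$free, 5))
  cat("species (mol/L):\n")
  print(signif(sort(x$species_conc, decreasing = TRUE), 5))
  invisible(x)
}

#' Species distribution across a pH range
#'
#' Solves the speciation problem on a regular pH grid (inclusive of both
#' endpoints, warm-starting each point from the previous one) and expresses
#' each species containing the reference component as a percentage of the
#' reference component's total: `100 * nu_ref * c_i / total_ref`.  The free
#' reference component is included as a column named after the component.
#' Percentages referenced to a ligand are obtained by calling the function
#' again with `reference` set to that ligand; they are never mixed into the
#' metal-referenced table.
#'
#' @inheritParams solve_speciation
#' @param pH_min,pH_max,step Grid definition; `pH_min < pH_max`, `step > 0`.
#' @param reference Component id the percentages refer to (default the first
#'   metal component, total Cu(II) in the bundled systems).
#' @return An object of class `"distribution_diagram"`: list with `pH`
#'   (grid), `reference`, `totals`, and `percent`, a matrix with one row per
#'   grid point and one column per reference-containing species (plus the
#'   free reference).
#' @examples
#' m <- bundled_model("Cu_Tyr")
#' d <- distribution(m, c(Cu = 1e-3, Tyr = 2e-3), 2.5, 11, step = 0.05)
#' peak(d, "CuH(Tyr)")
#' @export
distribution <- function(model, totals, pH_min = 2.5, pH_max = 11,
                         step = 0.01,
                         reference = model$components$id[model$components$role == "metal"][1],
                         tol = 1e-10) {
  stopifnot(pH_min < pH_max, step > 0, length(reference) == 1L,
            reference %in% .nonproton_ids(model))
  if (!reference %in% names(totals) || totals[[reference]] <= 0)
    stop(sprintf("reference component '%s' must have a positive total", reference))
  grid <- seq(pH_min, pH_max, by = step)
  S <- model$stoich
  nu_ref <- S[, reference]
  cols <- c(rownames(S)[nu_ref != 0], reference)
  pct <- matrix(NA_real_, length(grid), length(cols),
                dimnames = list(NULL, cols))
  warm <- NULL
  for (i in seq_along(grid)) {
    st <- tryCatch(
      solve_speciation(model, totals, grid[i], free_init = warm, tol = tol),
      error = function(e)
        stop(sprintf("distribution failed at pH %.3f: %s", grid[i],
                     conditionMessage(e)), call. = FALSE))
    warm <- st$free
    vals <- c(st$species_conc[rownames(S)[nu_ref != 0]] *
                nu_ref[nu_ref != 0],
              st$free[[reference]])
    pct[i, ] <- 100 * vals / totals[[reference]]
  }
  structure(list(pH = grid, reference = reference, totals = totals,
                 percent = pct),
            class = "distribution_diagram")
}

#' @export
print.distribution_diagram <- function(x, ...) {
  cat(sprintf("distribution diagram: %d pH points in [%.2f, %.2f], reference '%s'\n",
              length(x$pH), min(x$pH), max(x$pH), x$reference))
  pk <- t(vapply(colnames(x$percent), function(s) unlist(peak(x, s)),
                 numeric(2)))
  print(round(pk, 2))
  invisible(x)
}

#' @export
plot.distribution_diagram <- function(x, ...) {
  graphics::matplot(x$pH, x$percent, type = "l", lty = 1, xlab = "pH",
                    ylab = sprintf("%% of total %s", x$reference), ...)
  graphics::legend("right", legend = colnames(x$percent), lty = 1,
                   col = seq_len(ncol(x$percent)), cex = 0.7, bty = "n")
  invisible(x)
}

#' Most abundant complex at a given pH
#'
#' Returns the reference-containing species with the largest percentage at
#' the grid point nearest to `pH`.  The free reference component is excluded
#' unless the diagram contains no complex species.  Ties are broken by
#' lexicographic species name, with a warning.
#'
#' @param diagram A [distribution()] result.
#' @param pH pH value within the diagram's grid range.
#' @return Species name (character scalar).
#' @examples
#' m <- bundled_model("Cu_Tyr")
#' d <- distribution(m, c(Cu = 1e-3, Tyr = 2e-3), 2.5, 11, step = 0.05)
#' dominant_species(d, 10.2)
#' @export
dominant_species <- function(diagram, pH) {
  stopifnot(inherits(diagram, "distribution_diagram"), length(pH) == 1L)
  if (pH < min(diagram$pH) - 1e-9 || pH > max(diagram$pH) + 1e-9)
    stop(sprintf("pH %.3f outside diagram grid [%.3f, %.3f]", pH,
                 min(diagram$pH), max(diagram$pH)))
  i <- which.min(abs(diagram$pH - pH))
  cand <- setdiff(colnames(diagram$percent), diagram$reference)
  if (!length(cand)) cand <- diagram$reference
  v <- diagram$percent[i, cand]
  top <- cand[v == max(v)]
  if (length(top) > 1L) {
    warning("tie between species ", paste(top, collapse = ", "),
            "; returning the lexicographically first")
    top <- sort(top)[1]
  }
  top[which.max(diagram$percent[i, top])]
}

#' Peak of a species in a distribution diagram
#'
#' @param diagram A [distribution()] result.
#' @param species Species (or free-reference) column name.
#' @return List with `pH_at_max` and `max_percent` (grid argmax; for a
#'   species identically zero this is the first grid point with 0 percent).
#' @examples
#' m <- bundled_model("Cu_Tyr")
#' d <- distribution(m, c(Cu = 1e-3, Tyr = 2e-3), 2.5, 11, step = 0.05)
#' dominant_species(d, 3.0)
#' @export
peak <- function(diagram, species) {
  stopifnot(inherits(diagram, "distribution_diagram"))
  if (!species %in% colnames(diagram$percent))
    stop(sprintf("unknown species '%s' in diagram", species))
  i <- which.max(diagram$percent[, species])
  list(pH_at_max = diagram$pH[i],
       max_percent = unname(diagram$percent[i, species]))
}
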