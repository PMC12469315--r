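# Potentiometric titration simulation: strong base (NaOH) added to an
# acidified metal/ligand solution; at each titrant volume the diluted totals
# and the remaining titratable acidity define a full proton-condition solve.

#' Describe a potentiometric titration experiment
#'
#' Encodes the experiment as data: initial volume, titrant strength, the
#' strong-acid content, the analytical millimoles of each component placed
#' in the vessel, and the proton content the ligands carry as weighed
#' (e.g. zwitterionic tyrosine contributes two titratable protons per mole
#' relative to the fully deprotonated reference form).  Counterions are
#' treated as inert spectators.
#'
#' @param component_mmol Named numeric vector: analytical millimoles of each
#'   non-proton component in the initial solution.
#' @param acid_mmol Millimoles of strong mineral acid initially present.
#' @param v0_mL Initial sample volume in mL (default 30).
#' @param titrant_conc_M Concentration of the NaOH titrant in mol/L
#'   (default 0.20).
#' @param v_max_mL Final titrant volume in mL.
#' @param n_points Number of readings, uniform in titrant volume
#'   (default 250).
#' @param ligand_protons Named numeric vector: titratable protons delivered
#'   per mole of each component as weighed; missing components default to 0.
#' @return An object of class `"titration_protocol"`.
#' @examples
#' titration_protocol(c(Cu = 0.03, Tyr = 0.06), acid_mmol = 0.1,
#'                    v_max_mL = 2, ligand_protons = c(Tyr = 2))
#' @export
titration_protocol <- function(component_mmol, acid_mmol, v0_mL = 30,
                               titrant_conc_M = 0.20, v_max_mL,
                               n_points = 250L, ligand_protons = NULL) {
  stopifnot(is.numeric(component_mmol), !is.null(names(component_mmol)),
            all(component_mmol >= 0), length(acid_mmol) == 1L,
            v0_mL > 0, titrant_conc_M > 0, v_max_mL > 0, n_points >= 2L)
  lp <- setNames(numeric(length(component_mmol)), names(component_mmol))
  if (!is.null(ligand_protons)) {
    stopifnot(!is.null(names(ligand_protons)))
    lp[names(ligand_protons)] <- as.numeric(ligand_protons)
  }
  structure(list(v0_mL = v0_mL, titrant_conc_M = titrant_conc_M,
                 acid_mmol = as.numeric(acid_mmol),
                 component_mmol = component_mmol,
                 ligand_protons = lp, v_max_mL = v_max_mL,
                 n_points = as.integer(n_points)),
            class = "titration_protocol")
}

#' @export
print.titration_protocol <- function(x, ...) {
  cat(sprintf("titration protocol: V0 %.1f mL + up to %.3f mL of %.3f M NaOH (%d points)\n",
              x$v0_mL, x$v_max_mL, x$titrant_conc_M, x$n_points))
  cat(sprintf("  strong acid: %.5f mmol; total titratable H: %.5f mmol\n",
              x$acid_mmol, .total_acid_mmol(x)))
  print(data.frame(mmol = x$component_mmol, protons_as_weighed = x$ligand_protons))
  invisible(x)
}

# total titratable proton initially present, in mmol
.total_acid_mmol <- function(protocol) {
  protocol$acid_mmol + sum(protocol$ligand_protons * protocol$component_mmol)
}

# analytical totals (mol/L) at titrant volume v
.totals_at_volume <- function(protocol, v) {
  protocol$component_mmol / (protocol$v0_mL + v)
}

#' Simulate a potentiometric titration curve
#'
#' For each titrant volume the component totals are diluted by
#' `v0/(v0 + v)`, the added base enters the proton balance as negative
#' acidity, and the pH solves the full proton condition
#' `total titratable H = sum_i sH_i c_i + [H] - Kw/[H]`
#' simultaneously with all component mass balances.  Each point is solved by
#' the damped Newton iteration warm-started from the previous point, with a
#' monotone pH-bracketing fallback.  The returned curve is noise-free.
#'
#' @param model A [build_model()] / [bundled_model()] object.
#' @param protocol A [titration_protocol()].
#' @param volumes Optional explicit titrant volumes (mL); defaults to
#'   `n_points` uniform volumes from 0 to `v_max_mL`.
#' @param tol Relative tolerance on all balances (default 1e-10).
#' @return An object of class `"titration_curve"`: list with `points`
#'   (data frame `v_mL`, `pH`), `protocol`, `noise_sigma_pH = 0`.
#' @examples
#' m <- bundled_model("Cu_Tyr")
#' p <- titration_protocol(c(Cu = 0.03, Tyr = 0.06), acid_mmol = 0.12,
#'                         v_max_mL = 2.5, n_points = 50,
#'                         ligand_protons = c(Tyr = 2))
#' crv <- simulate_titration(m, p)
#' head(crv$points)
#' @export
simulate_titration <- function(model, protocol, volumes = NULL, tol = 1e-10) {
  stopifnot(inherits(model, "speciation_model"),
            inherits(protocol, "titration_protocol"))
  bad <- setdiff(names(protocol$component_mmol), .nonproton_ids(model))
  if (length(bad))
    stop("protocol names component(s) absent from the model: ",
         paste(bad, collapse = ", "))
  if (is.null(volumes))
    volumes <- seq(0, protocol$v_max_mL, length.out = protocol$n_points)
  stopifnot(all(diff(volumes) > 0) || length(volumes) == 1L)
  H0 <- .total_acid_mmol(protocol)
  pH <- numeric(length(volumes))

  # solver context built once per curve: the set of present components is
  # constant along a titration, only the totals are rescaled by dilution
  pro <- .proton_id(model)
  comps <- .nonproton_ids(model)
  mm <- setNames(numeric(length(comps)), comps)
  mm[names(protocol$component_mmol)] <- protocol$component_mmol
  keep <- comps[mm[comps] > 0]
  drop <- setdiff(comps, keep)
  S <- model$stoich
  sp_keep <- if (length(drop))
    rownames(S)[rowSums(S[, drop, drop = FALSE] != 0) == 0] else rownames(S)
  unknowns <- c(keep, pro)
  Su <- rbind(S[sp_keep, unknowns, drop = FALSE],
              OH_ = setNames(as.numeric(unknowns == pro) * -1, unknowns))
  lbu <- c(model$species$log_beta[match(sp_keep, model$species$name)],
           -model$pKw)
  warm <- NULL
  for (i in seq_along(volumes)) {
    v <- volumes[i]
    vt <- protocol$v0_mL + v
    TH <- (H0 - protocol$titrant_conc_M * v) / vt
    if (is.null(warm)) {
      st <- .solve_full(model, mm[keep] / vt, TH, tol = tol)
      if (!st$converged)
        stop(sprintf("proton balance could not be solved at titrant volume %.4f mL (residual %.3g)",
                     v, st$residual_norm))
      warm <- st$x
      pH[i] <- -log10(st$free[[pro]])
      next
    }
    res <- .newton_core(Su, lbu, c(mm[keep] / vt, TH), warm, tol)
    if (!res$converged) {
      st <- .solve_full(model, mm[keep] / vt, TH, x0 = warm, tol = tol)
      if (!st$converged)
        stop(sprintf("proton balance could not be solved at titrant volume %.4f mL (residual %.3g)",
                     v, st$residual_norm))
      res <- list(x = st$x)
    }
    warm <- res$x
    pH[i] <- -warm[length(warm)]
  }
  structure(list(points = data.frame(v_mL = volumes, pH = pH),
                 protocol = protocol, noise_sigma_pH = 0),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("titration curve: %d points, v %.3f-%.3f mL, pH %.2f-%.2f (noise sigma %.4g)\n",
              nrow(x$points), min(x$points$v_mL), max(x$points$v_mL),
              min(x$points$pH), max(x$points$pH), x$noise_sigma_pH))
  invisible(x)
}

#' @export
plot.titration_curve <- function(x, ...) {
  plot(x$points$v_mL, x$points$pH, type = "l", xlab = "titrant volume [mL]",
       ylab = "pH", ...)
  invisible(x)
}

#' Compare two titration curves point-by-point
#'
#' Computes the per-point pH difference `a - b` on the common volume grid
#' (the union of both curves' volumes within the overlapping range, with
#' linear interpolation in volume where the grids differ), the maximum
#' absolute difference, and the first point at which the curves diverge
#' beyond a threshold.
#'
#' @param a,b [simulate_titration()] / [generate_curve()] results.
#' @param threshold Divergence threshold in pH units (default 0.05).
#' @return An object of class `"curve_comparison"`: list with `volume`,
#'   `pH_a`, `pH_b`, `delta_pH`, `max_abs_dpH`, `threshold`, and
#'   `first_divergence` (list with `v_mL` and `pH` of curve `a`, or `NULL`
#'   if the curves never diverge beyond the threshold).
#' @examples
#' m <- bundled_model("Cu_Tyr")
#' p <- titration_protocol(c(Cu = 0.03, Tyr = 0.06), acid_mmol = 0.12,
#'                         v_max_mL = 2.5, n_points = 40,
#'                         ligand_protons = c(Tyr = 2))
#' crv <- simulate_titration(m, p)
#' compare_curves(crv, crv)$max_abs_dpH
#' @export
compare_curves <- function(a, b, threshold = 0.05) {
  stopifnot(inherits(a, "titration_curve"), inherits(b, "titration_curve"))
  lo <- max(min(a$points$v_mL), min(b$points$v_mL))
  hi <- min(max(a$points$v_mL), max(b$points$v_mL))
  if (lo > hi) stop("curves have disjoint volume ranges")
  grid <- sort(unique(c(a$points$v_mL, b$points$v_mL)))
  grid <- grid[grid >= lo - 1e-12 & grid <= hi + 1e-12]
  pa <- stats::approx(a$points$v_mL, a$points$pH, xout = grid, rule = 2)$y
  pb <- stats::approx(b$points$v_mL, b$points$pH, xout = grid, rule = 2)$y
  d <- pa - pb
  idx <- which(abs(d) > threshold)
  firstdiv <- if (length(idx))
    list(v_mL = grid[idx[1]], pH = pa[idx[1]]) else NULL
  structure(list(volume = grid, pH_a = pa, pH_b = pb, delta_pH = d,
                 max_abs_dpH = max(abs(d)), threshold = threshold,
                 first_divergence = firstdiv),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("curve comparison over %d common points: max |dpH| = %.4g\n",
              length(x$volume), x$max_abs_dpH))
  if (is.null(x$first_divergence)) {
    cat(sprintf("no divergence beyond %.3g pH units\n", x$threshold))
  } else {
    cat(sprintf("first divergence > %.3g at v = %.4f mL (pH %.3f)\n",
                x$threshold, x$first_divergence$v_mL, x$first_divergence$pH))
  }
  invisible(x)
}
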