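# Refinement of overall stability constants from potentiometric titration
# curves: Levenberg-Marquardt least squares on pH residuals, with asymptotic
# standard deviations from the scaled inverse normal matrix, and candidate
# species-model ranking.

#' Replace overall stability constants in a model
#'
#' @param model A `"speciation_model"`.
#' @param values Named numeric vector mapping species names to new
#'   `log_beta` values.
#' @return The updated model.
#' @export
set_log_beta <- function(model, values) {
  stopifnot(inherits(model, "speciation_model"), is.numeric(values),
            !is.null(names(values)))
  idx <- match(names(values), model$species$name)
  if (anyNA(idx))
    stop("unknown species: ", paste(names(values)[is.na(idx)], collapse = ", "))
  model$species$log_beta[idx] <- as.numeric(values)
  model
}

# weighted pH residuals (obs - calc) for a set of curves under a model;
# each curve is re-simulated at its own observed volumes and protocol
.pH_residuals <- function(model, curves, weights) {
  res <- lapply(seq_along(curves), function(k) {
    crv <- curves[[k]]
    sim <- simulate_titration(model, crv$protocol, volumes = crv$points$v_mL)
    (crv$points$pH - sim$points$pH) * sqrt(weights[k])
  })
  unlist(res, use.names = FALSE)
}

.curve_weights <- function(curves, weighting) {
  if (weighting == "unit") return(rep(1, length(curves)))
  sig <- vapply(curves, `[[`, numeric(1), "noise_sigma_pH")
  if (any(sig <= 0))
    stop("weighting = 'sigma_pH' requires a positive noise_sigma_pH on every curve")
  1 / sig^2
}

#' Refine overall stability constants from titration curves
#'
#' Minimizes the weighted sum of squared pH residuals
#' `Sigma = sum_i w_i (pH_obs,i - pH_calc,i)^2` over all points of all
#' curves by Levenberg-Marquardt, where `pH_calc` is obtained by
#' re-simulating each curve with the current constants.  Only the species
#' named in `free_species` are refined; every other constant (ligand
#' protonation, auxiliary binary constants) is held fixed, mirroring the
#' usual treatment of ternary-system refinement.  The Jacobian uses central
#' finite differences (step 1e-4 log units) and the reported standard
#' deviations come from the scaled inverse normal matrix,
#' `s^2 (J'WJ)^-1` with `s^2 = Sigma / (n - p)`.
#'
#' @param model Starting `"speciation_model"`; fixed constants are taken
#'   from it.
#' @param curves List of `"titration_curve"` objects (each with >= 2
#'   points).
#' @param free_species Character vector of species whose `log_beta` is
#'   refined.  May be empty: the fit is then a pure evaluation.
#' @param init Optional named starting values for the free constants
#'   (default: the model's current values).
#' @param weighting `"unit"` (default) or `"sigma_pH"`
#'   (`w = 1/sigma_pH^2` per curve).
#' @param max_iter Maximum Levenberg-Marquardt iterations (default 50).
#' @param fd_step Finite-difference step in log10 units (default 1e-4).
#' @param rel_tol Convergence threshold on the relative change of `Sigma`
#'   (default 1e-8); iteration also stops when the gradient infinity norm
#'   falls below `grad_tol`.
#' @param grad_tol Gradient convergence threshold (default 1e-8).
#' @return An object of class `"refinement_result"`: list with
#'   `log_beta_hat` (all model species, refined values substituted),
#'   `sigma` (free species), `Sigma_stat`, `n_iterations`, `converged`,
#'   `rejected_species` (empty here; see [select_model()]), `model` (the
#'   refined model), `n_obs`, `weighting`.
#' @examples
#' \donttest{
#' m <- bundled_model("Cu_Tyr")
#' p <- design_protocol("Cu_Tyr", n_points = 60L)
#' crv <- generate_curve(m, p, noise_model(0, 0))
#' start <- set_log_beta(m, c("CuH(Tyr)" = 18.54 + 0.2))
#' fit <- refine(start, list(crv), "CuH(Tyr)")
#' fit$log_beta_hat["CuH(Tyr)"]
#' }
#' @export
refine <- function(model, curves, free_species, init = NULL,
                   weighting = c("unit", "sigma_pH"), max_iter = 50L,
                   fd_step = 1e-4, rel_tol = 1e-8, grad_tol = 1e-8) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(model, "speciation_model"), is.list(curves),
            length(curves) >= 1L, is.character(free_species))
  ok <- vapply(curves, inherits, logical(1), "titration_curve")
  if (!all(ok)) stop("curves must be a list of titration_curve objects")
  if (any(vapply(curves, function(c) nrow(c$points), integer(1)) < 2L))
    stop("every curve needs at least 2 points")
  missing_sp <- setdiff(free_species, model$species$name)
  if (length(missing_sp))
    stop("free species not in model: ", paste(missing_sp, collapse = ", "))
  w <- .curve_weights(curves, weighting)
  p <- length(free_species)

  theta <- model$species$log_beta[match(free_species, model$species$name)]
  names(theta) <- free_species
  if (!is.null(init)) {
    stopifnot(!is.null(names(init)))
    bad <- setdiff(free_species, names(init))
    if (length(bad) && length(init))
      theta[intersect(names(init), free_species)] <-
        init[intersect(names(init), free_species)]
    else if (!length(bad)) theta[free_species] <- init[free_species]
  }

  resid_at <- function(th) .pH_residuals(set_log_beta(model, th), curves, w)

  r <- resid_at(theta)
  n <- length(r)
  Sigma <- sum(r^2)
  iter <- 0L
  converged <- p == 0L
  lambda <- 1e-3
  A <- NULL

  jac <- function(th) {
    J <- matrix(0, n, p)
    for (j in seq_len(p)) {
      up <- th; up[j] <- up[j] + fd_step
      dn <- th; dn[j] <- dn[j] - fd_step
      J[, j] <- (resid_at(up) - resid_at(dn)) / (2 * fd_step)
    }
    J
  }

  while (p > 0L && iter < max_iter) {
    iter <- iter + 1L
    J <- jac(theta)
    g <- crossprod(J, r)          # half-gradient of Sigma w.r.t. theta
    A <- crossprod(J)
    if (max(abs(g)) < grad_tol) { converged <- TRUE; break }
    accepted <- FALSE
    for (inner in 1:25) {
      D <- diag(pmax(diag(A), 1e-12) * lambda, p)
      delta <- tryCatch(solve(A + D, -g),
                        error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      th_new <- theta + as.numeric(delta)
      r_new <- tryCatch(resid_at(th_new), error = function(e) NULL)
      S_new <- if (is.null(r_new)) Inf else sum(r_new^2)
      if (S_new < Sigma) {
        accepted <- TRUE
        dS <- (Sigma - S_new) / max(Sigma, 1e-300)
        theta <- th_new; r <- r_new; Sigma <- S_new
        lambda <- max(lambda / 10, 1e-12)
        if (dS < rel_tol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!accepted) {
      # cannot decrease Sigma despite maximal damping: either at the
      # optimum (small gradient) or genuinely stuck
      converged <- max(abs(g)) < sqrt(grad_tol)
      if (!converged)
        warning(sprintf("refinement stalled at Sigma = %.6g (gradient %.3g)",
                        Sigma, max(abs(g))))
      break
    }
    if (converged) break
  }

  sigma <- setNames(rep(NA_real_, p), free_species)
  if (p > 0L) {
    if (is.null(A)) A <- crossprod(jac(theta))
    s2 <- if (n > p) Sigma / (n - p) else NaN
    # a parameter whose species has vanished from the fit leaves a null
    # column in the Jacobian: its uncertainty is infinite, not an error
    good <- diag(A) > 1e-10 * max(diag(A), 1e-300)
    sigma[!good] <- Inf
    if (any(good)) {
      Ag <- A[good, good, drop = FALSE]
      covg <- tryCatch(solve(Ag) * s2, error = function(e) {
        bad <- free_species[good][which.min(diag(Ag))]
        stop(sprintf("singular normal matrix (parameter '%s' is not determined by the data)",
                     bad))
      })
      sigma[good] <- sqrt(pmax(diag(covg), 0))
    }
  }

  refined_model <- set_log_beta(model, theta)
  lbh <- setNames(refined_model$species$log_beta, refined_model$species$name)
  structure(list(log_beta_hat = lbh, sigma = sigma, Sigma_stat = Sigma,
                 n_iterations = iter, converged = converged,
                 rejected_species = character(0), model = refined_model,
                 n_obs = n, weighting = weighting),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement: Sigma = %.6g over %d points, %d iterations, converged: %s\n",
              x$Sigma_stat, x$n_obs, x$n_iterations, x$converged))
  if (length(x$sigma)) {
    df <- data.frame(species = names(x$sigma),
                     log_beta = round(x$log_beta_hat[names(x$sigma)], 4),
                     sigma = signif(x$sigma, 3), row.names = NULL)
    print(df, row.names = FALSE)
  }
  if (length(x$rejected_species))
    cat("rejected:", paste(x$rejected_species, collapse = ", "), "\n")
  invisible(x)
}

# maximum formation percentage of each species over a coarse pH scan,
# relative to the total of its own reference component (metal if present,
# otherwise the first component with nonzero stoichiometry)
.max_formation_percent <- function(model, totals, species,
                                   pH_range = c(2.5, 11), step = 0.05) {
  metals <- model$components$id[model$components$role == "metal"]
  refs <- vapply(species, function(s) {
    st <- model$stoich[s, ]
    m <- intersect(metals, names(st)[st != 0])
    if (length(m)) m[1] else {
      nz <- intersect(.nonproton_ids(model), names(st)[st != 0])
      if (length(nz)) nz[1] else NA_character_
    }
  }, character(1))
  out <- setNames(numeric(length(species)), species)
  for (ref in unique(stats::na.omit(refs))) {
    if (!ref %in% names(totals) || totals[[ref]] <= 0) next
    d <- distribution(model, totals, pH_range[1], pH_range[2], step = step,
                      reference = ref)
    for (s in species[which(refs == ref)])
      if (s %in% colnames(d$percent)) out[s] <- max(d$percent[, s])
  }
  out
}

#' Refine and rank candidate species models
#'
#' Refines each candidate against the same set of curves and ranks them by
#' the criterion used for potentiometric model selection: the largest
#' number of accepted species, then the lowest mean standard deviation of
#' the refined constants, then the lowest `Sigma`.  A refined species is
#' flagged in `rejected_species` when its standard deviation exceeds
#' `sigma_max` or its maximal formation percentage (relative to its
#' reference component, scanned over pH 2.5-11) stays below
#' `percent_floor`.
#'
#' @param candidates List of candidate specifications, each a list with
#'   elements `model` (a `"speciation_model"`), `free_species` (character)
#'   and optionally `init` (named numeric starting values).
#' @param curves List of `"titration_curve"` objects shared by all
#'   candidates.
#' @param sigma_max Largest acceptable standard deviation of a refined
#'   `log_beta` (default 0.1).
#' @param percent_floor Smallest formation percentage regarded as a real
#'   species (default 2).
#' @param weighting Passed to [refine()].
#' @return An object of class `"model_selection"`: list of ranked entries,
#'   each with `spec`, `result`, `n_accepted`, `mean_sigma`.
#' @seealso [refine()]
#' @export
select_model <- function(candidates, curves, sigma_max = 0.1,
                         percent_floor = 2, weighting = "unit") {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  entries <- lapply(candidates, function(cand) {
    res <- tryCatch(
      refine(cand$model, curves, cand$free_species, init = cand$init,
             weighting = weighting),
      error = function(e) e)
    if (inherits(res, "error")) return(list(spec = cand, result = res))
    totals0 <- .totals_at_volume(curves[[1]]$protocol, 0)
    maxpct <- .max_formation_percent(res$model, totals0, cand$free_species)
    rej <- cand$free_species[res$sigma[cand$free_species] > sigma_max |
                               maxpct[cand$free_species] < percent_floor]
    res$rejected_species <- rej
    acc <- setdiff(cand$free_species, rej)
    list(spec = cand, result = res, n_accepted = length(acc),
         mean_sigma = if (length(acc)) mean(res$sigma[acc]) else Inf,
         max_percent = maxpct)
  })
  failed <- vapply(entries, function(e) inherits(e$result, "error"), logical(1))
  if (all(failed))
    stop("all candidate models failed to refine: ",
         conditionMessage(entries[[1]]$result))
  ok <- entries[!failed]
  ord <- order(-vapply(ok, `[[`, numeric(1), "n_accepted"),
               vapply(ok, `[[`, numeric(1), "mean_sigma"),
               vapply(ok, function(e) e$result$Sigma_stat, numeric(1)))
  structure(c(ok[ord], entries[failed]), class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  for (i in seq_along(x)) {
    e <- x[[i]]
    if (inherits(e$result, "error")) {
      cat(sprintf("#%d FAILED: %s\n", i, conditionMessage(e$result)))
    } else {
      cat(sprintf("#%d: %d accepted species, mean sigma %.4g, Sigma %.6g%s\n",
                  i, e$n_accepted, e$mean_sigma, e$result$Sigma_stat,
                  if (length(e$result$rejected_species))
                    paste0(" (rejected: ",
                           paste(e$result$rejected_species, collapse = ", "), ")")
                  else ""))
    }
  }
  invisible(x)
}
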