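# Seeded synthetic titration studies with the statistical structure of the
# bundled experiments: 30 mL initial volume, ~0.20 M NaOH, pH window
# 2.5-11.0, ~250 readings per curve, >= 6 replicate curves, i.i.d. Gaussian
# pH noise.  Noise affects only the pH axis; burette volumes are exact.

#' Gaussian pH-noise description
#'
#' @param sigma_pH Per-point standard deviation of the pH reading
#'   (electrode-grade default 0.005).
#' @param seed Integer seed; replicate curves derive their seeds as
#'   `seed + curve index`.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sigma_pH = 0.005, seed = 1L) {
  stopifnot(is.numeric(sigma_pH), length(sigma_pH) == 1L, sigma_pH >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(sigma_pH = as.numeric(sigma_pH), seed = as.integer(seed)),
            class = "noise_model")
}

# evaluate expr under a temporary RNG seed, restoring global state after
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

#' Design the standard titration protocol for a bundled system
#'
#' Builds the concentration design used throughout: binary system at
#' metal:ligand 1:2 with C_Cu = 1e-3 M, ternary systems equimolar 1:1:1 at
#' 1e-3 M each, initial volume 30 mL, ~0.20 M NaOH titrant.  The strong-acid
#' content is solved so that the curve starts at `pH_start`, and the final
#' titrant volume so that it ends at `pH_end` (defaults 2.5 and 11.0, the
#' working pH window).
#'
#' @param system A [bundled_systems()] identifier, or a
#'   `"speciation_model"` accompanied by explicit `component_mmol`.
#' @param component_mmol Optional named millimole vector overriding the
#'   standard design.
#' @param pH_start,pH_end Intended pH at zero and final titrant volume.
#' @param v0_mL,titrant_conc_M,n_points See [titration_protocol()].
#' @return A [titration_protocol()].
#' @examples
#' design_protocol("Cu_Tyr")
#' @export
design_protocol <- function(system, component_mmol = NULL, pH_start = 2.5,
                            pH_end = 11.0, v0_mL = 30, titrant_conc_M = 0.20,
                            n_points = 250L) {
  if (inherits(system, "speciation_model")) {
    model <- system
    if (is.null(component_mmol))
      stop("component_mmol must be given when passing a model directly")
  } else {
    model <- bundled_model(system)
    if (is.null(component_mmol)) {
      second <- setdiff(.nonproton_ids(model), c("Cu", "Tyr"))
      component_mmol <- if (length(second))
        setNames(c(1, 1, 1) * 1e-3 * v0_mL, c("Cu", "Tyr", second))
      else c(Cu = 1e-3, Tyr = 2e-3) * v0_mL
    }
  }
  # titratable protons per mole as weighed: zwitterionic Tyr and the free
  # acids of AMP/ATP carry 2, the ADP mono-salt 1, neutral adenosine 0
  lp_default <- c(Tyr = 2, Ado = 0, AMP = 2, ADP = 1, ATP = 2)
  lp <- lp_default[intersect(names(lp_default), names(component_mmol))]

  totals0 <- component_mmol / v0_mL
  H0 <- .proton_excess_at(model, totals0, pH_start) * v0_mL
  acid <- H0 - sum(lp * component_mmol[names(lp)])
  # final volume: fixed-point iteration on the diluted end-point balance
  v <- 2
  for (k in 1:40) {
    TH_end <- .proton_excess_at(model, component_mmol / (v0_mL + v), pH_end)
    v_new <- (H0 - TH_end * v0_mL) / (titrant_conc_M + TH_end)
    if (abs(v_new - v) < 1e-10) { v <- v_new; break }
    v <- v_new
  }
  titration_protocol(component_mmol = component_mmol, acid_mmol = acid,
                     v0_mL = v0_mL, titrant_conc_M = titrant_conc_M,
                     v_max_mL = v, n_points = n_points, ligand_protons = lp)
}

#' Generate one (optionally noisy) synthetic titration curve
#'
#' [simulate_titration()] output plus i.i.d. Gaussian pH noise.  Identical
#' inputs and seed give bitwise-identical curves; the global RNG state is
#' left untouched.
#'
#' @inheritParams simulate_titration
#' @param noise A [noise_model()].
#' @return A `"titration_curve"` with `noise_sigma_pH` recorded.
#' @examples
#' m <- bundled_model("Cu_Tyr")
#' p <- titration_protocol(c(Cu = 0.03, Tyr = 0.06), acid_mmol = 0.12,
#'                         v_max_mL = 2.5, n_points = 25,
#'                         ligand_protons = c(Tyr = 2))
#' crv <- generate_curve(m, p, noise_model(0.005, seed = 7))
#' @export
generate_curve <- function(model, protocol, noise = noise_model(0, 0),
                           volumes = NULL, tol = 1e-10) {
  stopifnot(inherits(noise, "noise_model"))
  crv <- simulate_titration(model, protocol, volumes = volumes, tol = tol)
  if (noise$sigma_pH > 0) {
    eps <- .with_seed(noise$seed,
                      stats::rnorm(nrow(crv$points), 0, noise$sigma_pH))
    crv$points$pH <- crv$points$pH + eps
  }
  crv$noise_sigma_pH <- noise$sigma_pH
  crv
}

#' Generate a seeded synthetic titration study
#'
#' Builds the standard concentration design for a bundled system (binary
#' 1:2 at C_Cu = 1e-3 M; ternary equimolar at 1e-3 M) and generates
#' `n_curves` replicate noisy curves whose seeds are derived
#' deterministically from the base seed (`seed + curve index`), so the
#' study is reproducible as a whole.
#'
#' @param system A [bundled_systems()] identifier.
#' @param n_curves Number of replicate curves (>= 1; the experimental
#'   design uses at least six).
#' @param noise A [noise_model()].
#' @param protocol Optional [titration_protocol()] override; defaults to
#'   [design_protocol()] for the system.
#' @return An object of class `"synthetic_study"`: list with `system`,
#'   `truth` (the generating model), `protocol`, `curves`, `noise`,
#'   `curve_seeds`.
#' @examples
#' st <- generate_study("Cu_Tyr", n_curves = 2,
#'                      noise = noise_model(0.005, seed = 1),
#'                      protocol = design_protocol("Cu_Tyr", n_points = 25L))
#' length(st$curves)
#' @export
generate_study <- function(system, n_curves = 6L, noise = noise_model(),
                           protocol = NULL) {
  stopifnot(n_curves >= 1L, inherits(noise, "noise_model"))
  truth <- bundled_model(system)
  if (is.null(protocol)) protocol <- design_protocol(system)
  seeds <- noise$seed + seq_len(n_curves)
  curves <- lapply(seeds, function(s)
    generate_curve(truth, protocol, noise_model(noise$sigma_pH, s)))
  structure(list(system = system, truth = truth, protocol = protocol,
                 curves = curves, noise = noise, curve_seeds = seeds),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic study '%s': %d curves x %d points, sigma_pH = %g, base seed %d\n",
              x$system, length(x$curves), nrow(x$curves[[1]]$points),
              x$noise$sigma_pH, x$noise$seed))
  invisible(x)
}
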