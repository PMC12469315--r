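#' Define a model component
#'
#' A component is a basis building block of a speciation model: a metal ion,
#' a ligand in its fully deprotonated reference form, or the proton.  Every
#' complex species is expressed as a stoichiometric combination of
#' components, and every mass balance is written per component.
#'
#' @param id Short unique identifier used in stoichiometries (e.g. `"Cu"`,
#'   `"Tyr"`, `"H"`).
#' @param name Free-text descriptive name; defaults to `id`.
#' @param role One of `"metal"`, `"ligand"`, `"proton"`.  A valid model has
#'   exactly one proton component.
#' @param charge Signed integer charge of the component (informational only;
#'   no charge balance is enforced on species).
#' @return An object of class `"eq_component"`.
#' @seealso [build_model()], [species_def()]
#' @examples
#' component("Cu", "copper(II)", "metal", +2)
#' @export
component <- function(id, name = id, role = c("metal", "ligand", "proton"),
                      charge = 0L) {
  role <- match.arg(role)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(name), length(name) == 1L)
  structure(list(id = id, name = name, role = role,
                 charge = as.integer(charge)),
            class = "eq_component")
}

#' Define a complex or protonated species
#'
#' A species is identified by its stoichiometry in the model components and
#' its overall formation constant, `log_beta`, on the molar concentration
#' scale: `[species] = 10^log_beta * prod_j [free_j]^stoich_j`.
#' Coordinated hydroxide is represented by a proton coefficient of -1 per OH
#' (the standard convention), so hydroxo species can carry negative proton
#' stoichiometry and negative `log_beta`.
#'
#' @param name Unique species name, plain ASCII (e.g. `"CuH2(Tyr)2"`,
#'   `"Cu(Tyr)(ADP)(OH)2"`).
#' @param stoich Named integer vector mapping component ids to signed
#'   stoichiometric coefficients; at least one coefficient must be nonzero.
#' @param log_beta Overall stability constant, base-10 logarithm.
#' @param sigma_log_beta Optional nonnegative standard deviation of
#'   `log_beta` (the "+/-" column of a refinement table).
#' @return An object of class `"eq_species"`.
#' @examples
#' species_def("CuH(Tyr)", c(Cu = 1, Tyr = 1, H = 1), 18.54, 0.03)
#' @export
species_def <- function(name, stoich, log_beta, sigma_log_beta = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(stoich), !is.null(names(stoich)),
            is.numeric(log_beta), length(log_beta) == 1L, is.finite(log_beta))
  structure(list(name = name, stoich = stoich, log_beta = as.numeric(log_beta),
                 sigma_log_beta = as.numeric(sigma_log_beta)),
            class = "eq_species")
}

#' Assemble and validate a speciation model
#'
#' Collects components and species into a `"speciation_model"` object
#' holding the species-by-component stoichiometry matrix, the overall
#' constants, and the medium description (pKw, temperature, ionic
#' strength).  All stability constants are treated as conditional constants
#' at the stated medium; no activity corrections are applied anywhere.
#'
#' @param components List of [component()] objects.
#' @param species List of [species_def()] objects.
#' @param pKw Autoprotolysis constant of water, `-log10([H][OH])` on the
#'   concentration scale.  The default 13.78 is the concentration product
#'   typical of a 0.1 M inert-electrolyte medium.
#' @param temperature_C Temperature in degrees Celsius (informational).
#' @param ionic_strength_M Ionic strength in mol/L (informational).
#' @param validate If `TRUE` (default) the assembled model is checked with
#'   [validate_model()] and assembly fails with all violations listed.
#'   `validate = FALSE` permits building intentionally broken models for
#'   inspection.
#' @return An object of class `"speciation_model"` with elements
#'   `components` (data frame), `species` (data frame with `name`,
#'   `log_beta`, `sigma_log_beta`), `stoich` (integer matrix, species by
#'   components), `pKw`, `temperature_C`, `ionic_strength_M`.
#' @examples
#' m <- build_model(
#'   list(component("M", role = "metal"), component("L", role = "ligand"),
#'        component("H", role = "proton")),
#'   list(species_def("ML", c(M = 1, L = 1), 3)))
#' m
#' @export
build_model <- function(components, species, pKw = 13.78,
                        temperature_C = 20, ionic_strength_M = 0.1,
                        validate = TRUE) {
  if (inherits(components, "eq_component")) components <- list(components)
  if (inherits(species, "eq_species")) species <- list(species)
  stopifnot(is.list(components), length(components) >= 1L, is.list(species))
  ok <- vapply(components, inherits, logical(1), "eq_component")
  if (!all(ok)) stop("`components` must be a list of component() objects")
  ok <- vapply(species, inherits, logical(1), "eq_species")
  if (!all(ok)) stop("`species` must be a list of species_def() objects")

  comp_df <- data.frame(
    id = vapply(components, `[[`, character(1), "id"),
    name = vapply(components, `[[`, character(1), "name"),
    role = vapply(components, `[[`, character(1), "role"),
    charge = vapply(components, `[[`, integer(1), "charge"),
    stringsAsFactors = FALSE)

  sp_names <- vapply(species, `[[`, character(1), "name")
  # matrix columns span declared ids plus any stray stoichiometry keys, so
  # that validate_model() can report undeclared components
  all_keys <- unique(c(comp_df$id,
                       unlist(lapply(species, function(s) names(s$stoich)))))
  stoich <- matrix(0, nrow = length(species), ncol = length(all_keys),
                   dimnames = list(sp_names, all_keys))
  for (i in seq_along(species)) {
    s <- species[[i]]$stoich
    stoich[i, names(s)] <- stoich[i, names(s)] + as.numeric(s)
  }

  model <- structure(list(
    components = comp_df,
    species = data.frame(
      name = sp_names,
      log_beta = vapply(species, `[[`, numeric(1), "log_beta"),
      sigma_log_beta = vapply(species, `[[`, numeric(1), "sigma_log_beta"),
      stringsAsFactors = FALSE, row.names = NULL),
    stoich = stoich,
    pKw = as.numeric(pKw),
    temperature_C = as.numeric(temperature_C),
    ionic_strength_M = as.numeric(ionic_strength_M)),
    class = "speciation_model")

  if (validate) {
    bad <- validate_model(model)
    if (length(bad))
      stop("invalid speciation model:\n  - ", paste(bad, collapse = "\n  - "))
  }
  model
}

#' Validate a speciation model
#'
#' Checks every structural invariant of a model and returns the violations
#' as a character vector (empty when the model is valid).  Violations are
#' reported, never thrown, so the function can be used as a lint step.
#'
#' @param model A `"speciation_model"` (possibly built with
#'   `validate = FALSE`).
#' @return Character vector of human-readable violations; `character(0)` if
#'   the model is valid.
#' @examples
#' validate_model(bundled_model("Cu_Tyr"))
#' @export
validate_model <- function(model) {
  v <- character(0)
  if (!inherits(model, "speciation_model"))
    return("not a speciation_model object")
  cd <- model$components
  if (anyDuplicated(cd$id))
    v <- c(v, sprintf("duplicate component id(s): %s",
                      paste(unique(cd$id[duplicated(cd$id)]), collapse = ", ")))
  npro <- sum(cd$role == "proton")
  if (npro != 1L)
    v <- c(v, sprintf("model must have exactly one proton component (found %d)",
                      npro))
  sp <- model$species
  if (anyDuplicated(sp$name))
    v <- c(v, sprintf("duplicate species name(s): %s",
                      paste(unique(sp$name[duplicated(sp$name)]),
                            collapse = ", ")))
  undeclared <- setdiff(colnames(model$stoich), cd$id)
  if (length(undeclared))
    v <- c(v, sprintf("stoichiometry references undeclared component(s): %s",
                      paste(undeclared, collapse = ", ")))
  if (nrow(model$stoich)) {
    allzero <- rowSums(model$stoich != 0) == 0
    if (any(allzero))
      v <- c(v, sprintf("species with all-zero stoichiometry: %s",
                        paste(rownames(model$stoich)[allzero], collapse = ", ")))
  }
  if (!is.finite(model$pKw) || model$pKw <= 0)
    v <- c(v, "pKw must be a positive real")
  bad_sigma <- !is.na(sp$sigma_log_beta) & sp$sigma_log_beta < 0
  if (any(bad_sigma))
    v <- c(v, sprintf("negative sigma_log_beta for: %s",
                      paste(sp$name[bad_sigma], collapse = ", ")))
  v
}

#' @export
print.speciation_model <- function(x, ...) {
  cat(sprintf("speciation model: %d components, %d species (pKw %.2f, %g C, I = %g M)\n",
              nrow(x$components), nrow(x$species), x$pKw, x$temperature_C,
              x$ionic_strength_M))
  cat("components:", paste(sprintf("%s[%s]", x$components$id,
                                   substr(x$components$role, 1, 1)),
                           collapse = " "), "\n")
  df <- x$species
  df$log_beta <- sprintf("%.2f", df$log_beta)
  print(df, row.names = FALSE)
  invisible(x)
}

# internal: id of the proton component
.proton_id <- function(model) model$components$id[model$components$role == "proton"]

# internal: non-proton component ids
.nonproton_ids <- function(model) model$components$id[model$components$role != "proton"]

#' Remove a component (and all species containing it) from a model
#'
#' Convenience for building reduced reference systems, e.g. the Cu-free
#' ligand-only model used to localize the onset of complex formation in a
#' titration-curve comparison.
#'
#' @param model A `"speciation_model"`.
#' @param id Component id to remove (must not be the proton).
#' @return A validated `"speciation_model"` without the component.
#' @examples
#' drop_component(bundled_model("Cu_Tyr"), "Cu")
#' @export
drop_component <- function(model, id) {
  stopifnot(inherits(model, "speciation_model"), length(id) == 1L)
  if (!id %in% model$components$id)
    stop(sprintf("no component '%s' in model", id))
  if (id == .proton_id(model)) stop("cannot drop the proton component")
  keep_sp <- model$stoich[, id] == 0
  comps <- lapply(which(model$components$id != id), function(i)
    do.call(component, as.list(model$components[i, ])))
  sp <- lapply(which(keep_sp), function(i) {
    st <- model$stoich[i, ]
    species_def(model$species$name[i], st[st != 0 & names(st) != id],
                model$species$log_beta[i], model$species$sigma_log_beta[i])
  })
  build_model(comps, sp, pKw = model$pKw, temperature_C = model$temperature_C,
              ionic_strength_M = model$ionic_strength_M)
}
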