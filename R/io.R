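# Readers and writers for the artifact formats: model JSON, titration CSV
# ("volume_mL,pH"), distribution TSV, study manifest JSON.  All formats are
# plain text; species names are plain ASCII.

#' Write / read a speciation model as JSON
#'
#' The JSON schema has keys `components` (id, name, role, charge),
#' `species` (name, stoich map of nonzero coefficients, log_beta, optional
#' sigma), `pKw`, `temperature_C`, `ionic_strength_M`.  Numbers are written
#' at full precision, so a write/read round trip reproduces `log_beta`
#' bit-exactly.
#'
#' @param model A `"speciation_model"`.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   validated model.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_model(bundled_model("Cu_Tyr"), f)
#' m <- read_model(f)
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "speciation_model"))
  sp <- lapply(seq_len(nrow(model$species)), function(i) {
    st <- model$stoich[i, ]
    st <- st[st != 0]
    out <- list(name = model$species$name[i],
                stoich = as.list(st),
                log_beta = model$species$log_beta[i])
    if (!is.na(model$species$sigma_log_beta[i]))
      out$sigma <- model$species$sigma_log_beta[i]
    out
  })
  comp <- lapply(seq_len(nrow(model$components)), function(i)
    as.list(model$components[i, ]))
  jsonlite::write_json(
    list(components = comp, species = sp, pKw = model$pKw,
         temperature_C = model$temperature_C,
         ionic_strength_M = model$ionic_strength_M),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  stop(sprintf("cannot parse %s: %s", path,
                               conditionMessage(e)), call. = FALSE))
  problems <- character(0)
  for (key in c("components", "species", "pKw"))
    if (is.null(x[[key]]))
      problems <- c(problems, sprintf("missing key '%s'", key))
  if (!is.null(x$components)) {
    for (i in seq_along(x$components))
      for (key in c("id", "role"))
        if (is.null(x$components[[i]][[key]]))
          problems <- c(problems,
                        sprintf("components[%d]: missing '%s'", i, key))
  }
  if (!is.null(x$species)) {
    for (i in seq_along(x$species))
      for (key in c("name", "stoich", "log_beta"))
        if (is.null(x$species[[i]][[key]]))
          problems <- c(problems, sprintf("species[%d]: missing '%s'", i, key))
  }
  if (length(problems))
    stop(sprintf("schema violations in %s:\n  - %s", path,
                 paste(problems, collapse = "\n  - ")))
  comps <- lapply(x$components, function(cc)
    component(cc$id, cc$name %||% cc$id, cc$role, cc$charge %||% 0L))
  sp <- lapply(x$species, function(s)
    species_def(s$name, unlist(s$stoich), s$log_beta,
                s$sigma %||% NA_real_))
  build_model(comps, sp, pKw = x$pKw,
              temperature_C = x$temperature_C %||% NA_real_,
              ionic_strength_M = x$ionic_strength_M %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a titration curve as CSV
#'
#' Two columns `volume_mL,pH`, one header line, 10 decimal places (so a
#' round trip is identical to well below 1e-9 pH units).
#'
#' @param curve A `"titration_curve"`.
#' @param path File path.
#' @return `write_curve` returns `path` invisibly; `read_curve` returns a
#'   `"titration_curve"` (without protocol; attach one for refinement).
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  lines <- c("volume_mL,pH",
             sprintf("%.10f,%.10f", curve$points$v_mL, curve$points$pH))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop(sprintf("curve file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(colnames(df)[1:2], c("volume_mL", "pH")))
    stop(sprintf("%s: expected header 'volume_mL,pH', found '%s'", path,
                 paste(colnames(df), collapse = ",")))
  v <- suppressWarnings(as.numeric(df$volume_mL))
  p <- suppressWarnings(as.numeric(df$pH))
  bad <- which(is.na(v) | is.na(p))
  if (length(bad))
    stop(sprintf("%s: non-numeric cell at data row %d", path, bad[1]))
  nonmono <- which(diff(v) <= 0)
  if (length(nonmono))
    stop(sprintf("%s: volumes not strictly increasing at data row %d", path,
                 nonmono[1] + 1L))
  structure(list(points = data.frame(v_mL = v, pH = p), protocol = NULL,
                 noise_sigma_pH = 0),
            class = "titration_curve")
}

#' Write a distribution diagram as TSV
#'
#' First column `pH`, one column per species (header row of species
#' names), percentages with 4 decimals.
#'
#' @param diagram A [distribution()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(diagram, path) {
  stopifnot(inherits(diagram, "distribution_diagram"))
  df <- data.frame(pH = sprintf("%.4f", diagram$pH),
                   apply(diagram$percent, 2, function(x) sprintf("%.4f", x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic study to a directory
#'
#' One CSV per curve (`curve_01.csv`, ...) plus a `manifest.json` recording
#' the system, protocol, noise model and per-curve seeds.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("curve_%02d.csv", seq_along(study$curves))
  for (i in seq_along(study$curves))
    write_curve(study$curves[[i]], file.path(dir, files[i]))
  p <- study$protocol
  manifest <- list(
    system = study$system,
    protocol = list(v0_mL = p$v0_mL, titrant_conc_M = p$titrant_conc_M,
                    acid_mmol = p$acid_mmol,
                    component_mmol = as.list(p$component_mmol),
                    ligand_protons = as.list(p$ligand_protons),
                    v_max_mL = p$v_max_mL, n_points = p$n_points),
    noise = list(sigma_pH = study$noise$sigma_pH, seed = study$noise$seed),
    curve_seeds = study$curve_seeds, curve_files = files)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a study manifest back into a protocol
#'
#' @param path Path to a `manifest.json` written by [write_study()].
#' @return A list with `protocol` (a [titration_protocol()]), `system`,
#'   `noise`, `curve_files`.
#' @export
read_manifest <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  proto <- titration_protocol(
    component_mmol = unlist(x$protocol$component_mmol),
    acid_mmol = x$protocol$acid_mmol, v0_mL = x$protocol$v0_mL,
    titrant_conc_M = x$protocol$titrant_conc_M,
    v_max_mL = x$protocol$v_max_mL, n_points = x$protocol$n_points,
    ligand_protons = unlist(x$protocol$ligand_protons))
  list(protocol = proto, system = x$system, noise = x$noise,
       curve_files = x$curve_files)
}
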