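# Bundled equilibrium models: Cu(II)/tyrosine binary and
# Cu(II)/tyrosine/nucleoside(-tide) ternary systems at 0.1 M KNO3, 20 C.
# log beta values are conditional overall stability constants on the molar
# concentration scale; hydroxo species use proton stoichiometry -1 per OH.

.bf_components <- list(
  Cu  = c("copper(II)", "metal", 2L),
  Tyr = c("tyrosinate (fully deprotonated L-tyrosine)", "ligand", -2L),
  Ado = c("adenosine (neutral)", "ligand", 0L),
  AMP = c("adenosine-5'-monophosphate (fully deprotonated)", "ligand", -2L),
  ADP = c("adenosine-5'-diphosphate (fully deprotonated)", "ligand", -3L),
  ATP = c("adenosine-5'-triphosphate (fully deprotonated)", "ligand", -4L),
  H   = c("proton", "proton", 1L))

# per-block species tables: name, stoich (Cu, L, H or Cu, Tyr, Lp, H), log beta, sigma
.bf_tyr_block <- list(
  # tyrosine protonation ladder
  list("H(Tyr)",     c(Tyr = 1, H = 1), 10.28, 0.02),
  list("H2(Tyr)",    c(Tyr = 1, H = 2), 19.29, 0.02),
  list("H3(Tyr)",    c(Tyr = 1, H = 3), 21.81, 0.03),
  # binary Cu(II)/Tyr complexes
  list("CuH2(Tyr)",  c(Cu = 1, Tyr = 1, H = 2), 22.39, 0.05),
  list("CuH(Tyr)",   c(Cu = 1, Tyr = 1, H = 1), 18.54, 0.03),
  list("CuH2(Tyr)2", c(Cu = 1, Tyr = 2, H = 2), 35.38, 0.03),
  list("CuH(Tyr)2",  c(Cu = 1, Tyr = 2, H = 1), 25.99, 0.03))

.bf_cu_hydrolysis <- list(
  list("Cu(OH)2", c(Cu = 1, H = -2), -13.13, NA_real_))

.bf_aux_blocks <- list(
  Ado = list(
    list("H(Ado)",       c(Ado = 1, H = 1),   3.92, 0.01),
    list("Cu(Ado)",      c(Cu = 1, Ado = 1),  2.88, 0.15),
    list("Cu(Ado)(OH)2", c(Cu = 1, Ado = 1, H = -2), -11.41, 0.08),
    list("Cu(Ado)(OH)3", c(Cu = 1, Ado = 1, H = -3), -20.92, 0.14)),
  AMP = list(
    list("H(AMP)",      c(AMP = 1, H = 1),  6.43, 0.02),
    list("H2(AMP)",     c(AMP = 1, H = 2), 10.45, 0.02),
    list("Cu(AMP)",     c(Cu = 1, AMP = 1), 3.02, 0.08),
    list("Cu(AMP)(OH)", c(Cu = 1, AMP = 1, H = -1), -3.82, 0.05)),
  ADP = list(
    list("H(ADP)",      c(ADP = 1, H = 1),  6.55, 0.01),
    list("H2(ADP)",     c(ADP = 1, H = 2), 10.63, 0.02),
    list("CuH(ADP)",    c(Cu = 1, ADP = 1, H = 1), 10.84, 0.03),
    list("Cu(ADP)",     c(Cu = 1, ADP = 1),  6.99, 0.06),
    list("Cu(ADP)(OH)", c(Cu = 1, ADP = 1, H = -1), -1.03, 0.02)),
  ATP = list(
    list("H(ATP)",      c(ATP = 1, H = 1),  6.50, 0.01),
    list("H2(ATP)",     c(ATP = 1, H = 2), 10.88, 0.02),
    list("CuH(ATP)",    c(Cu = 1, ATP = 1, H = 1), 10.53, 0.03),
    list("Cu(ATP)",     c(Cu = 1, ATP = 1),  6.63, 0.02),
    list("Cu(ATP)(OH)", c(Cu = 1, ATP = 1, H = -1), -1.25, 0.02)))

.bf_ternary_blocks <- list(
  Ado = list(
    list("Cu(Tyr)H3(Ado)",   c(Cu = 1, Tyr = 1, Ado = 1, H = 3), 31.40, 0.07),
    list("Cu(Tyr)H2(Ado)",   c(Cu = 1, Tyr = 1, Ado = 1, H = 2), 27.77, 0.06),
    list("Cu(Tyr)H(Ado)",    c(Cu = 1, Tyr = 1, Ado = 1, H = 1), 23.15, 0.06),
    list("Cu(Tyr)(Ado)",     c(Cu = 1, Tyr = 1, Ado = 1),        15.19, 0.08),
    list("Cu(Tyr)(Ado)(OH)", c(Cu = 1, Tyr = 1, Ado = 1, H = -1), 5.35, 0.08)),
  AMP = list(
    list("Cu(Tyr)H3(AMP)",   c(Cu = 1, Tyr = 1, AMP = 1, H = 3), 32.11, 0.07),
    list("Cu(Tyr)H2(AMP)",   c(Cu = 1, Tyr = 1, AMP = 1, H = 2), 27.59, 0.07),
    list("Cu(Tyr)H(AMP)",    c(Cu = 1, Tyr = 1, AMP = 1, H = 1), 22.14, 0.03),
    list("Cu(Tyr)(AMP)",     c(Cu = 1, Tyr = 1, AMP = 1),        14.87, 0.04),
    list("Cu(Tyr)(AMP)(OH)", c(Cu = 1, Tyr = 1, AMP = 1, H = -1), 4.62, 0.05)),
  ADP = list(
    list("Cu(Tyr)H3(ADP)",    c(Cu = 1, Tyr = 1, ADP = 1, H = 3), 33.65, 0.03),
    list("Cu(Tyr)H2(ADP)",    c(Cu = 1, Tyr = 1, ADP = 1, H = 2), 29.73, 0.03),
    list("Cu(Tyr)H(ADP)",     c(Cu = 1, Tyr = 1, ADP = 1, H = 1), 25.11, 0.02),
    list("Cu(Tyr)(ADP)",      c(Cu = 1, Tyr = 1, ADP = 1),        19.01, 0.02),
    list("Cu(Tyr)(ADP)(OH)",  c(Cu = 1, Tyr = 1, ADP = 1, H = -1), 10.14, 0.02),
    list("Cu(Tyr)(ADP)(OH)2", c(Cu = 1, Tyr = 1, ADP = 1, H = -2), -0.27, 0.02)),
  ATP = list(
    list("Cu(Tyr)H4(ATP)", c(Cu = 1, Tyr = 1, ATP = 1, H = 4), 38.44, 0.04),
    list("Cu(Tyr)H3(ATP)", c(Cu = 1, Tyr = 1, ATP = 1, H = 3), 34.76, 0.04),
    list("Cu(Tyr)H2(ATP)", c(Cu = 1, Tyr = 1, ATP = 1, H = 2), 30.78, 0.04),
    list("Cu(Tyr)H(ATP)",  c(Cu = 1, Tyr = 1, ATP = 1, H = 1), 24.51, 0.02),
    list("Cu(Tyr)(ATP)",   c(Cu = 1, Tyr = 1, ATP = 1),        14.56, 0.07)))

#' Bundled system identifiers
#'
#' @return Character vector of the identifiers accepted by
#'   [bundled_model()] and [generate_study()].
#' @export
bundled_systems <- function() {
  c("Cu_Tyr", "Cu_Tyr_Ado", "Cu_Tyr_AMP", "Cu_Tyr_ADP", "Cu_Tyr_ATP")
}

#' Bundled equilibrium models
#'
#' Ready-made speciation models for the Cu(II)/tyrosine binary system and
#' the four mixed-ligand Cu(II)/tyrosine/nucleoside(-tide) ternary systems,
#' with the published conditional overall stability constants (0.1 M KNO3,
#' 20 C).  The binary model contains the tyrosine protonation ladder and the
#' four Cu complexes; each ternary model additionally contains the ternary
#' species, the auxiliary second-ligand protonation and binary
#' Cu/second-ligand constants, and Cu(OH)2.
#'
#' The returned object is built afresh on every call and is therefore
#' immutable across calls.
#'
#' @param system One of `"Cu_Tyr"`, `"Cu_Tyr_Ado"`, `"Cu_Tyr_AMP"`,
#'   `"Cu_Tyr_ADP"`, `"Cu_Tyr_ATP"`.
#' @return A validated [build_model()] object.
#' @examples
#' m <- bundled_model("Cu_Tyr")
#' subset(m$species, name == "CuH(Tyr)")
#' @export
bundled_model <- function(system) {
  stopifnot(is.character(system), length(system) == 1L)
  if (!system %in% bundled_systems())
    stop(sprintf("unknown system '%s'; available: %s", system,
                 paste(bundled_systems(), collapse = ", ")))
  second <- if (system == "Cu_Tyr") NULL else sub("^Cu_Tyr_", "", system)
  comp_ids <- c("Cu", "Tyr", second, "H")
  comps <- lapply(comp_ids, function(id) {
    info <- .bf_components[[id]]
    component(id, info[[1]], info[[2]], as.integer(info[[3]]))
  })
  blocks <- .bf_tyr_block
  if (!is.null(second))
    blocks <- c(blocks, .bf_ternary_blocks[[second]],
                .bf_aux_blocks[[second]], .bf_cu_hydrolysis)
  sp <- lapply(blocks, function(b) species_def(b[[1]], b[[2]], b[[3]], b[[4]]))
  build_model(comps, sp, pKw = 13.78, temperature_C = 20,
              ionic_strength_M = 0.1)
}
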