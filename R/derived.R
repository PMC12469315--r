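# Stepwise/equilibrium constants (log Ke) from overall stability constants:
# for a component-balanced reaction, log Ke is the signed sum of the log beta
# values of products minus reactants (free components count as log beta = 0).

# resolve a species or free-component name to its component stoichiometry
# and log beta; water is handled upstream by the parser
.resolve_species <- function(model, name) {
  i <- match(name, model$species$name)
  if (!is.na(i))
    return(list(stoich = model$stoich[i, ], log_beta = model$species$log_beta[i]))
  if (name %in% model$components$id) {
    st <- setNames(numeric(ncol(model$stoich)), colnames(model$stoich))
    st[name] <- 1
    return(list(stoich = st, log_beta = 0))
  }
  stop(sprintf("unknown species '%s' (not a species or free component of the model)",
               name))
}

#' Parse a reaction string
#'
#' Grammar: two sides separated by an equilibrium arrow (the unicode
#' harpoons, `<=>` or `=`); each side is a `+`-separated list of terms; a
#' term is an optional positive integer coefficient followed by a species
#' or free-component name.  Whitespace is ignored.  `H2O` is treated as
#' solvent with unit activity and dropped during parsing, so hydroxo
#' formation reactions written with explicit water balance under the
#' OH = H(-1) convention.
#'
#' @param text Reaction string, e.g.
#'   `"CuH(Tyr) + H(Tyr) = CuH2(Tyr)2"`.
#' @return An object of class `"reaction_spec"`: list with named integer
#'   vectors `reactants` and `products`.  Species-name resolution is
#'   deferred to [log_Ke()].
#' @examples
#' parse_reaction("CuH(Tyr) + H(Tyr) = CuH2(Tyr)2")
#' parse_reaction("Cu(Tyr)(Ado) + H2O = Cu(Tyr)(Ado)(OH) + H")
#' @export
parse_reaction <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  arrows <- c("\u21cc", "<=>", "=")
  sides <- NULL
  for (a in arrows) {
    if (grepl(a, text, fixed = TRUE)) {
      sides <- strsplit(text, a, fixed = TRUE)[[1]]
      if (length(sides) != 2L)
        stop(sprintf("syntax error: expected exactly one '%s' separator in \"%s\"",
                     a, text))
      break
    }
  }
  if (is.null(sides))
    stop(sprintf("syntax error: no equilibrium arrow found in \"%s\"", text))

  parse_side <- function(s, label) {
    terms <- strsplit(s, "+", fixed = TRUE)[[1]]
    if (!length(terms) || !any(nzchar(trimws(terms))))
      stop(sprintf("syntax error: empty %s side in \"%s\"", label, text))
    out <- integer(0)
    for (k in seq_along(terms)) {
      term <- trimws(terms[k])
      if (!nzchar(term))
        stop(sprintf("syntax error: empty term %d on %s side of \"%s\"",
                     k, label, text))
      mm <- regmatches(term, regexec("^([0-9]+)?\\s*(\\S.*?)\\s*$", term))[[1]]
      if (length(mm) != 3L || !nzchar(mm[3]))
        stop(sprintf("syntax error in term %d ('%s') on %s side", k, term, label))
      coef <- if (nzchar(mm[2])) as.integer(mm[2]) else 1L
      name <- mm[3]
      if (name == "H2O") next  # solvent, activity 1
      out[name] <- (if (name %in% names(out)) out[[name]] else 0L) + coef
    }
    out
  }
  structure(list(reactants = parse_side(sides[1], "reactant"),
                 products = parse_side(sides[2], "product")),
            class = "reaction_spec")
}

#' @export
print.reaction_spec <- function(x, ...) {
  fmt <- function(v) paste(ifelse(v > 1, paste0(v, " ", names(v)), names(v)),
                           collapse = " + ")
  cat(fmt(x$reactants), "<=>", fmt(x$products), "\n")
  invisible(x)
}

#' Equilibrium constant of a formation reaction
#'
#' For a reaction balanced in the model components, returns
#' `log Ke = sum(products: coef * log beta) - sum(reactants: coef * log beta)`
#' by exact arithmetic on the stored constants.  Free components have
#' `log beta = 0`; hydroxide enters through the `H(-1)` convention (parse
#' reactions written with `H2O` via [parse_reaction()], which drops the
#' solvent).
#'
#' @param model A `"speciation_model"`.
#' @param reaction A [parse_reaction()] result or a reaction string.
#' @return `log Ke` (numeric scalar).
#' @examples
#' m <- bundled_model("Cu_Tyr")
#' log_Ke(m, "CuH(Tyr) + H(Tyr) = CuH2(Tyr)2")  # 6.56
#' @export
log_Ke <- function(model, reaction) {
  stopifnot(inherits(model, "speciation_model"))
  if (is.character(reaction)) reaction <- parse_reaction(reaction)
  stopifnot(inherits(reaction, "reaction_spec"))
  side_sum <- function(side) {
    st <- setNames(numeric(ncol(model$stoich)), colnames(model$stoich))
    lb <- 0
    for (nm in names(side)) {
      r <- .resolve_species(model, nm)
      st <- st + side[[nm]] * r$stoich
      lb <- lb + side[[nm]] * r$log_beta
    }
    list(st = st, lb = lb)
  }
  lhs <- side_sum(reaction$reactants)
  rhs <- side_sum(reaction$products)
  imbalance <- rhs$st - lhs$st
  if (any(imbalance != 0)) {
    bad <- imbalance[imbalance != 0]
    stop("reaction not balanced in components: ",
         paste(sprintf("%s (%+g)", names(bad), bad), collapse = ", "))
  }
  rhs$lb - lhs$lb
}

#' Stepwise protonation constants of a ligand
#'
#' Extracts the protonation ladder `H(L)`, `H2(L)`, ... of a ligand
#' (species whose stoichiometry is exactly one ligand and `n >= 1` protons)
#' and returns the stepwise constants, highest-pKa step first:
#' `log K1 = log beta_HL`, `log K2 = log beta_H2L - log beta_HL`, ...
#'
#' @param model A `"speciation_model"`.
#' @param ligand Component id of the ligand.
#' @return Named numeric vector of stepwise `log K`, names `HL`, `H2L`, ...
#' @examples
#' stepwise_protonation(bundled_model("Cu_Tyr"), "Tyr")  # 10.28 9.01 2.52
#' @export
stepwise_protonation <- function(model, ligand) {
  stopifnot(inherits(model, "speciation_model"), length(ligand) == 1L)
  if (!ligand %in% .nonproton_ids(model))
    stop(sprintf("unknown ligand component '%s'", ligand))
  pro <- .proton_id(model)
  S <- model$stoich
  others <- setdiff(colnames(S), c(ligand, pro))
  is_ladder <- S[, ligand] == 1 & S[, pro] >= 1 &
    rowSums(S[, others, drop = FALSE] != 0) == 0
  if (!any(is_ladder))
    stop(sprintf("no protonation species found for ligand '%s'", ligand))
  n <- S[is_ladder, pro]
  lb <- model$species$log_beta[match(rownames(S)[is_ladder],
                                     model$species$name)][order(n)]
  n <- sort(n)
  if (!identical(as.numeric(n), as.numeric(seq_along(n))))
    stop(sprintf("protonation ladder for '%s' is not contiguous (found H-counts: %s)",
                 ligand, paste(n, collapse = ", ")))
  setNames(diff(c(0, lb)),
           paste0("H", ifelse(seq_along(n) > 1, seq_along(n), ""), "(", ligand, ")"))
}
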