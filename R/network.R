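#' @useDynLib endonet, .registration = TRUE
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define a model species
#'
#' A species lives in exactly one compartment and carries a composition: a
#' multiset of monomer names with copy counts (e.g. a ligand-induced Tie2
#' cluster is \code{c(Tie2 = 4, Ang1 = 1)}).  Compositions drive both the
#' monomer-balance check on reaction rules and the automatic derivation of
#' conserved pools.
#'
#' @param name Unique species identifier.
#' @param compartment One of \code{"extracellular"}, \code{"surface"},
#'   \code{"junctional"}, \code{"cytosol"}, \code{"ER"}, \code{"internalized"},
#'   \code{"WPB"}.
#' @param composition Named integer vector of monomer copy counts (positive).
#' @param init_key Name of the parameter holding the initial abundance, or
#'   \code{NA} for species that start at zero.
#' @return A \code{species_def} list.
#' @export
species_def <- function(name, compartment,
                        composition = NULL, init_key = NA_character_) {
  comps <- c("extracellular", "surface", "junctional", "cytosol",
             "ER", "internalized", "WPB")
  if (!compartment %in% comps)
    stop("unknown compartment '", compartment, "' for species '", name, "'")
  composition <- composition %||% stats::setNames(integer(0), character(0))
  if (length(composition) && (is.null(names(composition)) ||
                              any(composition <= 0) ||
                              any(composition != round(composition))))
    stop("composition of '", name, "' must be named positive integer counts")
  structure(list(name = name, compartment = compartment,
                 composition = composition, init_key = init_key),
            class = "species_def")
}

#' Define a reaction rule
#'
#' Rules are the unit from which the ODE right-hand side is compiled.  A rule
#' has at most two distinct reactant species; the rate is first order in each
#' listed reactant (lumped cluster-assembly steps consume more copies through
#' the stoichiometry while staying bimolecular in rate).  Enzymatic rules have
#' exactly one substrate plus a modifier (a species or a named observable).
#'
#' @param name Unique rule identifier.
#' @param reactants Named integer vector, species name -> copies consumed
#'   (at most two distinct species; \code{NULL} for synthesis).
#' @param products Named integer vector, species name -> copies produced.
#' @param law \code{"mass_action"}, \code{"michaelis_menten"} (k * E * S/(Km+S),
#'   E the modifier) or \code{"saturating_hill"} (Vmax form k * S/(Km+S)).
#' @param k Character vector of parameter keys whose product (times
#'   \code{scale}) is the rate constant.
#' @param Km Parameter key for the Michaelis constant (enzymatic laws).
#' @param modifier Species or observable name whose level multiplies a
#'   mass-action rate or acts as the enzyme in an enzymatic rate.
#' @param sat List of \code{c(var, K_key)} pairs; each contributes a
#'   multiplicative saturating factor X/(K+X) where X is a species or
#'   observable level.
#' @param scale Fixed numeric multiplier on the rate constant.
#' @param rev Parameter key for the reverse rate constant; the rule is then
#'   expanded into a forward/reverse pair at model assembly.
#' @param non_conserving Set \code{TRUE} for synthesis, degradation and
#'   shedding rules, which are exempt from the monomer-balance check and are
#'   credited separately in [conservation_report()].
#' @param tag Catalytic-node tag (\code{"Src"}, \code{"Axl"}, \code{"Akt"},
#'   \code{"VEGFR2"}) used by inhibitors to scale rate constants.
#' @return A \code{reaction_rule} list.
#' @export
reaction_rule <- function(name, reactants = NULL, products = NULL,
                          law = "mass_action", k, Km = NULL, modifier = NULL,
                          sat = NULL, scale = 1, rev = NULL,
                          non_conserving = FALSE, tag = NA_character_) {
  laws <- c("mass_action", "michaelis_menten", "saturating_hill")
  if (!law %in% laws) stop("unknown rate law '", law, "' in rule '", name, "'")
  reactants <- reactants %||% stats::setNames(integer(0), character(0))
  products <- products %||% stats::setNames(integer(0), character(0))
  if (length(reactants) > 2)
    stop("rule '", name, "' has more than two distinct reactants")
  if (law != "mass_action") {
    if (length(reactants) != 1)
      stop("enzymatic rule '", name, "' must have exactly one substrate")
    if (law == "michaelis_menten" && is.null(modifier))
      stop("michaelis_menten rule '", name, "' needs a modifier (enzyme)")
    if (is.null(Km)) stop("enzymatic rule '", name, "' needs a Km key")
  }
  structure(list(name = name, reactants = reactants, products = products,
                 law = law, k = k, Km = Km, modifier = modifier,
                 sat = sat, scale = scale, rev = rev,
                 non_conserving = non_conserving, tag = tag),
            class = "reaction_rule")
}

#' Construct a parameter set
#'
#' @param values Named numeric vector of strictly positive (or zero, for
#'   optional fluxes) parameter values.
#' @param bounds Optional named list of \code{c(lo, hi)} pairs; defaults to
#'   \code{[value/100, value*100]} for positive entries.
#' @param meta Optional named character vector of source tags
#'   (\code{"calibrated"}, \code{"literature"}, \code{"fixed"}).
#' @return A \code{parameter_set} object.
#' @export
parameter_set <- function(values, bounds = NULL, meta = NULL) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("all parameters must be named")
  if (anyDuplicated(names(values))) stop("duplicate parameter names")
  if (any(!is.finite(values)) || any(values < 0))
    stop("parameter values must be finite and non-negative")
  nm <- names(values)
  if (is.null(bounds)) {
    bounds <- lapply(nm, function(n) {
      v <- values[[n]]
      if (v > 0) c(v / 100, v * 100) else c(0, 1)
    })
    names(bounds) <- nm
  }
  meta <- meta %||% stats::setNames(rep("calibrated", length(nm)), nm)
  for (n in names(bounds)) {
    b <- bounds[[n]]
    if (n %in% nm && (values[[n]] < b[1] - 1e-12 || values[[n]] > b[2] + 1e-12))
      stop("parameter '", n, "' outside its bounds")
  }
  structure(list(values = values, bounds = bounds, meta = meta),
            class = "parameter_set")
}

#' Update values in a parameter set
#' @param params A [parameter_set()].
#' @param updates Named numeric vector of replacement values.
#' @return The modified parameter set.
#' @export
update_params <- function(params, updates) {
  stopifnot(inherits(params, "parameter_set"))
  bad <- setdiff(names(updates), names(params$values))
  if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  params$values[names(updates)] <- updates
  params
}

#' Specify an inhibitor
#'
#' Inhibitors are instantaneous activity scalings: from \code{apply_time}
#' onward every rate constant tagged with the target node is multiplied by
#' \code{1 - fraction}.
#'
#' @param target One of \code{"Src"}, \code{"Axl"}, \code{"Akt"},
#'   \code{"VEGFR2"}.
#' @param fraction Inhibition fraction in \code{[0, 1]}.
#' @param apply_time Application time in minutes (default 0).
#' @return An \code{inhibitor_spec} list.
#' @export
inhibitor_spec <- function(target, fraction, apply_time = 0) {
  if (!target %in% c("Src", "Axl", "Akt", "VEGFR2"))
    stop("unknown inhibitor target '", target, "'")
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("inhibition fraction must lie in [0, 1]")
  structure(list(target = target, fraction = fraction,
                 apply_time = apply_time), class = "inhibitor_spec")
}

.expand_rules <- function(rules) {
  out <- list()
  for (r in rules) {
    if (!is.null(r$rev)) {
      fwd <- r
      fwd$rev <- NULL
      fwd$name <- paste0(r$name, "_f")
      bwd <- reaction_rule(paste0(r$name, "_r"),
                           reactants = r$products, products = r$reactants,
                           law = "mass_action", k = r$rev,
                           non_conserving = r$non_conserving, tag = r$tag)
      out <- c(out, list(fwd, bwd))
    } else {
      out <- c(out, list(r))
    }
  }
  out
}

.rule_balance <- function(rule, comp) {
  tally <- function(side) {
    tot <- stats::setNames(numeric(0), character(0))
    for (s in names(side)) {
      cc <- comp[[s]]
      if (!length(cc)) next
      for (m in names(cc)) tot[m] <- (if (m %in% names(tot)) tot[m] else 0) +
          side[[s]] * cc[[m]]
    }
    tot
  }
  lhs <- tally(rule$reactants)
  rhs <- tally(rule$products)
  mons <- union(names(lhs), names(rhs))
  get0n <- function(v, m) if (m %in% names(v)) v[[m]] else 0
  all(vapply(mons, function(m) get0n(lhs, m) == get0n(rhs, m), logical(1)))
}

#' Assemble a network model
#'
#' Expands reversible rules into forward/reverse pairs, builds the species-by-
#' reaction stoichiometry matrix, verifies monomer balance of every rule not
#' flagged \code{non_conserving}, checks that every referenced parameter key
#' resolves, and derives conserved pools from species compositions.
#'
#' @param species List of [species_def()] objects.
#' @param rules List of [reaction_rule()] objects.
#' @param observables Named list; each entry a named numeric vector of species
#'   weights.  Observables may be referenced by rules as modifiers.
#' @param params A [parameter_set()] used to validate key references.
#' @param config Optional list recording which sub-modules were included.
#' @return A \code{network_model} object.
#' @export
network_model <- function(species, rules, observables, params,
                          config = list()) {
  sp_names <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(sp_names)) stop("duplicate species names")
  comp <- stats::setNames(lapply(species, `[[`, "composition"), sp_names)

  rules <- .expand_rules(rules)
  rnames <- vapply(rules, `[[`, character(1), "name")
  if (anyDuplicated(rnames)) stop("duplicate rule names")

  # reference checks
  for (r in rules) {
    refs <- c(names(r$reactants), names(r$products))
    bad <- setdiff(refs, sp_names)
    if (length(bad))
      stop("rule '", r$name, "' references unknown species: ",
           paste(bad, collapse = ", "))
    if (!is.null(r$modifier) &&
        !(r$modifier %in% sp_names || r$modifier %in% names(observables)))
      stop("rule '", r$name, "' has unknown modifier '", r$modifier, "'")
    for (s in r$sat %||% list())
      if (!(s[[1]] %in% sp_names || s[[1]] %in% names(observables)))
        stop("rule '", r$name, "' has unknown saturation variable '",
             s[[1]], "'")
    keys <- c(r$k, r$Km, vapply(r$sat %||% list(), `[[`, character(1), 2))
    missing <- setdiff(keys, names(params$values))
    if (length(missing))
      stop("rule '", r$name, "' references missing parameter key(s): ",
           paste(missing, collapse = ", "))
    if (!r$non_conserving && !.rule_balance(r, comp))
      stop("rule '", r$name,
           "' violates monomer balance and is not flagged non_conserving")
  }
  for (s in species)
    if (!is.na(s$init_key) && !s$init_key %in% names(params$values))
      stop("species '", s$name, "' has missing initial-value key '",
           s$init_key, "'")
  for (o in names(observables)) {
    bad <- setdiff(names(observables[[o]]), sp_names)
    if (length(bad))
      stop("observable '", o, "' references unknown species: ",
           paste(bad, collapse = ", "))
  }

  # stoichiometry matrix (species x reaction)
  S <- matrix(0, nrow = length(species), ncol = length(rules),
              dimnames = list(sp_names, rnames))
  for (j in seq_along(rules)) {
    r <- rules[[j]]
    for (s in names(r$reactants)) S[s, j] <- S[s, j] - r$reactants[[s]]
    for (s in names(r$products)) S[s, j] <- S[s, j] + r$products[[s]]
  }

  # conserved pools: one per monomer name
  monomers <- unique(unlist(lapply(comp, names)))
  pools <- lapply(monomers, function(m) {
    mult <- vapply(sp_names, function(s) {
      cc <- comp[[s]]
      if (m %in% names(cc)) as.numeric(cc[[m]]) else 0
    }, numeric(1))
    mult[mult > 0]
  })
  names(pools) <- monomers

  structure(list(species = species, species_names = sp_names,
                 rules = rules, rule_names = rnames,
                 stoichiometry = S, observables = observables,
                 conserved_pools = pools, composition = comp,
                 inhibitors = list(), config = config),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", length(x$species), " species, ",
      length(x$rules), " reactions, ", length(x$observables),
      " observables, ", length(x$conserved_pools), " conserved pools\n",
      sep = "")
  if (length(x$inhibitors))
    for (i in x$inhibitors)
      cat("  inhibitor: ", i$target, " fraction ", i$fraction,
          " from t=", i$apply_time, " min\n", sep = "")
  invisible(x)
}

#' Apply an inhibitor to a model
#'
#' Returns a copy of the model whose target node's tagged activation and
#' catalytic rate constants are scaled by \code{1 - fraction} from
#' \code{apply_time} onward (the simulator splits the integration at that
#' time).  Rules are otherwise untouched.
#'
#' @param model A [network_model()].
#' @param spec An [inhibitor_spec()].
#' @return The model with the inhibitor registered.
#' @export
apply_inhibitor <- function(model, spec) {
  stopifnot(inherits(model, "network_model"), inherits(spec, "inhibitor_spec"))
  tags <- vapply(model$rules, `[[`, character(1), "tag")
  if (!spec$target %in% tags)
    stop("model has no rules tagged for target '", spec$target, "'")
  model$inhibitors <- c(model$inhibitors, list(spec))
  model
}

#' Flag negative entries in a state vector
#'
#' The right-hand side remains defined for (slightly) negative states, but
#' callers can use this utility to detect them.
#'
#' @param state Named numeric state vector.
#' @param tol Absolute tolerance below zero that is still accepted.
#' @return Character vector of offending species names (empty if none).
#' @export
validate_state <- function(state, tol = 1e-9) {
  names(state)[state < -tol]
}
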