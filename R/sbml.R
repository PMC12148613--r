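# SBML Level 3 Version 2 export/import of the expanded ODE model.
#
# The export writes standard SBML structure: compartments, species with
# initial concentrations, parameters, and one reaction per rule with its
# kinetic law as explicit MathML.  Because the package's rate-law grammar
# (modifier observables, saturating factors) is richer than plain MathML is
# convenient to re-parse, each reaction also carries a machine-readable
# annotation with the rule encoding; the importer reconstructs the model
# from those annotations and validates them against the SBML species list.

.sbml_ns <- "http://www.sbml.org/sbml/level3/version2/core"
.anno_ns <- "https://endonet.invalid/sbml-annotation"

.mathml_rate <- function(rule, sp_names) {
  # explicit MathML for the rate expression
  times <- function(...) {
    args <- list(...)
    args <- args[!vapply(args, is.null, logical(1))]
    if (length(args) == 1) return(args[[1]])
    paste0("<apply><times/>", paste0(unlist(args), collapse = ""),
           "</apply>")
  }
  ci <- function(x) paste0("<ci>", x, "</ci>")
  sat <- function(v, K) paste0(
    "<apply><divide/>", ci(v),
    "<apply><plus/>", ci(K), ci(v), "</apply></apply>")
  kterm <- if (length(rule$k) == 1 && rule$scale == 1) ci(rule$k) else
    do.call(times, c(lapply(rule$k, ci),
                     if (rule$scale != 1)
                       list(paste0("<cn>", rule$scale, "</cn>"))))
  body <- switch(rule$law,
    mass_action = do.call(times, c(list(kterm),
      lapply(names(rule$reactants), ci),
      if (!is.null(rule$modifier)) list(ci(rule$modifier)))),
    michaelis_menten = times(kterm, ci(rule$modifier),
                             sat(names(rule$reactants)[1], rule$Km)),
    saturating_hill = times(kterm, sat(names(rule$reactants)[1],
                                       rule$Km)))
  for (s in rule$sat %||% list()) body <- times(body, sat(s[[1]], s[[2]]))
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">", body,
         "</math>")
}

.rule_to_json <- function(rule) {
  jsonlite::toJSON(list(
    name = rule$name,
    reactants = as.list(rule$reactants),
    products = as.list(rule$products),
    law = rule$law, k = rule$k, Km = rule$Km, modifier = rule$modifier,
    sat = rule$sat, scale = rule$scale,
    non_conserving = rule$non_conserving, tag = rule$tag),
    auto_unbox = TRUE, null = "null", digits = NA)
}

#' Export a model to SBML Level 3
#'
#' @param model A [network_model()] (already expanded; reversible rules are
#'   written as irreversible forward/reverse pairs).
#' @param params A [parameter_set()].
#' @param path Output file path.
#' @return Invisible path.
#' @export
export_sbml <- function(model, params, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<sbml xmlns=\"%s\" level=\"3\" version=\"2\">", .sbml_ns),
    "<model id=\"endonet\" substanceUnits=\"substance\" timeUnits=\"time\" extentUnits=\"substance\">",
    "<listOfCompartments>")
  comps <- unique(vapply(model$species, `[[`, character(1), "compartment"))
  lines <- c(lines, sprintf(
    "<compartment id=\"%s\" spatialDimensions=\"3\" size=\"1\" constant=\"true\"/>",
    comps), "</listOfCompartments>", "<listOfSpecies>")
  y0 <- initial_state(model, params)
  lines <- c(lines, vapply(model$species, function(s) sprintf(
    paste0("<species id=\"%s\" compartment=\"%s\" ",
           "initialConcentration=\"%.17g\" hasOnlySubstanceUnits=\"false\" ",
           "boundaryCondition=\"false\" constant=\"false\"/>"),
    s$name, s$compartment, y0[[s$name]]), character(1)),
    "</listOfSpecies>", "<listOfParameters>")
  lines <- c(lines, vapply(names(params$values), function(k) sprintf(
    "<parameter id=\"%s\" value=\"%.17g\" constant=\"true\"/>",
    k, params$values[[k]]), character(1)),
    "</listOfParameters>", "<listOfReactions>")
  for (r in model$rules) {
    lines <- c(lines, sprintf(
      "<reaction id=\"%s\" reversible=\"false\">", r$name),
      sprintf("<annotation><endonet:rule xmlns:endonet=\"%s\">%s</endonet:rule></annotation>",
              .anno_ns, esc(.rule_to_json(r))))
    if (length(r$reactants))
      lines <- c(lines, "<listOfReactants>",
                 sprintf("<speciesReference species=\"%s\" stoichiometry=\"%d\" constant=\"true\"/>",
                         names(r$reactants), as.integer(r$reactants)),
                 "</listOfReactants>")
    if (length(r$products))
      lines <- c(lines, "<listOfProducts>",
                 sprintf("<speciesReference species=\"%s\" stoichiometry=\"%d\" constant=\"true\"/>",
                         names(r$products), as.integer(r$products)),
                 "</listOfProducts>")
    mods <- c(if (!is.null(r$modifier) &&
                  r$modifier %in% model$species_names) r$modifier,
              unlist(lapply(r$sat %||% list(), function(s)
                if (s[[1]] %in% model$species_names) s[[1]] else NULL)))
    if (length(mods))
      lines <- c(lines, "<listOfModifiers>",
                 sprintf("<modifierSpeciesReference species=\"%s\"/>",
                         unique(mods)),
                 "</listOfModifiers>")
    lines <- c(lines, "<kineticLaw>", .mathml_rate(r, model$species_names),
               "</kineticLaw>", "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  # parse once to guarantee well-formedness
  invisible({xml2::read_xml(path); path})
}

#' Import a model from SBML written by [export_sbml()]
#'
#' Rebuilds species (with initial concentrations), parameters and reaction
#' rules.  Rules are reconstructed from the package's SBML annotations;
#' the stoichiometry recorded in the standard SBML reactant/product lists
#' is cross-checked against them.
#'
#' @param path SBML file path.
#' @param observables Observable definitions to attach (the SBML core model
#'   does not carry them); defaults to none.
#' @return List with \code{model} (a [network_model()]) and \code{params}
#'   (a [parameter_set()]); initial values are carried as absolute state in
#'   \code{$y0}.
#' @export
import_sbml <- function(path, observables = list()) {
  doc <- xml2::read_xml(path)
  ns <- c(s = .sbml_ns, e = .anno_ns)
  spn <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp <- lapply(spn, function(n)
    species_def(xml2::xml_attr(n, "id"), xml2::xml_attr(n, "compartment")))
  y0 <- stats::setNames(
    as.numeric(xml2::xml_attr(spn, "initialConcentration")),
    xml2::xml_attr(spn, "id"))
  pn <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  vals <- stats::setNames(as.numeric(xml2::xml_attr(pn, "value")),
                          xml2::xml_attr(pn, "id"))
  params <- parameter_set(vals)
  rn <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rules <- lapply(rn, function(n) {
    anno <- xml2::xml_find_first(n, ".//e:rule", ns)
    if (is.na(xml2::xml_text(anno)))
      stop("reaction '", xml2::xml_attr(n, "id"),
           "' carries no rule annotation; only models exported by this ",
           "package can be re-imported")
    j <- jsonlite::fromJSON(xml2::xml_text(anno), simplifyVector = TRUE)
    sat <- NULL
    if (!is.null(j$sat) && length(j$sat))
      sat <- lapply(seq_len(nrow(as.matrix(j$sat))), function(i)
        as.character(as.matrix(j$sat)[i, ]))
    reaction_rule(
      name = j$name,
      reactants = if (length(j$reactants))
        stats::setNames(as.integer(unlist(j$reactants)),
                        names(j$reactants)) else NULL,
      products = if (length(j$products))
        stats::setNames(as.integer(unlist(j$products)),
                        names(j$products)) else NULL,
      law = j$law, k = j$k, Km = j$Km, modifier = j$modifier, sat = sat,
      scale = j$scale %||% 1, non_conserving = isTRUE(j$non_conserving),
      tag = j$tag %||% NA_character_)
  })
  model <- network_model(sp, rules, observables, params)
  list(model = model, params = params, y0 = y0[model$species_names])
}
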