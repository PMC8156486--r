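#' Export a reaction network to SBML Level 3
#'
#' Writes an SBML Level 3 Version 2 document with one compartment, the
#' network's species (with initial concentrations, if supplied), and one
#' irreversible SBML reaction per directed reaction: mass-action kinetic
#' laws `k * prod(u_i^sigma_i)` with a local parameter `k`, and
#' Michaelis--Menten laws `v_max * u_S / (kappa_m + u_S)` with local
#' `v_max` and `kappa_m`. Constant sources/sinks are exported as reactions
#' with an empty reactant (source) or product (sink) side and a constant
#' kinetic law. Export is one way; the written numbers use full double
#' precision so that parsing the document back reproduces the dynamics to
#' `1e-9` or better.
#'
#' @param network a [reaction_network()].
#' @param path output file path.
#' @param u0 optional named initial concentrations.
#' @param model_id SBML model id.
#' @return invisibly, the path.
#' @export
write_sbml <- function(network, path, u0 = NULL, model_id = "catflow_model") {
  num <- function(x) sprintf("%.17g", x)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mod <- xml2::xml_add_child(doc, "model", id = model_id)
  comp <- xml2::xml_add_child(mod, "listOfCompartments")
  xml2::xml_add_child(comp, "compartment", id = "cell", size = "1",
                      spatialDimensions = "3", constant = "true")
  los <- xml2::xml_add_child(mod, "listOfSpecies")
  for (sp in network$species)
    xml2::xml_add_child(los, "species", id = sp, compartment = "cell",
                        initialConcentration =
                          num(if (!is.null(u0)) u0[[sp]] else 0),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  lor <- xml2::xml_add_child(mod, "listOfReactions")
  add_math <- function(kl, expr) {
    math <- xml2::xml_add_child(kl, "math",
      xmlns = "http://www.w3.org/1998/Math/MathML")
    build <- function(parent, e) {
      if (is.character(e)) xml2::xml_add_child(parent, "ci", e)
      else if (is.numeric(e)) xml2::xml_add_child(parent, "cn", num(e))
      else {
        ap <- xml2::xml_add_child(parent, "apply")
        xml2::xml_add_child(ap, e$op)
        for (a in e$args) build(ap, a)
      }
    }
    build(math, expr)
  }
  ex <- function(op, ...) list(op = op, args = list(...))
  add_reaction <- function(id, reactants, products, law, params) {
    rx <- xml2::xml_add_child(lor, "reaction", id = id, reversible = "false")
    if (length(reactants)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (s in names(reactants))
        xml2::xml_add_child(lr, "speciesReference", species = s,
                            stoichiometry = num(reactants[[s]]),
                            constant = "true")
    }
    if (length(products)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (s in names(products))
        xml2::xml_add_child(lp, "speciesReference", species = s,
                            stoichiometry = num(products[[s]]),
                            constant = "true")
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    add_math(kl, law)
    if (length(params)) {
      lpar <- xml2::xml_add_child(kl, "listOfLocalParameters")
      for (p in names(params))
        xml2::xml_add_child(lpar, "localParameter", id = p,
                            value = num(params[[p]]))
    }
  }
  for (nm in names(network$reactions)) {
    r <- network$reactions[[nm]]
    if (inherits(r, "mass_action_reaction")) {
      fwd_law <- Reduce(function(acc, s) ex("times", acc,
        if (r$substrates[[s]] == 1) s else ex("power", s, r$substrates[[s]])),
        names(r$substrates), init = "kf")
      add_reaction(paste0(nm, "_f"), as.list(r$substrates),
                   as.list(r$products), fwd_law, list(kf = r$kf))
      if (r$kr > 0) {
        rev_law <- Reduce(function(acc, s) ex("times", acc,
          if (r$products[[s]] == 1) s else ex("power", s, r$products[[s]])),
          names(r$products), init = "kr")
        add_reaction(paste0(nm, "_r"), as.list(r$products),
                     as.list(r$substrates), rev_law, list(kr = r$kr))
      }
    } else {
      law <- ex("divide", ex("times", "v_max", r$substrate),
                ex("plus", "kappa_m", r$substrate))
      prods <- if (!is.na(r$product)) stats::setNames(list(1), r$product)
               else list()
      add_reaction(nm, stats::setNames(list(1), r$substrate), prods, law,
                   list(v_max = r$v_max, kappa_m = r$kappa_m))
    }
  }
  for (sp in names(network$sources)) {
    s <- network$sources[[sp]]
    if (s == 0) next
    if (s > 0)
      add_reaction(paste0("source_", sp), list(),
                   stats::setNames(list(1), sp), "influx",
                   list(influx = s))
    else
      add_reaction(paste0("sink_", sp), stats::setNames(list(1), sp),
                   list(), "efflux", list(efflux = -s))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
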