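# Network serialization. The native interchange format is a declarative
# YAML document (species table + reaction table); SBML and CellML import
# are best-effort adapters restricted to mass-action kinetics.

#' Write a network to the native model format
#'
#' The native format is YAML with top-level keys `cell_volume`, `species`,
#' `reactions` and optionally `tracked`. Each species entry has `id`,
#' `name`, `initial_amount`, optional `tags`, `mol_weight`, `amount_unit`;
#' each reaction entry has `reactants`, `products` (ids, optionally with a
#' stoichiometry prefix such as `"2 EGFR"`), `kf` and optionally `kr`,
#' `time_unit`, `conc_unit`.
#'
#' @param net a `reaction_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  sp <- lapply(seq_len(nrow(net$species)), function(i) {
    row <- net$species[i, ]
    out <- list(id = row$id, name = row$name,
                initial_amount = row$initial_amount)
    if (length(row$tags[[1]])) out$tags <- as.list(row$tags[[1]])
    if (!is.na(row$mol_weight)) out$mol_weight <- row$mol_weight
    if (row$amount_unit != "molecules") out$amount_unit <- row$amount_unit
    out
  })
  rx <- lapply(net$reactions, function(r) {
    out <- list(reactants = as.list(format_side(r$reactants)),
                products = as.list(format_side(r$products)),
                kf = r$kf)
    if (!is.na(r$kr)) out$kr <- r$kr
    if (r$time_unit != "per_min") out$time_unit <- r$time_unit
    if (r$conc_unit != "per_molecule") out$conc_unit <- r$conc_unit
    out
  })
  doc <- list(cell_volume = net$cell_volume, species = sp, reactions = rx)
  if (!is.null(net$tracked)) doc$tracked <- as.list(net$tracked)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Load a reaction network from a model document
#'
#' Reads the native YAML format, or imports the mass-action subset of SBML
#' Level 2/3 and CellML 1.0/1.1 documents. Non-mass-action kinetic laws
#' are rejected with a format error; unresolved species references raise a
#' structural error.
#'
#' @param path model file path.
#' @param format one of `"native"`, `"sbml"`, `"cellml"`.
#' @return a validated `reaction_network`.
#' @export
load_network <- function(path, format = c("native", "sbml", "cellml")) {
  format <- match.arg(format)
  switch(format,
         native = read_native_network(path),
         sbml = read_sbml_network(path),
         cellml = read_cellml_network(path))
}

read_native_network <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$species) || is.null(doc$reactions))
    stop("format error: native model file must declare species and reactions")
  sp <- species_table(
    id = vapply(doc$species, function(s) as.character(s$id), character(1)),
    name = vapply(doc$species, function(s) as.character(s$name %||% s$id), character(1)),
    initial_amount = vapply(doc$species, function(s) as.numeric(s$initial_amount), numeric(1)),
    tags = lapply(doc$species, function(s) unlist(s$tags)),
    mol_weight = vapply(doc$species, function(s) as.numeric(s$mol_weight %||% NA_real_), numeric(1)),
    amount_unit = vapply(doc$species, function(s) as.character(s$amount_unit %||% "molecules"), character(1)))
  rx <- lapply(doc$reactions, function(r) {
    reaction(unlist(r$reactants), unlist(r$products), kf = r$kf,
             kr = r$kr %||% NA_real_,
             time_unit = r$time_unit %||% "per_min",
             conc_unit = r$conc_unit %||% "per_molecule")
  })
  reaction_network(sp, rx, cell_volume = doc$cell_volume %||% 1e-12,
                   tracked = if (!is.null(doc$tracked)) unlist(doc$tracked))
}

# --- SBML (mass-action subset) ----------------------------------------------
# Accepts kinetic laws whose MathML is k * [reactants] or
# kf * [reactants] - kr * [products]; anything else is rejected.

read_sbml_network <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp_nodes)) stop("format error: SBML document declares no species")
  ids <- xml2::xml_attr(sp_nodes, "id")
  amounts <- as.numeric(xml2::xml_attr(sp_nodes, "initialAmount"))
  conc <- as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration"))
  amounts[is.na(amounts)] <- conc[is.na(amounts)]
  amounts[is.na(amounts)] <- 0
  names <- xml2::xml_attr(sp_nodes, "name")
  names[is.na(names)] <- ids[is.na(names)]
  sp <- species_table(id = ids, name = names, initial_amount = amounts)

  # global parameters usable in kinetic laws
  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxs <- lapply(rx_nodes, function(node) sbml_reaction(node, ns, pars, ids))
  reaction_network(sp, rxs)
}

sbml_side <- function(node, which, ns) {
  refs <- xml2::xml_find_all(
    node, paste0("./s:", which, "/s:speciesReference"), ns)
  id <- xml2::xml_attr(refs, "species")
  st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
  st[is.na(st)] <- 1
  data.frame(id = id, stoich = st, stringsAsFactors = FALSE)
}

sbml_reaction <- function(node, ns, pars, species_ids) {
  re <- sbml_side(node, "listOfReactants", ns)
  pr <- sbml_side(node, "listOfProducts", ns)
  missing <- setdiff(c(re$id, pr$id), species_ids)
  if (length(missing))
    stop("structural error: reaction references undeclared species ",
         paste(missing, collapse = ", "))
  kl <- xml2::xml_find_first(node, "./s:kineticLaw", ns)
  if (inherits(kl, "xml_missing"))
    stop("format error: reaction without kinetic law")
  loc <- xml2::xml_find_all(
    kl, "./s:listOfParameters/s:parameter | ./s:listOfLocalParameters/s:localParameter", ns)
  local_pars <- stats::setNames(as.numeric(xml2::xml_attr(loc, "value")),
                                xml2::xml_attr(loc, "id"))
  pars <- c(local_pars, pars)
  math <- xml2::xml_find_first(kl, ".//m:math", c(m = "http://www.w3.org/1998/Math/MathML"))
  if (inherits(math, "xml_missing"))
    stop("format error: kinetic law has no MathML body")
  terms <- mathml_mass_action(xml2::xml_find_first(math, "./*"), pars)
  k_of <- function(term, side) {
    counts <- table(rep(side$id, side$stoich))
    got <- table(term$species)
    if (length(counts) != length(got) || !all(names(counts) %in% names(got)) ||
        !all(got[names(counts)] == counts))
      stop("format error: kinetic law is not mass action on the declared ",
           "reactants/products")
    term$k
  }
  if (length(terms) == 1) {
    reaction(format_side(re), format_side(pr), kf = k_of(terms[[1]], re))
  } else if (length(terms) == 2) {
    reaction(format_side(re), format_side(pr),
             kf = k_of(terms[[1]], re), kr = k_of(terms[[2]], pr))
  } else stop("format error: unsupported kinetic law")
}

# Decompose MathML into mass-action terms: returns a list of
# list(k = rate constant value, species = character vector with
# multiplicity). Supports <times> products of one constant and species
# <ci>s, optionally wrapped in a top-level <minus> for reversible laws.
mathml_mass_action <- function(node, pars) {
  name <- xml2::xml_name(node)
  if (name == "apply") {
    children <- xml2::xml_find_all(node, "./*")
    op <- xml2::xml_name(children[[1]])
    args <- children[-1]
    if (op == "minus" && length(args) == 2) {
      return(c(mathml_mass_action(args[[1]], pars),
               mathml_mass_action(args[[2]], pars)))
    }
    if (op == "times") {
      k <- 1; seen_k <- FALSE; species <- character()
      for (a in args) {
        an <- xml2::xml_name(a)
        if (an == "cn") { k <- k * as.numeric(xml2::xml_text(a)); seen_k <- TRUE }
        else if (an == "ci") {
          sym <- trimws(xml2::xml_text(a))
          if (sym %in% names(pars)) { k <- k * pars[[sym]]; seen_k <- TRUE }
          else species <- c(species, sym)
        } else if (an == "apply") {
          sub <- xml2::xml_find_all(a, "./*")
          if (xml2::xml_name(sub[[1]]) == "power") {
            sym <- trimws(xml2::xml_text(sub[[2]]))
            p <- as.numeric(xml2::xml_text(sub[[3]]))
            if (p != round(p) || p < 1)
              stop("format error: non-integer power in kinetic law")
            species <- c(species, rep(sym, p))
          } else stop("format error: unsupported kinetic law operator")
        } else stop("format error: unsupported kinetic law node <", an, ">")
      }
      if (!seen_k)
        stop("format error: kinetic law term lacks a rate constant")
      return(list(list(k = k, species = species)))
    }
  }
  stop("format error: unsupported kinetic law (mass action required)")
}

# --- CellML (reaction-markup subset) ----------------------------------------
# CellML 1.0 optionally encodes biochemical reactions as <reaction>
# elements with <variable_ref>/<role> children; the adapter reads that
# markup (with delta_variable rate constants resolved from initial_value
# attributes). Documents encoding the model purely as ODE maths are not
# importable and are rejected.

read_cellml_network <- function(path) {
  doc <- xml2::read_xml(path)
  ns_all <- xml2::xml_ns(doc)
  cn <- names(ns_all)[as.character(ns_all) %in%
                        c("http://www.cellml.org/cellml/1.0#",
                          "http://www.cellml.org/cellml/1.1#")]
  if (!length(cn)) stop("format error: not a CellML 1.0/1.1 document")
  ns <- stats::setNames(as.character(ns_all[cn[1]]), "c")
  var_nodes <- xml2::xml_find_all(doc, ".//c:component/c:variable", ns)
  init <- stats::setNames(as.numeric(xml2::xml_attr(var_nodes, "initial_value")),
                          xml2::xml_attr(var_nodes, "name"))
  rx_nodes <- xml2::xml_find_all(doc, ".//c:reaction", ns)
  if (!length(rx_nodes))
    stop("format error: CellML document has no <reaction> markup; ",
         "only the mass-action reaction subset is importable")
  sides <- lapply(rx_nodes, function(node) {
    refs <- xml2::xml_find_all(node, "./c:variable_ref", ns)
    role_of <- function(ref) xml2::xml_attr(
      xml2::xml_find_first(ref, "./c:role", ns), "role")
    stoich_of <- function(ref) {
      s <- xml2::xml_attr(xml2::xml_find_first(ref, "./c:role", ns), "stoichiometry")
      if (is.na(s)) 1 else as.numeric(s)
    }
    vars <- xml2::xml_attr(refs, "variable")
    roles <- vapply(refs, role_of, character(1))
    st <- vapply(refs, stoich_of, numeric(1))
    list(re = data.frame(id = vars[roles == "reactant"],
                         stoich = st[roles == "reactant"]),
         pr = data.frame(id = vars[roles == "product"],
                         stoich = st[roles == "product"]),
         rate = vars[roles == "rate"])
  })
  species_ids <- sort(unique(unlist(lapply(sides, function(s) c(s$re$id, s$pr$id)))))
  amounts <- init[species_ids]
  amounts[is.na(amounts)] <- 0
  sp <- species_table(id = species_ids, initial_amount = amounts)
  rxs <- lapply(sides, function(s) {
    if (!length(s$rate) || is.na(init[s$rate[1]]))
      stop("format error: reaction rate constant not resolvable from ",
           "initial_value attributes")
    reaction(format_side(s$re), format_side(s$pr), kf = init[[s$rate[1]]])
  })
  reaction_network(sp, rxs)
}
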