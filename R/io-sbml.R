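# SBML Level-3 + FBC version-2 I/O (the profile BiGG exports use): flux
# bounds as global parameters referenced through fbc:lowerFluxBound /
# fbc:upperFluxBound, GPR rules as fbc:geneProductAssociation trees, the
# objective as an fbc:listOfObjectives entry, and subsystems as groups:group
# members.  Older SBML levels are rejected rather than half-parsed.
#
# Identifiers are written with the conventional R_ / M_ / G_ prefixes (SBML
# SIds must not start with a digit) and stripped again on read, so a
# write -> read round trip reproduces the in-memory model.

xml_attr_or <- function(x, a) {
  v <- xml2::xml_attr(x, a)
  if (is.na(v)) NULL else v
}

SBML_NS <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
  groups = "http://www.sbml.org/sbml/level3/version1/groups/version1"
)

sbml_sid <- function(prefix, id) paste0(prefix, gsub("[^A-Za-z0-9_]", "__", id))
strip_sid <- function(x, prefix) sub(paste0("^", prefix), "", x)

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
    error = function(e) abort(sprintf("SBML parse failure in '%s': %s",
                                      path, conditionMessage(e))))
  root <- xml2::xml_find_first(doc, "/sbml:sbml", SBML_NS)
  if (is.na(xml2::xml_attr(doc, "level")) && inherits(root, "xml_missing")) {
    abort(sprintf("'%s' is not an SBML document", path))
  }
  level <- xml2::xml_attr(doc, "level")
  if (!identical(level, "3")) {
    abort(sprintf(
      "unsupported SBML dialect in '%s': level %s; only Level 3 with FBC v2 is supported",
      path, level %||% "?"))
  }
  model_node <- xml2::xml_find_first(doc, "//sbml:model", SBML_NS)
  if (inherits(model_node, "xml_missing")) {
    abort(sprintf("format error in '%s': no <model> element", path))
  }

  comp_nodes <- xml2::xml_find_all(doc, "//sbml:listOfCompartments/sbml:compartment", SBML_NS)
  compartments <- setNames(
    xml2::xml_attr(comp_nodes, "name"),
    xml2::xml_attr(comp_nodes, "id")
  )
  compartments[is.na(compartments)] <- names(compartments)[is.na(compartments)]

  sp_nodes <- xml2::xml_find_all(doc, "//sbml:listOfSpecies/sbml:species", SBML_NS)
  mets <- tibble(
    id = strip_sid(xml2::xml_attr(sp_nodes, "id"), "M_"),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"),
                           strip_sid(xml2::xml_attr(sp_nodes, "id"), "M_")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = xml2::xml_attr(sp_nodes, "chemicalFormula")
  )

  par_nodes <- xml2::xml_find_all(doc, "//sbml:listOfParameters/sbml:parameter", SBML_NS)
  params <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                     xml2::xml_attr(par_nodes, "id"))

  gp_nodes <- xml2::xml_find_all(doc, "//fbc:listOfGeneProducts/fbc:geneProduct", SBML_NS)
  gene_labels <- setNames(
    dplyr::coalesce(xml2::xml_attr(gp_nodes, "label"),
                    strip_sid(xml2::xml_attr(gp_nodes, "id"), "G_")),
    xml2::xml_attr(gp_nodes, "id")
  )

  # objective coefficients (active objective)
  active <- xml2::xml_attr(
    xml2::xml_find_first(doc, "//fbc:listOfObjectives", SBML_NS),
    "activeObjective")
  fo_nodes <- xml2::xml_find_all(
    doc, sprintf("//fbc:objective[@fbc:id='%s']//fbc:fluxObjective",
                 active %||% ""), SBML_NS)
  obj_map <- setNames(
    as.numeric(xml2::xml_attr(fo_nodes, "coefficient")),
    strip_sid(xml2::xml_attr(fo_nodes, "reaction"), "R_")
  )

  # subsystems from groups
  subsystem_map <- character(0)
  grp_nodes <- xml2::xml_find_all(doc, "//groups:group", SBML_NS)
  for (g in grp_nodes) {
    nm <- xml_attr_or(g, "name") %||% xml_attr_or(g, "id")
    members <- xml2::xml_find_all(g, ".//groups:member", SBML_NS)
    ids <- strip_sid(xml2::xml_attr(members, "idRef"), "R_")
    subsystem_map[ids] <- nm
  }

  rxn_nodes <- xml2::xml_find_all(doc, "//sbml:listOfReactions/sbml:reaction", SBML_NS)
  rxns <- list()
  st <- list()
  for (rn in rxn_nodes) {
    rid <- strip_sid(xml2::xml_attr(rn, "id"), "R_")
    reversible <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(params)) params[[lb_ref]]
          else if (reversible) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(params)) params[[ub_ref]]
          else 1000

    for (side in c(-1, 1)) {
      xp <- if (side < 0) ".//sbml:listOfReactants/sbml:speciesReference"
            else ".//sbml:listOfProducts/sbml:speciesReference"
      refs <- xml2::xml_find_all(rn, xp, SBML_NS)
      if (length(refs)) {
        st[[length(st) + 1L]] <- tibble(
          reaction = rid,
          metabolite = strip_sid(xml2::xml_attr(refs, "species"), "M_"),
          coef = side * as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        )
      }
    }

    gpa <- xml2::xml_find_first(rn, ".//fbc:geneProductAssociation", SBML_NS)
    gpr <- if (inherits(gpa, "xml_missing")) NA_character_ else {
      node <- xml2::xml_find_first(gpa, "./*")
      sbml_gpa_to_rule(node, gene_labels)
    }

    rxns[[length(rxns) + 1L]] <- tibble(
      id = rid,
      name = dplyr::coalesce(xml2::xml_attr(rn, "name"), rid),
      lb = lb, ub = ub,
      gpr = gpr,
      subsystem = if (rid %in% names(subsystem_map)) subsystem_map[[rid]] else NA_character_,
      objective_coef = if (rid %in% names(obj_map)) obj_map[[rid]] else 0
    )
  }

  bad <- setdiff(unique(dplyr::bind_rows(st)$metabolite), mets$id)
  if (length(bad)) {
    abort(paste0("validation error: reaction references undeclared metabolite(s): ",
                 paste(bad, collapse = ", ")))
  }

  metabolic_model(
    id = xml2::xml_attr(model_node, "id") %||% "sbml_model",
    metabolites = mets,
    reactions = dplyr::bind_rows(rxns),
    stoichiometry = dplyr::bind_rows(st),
    compartments = compartments
  )
}

sbml_gpa_to_rule <- function(node, gene_labels) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    lbl <- unname(gene_labels[gid])
    return(if (is.na(lbl)) strip_sid(gid, "G_") else lbl)
  }
  children <- xml2::xml_find_all(node, "./*")
  parts <- vapply(children, sbml_gpa_to_rule, character(1), gene_labels = gene_labels)
  joiner <- if (name == "and") " and " else " or "
  paste0("(", paste(parts, collapse = joiner), ")")
}

sbml_rule_to_gpa <- function(parent, node) {
  if (node$kind == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = sbml_sid("G_", node$id))
    return(invisible(NULL))
  }
  el <- xml2::xml_add_child(parent, paste0("fbc:", node$kind))
  for (ch in node$children) sbml_rule_to_gpa(el, ch)
  invisible(NULL)
}

write_model_sbml <- function(model, path) {
  root <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS[["sbml"]],
    "xmlns:fbc" = SBML_NS[["fbc"]],
    "xmlns:groups" = SBML_NS[["groups"]],
    level = "3", version = "1",
    "fbc:required" = "false", "groups:required" = "false"
  )
  mnode <- xml2::xml_add_child(root, "model", id = sbml_sid("", model$id),
                               "fbc:strict" = "true")

  loc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (code in names(model$compartments)) {
    xml2::xml_add_child(loc, "compartment", id = code,
                        name = model$compartments[[code]], constant = "true")
  }

  los <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(los, "species",
      id = sbml_sid("M_", m$id), name = m$name, compartment = m$compartment,
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(m$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
  }

  lop <- xml2::xml_add_child(mnode, "listOfParameters")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    sid <- sbml_sid("R_", r$id)
    xml2::xml_add_child(lop, "parameter", id = paste0("lb_", sid),
                        value = format(r$lb, digits = 17), constant = "true")
    xml2::xml_add_child(lop, "parameter", id = paste0("ub_", sid),
                        value = format(r$ub, digits = 17), constant = "true")
  }

  lor <- xml2::xml_add_child(mnode, "listOfReactions")
  st_by_rxn <- split(model$stoichiometry, model$stoichiometry$reaction)
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    sid <- sbml_sid("R_", r$id)
    rn <- xml2::xml_add_child(lor, "reaction",
      id = sid, name = r$name,
      reversible = if (r$lb < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = paste0("lb_", sid),
      "fbc:upperFluxBound" = paste0("ub_", sid))
    stc <- st_by_rxn[[r$id]]
    if (!is.null(stc)) {
      reac <- stc[stc$coef < 0, ]
      prod <- stc[stc$coef > 0, ]
      if (nrow(reac)) {
        lr <- xml2::xml_add_child(rn, "listOfReactants")
        for (k in seq_len(nrow(reac))) {
          xml2::xml_add_child(lr, "speciesReference",
            species = sbml_sid("M_", reac$metabolite[k]),
            stoichiometry = format(-reac$coef[k], digits = 17),
            constant = "true")
        }
      }
      if (nrow(prod)) {
        lp <- xml2::xml_add_child(rn, "listOfProducts")
        for (k in seq_len(nrow(prod))) {
          xml2::xml_add_child(lp, "speciesReference",
            species = sbml_sid("M_", prod$metabolite[k]),
            stoichiometry = format(prod$coef[k], digits = 17),
            constant = "true")
        }
      }
    }
    if (!is.na(r$gpr) && nzchar(r$gpr)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      sbml_rule_to_gpa(gpa, unclass(parse_gpr(r$gpr)))
    }
  }

  genes <- model_genes(model)
  if (length(genes)) {
    logp <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(logp, "fbc:geneProduct",
        "fbc:id" = sbml_sid("G_", g), "fbc:label" = g)
    }
  }

  obj <- model$reactions[model$reactions$objective_coef != 0, ]
  loo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  on <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(on, "fbc:listOfFluxObjectives")
  for (i in seq_len(nrow(obj))) {
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
      "fbc:reaction" = sbml_sid("R_", obj$id[i]),
      "fbc:coefficient" = format(obj$objective_coef[i], digits = 17))
  }

  subs <- model$reactions[!is.na(model$reactions$subsystem), ]
  if (nrow(subs)) {
    log_ <- xml2::xml_add_child(mnode, "groups:listOfGroups")
    for (s in unique(subs$subsystem)) {
      gn <- xml2::xml_add_child(log_, "groups:group",
        "groups:id" = sbml_sid("g_", s), "groups:kind" = "partonomy",
        "groups:name" = s)
      lm <- xml2::xml_add_child(gn, "groups:listOfMembers")
      for (rid in subs$id[subs$subsystem == s]) {
        xml2::xml_add_child(lm, "groups:member",
          "groups:idRef" = sbml_sid("R_", rid))
      }
    }
  }

  xml2::write_xml(root, path)
  invisible(path)
}
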