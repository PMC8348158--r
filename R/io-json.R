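# BiGG-style JSON model dialect: top-level lists `metabolites`, `reactions`,
# `genes`, plus `compartments` and `id`.  Reactions carry a `metabolites`
# map (id -> coefficient), `lower_bound` / `upper_bound`,
# `gene_reaction_rule` and `subsystem`, with `objective_coefficient` for the
# objective -- the dialect BiGG database exports use.

read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("JSON parse failure in '%s': %s",
                                      path, conditionMessage(e)))
  )
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    abort(sprintf("'%s' is not a BiGG-style model: missing metabolites/reactions",
                  path))
  }
  mets <- dplyr::bind_rows(lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) abort("JSON format error: metabolite without id")
    tibble(
      id = m$id,
      name = m$name %||% m$id,
      compartment = m$compartment %||% guess_compartment(m$id),
      formula = m$formula %||% NA_character_
    )
  }))

  rxns <- list()
  st <- list()
  for (r in doc$reactions) {
    if (is.null(r$id)) abort("JSON format error: reaction without id")
    coefs <- unlist(r$metabolites)
    if (length(coefs)) {
      st[[length(st) + 1L]] <- tibble(
        reaction = r$id, metabolite = names(coefs), coef = as.numeric(coefs)
      )
    }
    # BiGG default bound convention when bounds are absent
    reversible <- isTRUE(r$reversible) || is.null(r$lower_bound)
    lb_default <- if (reversible) -1000 else 0
    rxns[[length(rxns) + 1L]] <- tibble(
      id = r$id,
      name = r$name %||% r$id,
      lb = as.numeric(r$lower_bound %||% lb_default),
      ub = as.numeric(r$upper_bound %||% 1000),
      gpr = empty_to_na(r$gene_reaction_rule),
      subsystem = empty_to_na(r$subsystem),
      objective_coef = as.numeric(r$objective_coefficient %||% 0)
    )
  }
  metabolic_model(
    id = doc$id %||% tools::file_path_sans_ext(basename(path)),
    metabolites = mets,
    reactions = dplyr::bind_rows(rxns),
    stoichiometry = dplyr::bind_rows(st),
    compartments = json_compartments(doc, mets)
  )
}

json_compartments <- function(doc, mets) {
  if (!is.null(doc$compartments) && length(doc$compartments)) {
    return(unlist(doc$compartments))
  }
  codes <- unique(mets$compartment)
  setNames(codes, codes)
}

guess_compartment <- function(met_id) {
  # BiGG metabolite ids end in _<compartment code>
  sub(".*_([a-z0-9]+)$", "\\1", met_id)
}

empty_to_na <- function(x) {
  if (is.null(x) || !nzchar(trimws(x))) NA_character_ else x
}

write_model_json <- function(model, path) {
  genes <- model_genes(model)
  st_by_rxn <- split(model$stoichiometry, model$stoichiometry$reaction)
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      out
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      stc <- st_by_rxn[[r$id]]
      coefs <- if (is.null(stc)) list() else as.list(setNames(stc$coef, stc$metabolite))
      list(
        id = r$id,
        name = r$name,
        metabolites = coefs,
        lower_bound = r$lb,
        upper_bound = r$ub,
        gene_reaction_rule = if (is.na(r$gpr)) "" else r$gpr,
        subsystem = if (is.na(r$subsystem)) "" else r$subsystem,
        objective_coefficient = r$objective_coef
      )
    }),
    genes = lapply(genes, function(g) list(id = g, name = g)),
    compartments = as.list(model$compartments)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
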