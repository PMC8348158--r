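#' Construct a genome-scale metabolic model
#'
#' The central container of the package: a stoichiometric network with flux
#' bounds, gene-protein-reaction (GPR) rules, subsystem and compartment
#' annotations, and a linear objective. All tabular pieces are tibbles so the
#' model composes naturally with dplyr verbs via [tidy()].
#'
#' @param id model identifier.
#' @param metabolites tibble with columns `id`, `name`, `compartment`, and
#'   optionally `formula`.
#' @param reactions tibble with columns `id`, `name`, `lb`, `ub`, `gpr`
#'   (rule string, `NA`/`""` for none), `subsystem`, `objective_coef`.
#' @param stoichiometry long-format tibble with columns `reaction`,
#'   `metabolite`, `coef` (negative = consumed).
#' @param compartments named character vector mapping compartment code to
#'   display name.
#'
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            compartments) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  stoichiometry <- as_tibble(stoichiometry)
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"gpr" %in% names(reactions)) reactions$gpr <- NA_character_
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- NA_character_
  if (!"objective_coef" %in% names(reactions)) reactions$objective_coef <- 0

  if (anyDuplicated(metabolites$id)) {
    abort(paste0("duplicate metabolite ids: ",
                 paste(unique(metabolites$id[duplicated(metabolites$id)]),
                       collapse = ", ")))
  }
  if (anyDuplicated(reactions$id)) {
    abort(paste0("duplicate reaction ids: ",
                 paste(unique(reactions$id[duplicated(reactions$id)]),
                       collapse = ", ")))
  }
  bad_met <- setdiff(stoichiometry$metabolite, metabolites$id)
  if (length(bad_met)) {
    abort(paste0("stoichiometry references undeclared metabolite(s): ",
                 paste(bad_met, collapse = ", ")))
  }
  bad_rxn <- setdiff(stoichiometry$reaction, reactions$id)
  if (length(bad_rxn)) {
    abort(paste0("stoichiometry references undeclared reaction(s): ",
                 paste(bad_rxn, collapse = ", ")))
  }
  bad_cmp <- setdiff(metabolites$compartment, names(compartments))
  if (length(bad_cmp)) {
    abort(paste0("metabolite compartment(s) not declared: ",
                 paste(bad_cmp, collapse = ", ")))
  }
  if (any(!is.finite(stoichiometry$coef)) || any(stoichiometry$coef == 0)) {
    abort("stoichiometric coefficients must be finite and non-zero")
  }
  if (any(reactions$lb > reactions$ub)) {
    abort(paste0("lb > ub for reaction(s): ",
                 paste(reactions$id[reactions$lb > reactions$ub],
                       collapse = ", ")))
  }

  # exchange reactions identified structurally (single metabolite touched);
  # the EX_ prefix is only a fallback annotation aid
  n_met <- table(factor(stoichiometry$reaction, levels = reactions$id))
  reactions$is_exchange <- as.integer(n_met[reactions$id]) == 1L |
    startsWith(reactions$id, "EX_")

  structure(
    list(
      id = id,
      metabolites = metabolites,
      reactions = reactions,
      stoichiometry = stoichiometry,
      compartments = compartments
    ),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "<metabolic_model '%s'>  %d metabolites x %d reactions, %d compartments\n",
    x$id, nrow(x$metabolites), nrow(x$reactions), length(x$compartments)
  ))
  subs <- unique(stats::na.omit(x$reactions$subsystem))
  if (length(subs)) cat("  subsystems:", paste(subs, collapse = ", "), "\n")
  obj <- x$reactions$id[x$reactions$objective_coef != 0]
  if (length(obj)) cat("  objective:", paste(obj, collapse = ", "), "\n")
  invisible(x)
}

# --- accessors ----------------------------------------------------------

reaction_ids <- function(model) model$reactions$id
metabolite_ids <- function(model) model$metabolites$id
model_lb <- function(model) setNames(model$reactions$lb, model$reactions$id)
model_ub <- function(model) setNames(model$reactions$ub, model$reactions$id)
n_reactions <- function(model) nrow(model$reactions)

objective_vector <- function(model) {
  setNames(model$reactions$objective_coef, model$reactions$id)
}

#' Assemble the stoichiometric matrix S
#'
#' @param model a [metabolic_model()].
#' @return a sparse `Matrix::dgCMatrix` of dimension metabolites x reactions,
#'   with `S[i, j]` the coefficient of metabolite i in reaction j and row /
#'   column order equal to the model's metabolite / reaction order.
#' @export
stoichiometric_matrix <- function(model) {
  i <- match(model$stoichiometry$metabolite, model$metabolites$id)
  j <- match(model$stoichiometry$reaction, model$reactions$id)
  Matrix::sparseMatrix(
    i = i, j = j, x = model$stoichiometry$coef,
    dims = c(nrow(model$metabolites), nrow(model$reactions)),
    dimnames = list(model$metabolites$id, model$reactions$id)
  )
}

#' Structural validation findings for a model
#'
#' Reports dangling metabolites (used by no reaction), dead-end metabolites
#' (only ever produced or only ever consumed by irreversible reactions),
#' reactions with crossed bounds, and a missing objective. Findings are
#' reports, not errors: a model with findings is still usable.
#'
#' @param model a [metabolic_model()].
#' @return tibble with columns `finding`, `id`, `severity`, `message`.
#' @export
validate_model <- function(model) {
  out <- list()
  used <- unique(model$stoichiometry$metabolite)
  dangling <- setdiff(model$metabolites$id, used)
  for (m in dangling) {
    out[[length(out) + 1L]] <- tibble(
      finding = "dangling", id = m, severity = "warning",
      message = sprintf("metabolite '%s' appears in no reaction", m)
    )
  }
  # dead ends: metabolite that can only be produced or only consumed,
  # taking reversibility into account
  rev <- setNames(model$reactions$lb < 0, model$reactions$id)
  st <- model$stoichiometry
  for (m in setdiff(used, dangling)) {
    rows <- st[st$metabolite == m, ]
    r_rev <- rev[rows$reaction]
    can_produce <- any(rows$coef > 0 | r_rev)
    can_consume <- any(rows$coef < 0 | r_rev)
    if (!can_produce || !can_consume) {
      out[[length(out) + 1L]] <- tibble(
        finding = "dead_end", id = m, severity = "warning",
        message = sprintf("metabolite '%s' is only %s", m,
                          if (can_produce) "produced" else "consumed")
      )
    }
  }
  bad <- model$reactions$id[model$reactions$lb > model$reactions$ub]
  for (r in bad) {
    out[[length(out) + 1L]] <- tibble(
      finding = "bounds", id = r, severity = "error",
      message = sprintf("reaction '%s' has lb > ub", r)
    )
  }
  if (all(model$reactions$objective_coef == 0)) {
    out[[length(out) + 1L]] <- tibble(
      finding = "objective", id = NA_character_, severity = "warning",
      message = "model declares no objective"
    )
  }
  if (!length(out)) {
    return(tibble(finding = character(), id = character(),
                  severity = character(), message = character()))
  }
  dplyr::bind_rows(out)
}

#' Override flux bounds on a reaction
#'
#' @param model a [metabolic_model()].
#' @param reaction reaction id.
#' @param lb,ub new bounds (either may be omitted to keep the current value).
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction, lb = NULL, ub = NULL) {
  i <- match(reaction, model$reactions$id)
  if (is.na(i)) abort(sprintf("unknown reaction '%s'", reaction))
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  if (model$reactions$lb[i] > model$reactions$ub[i]) {
    abort(sprintf("set_bounds would leave lb > ub on '%s'", reaction))
  }
  model
}

#' Set the model objective
#'
#' @param model a [metabolic_model()].
#' @param reaction reaction id (or named numeric vector of coefficients).
#' @return the modified model.
#' @export
set_objective <- function(model, reaction) {
  model$reactions$objective_coef <- 0
  if (is.character(reaction)) reaction <- setNames(rep(1, length(reaction)), reaction)
  i <- match(names(reaction), model$reactions$id)
  if (anyNA(i)) {
    abort(paste0("unknown objective reaction(s): ",
                 paste(names(reaction)[is.na(i)], collapse = ", ")))
  }
  model$reactions$objective_coef[i] <- as.numeric(reaction)
  model
}

#' Restrict a model to a set of reactions
#'
#' Keeps the named reactions and every metabolite they touch; all other
#' reactions and now-unused metabolites are dropped.
#'
#' @param model a [metabolic_model()].
#' @param keep character vector of reaction ids to retain.
#' @return a [metabolic_model()] over the subnetwork.
#' @export
subset_model <- function(model, keep) {
  missing <- setdiff(keep, model$reactions$id)
  if (length(missing)) {
    abort(paste0("subset_model: unknown reaction(s): ",
                 paste(missing, collapse = ", ")))
  }
  reactions <- model$reactions[model$reactions$id %in% keep, ]
  st <- model$stoichiometry[model$stoichiometry$reaction %in% keep, ]
  mets <- model$metabolites[model$metabolites$id %in% unique(st$metabolite), ]
  metabolic_model(model$id, mets, reactions[setdiff(names(reactions), "is_exchange")],
                  st, model$compartments)
}

# --- broom-style methods ------------------------------------------------

#' @export
tidy.metabolic_model <- function(x, ...) {
  x$reactions |>
    dplyr::select(dplyr::all_of(c("id", "name", "lb", "ub", "gpr",
                                  "subsystem", "objective_coef", "is_exchange")))
}

#' @export
glance.metabolic_model <- function(x, ...) {
  tibble(
    id = x$id,
    n_metabolites = nrow(x$metabolites),
    n_reactions = nrow(x$reactions),
    n_genes = length(model_genes(x)),
    n_compartments = length(x$compartments),
    n_subsystems = length(unique(stats::na.omit(x$reactions$subsystem)))
  )
}

# All gene ids referenced by the model's GPR rules
model_genes <- function(model) {
  rules <- model$reactions$gpr
  rules <- rules[!is.na(rules) & nzchar(rules)]
  sort(unique(unlist(lapply(rules, function(r) gpr_genes(parse_gpr(r))))))
}
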