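# Context-specific model extraction: reaction classification from gene
# calls, flux-consistency pruning (FASTCC), minimal core-preserving
# subnetwork extraction (FASTCORE), the composed per-sample builder, and
# metabolic-task feasibility checks.

#' Extraction configuration
#'
#' @param epsilon minimum flux magnitude for a reaction to count as active in
#'   consistency testing and extraction (default 1e-4; bounds are of
#'   magnitude 1000, so this cleanly separates numerical zero from flux).
#' @param scaling_factor bound inflation for the extraction sparsity LP
#'   (kept for provenance; the LPs here run unscaled at desk scale).
#' @param max_iterations iteration cap for the extraction loop.
#' @param z_margin discretisation margin, see [discretize_genes()].
#' @param fit mixture fitting mode, see [discretize_cohort()].
#' @param protect_objective always place objective reactions in the core so
#'   extracted models stay simulatable.
#' @return a list with class `extraction_config`.
#' @export
extraction_config <- function(epsilon = 1e-4, scaling_factor = 1000,
                              max_iterations = 100L, z_margin = 1.0,
                              fit = c("per_sample", "pooled"),
                              protect_objective = TRUE) {
  stopifnot(epsilon > 0)
  structure(
    list(epsilon = epsilon, scaling_factor = scaling_factor,
         max_iterations = as.integer(max_iterations), z_margin = z_margin,
         fit = match.arg(fit), protect_objective = protect_objective),
    class = "extraction_config"
  )
}

#' Classify reactions as core / noncore / inactive from gene calls
#'
#' Each reaction's GPR rule is evaluated on the discrete gene categories
#' (`and` = min, `or` = max): +1 makes the reaction core, 0 noncore, -1
#' inactive. Reactions without a GPR rule are noncore — absence of evidence
#' must not close transport or spontaneous reactions.
#'
#' @param model a [metabolic_model()].
#' @param disc a `gene_discretization` from [discretize_genes()].
#' @return a `core_sets` object: list with character vectors `core`,
#'   `noncore`, `inactive` partitioning the model's reactions.
#' @export
classify_reactions <- function(model, disc) {
  categories <- disc$category
  cls <- vapply(seq_len(n_reactions(model)), function(i) {
    rule <- model$reactions$gpr[i]
    if (is.na(rule) || !nzchar(rule)) return(0L)
    gpr_eval_discrete(parse_gpr(rule), categories, default_missing = 0L)
  }, integer(1))
  ids <- reaction_ids(model)
  structure(
    list(core = ids[cls == 1L], noncore = ids[cls == 0L],
         inactive = ids[cls == -1L]),
    class = "core_sets"
  )
}

#' @export
print.core_sets <- function(x, ...) {
  cat(sprintf("<core_sets>  core: %d, noncore: %d, inactive: %d\n",
              length(x$core), length(x$noncore), length(x$inactive)))
  invisible(x)
}

#' @export
tidy.core_sets <- function(x, ...) {
  dplyr::bind_rows(
    tibble(reaction = x$core, class = "core"),
    tibble(reaction = x$noncore, class = "noncore"),
    tibble(reaction = x$inactive, class = "inactive")
  )
}

# LP7 of the FASTCC/FASTCORE family: maximise the number of reactions in J
# that reach forward flux >= eps, via auxiliary z_i in [0, eps], z_i <= v_i.
# Operates on a "work" representation (dense S, bounds) so reactions can be
# sign-flipped cheaply.
lp7 <- function(S, lb, ub, J, eps) {
  n <- ncol(S)
  k <- length(J)
  mat <- cbind(S, matrix(0, nrow(S), k))
  zrows <- matrix(0, k, n + k)
  zrows[cbind(seq_len(k), J)] <- -1
  zrows[cbind(seq_len(k), n + seq_len(k))] <- 1
  res <- lp_run(
    obj = c(numeric(n), rep(1, k)),
    mat = rbind(mat, zrows),
    dir = c(rep("=", nrow(S)), rep("<=", k)),
    rhs = numeric(nrow(S) + k),
    lb = c(lb, numeric(k)),
    ub = c(ub, rep(eps, k)),
    maximize = TRUE
  )
  if (res$status != "optimal") {
    abort(sprintf("consistency LP is %s: model admits no steady state", res$status))
  }
  res$v[seq_len(n)]
}

# LP10: minimise sum of |v_i| over the penalty set P subject to v_k >= eps
# for the supported core subset K (L1 surrogate for adding as few penalty
# reactions as possible).
lp10 <- function(S, lb, ub, K, P, eps) {
  n <- ncol(S)
  p <- length(P)
  big <- pmax(abs(lb[P]), abs(ub[P]))
  mat <- cbind(S, matrix(0, nrow(S), p))
  dir <- rep("=", nrow(S))
  rhs <- numeric(nrow(S))
  if (length(K)) {
    krows <- matrix(0, length(K), n + p)
    krows[cbind(seq_along(K), K)] <- 1
    mat <- rbind(mat, krows)
    dir <- c(dir, rep(">=", length(K)))
    rhs <- c(rhs, rep(eps, length(K)))
  }
  if (p) {
    t1 <- matrix(0, p, n + p)   # t_i - v_i >= 0
    t1[cbind(seq_len(p), P)] <- -1
    t1[cbind(seq_len(p), n + seq_len(p))] <- 1
    t2 <- matrix(0, p, n + p)   # t_i + v_i >= 0
    t2[cbind(seq_len(p), P)] <- 1
    t2[cbind(seq_len(p), n + seq_len(p))] <- 1
    mat <- rbind(mat, t1, t2)
    dir <- c(dir, rep(">=", 2 * p))
    rhs <- c(rhs, numeric(2 * p))
  }
  res <- lp_run(
    obj = c(numeric(n), rep(1, p)),
    mat = mat, dir = dir, rhs = rhs,
    lb = c(lb, numeric(p)), ub = c(ub, big),
    maximize = FALSE
  )
  if (res$status != "optimal") return(NULL)
  res$v[seq_len(n)]
}

#' Maximal flux-consistent reaction set (FASTCC)
#'
#' Finds all reactions that can carry flux of magnitude at least `epsilon`
#' in some steady-state solution. Blocks of reactions are certified together
#' with the LP7 support LP; reversible reactions failing in the forward
#' orientation are retried sign-flipped; stragglers are tested singly. The
#' complement of the returned set is blocked at `epsilon`.
#'
#' @param model a [metabolic_model()].
#' @param config an [extraction_config()].
#' @return character vector of consistent reaction ids (in model order).
#' @export
fastcc_consistent <- function(model, config = extraction_config()) {
  eps <- config$epsilon
  n <- n_reactions(model)
  if (n == 0L) return(character(0))
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- unname(model_lb(model)); ub <- unname(model_ub(model))
  irr <- lb >= 0
  supp_tol <- eps * 0.99

  flip <- function(idx) {
    S[, idx] <<- -S[, idx]
    tmp <- lb[idx]
    lb[idx] <<- -ub[idx]
    ub[idx] <<- -tmp
  }

  A <- integer(0)
  J <- which(irr)
  if (length(J)) {
    v <- lp7(S, lb, ub, J, eps)
    A <- which(abs(v) >= supp_tol)
    inc_irr <- setdiff(J, A)
  } else {
    inc_irr <- integer(0)
  }
  J <- setdiff(seq_len(n), union(A, inc_irr))
  singleton <- FALSE
  flipped <- FALSE
  while (length(J)) {
    Ji <- if (singleton) J[1] else J
    v <- lp7(S, lb, ub, Ji, eps)
    A <- union(A, which(abs(v) >= supp_tol))
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
    } else {
      Ji_rev <- setdiff(Ji, which(irr))
      if (flipped || !length(Ji_rev)) {
        flipped <- FALSE
        if (singleton) {
          J <- setdiff(J, Ji)    # blocked
        } else {
          singleton <- TRUE
        }
      } else {
        flip(Ji_rev)
        flipped <- TRUE
      }
    }
  }
  reaction_ids(model)[sort(A)]
}

#' Minimal core-preserving extraction (FASTCORE)
#'
#' Given a flux-consistent model and a core set, finds a flux-consistent
#' subnetwork containing every core reaction and few others, by alternating
#' the LP7 support LP (how many core reactions reach flux >= epsilon) with
#' the LP10 L1-sparsity LP (minimise total absolute flux through non-core
#' reactions while the supported core carries flux). Unsatisfied reversible
#' core reactions are retried sign-flipped.
#'
#' @param model a [metabolic_model()] that is flux-consistent at
#'   `config$epsilon` (inactive reactions already removed; see
#'   [fastcc_consistent()]).
#' @param core character vector of core reaction ids.
#' @param config an [extraction_config()].
#' @return a `context_model`: list with the extracted `model`,
#'   `kept_reactions`, `removed_reactions`, and `provenance`.
#' @export
fastcore_extract <- function(model, core, config = extraction_config()) {
  ids <- reaction_ids(model)
  bad <- setdiff(core, ids)
  if (length(bad)) {
    abort(paste0("core reaction(s) not in model: ", paste(bad, collapse = ", ")))
  }
  eps <- config$epsilon
  supp_tol <- eps * 0.99
  n <- n_reactions(model)
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- unname(model_lb(model)); ub <- unname(model_ub(model))
  irr <- which(lb >= 0)
  C <- match(core, ids)

  flip <- function(idx) {
    S[, idx] <<- -S[, idx]
    tmp <- lb[idx]
    lb[idx] <<- -ub[idx]
    ub[idx] <<- -tmp
  }

  find_sparse_mode <- function(J, P) {
    if (!length(J)) return(numeric(n))
    v1 <- lp7(S, lb, ub, J, eps)
    K <- J[v1[J] >= supp_tol]
    if (!length(K)) return(numeric(n))
    v2 <- lp10(S, lb, ub, K, P, eps)
    if (is.null(v2)) return(numeric(n))
    v2
  }

  if (!length(C)) {
    return(new_context_model(model, character(0), ids, config,
                             note = "empty core"))
  }

  A <- integer(0)
  J <- intersect(C, irr)
  P <- setdiff(seq_len(n), C)
  v <- find_sparse_mode(J, P)
  A <- union(A, which(abs(v) >= supp_tol))
  if (!all(J %in% A)) {
    abort(paste0("inconsistent irreversible core reaction(s): ",
                 paste(ids[setdiff(J, A)], collapse = ", ")))
  }
  J <- setdiff(C, A)
  singleton <- FALSE
  flipped <- FALSE
  iter <- 0L
  while (length(J)) {
    iter <- iter + 1L
    if (iter > config$max_iterations) {
      abort("extraction did not converge within max_iterations")
    }
    P <- setdiff(P, A)
    Ji <- if (singleton) J[1] else J
    v <- find_sparse_mode(Ji, P)
    A <- union(A, which(abs(v) >= supp_tol))
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
    } else {
      Ji_rev <- setdiff(Ji, irr)
      if (flipped || !length(Ji_rev)) {
        if (singleton) {
          abort(paste0("core reaction(s) unsupportable in the consistent model: ",
                       paste(ids[Ji], collapse = ", ")))
        }
        flipped <- FALSE
        singleton <- TRUE
      } else {
        flip(Ji_rev)
        flipped <- TRUE
      }
    }
  }
  kept <- ids[sort(A)]

  # redundancy pruning: sparse modes can carry incidental flux through
  # non-core reactions that a different mode would not need; drop any added
  # reaction whose removal leaves a flux-consistent network still
  # containing the whole core
  for (r in setdiff(kept, core)) {
    cand <- setdiff(kept, r)
    if (!length(cand)) next
    sub_c <- subset_model(model, cand)
    cons_c <- tryCatch(fastcc_consistent(sub_c, config),
                       error = function(e) character(0))
    if (length(cons_c) == length(cand)) kept <- cand
  }

  new_context_model(model, kept, setdiff(ids, kept), config)
}

new_context_model <- function(parent, kept, removed, config, note = NULL,
                              provenance = list()) {
  sub <- if (length(kept)) subset_model(parent, kept) else NULL
  structure(
    list(
      model = sub,
      kept_reactions = kept,
      removed_reactions = removed,
      provenance = c(list(parent = parent$id, config = unclass(config),
                          note = note), provenance)
    ),
    class = "context_model"
  )
}

#' @export
print.context_model <- function(x, ...) {
  cat(sprintf("<context_model of '%s'>  kept %d, removed %d reactions\n",
              x$provenance$parent, length(x$kept_reactions),
              length(x$removed_reactions)))
  invisible(x)
}

#' @export
glance.context_model <- function(x, ...) {
  base <- if (is.null(x$model)) {
    tibble(n_metabolites = 0L, n_reactions = 0L, n_genes = 0L)
  } else {
    glance(x$model)[c("n_metabolites", "n_reactions", "n_genes")]
  }
  dplyr::bind_cols(
    tibble(sample = x$provenance$sample_id %||% NA_character_,
           group = x$provenance$group %||% NA_character_),
    base,
    tibble(n_removed = length(x$removed_reactions),
           n_active_genes = x$provenance$n_active_genes %||% NA_integer_)
  )
}

#' Build a context-specific model for one sample
#'
#' The composed per-sample workflow: discretise the sample's expression,
#' classify reactions via GPR rules, remove inactive reactions, prune to the
#' flux-consistent subnetwork, and extract the minimal consistent subnetwork
#' containing the core. Component counts are recorded in the provenance for
#' cohort-level reporting.
#'
#' @param model the parent [metabolic_model()].
#' @param expr an [expression_matrix()] containing `sample_id`.
#' @param sample_id sample to build.
#' @param config an [extraction_config()].
#' @param disc optional pre-computed `gene_discretization` (e.g. from a
#'   pooled fit); when supplied the expression arguments are not consulted
#'   for fitting.
#' @return a `context_model` whose `model` retains the parent objective
#'   (objective reactions are protected into the core when
#'   `config$protect_objective`).
#' @export
build_context_model <- function(model, expr, sample_id,
                                config = extraction_config(), disc = NULL) {
  if (is.null(disc)) {
    tpmv <- expr$tpm[, sample_id]
    params <- fit_expression_mixture(log2(tpmv[tpmv > 0] + 1))
    disc <- discretize_genes(expr, sample_id, params, config$z_margin)
  }
  sets <- classify_reactions(model, disc)

  core <- sets$core
  if (config$protect_objective) {
    core <- union(core, model$reactions$id[model$reactions$objective_coef != 0])
  }
  keep0 <- setdiff(reaction_ids(model), setdiff(sets$inactive, core))
  sub <- subset_model(model, keep0)

  consistent <- fastcc_consistent(sub, config)
  sub2 <- subset_model(sub, consistent)
  core2 <- intersect(core, consistent)

  ctx <- fastcore_extract(sub2, core2, config)
  ctx$removed_reactions <- setdiff(reaction_ids(model), ctx$kept_reactions)
  ctx$provenance$parent <- model$id
  ctx$provenance$sample_id <- sample_id
  ctx$provenance$core_sets <- vapply(sets, length, integer(1))
  ctx$provenance$n_active_genes <- sum(disc$category == 1L)
  ctx$provenance$n_inactive_genes <- sum(disc$category == -1L)
  ctx$discretization <- disc
  ctx
}

# --- metabolic tasks ----------------------------------------------------

#' Define a metabolic task
#'
#' A feasibility probe: with all exchanges closed, can the model produce the
#' required outputs from the allowed inputs?
#'
#' @param id task identifier.
#' @param allowed_inputs named numeric vector: metabolite id -> maximum
#'   uptake.
#' @param required_outputs named numeric vector: metabolite id -> minimum
#'   production.
#' @param description free-text description.
#' @return a `task_definition`.
#' @export
task_definition <- function(id, allowed_inputs, required_outputs,
                            description = "") {
  if (!length(required_outputs)) abort("a task needs at least one required output")
  structure(
    list(id = id, allowed_inputs = allowed_inputs,
         required_outputs = required_outputs, description = description),
    class = "task_definition"
  )
}

#' Read task definitions from YAML or JSON
#'
#' Expected structure: a list of entries with `id`, `inputs` (metabolite ->
#' max uptake), `outputs` (metabolite -> min production), `description`.
#'
#' @param path file path (`.yml`/`.yaml`/`.json`).
#' @return list of [task_definition()].
#' @export
read_tasks <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(t) {
    task_definition(
      id = t$id,
      allowed_inputs = unlist(t$inputs) %||% numeric(0),
      required_outputs = unlist(t$outputs),
      description = t$description %||% ""
    )
  })
}

#' Check metabolic task feasibility
#'
#' For each task: all exchange reactions are closed, temporary uptake
#' reactions are opened for the allowed inputs (at their stated maxima) and
#' temporary demand reactions for the required outputs (at their stated
#' minima), and steady-state feasibility is tested. The input model is not
#' modified. Tasks naming metabolites absent from the model are reported
#' infeasible with reason `"unsupported"`.
#'
#' @param model a [metabolic_model()].
#' @param tasks list of [task_definition()] (or a single one).
#' @return tibble with columns `task_id`, `feasible`, `reason`.
#' @export
check_tasks <- function(model, tasks) {
  if (inherits(tasks, "task_definition")) tasks <- list(tasks)
  purrr::map_dfr(tasks, function(task) {
    mets <- c(names(task$allowed_inputs), names(task$required_outputs))
    missing <- setdiff(mets, metabolite_ids(model))
    if (length(missing)) {
      return(tibble(task_id = task$id, feasible = FALSE,
                    reason = "unsupported"))
    }
    m <- model
    orig <- m$reactions
    # map metabolite -> its exchange reaction (standard coef -1 convention:
    # positive flux exports, negative imports)
    exch_ids <- orig$id[orig$is_exchange]
    exch_map <- character(0)
    for (r in exch_ids) {
      stc <- m$stoichiometry[m$stoichiometry$reaction == r, ]
      if (nrow(stc) == 1L && stc$coef == -1) exch_map[stc$metabolite] <- r
    }
    orig_lb <- setNames(orig$lb, orig$id)
    orig_ub <- setNames(orig$ub, orig$id)
    for (r in exch_ids) m <- set_bounds(m, r, lb = 0, ub = 0)

    extra_rxns <- list()
    extra_st <- list()
    for (met in names(task$allowed_inputs)) {
      cap <- task$allowed_inputs[[met]]
      if (met %in% names(exch_map)) {
        # open uptake through the model's own exchange, never wider than the
        # model's medium allows (so e.g. a respirometry-closed oxygen
        # exchange stays closed)
        r <- exch_map[[met]]
        m <- set_bounds(m, r, lb = max(orig_lb[[r]], -cap), ub = 0)
      } else {
        rid <- paste0("TASK_in_", met)
        extra_rxns[[rid]] <- tibble(
          id = rid, name = rid, lb = 0, ub = cap,
          gpr = NA_character_, subsystem = "task", objective_coef = 0)
        extra_st[[rid]] <- tibble(reaction = rid, metabolite = met, coef = 1)
      }
    }
    for (met in names(task$required_outputs)) {
      need <- task$required_outputs[[met]]
      if (met %in% names(exch_map)) {
        r <- exch_map[[met]]
        m <- set_bounds(m, r, lb = need, ub = max(orig_ub[[r]], need))
      } else {
        rid <- paste0("TASK_out_", met)
        extra_rxns[[rid]] <- tibble(
          id = rid, name = rid, lb = need, ub = 1e6,
          gpr = NA_character_, subsystem = "task", objective_coef = 0)
        extra_st[[rid]] <- tibble(reaction = rid, metabolite = met, coef = -1)
      }
    }
    m2 <- metabolic_model(
      id = paste0(m$id, "_task"),
      metabolites = m$metabolites,
      reactions = dplyr::bind_rows(
        m$reactions[setdiff(names(m$reactions), "is_exchange")],
        dplyr::bind_rows(extra_rxns)),
      stoichiometry = dplyr::bind_rows(m$stoichiometry,
                                       dplyr::bind_rows(extra_st)),
      compartments = m$compartments
    )
    res <- flux_lp(m2, setNames(numeric(n_reactions(m2)), reaction_ids(m2)),
                   maximize = FALSE)
    tibble(task_id = task$id, feasible = res$status == "optimal",
           reason = if (res$status == "optimal") NA_character_ else res$status)
  })
}
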