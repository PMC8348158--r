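# Shared fixtures and independent oracles, all built in code.

# minimal linear chain: EX_a (uptake of A) -> R1 (A -> B) -> EX_b (export)
make_chain_model <- function(ub = 10) {
  metabolic_model(
    "chain",
    tibble::tibble(id = c("A", "B"), name = c("A", "B"), compartment = "c"),
    tibble::tibble(
      id = c("EX_a", "R1", "EX_b"), name = c("EX_a", "R1", "EX_b"),
      lb = 0, ub = ub, gpr = NA_character_, subsystem = NA_character_,
      objective_coef = c(0, 0, 1)),
    tibble::tibble(
      reaction = c("EX_a", "R1", "R1", "EX_b"),
      metabolite = c("A", "A", "B", "B"),
      coef = c(1, -1, 1, -1)),
    c(c = "cytosol")
  )
}

# two routes from A to B: direct R_fast, or the two-step detour R_s1 + R_s2
make_parallel_model <- function() {
  metabolic_model(
    "parallel",
    tibble::tibble(id = c("A", "B", "X"), name = c("A", "B", "X"),
                   compartment = "c"),
    tibble::tibble(
      id = c("EX_a", "R_fast", "R_s1", "R_s2", "EX_b"),
      name = c("EX_a", "R_fast", "R_s1", "R_s2", "EX_b"),
      lb = 0, ub = 10, gpr = NA_character_, subsystem = NA_character_,
      objective_coef = c(0, 0, 0, 0, 1)),
    tibble::tibble(
      reaction = c("EX_a", "R_fast", "R_fast", "R_s1", "R_s1",
                   "R_s2", "R_s2", "EX_b"),
      metabolite = c("A", "A", "B", "A", "X", "X", "B", "B"),
      coef = c(1, -1, 1, -1, 1, -1, 1, -1)),
    c(c = "cytosol")
  )
}

# Independent dense LP re-solve through the system python's scipy (HiGHS):
# max/min obj'v s.t. S v = 0, lb <= v <= ub. A wholly separate
# implementation lineage from the package's own simplex kernel. Problems
# are passed as a JSON batch so one interpreter start-up covers many LPs.
oracle_lp_batch <- function(problems) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(problems, infile, auto_unbox = FALSE, digits = NA)
  script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog
with open(sys.argv[1]) as fh:
    problems = json.load(fh)
out = []
for p in problems:
    c = np.array(p["obj"], float)
    sense = -1.0 if p["maximize"][0] else 1.0
    res = linprog(sense * c, A_eq=np.array(p["S"], float),
                  b_eq=np.zeros(len(p["S"])),
                  bounds=list(zip(p["lb"], p["ub"])), method="highs")
    out.append({"status": int(res.status),
                "objective": float(np.dot(c, res.x)) if res.status == 0 else None,
                "x": list(map(float, res.x)) if res.status == 0 else None})
with open(sys.argv[2], "w") as fh:
    json.dump(out, fh)
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, infile, outfile), stdout = FALSE)
  if (status != 0) return(NULL)
  jsonlite::fromJSON(outfile, simplifyVector = FALSE)
}

oracle_lp_problem <- function(model, obj, maximize = TRUE) {
  S <- as.matrix(stoichiometric_matrix(model))
  list(S = unname(apply(S, 1, as.numeric, simplify = FALSE)),
       obj = as.numeric(obj),
       lb = as.numeric(gemflux:::model_lb(model)),
       ub = as.numeric(gemflux:::model_ub(model)),
       maximize = maximize)
}

oracle_lp <- function(model, obj, maximize = TRUE) {
  res <- oracle_lp_batch(list(oracle_lp_problem(model, obj, maximize)))
  if (is.null(res) || res[[1]]$status != 0) return(NULL)
  list(objective = res[[1]]$objective, v = unlist(res[[1]]$x))
}

# per-reaction FVA brute force: a reaction is flux-consistent iff it can
# reach |v| >= eps at steady state
oracle_consistent <- function(model, eps = 1e-4) {
  fr <- fva(model, fraction_of_optimum = 0)
  fr$reaction[fr$max >= eps * 0.99 | fr$min <= -eps * 0.99]
}

# cheap yes/no consistency check with early exit: is every reaction of the
# model consistent at eps?
oracle_all_consistent <- function(model, eps = 1e-4) {
  ids <- gemflux:::reaction_ids(model)
  n <- length(ids)
  for (r in ids) {
    unit <- setNames(numeric(n), ids)
    unit[r] <- 1
    hi <- gemflux:::flux_lp(model, unit, maximize = TRUE)
    if (hi$status == "optimal" && hi$objective >= eps * 0.99) next
    lo <- gemflux:::flux_lp(model, unit, maximize = FALSE)
    if (!(lo$status == "optimal" && lo$objective <= -eps * 0.99)) return(FALSE)
  }
  TRUE
}

# exhaustive minimal consistent-superset search at toy scale: smallest
# number of non-core reactions whose union with the core forms a
# flux-consistent subnetwork supporting every core reaction
oracle_min_added <- function(model, core, eps = 1e-4) {
  ids <- gemflux:::reaction_ids(model)
  noncore <- setdiff(ids, core)
  for (k in 0:length(noncore)) {
    combos <- if (k == 0) list(character(0)) else
      utils::combn(noncore, k, simplify = FALSE)
    for (add in combos) {
      keep <- c(core, add)
      sub <- subset_model(model, keep)
      ok <- tryCatch(oracle_all_consistent(sub, eps), error = function(e) FALSE)
      if (ok) return(k)
    }
  }
  NA_integer_
}

# random GPR rule generator over a small gene pool
random_gpr <- function(n_genes, max_depth = 3) {
  genes <- paste0("g", seq_len(n_genes))
  build <- function(depth) {
    if (depth >= max_depth || runif(1) < 0.4) {
      return(sample(genes, 1))
    }
    op <- sample(c("and", "or"), 1)
    k <- sample(2:3, 1)
    parts <- vapply(seq_len(k), function(i) build(depth + 1), character(1))
    paste0("(", paste(parts, collapse = paste0(" ", op, " ")), ")")
  }
  build(0)
}

# independent recursive evaluators over the parsed AST
oracle_eval_discrete <- function(node, categories, default_missing = 0L) {
  node <- unclass(node)
  if (node$kind == "gene") {
    v <- categories[node$id]
    return(if (is.na(v)) default_missing else unname(v))
  }
  vals <- vapply(node$children, oracle_eval_discrete, numeric(1),
                 categories = categories, default_missing = default_missing)
  if (node$kind == "and") min(vals) else max(vals)
}

oracle_eval_continuous <- function(node, levels, or_mode = "sum") {
  node <- unclass(node)
  if (node$kind == "gene") {
    v <- levels[node$id]
    return(if (is.na(v)) 0 else unname(v))
  }
  vals <- vapply(node$children, oracle_eval_continuous, numeric(1),
                 levels = levels, or_mode = or_mode)
  if (node$kind == "and") min(vals)
  else if (or_mode == "sum") sum(vals) else max(vals)
}
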