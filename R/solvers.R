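# Flux simulation machinery: FBA, parsimonious FBA, flux variability
# analysis, and hit-and-run sampling of the steady-state polytope
# {v : S v = 0, lb <= v <= ub}.

new_flux_distribution <- function(fluxes, objective_value, status, method) {
  structure(
    list(fluxes = fluxes, objective_value = objective_value,
         status = status, method = method),
    class = "flux_distribution"
  )
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution %s>  status: %s, objective: %s\n",
              x$method, x$status,
              if (is.na(x$objective_value)) "NA"
              else format(x$objective_value, digits = 6)))
  invisible(x)
}

#' @export
tidy.flux_distribution <- function(x, ...) {
  tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' @export
glance.flux_distribution <- function(x, ...) {
  tibble(status = x$status, objective_value = x$objective_value,
         method = x$method, total_flux = sum(abs(x$fluxes)))
}

#' Flux balance analysis
#'
#' Maximises the model objective `c'v` over the steady-state polytope.
#'
#' @param model a [metabolic_model()] with a declared objective (or an
#'   `objective` override).
#' @param objective optional named numeric vector of objective coefficients
#'   overriding the model's.
#' @return a `flux_distribution` with `status` one of `"optimal"`,
#'   `"infeasible"`, `"unbounded"`.
#' @export
fba <- function(model, objective = NULL) {
  obj <- fba_objective(model, objective)
  res <- flux_lp(model, obj, maximize = TRUE)
  new_flux_distribution(
    fluxes = if (res$status == "optimal") setNames(res$v, reaction_ids(model))
             else setNames(rep(NA_real_, n_reactions(model)), reaction_ids(model)),
    objective_value = res$objective,
    status = res$status, method = "fba"
  )
}

fba_objective <- function(model, objective = NULL) {
  if (is.null(objective)) {
    obj <- objective_vector(model)
    if (all(obj == 0)) {
      abort("model has no objective; declare one or pass `objective`")
    }
    return(obj)
  }
  obj <- setNames(numeric(n_reactions(model)), reaction_ids(model))
  bad <- setdiff(names(objective), names(obj))
  if (length(bad)) abort(paste0("unknown objective reaction(s): ",
                                paste(bad, collapse = ", ")))
  obj[names(objective)] <- objective
  obj
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP: stage 1 finds the optimal objective value, stage 2 minimises
#' total absolute flux `sum(|v|)` subject to retaining at least
#' `fraction_of_optimum` of it. The stage-2 solution is the canonical flux
#' state reported throughout the package: plain FBA optima are typically
#' degenerate and solver-dependent, the parsimonious one is reproducible.
#'
#' @inheritParams fba
#' @param fraction_of_optimum fraction of the stage-1 optimum that must be
#'   retained (default 1.0).
#' @return a `flux_distribution` (method `"pfba"`); `objective_value` is the
#'   achieved `c'v`, and `total_flux` in [glance()] the minimised `sum(|v|)`.
#' @export
pfba <- function(model, objective = NULL, fraction_of_optimum = 1.0) {
  obj <- fba_objective(model, objective)
  stage1 <- flux_lp(model, obj, maximize = TRUE)
  if (stage1$status != "optimal") {
    return(new_flux_distribution(
      setNames(rep(NA_real_, n_reactions(model)), reaction_ids(model)),
      NA_real_, stage1$status, "pfba"))
  }
  n <- n_reactions(model)
  lb <- model_lb(model); ub <- model_ub(model)
  S <- as.matrix(stoichiometric_matrix(model))

  # split v = p - q, p,q >= 0, minimise sum(p + q); rows: S(p-q) = 0,
  # c'(p-q) >= fraction * optimum, and explicit rows where a bound does not
  # survive the split (lb > 0 or ub < 0)
  mat <- cbind(S, -S)
  dir <- rep("=", nrow(S))
  rhs <- rep(0, nrow(S))
  mat <- rbind(mat, c(obj, -obj))
  dir <- c(dir, ">=")
  rhs <- c(rhs, fraction_of_optimum * stage1$objective)
  pos <- which(lb > 0)
  if (length(pos)) {
    rows <- matrix(0, length(pos), 2 * n)
    rows[cbind(seq_along(pos), pos)] <- 1
    rows[cbind(seq_along(pos), n + pos)] <- -1
    mat <- rbind(mat, rows); dir <- c(dir, rep(">=", length(pos)))
    rhs <- c(rhs, lb[pos])
  }
  neg <- which(ub < 0)
  if (length(neg)) {
    rows <- matrix(0, length(neg), 2 * n)
    rows[cbind(seq_along(neg), neg)] <- 1
    rows[cbind(seq_along(neg), n + neg)] <- -1
    mat <- rbind(mat, rows); dir <- c(dir, rep("<=", length(neg)))
    rhs <- c(rhs, ub[neg])
  }
  res <- lp_run(
    obj = rep(1, 2 * n), mat = mat, dir = dir, rhs = rhs,
    lb = rep(0, 2 * n), ub = c(pmax(ub, 0), pmax(-lb, 0)),
    maximize = FALSE
  )
  if (res$status != "optimal") {
    return(new_flux_distribution(
      setNames(rep(NA_real_, n), reaction_ids(model)),
      NA_real_, res$status, "pfba"))
  }
  v <- res$v[seq_len(n)] - res$v[n + seq_len(n)]
  new_flux_distribution(setNames(v, reaction_ids(model)),
                        sum(obj * v), "optimal", "pfba")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to steady state, bounds,
#' and (when the model has an objective and `fraction_of_optimum > 0`)
#' retention of at least that fraction of the FBA optimum.
#'
#' @inheritParams fba
#' @param reactions reaction ids to analyse (default: all).
#' @param fraction_of_optimum fraction of the optimum to retain; use 0 to
#'   explore the unconstrained polytope.
#' @return an `fva_result`: a tibble with columns `reaction`, `min`, `max`
#'   and attribute `fraction`.
#' @export
fva <- function(model, reactions = NULL, fraction_of_optimum = 1.0,
                objective = NULL) {
  reactions <- reactions %||% reaction_ids(model)
  bad <- setdiff(reactions, reaction_ids(model))
  if (length(bad)) abort(paste0("unknown reaction(s): ", paste(bad, collapse = ", ")))

  extra <- fva_objective_row(model, objective, fraction_of_optimum)
  n <- n_reactions(model)
  out <- purrr::map(reactions, function(r) {
    unit <- setNames(numeric(n), reaction_ids(model))
    unit[r] <- 1
    lo <- flux_lp(model, unit, maximize = FALSE, extra_mat = extra$mat,
                  extra_dir = extra$dir, extra_rhs = extra$rhs)
    hi <- flux_lp(model, unit, maximize = TRUE, extra_mat = extra$mat,
                  extra_dir = extra$dir, extra_rhs = extra$rhs)
    if (lo$status != "optimal" || hi$status != "optimal") {
      abort(sprintf("FVA subproblem not optimal for '%s' (%s)", r, lo$status))
    }
    tibble(reaction = r, min = lo$objective, max = hi$objective)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "fraction") <- fraction_of_optimum
  class(res) <- c("fva_result", class(res))
  res
}

fva_objective_row <- function(model, objective, fraction_of_optimum) {
  none <- list(mat = NULL, dir = NULL, rhs = NULL)
  if (fraction_of_optimum <= 0) return(none)
  obj <- tryCatch(fba_objective(model, objective), error = function(e) NULL)
  if (is.null(obj)) return(none)
  base <- flux_lp(model, obj, maximize = TRUE)
  if (base$status != "optimal") {
    abort(sprintf("base FBA is %s; cannot run constrained FVA", base$status))
  }
  list(mat = matrix(obj, nrow = 1), dir = ">=",
       rhs = fraction_of_optimum * base$objective)
}

#' Hit-and-run sampling of the steady-state flux polytope
#'
#' Coordinate hit-and-run in null-space coordinates of S: each step moves
#' along one basis direction of `null(S)`, along the chord the flux bounds
#' admit. The chain is warm-started from the centroid of the FVA extreme
#' solutions (a deep interior point of the polytope) and thinned.
#'
#' @param model a feasible [metabolic_model()].
#' @param n_samples number of samples to return (default 2000).
#' @param seed integer seed; the ensemble is reproducible given it.
#' @param thinning steps between retained samples (default 100).
#' @return a `sample_ensemble`: list with `samples`
#'   (`n_samples x n_reactions` matrix), `seed`, `method`, `thinning`.
#' @export
sample_fluxes <- function(model, n_samples = 2000L, seed = 1L,
                          thinning = 100L) {
  n <- n_reactions(model)
  lb <- model_lb(model); ub <- model_ub(model)
  extremes <- fva_extreme_points(model)
  v0 <- rowMeans(extremes)
  v0 <- pmin(pmax(v0, lb), ub)

  S <- as.matrix(stoichiometric_matrix(model))
  N <- null_space(S)
  if (ncol(N) == 0L) {
    samples <- matrix(rep(v0, each = n_samples), nrow = n_samples)
  } else {
    set.seed(seed)
    samples <- cpp_hit_and_run(N, v0, lb, ub, as.integer(n_samples),
                               as.integer(thinning))
  }
  colnames(samples) <- reaction_ids(model)
  structure(
    list(samples = samples, seed = seed, method = "hit_and_run",
         thinning = thinning),
    class = "sample_ensemble"
  )
}

# One optimal vertex per FVA direction; used as warm-start material only
fva_extreme_points <- function(model) {
  n <- n_reactions(model)
  ids <- reaction_ids(model)
  cols <- lapply(ids, function(r) {
    unit <- setNames(numeric(n), ids); unit[r] <- 1
    lo <- flux_lp(model, unit, maximize = FALSE)
    hi <- flux_lp(model, unit, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      abort("flux polytope is empty; cannot sample")
    }
    cbind(lo$v, hi$v)
  })
  do.call(cbind, cols)
}

null_space <- function(S) {
  n <- ncol(S)
  qr_t <- qr(t(S))
  r <- qr_t$rank
  if (r >= n) return(matrix(0, n, 0))
  Q <- qr.Q(qr_t, complete = TRUE)
  Q[, (r + 1):n, drop = FALSE]
}

#' @export
print.sample_ensemble <- function(x, ...) {
  cat(sprintf("<sample_ensemble %s>  %d samples x %d reactions (seed %d, thinning %d)\n",
              x$method, nrow(x$samples), ncol(x$samples), x$seed, x$thinning))
  invisible(x)
}

#' @export
tidy.sample_ensemble <- function(x, ...) {
  as_tibble(x$samples) |>
    dplyr::mutate(draw = dplyr::row_number()) |>
    tidyr::pivot_longer(-"draw", names_to = "reaction", values_to = "flux")
}

#' Verify a sampled ensemble against its model
#'
#' Checks every sampled flux vector for steady state (`max |S v|`) and bound
#' violations; useful as an invariant gate before analysis.
#'
#' @param ensemble a `sample_ensemble`.
#' @param model the sampled [metabolic_model()].
#' @return tibble with `max_steady_state_violation`, `max_bound_violation`.
#' @export
check_ensemble <- function(ensemble, model) {
  S <- as.matrix(stoichiometric_matrix(model))
  V <- ensemble$samples
  sv <- max(abs(S %*% t(V)))
  lb <- model_lb(model); ub <- model_ub(model)
  bv <- max(0, max(sweep(V, 2, ub, "-")), max(sweep(-V, 2, -lb, "-")))
  tibble(max_steady_state_violation = sv, max_bound_violation = bv)
}
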