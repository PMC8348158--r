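# Generic linear-programming front end over the package's dense two-phase
# simplex kernel (src/simplex.cpp).  All flux LPs in the package -- FBA, pFBA,
# FVA, FASTCC's LP7, FASTCORE's sparsity LP -- are expressed through lp_run().
#
# Problem form:  optimise  obj'v   subject to
#   mat v (dir) rhs   with dir in {"=", "<=", ">="}  and  lb <= v <= ub.
# All variable bounds must be finite (constraint-based models use finite
# default bounds, +-1000 by convention), which keeps the standard-form
# translation elementary: shift v to x = v - lb >= 0, turn upper bounds into
# explicit rows, add slack columns for inequalities.

lp_run <- function(obj, mat, dir, rhs, lb, ub, maximize = FALSE) {
  n <- length(obj)
  mat <- as.matrix(mat)
  if (length(dir) != nrow(mat) || length(rhs) != nrow(mat)) {
    abort("lp_run: constraint dimensions disagree")
  }
  if (!all(is.finite(lb)) || !all(is.finite(ub))) {
    abort("lp_run: variable bounds must be finite")
  }
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", v = rep(NA_real_, n), objective = NA_real_))
  }

  # shift: x = v - lb
  shift_rhs <- rhs - as.vector(mat %*% lb)

  eq <- dir == "="
  le <- dir == "<="
  ge <- dir == ">="

  a_eq <- mat[eq, , drop = FALSE]
  b_eq <- shift_rhs[eq]
  a_le <- rbind(
    mat[le, , drop = FALSE],
    -mat[ge, , drop = FALSE],
    diag(n)                                   # x_i <= ub_i - lb_i
  )
  b_le <- c(shift_rhs[le], -shift_rhs[ge], ub - lb)

  n_le <- nrow(a_le)
  A <- rbind(
    cbind(a_eq, matrix(0, nrow(a_eq), n_le)),
    cbind(a_le, diag(n_le))
  )
  b <- c(b_eq, b_le)

  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }

  cost <- c(if (maximize) -obj else obj, rep(0, n_le))
  res <- cpp_simplex(A, b, cost)

  status <- switch(as.character(res$status),
    "0" = "optimal", "1" = "infeasible", "2" = "unbounded", "3" = "maxiter"
  )
  if (status != "optimal") {
    return(list(status = status, v = rep(NA_real_, n), objective = NA_real_))
  }
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", v = v, objective = sum(obj * v))
}

# Convenience: steady-state flux LP (S v = 0, bounds) with an arbitrary
# linear objective over reactions, optionally with extra constraint rows.
flux_lp <- function(model, obj, maximize = TRUE,
                    extra_mat = NULL, extra_dir = NULL, extra_rhs = NULL) {
  S <- as.matrix(stoichiometric_matrix(model))
  n <- ncol(S)
  mat <- S
  dir <- rep("=", nrow(S))
  rhs <- rep(0, nrow(S))
  if (!is.null(extra_mat)) {
    mat <- rbind(mat, extra_mat)
    dir <- c(dir, extra_dir)
    rhs <- c(rhs, extra_rhs)
  }
  lp_run(obj, mat, dir, rhs, model_lb(model), model_ub(model), maximize = maximize)
}
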