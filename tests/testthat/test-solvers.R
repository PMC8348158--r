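test_that("FBA solves bottleneck and infeasible/closed cases", {
  m <- make_chain_model(ub = 10)
  m <- set_bounds(m, "EX_a", ub = 10)
  m <- set_bounds(m, "R1", ub = 1000)
  sol <- fba(m)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)

  closed <- set_bounds(m, "EX_a", lb = 0, ub = 0)
  expect_equal(fba(closed)$objective_value, 0)

  expect_error(fba(metabolic_model(
    "noobj",
    tibble::tibble(id = "A", name = "A", compartment = "c"),
    tibble::tibble(id = "EX_a", name = "EX_a", lb = 0, ub = 1,
                   gpr = NA, subsystem = NA, objective_coef = 0),
    tibble::tibble(reaction = "EX_a", metabolite = "A", coef = 1),
    c(c = "c"))), "no objective")
})

test_that("toy network ATP yields equal their designed integer values", {
  m <- make_toy_model()
  m <- set_bounds(m, "DM_aa", lb = 0)  # isolate energy metabolism
  yield <- function(m, subs) {
    for (r in c("EX_glc_e", "EX_lac_e", "EX_pyr_e", "EX_ffa_e", "EX_gln_e")) {
      m <- set_bounds(m, r, lb = 0)
    }
    for (s in names(subs)) m <- set_bounds(m, s, lb = -subs[[s]])
    fba(m)$objective_value
  }
  expect_equal(yield(m, c(EX_glc_e = 1)), 26)
  expect_equal(yield(set_bounds(m, "EX_o2_e", lb = 0), c(EX_glc_e = 1)), 2)
  expect_equal(yield(set_bounds(m, "CPLX1", lb = 0, ub = 0), c(EX_glc_e = 1)), 16)
  expect_equal(yield(m, c(EX_ffa_e = 1)), 83)
  expect_equal(yield(m, c(EX_gln_e = 1)), 17)
})

test_that("pFBA picks the shortest of parallel routes and kills futile cycles", {
  m <- make_parallel_model()
  sol <- pfba(m)
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes[["R_fast"]]), 10)
  expect_equal(unname(sol$fluxes[["R_s1"]]), 0)
  expect_equal(unname(sol$fluxes[["R_s2"]]), 0)

  # unique pathway: pfba equals fba
  chain <- make_chain_model()
  expect_equal(pfba(chain)$fluxes, fba(chain)$fluxes, tolerance = 1e-8)

  # add a futile cycle A <-> B; pfba assigns it zero net extra flux
  cyc <- metabolic_model(
    "cyc", chain$metabolites,
    dplyr::bind_rows(tidy(chain)[1:7],
                     tibble::tibble(id = "R_back", name = "R_back", lb = 0,
                                    ub = 10, gpr = NA, subsystem = NA,
                                    objective_coef = 0)),
    dplyr::bind_rows(chain$stoichiometry,
                     tibble::tibble(reaction = "R_back",
                                    metabolite = c("B", "A"), coef = c(-1, 1))),
    chain$compartments)
  sc <- pfba(cyc)
  expect_equal(unname(sc$fluxes[["R_back"]]), 0)
  expect_equal(sum(abs(sc$fluxes)), sum(abs(pfba(chain)$fluxes)))
})

test_that("pFBA total flux never exceeds the FBA solution's at equal objective", {
  for (m in list(make_chain_model(), make_parallel_model(), make_toy_model())) {
    f <- fba(m); p <- pfba(m)
    expect_equal(p$objective_value, f$objective_value, tolerance = 1e-6)
    expect_lte(sum(abs(p$fluxes)), sum(abs(f$fluxes)) + 1e-6)
  }
})

test_that("FVA brackets fluxes correctly across regimes", {
  chain <- make_chain_model()
  fr <- fva(chain, fraction_of_optimum = 1.0)
  expect_equal(fr$min, fr$max, tolerance = 1e-8)   # unique pathway: no slack

  par <- make_parallel_model()
  fp <- fva(par, fraction_of_optimum = 1.0)
  expect_equal(fp$min[fp$reaction == "R_fast"], 0, tolerance = 1e-8)
  expect_equal(fp$max[fp$reaction == "R_fast"], 10, tolerance = 1e-8)
  expect_equal(fp$min[fp$reaction == "R_s1"], 0, tolerance = 1e-8)
  expect_equal(fp$max[fp$reaction == "R_s1"], 10, tolerance = 1e-8)

  # fraction 0: plain bound-constrained extremes
  f0 <- fva(chain, fraction_of_optimum = 0)
  expect_equal(f0$min, rep(0, 3), tolerance = 1e-9)
  expect_equal(f0$max, rep(10, 3), tolerance = 1e-9)
})

test_that("pFBA fluxes lie within FVA ranges", {
  for (m in list(make_parallel_model(), make_toy_model())) {
    p <- pfba(m)
    fr <- fva(m, fraction_of_optimum = 1.0)
    v <- p$fluxes[fr$reaction]
    expect_true(all(fr$min - 1e-6 <= v & v <= fr$max + 1e-6))
  }
})

test_that("LP results agree with an independent dense re-solve", {
  models <- list(make_chain_model(), make_parallel_model(), make_toy_model())
  for (m in models) {
    obj <- gemflux:::objective_vector(m)
    ours <- fba(m)
    ref <- oracle_lp(m, obj, maximize = TRUE)
    expect_false(is.null(ref))
    expect_equal(ours$objective_value, ref$objective, tolerance = 1e-6)
  }
  # FVA endpoints against the oracle on the small fixtures
  for (m in models[1:2]) {
    fr <- fva(m, fraction_of_optimum = 0)
    for (i in seq_len(nrow(fr))) {
      unit <- setNames(numeric(nrow(fr)), fr$reaction)
      unit[fr$reaction[i]] <- 1
      hi <- oracle_lp(m, unit, maximize = TRUE)
      lo <- oracle_lp(m, unit, maximize = FALSE)
      expect_equal(fr$max[i], hi$objective, tolerance = 1e-6)
      expect_equal(fr$min[i], lo$objective, tolerance = 1e-6)
    }
  }
})

test_that("hit-and-run samples are valid, deterministic and well mixed", {
  chain <- make_chain_model()
  ens <- sample_fluxes(chain, n_samples = 2000, seed = 31)
  chk <- check_ensemble(ens, chain)
  expect_lt(chk$max_steady_state_violation, 1e-6)
  expect_lte(chk$max_bound_violation, 1e-9)

  # the 1-D polytope is the interval [0, 10]: uniform mean is 5
  x <- ens$samples[, "EX_b"]
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 5), 3 * se)

  # extrema within FVA ranges
  fr <- fva(chain, fraction_of_optimum = 0)
  for (i in seq_len(nrow(fr))) {
    col <- ens$samples[, fr$reaction[i]]
    expect_gte(min(col), fr$min[i] - 1e-9)
    expect_lte(max(col), fr$max[i] + 1e-9)
  }

  expect_identical(sample_fluxes(chain, n_samples = 200, seed = 7)$samples,
                   sample_fluxes(chain, n_samples = 200, seed = 7)$samples)

  # point polytope: all samples identical
  fixed <- set_bounds(set_bounds(chain, "EX_a", lb = 4, ub = 4),
                      "EX_b", lb = 4, ub = 4)
  ef <- sample_fluxes(fixed, n_samples = 50, seed = 2)
  expect_equal(max(apply(ef$samples, 2, function(c) diff(range(c)))), 0,
               tolerance = 1e-9)
})

test_that("sampling a toy context polytope satisfies the ensemble invariants", {
  m <- make_toy_model()
  ens <- sample_fluxes(m, n_samples = 300, seed = 5)
  chk <- check_ensemble(ens, m)
  expect_lt(chk$max_steady_state_violation, 1e-6)
  expect_lte(chk$max_bound_violation, 1e-9)
})
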