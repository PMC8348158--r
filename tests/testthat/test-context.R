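test_that("reaction classification follows GPR evaluation of gene calls", {
  m <- make_chain_model()
  m$reactions$gpr <- c(NA, "g1 or g2", "g1 and g2")
  disc <- structure(list(sample_id = "s",
                         category = c(g1 = 1L, g2 = -1L),
                         score = c(g1 = 5, g2 = 0)),
                    class = "gene_discretization")
  sets <- classify_reactions(m, disc)
  expect_true("EX_a" %in% sets$noncore)    # no GPR -> noncore
  expect_true("R1" %in% sets$core)         # or: max(+1,-1) = +1
  expect_true("EX_b" %in% sets$inactive)   # and: min(+1,-1) = -1
  # the three sets partition the reactions
  expect_setequal(c(sets$core, sets$noncore, sets$inactive),
                  tidy(m)$id)
})

test_that("flux-consistency testing matches the chain and orphan examples", {
  chain <- make_chain_model()
  expect_setequal(fastcc_consistent(chain), c("EX_a", "R1", "EX_b"))

  # orphan C -> D with no source of C is blocked
  orphan <- metabolic_model(
    "orphan",
    dplyr::bind_rows(chain$metabolites,
                     tibble::tibble(id = c("C", "D"), name = c("C", "D"),
                                    compartment = "c", formula = NA)),
    dplyr::bind_rows(tidy(chain)[1:7],
                     tibble::tibble(id = "R_cd", name = "R_cd", lb = 0, ub = 10,
                                    gpr = NA, subsystem = NA, objective_coef = 0),
                     tibble::tibble(id = "EX_d", name = "EX_d", lb = 0, ub = 10,
                                    gpr = NA, subsystem = NA, objective_coef = 0)),
    dplyr::bind_rows(chain$stoichiometry,
                     tibble::tibble(reaction = c("R_cd", "R_cd", "EX_d"),
                                    metabolite = c("C", "D", "D"),
                                    coef = c(-1, 1, -1))),
    chain$compartments)
  cons <- fastcc_consistent(orphan)
  expect_false("R_cd" %in% cons)
  expect_false("EX_d" %in% cons)
  expect_setequal(cons, c("EX_a", "R1", "EX_b"))
})

test_that("flux consistency equals the per-reaction FVA oracle on random networks", {
  for (seed in 1:25) {
    m <- make_random_toy_network(seed)
    expect_setequal(fastcc_consistent(m), oracle_consistent(m))
  }
})

test_that("extraction keeps the core and adds the brute-force minimum", {
  # toy chain: core = {EX_b} forces the two upstream reactions in
  chain <- make_chain_model()
  ctx <- fastcore_extract(chain, "EX_b")
  expect_setequal(ctx$kept_reactions, c("EX_a", "R1", "EX_b"))
  expect_equal(length(setdiff(ctx$kept_reactions, "EX_b")),
               oracle_min_added(chain, "EX_b"))

  # core = everything: nothing added
  m <- make_parallel_model()
  all_ids <- tidy(m)$id
  ctx2 <- fastcore_extract(m, all_ids)
  expect_setequal(ctx2$kept_reactions, all_ids)

  # empty core: empty model
  ctx3 <- fastcore_extract(m, character(0))
  expect_length(ctx3$kept_reactions, 0)
})

test_that("extraction added-reaction counts equal exhaustive search on random instances", {
  set.seed(300)
  tested <- 0
  seed <- 0
  while (tested < 12 && seed < 100) {
    seed <- seed + 1
    m <- make_random_toy_network(seed + 400)
    cons <- fastcc_consistent(m)
    if (length(cons) < 4) next
    sub <- subset_model(m, cons)
    core <- sample(cons, max(2, ceiling(length(cons) * 0.6)))
    ctx <- fastcore_extract(sub, core)
    added <- length(setdiff(ctx$kept_reactions, core))
    expect_equal(added, oracle_min_added(sub, core),
                 info = sprintf("instance seed %d", seed + 400))
    # extraction output is itself flux-consistent and contains the core
    kept_model <- subset_model(sub, ctx$kept_reactions)
    expect_setequal(fastcc_consistent(kept_model), ctx$kept_reactions)
    expect_true(all(core %in% ctx$kept_reactions))
    tested <- tested + 1
  }
  expect_gte(tested, 12)
})

test_that("extraction is deterministic", {
  m <- subset_model(make_toy_model(), fastcc_consistent(make_toy_model()))
  core <- c("ATPS", "HEX_PFK", "GLS_GDH")
  a <- fastcore_extract(m, core)
  b <- fastcore_extract(m, core)
  expect_identical(a$kept_reactions, b$kept_reactions)
})

test_that("context building retains expressed pathways and prunes to consistency", {
  model <- make_toy_model()
  sim <- simulate_expression(model, cohort_config(seed = 77))
  ctx <- build_context_model(model, sim$expr, "control_1")
  kept <- ctx$kept_reactions
  sub <- tidy(ctx$model)
  # control sample keeps the energy backbone
  expect_true(all(c("HEX_PFK", "GAPDH_PGK", "ENO_PYK") %in% kept))
  expect_true(any(sub$subsystem == "oxphos"))
  # the kept network is flux-consistent: re-running consistency removes nothing
  expect_setequal(fastcc_consistent(ctx$model), kept)
  # component counts recorded for reporting
  g <- glance(ctx)
  expect_identical(g$sample, "control_1")
  expect_gt(g$n_active_genes, 0)
})

test_that("all genes expressed yields the consistent part of the parent model", {
  model <- make_toy_model()
  genes <- gemflux:::model_genes(model)
  disc <- structure(list(sample_id = "all_on",
                         category = setNames(rep(1L, length(genes)), genes),
                         score = setNames(rep(10, length(genes)), genes)),
                    class = "gene_discretization")
  sets <- classify_reactions(model, disc)
  cons <- fastcc_consistent(model)
  sub <- subset_model(model, cons)
  ctx <- fastcore_extract(sub, intersect(sets$core, cons))
  # every consistent reaction is either core or needed to support it here
  expect_true(all(intersect(sets$core, cons) %in% ctx$kept_reactions))
})

test_that("task checking honours inputs, outputs and unsupported metabolites", {
  m <- make_toy_model()
  tasks <- toy_tasks()
  res <- check_tasks(m, tasks)
  expect_true(all(res$feasible))

  # deleting ATP synthase and glycolytic phosphorylation kills ATP production
  broken <- set_bounds(set_bounds(m, "ATPS", lb = 0, ub = 0),
                       "GAPDH_PGK", lb = 0, ub = 0)
  broken <- set_bounds(broken, "ENO_PYK", lb = 0, ub = 0)
  atp_task <- tasks[[which(vapply(tasks, function(t) t$id, "") ==
                             "atp_from_glucose_aerobic")]]
  expect_false(check_tasks(broken, atp_task)$feasible)

  ghost <- task_definition("ghost", c(glc_e = 1), c(unobtainium_c = 1))
  rg <- check_tasks(m, ghost)
  expect_false(rg$feasible)
  expect_identical(rg$reason, "unsupported")

  # the model is not modified by task checking
  before <- tidy(m)
  invisible(check_tasks(m, tasks[[1]]))
  expect_identical(tidy(m), before)
})

test_that("task definitions read from YAML and JSON", {
  tasks <- toy_tasks()
  expect_gte(length(tasks), 10L)
  expect_true(all(vapply(tasks, function(t) length(t$required_outputs) >= 1, TRUE)))
  # JSON round trip of the same structure
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    lapply(tasks, function(t) list(id = t$id, inputs = as.list(t$allowed_inputs),
                                   outputs = as.list(t$required_outputs),
                                   description = t$description)),
    path, auto_unbox = TRUE)
  tasks2 <- read_tasks(path)
  expect_identical(vapply(tasks2, function(t) t$id, ""),
                   vapply(tasks, function(t) t$id, ""))
})
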