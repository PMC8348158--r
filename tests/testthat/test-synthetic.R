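test_that("the packaged toy network is fully flux-consistent", {
  m <- make_toy_model()
  cons <- fastcc_consistent(m)
  expect_setequal(cons, tidy(m)$id)
  # verified independently by the per-reaction FVA oracle
  expect_setequal(oracle_consistent(m), tidy(m)$id)
})

test_that("the toy network satisfies its structural contract", {
  m <- make_toy_model()
  td <- tidy(m)
  expect_equal(length(m$compartments), 3L)
  expect_setequal(
    unique(stats::na.omit(td$subsystem)),
    c("exchange", "transport", "glycolysis", "tca", "oxphos",
      "fatty_acid_oxidation", "amino_acid_metabolism", "atp_demand"))
  # oxphos has the four distinct machinery reactions
  expect_true(all(c("CPLX1", "CPLX2", "G3PSH", "ATPS") %in%
                    td$id[td$subsystem == "oxphos"]))
  # every enzymatic (non-exchange, non-demand) reaction carries a GPR
  enz <- td[!td$is_exchange & !td$id %in% c("O2t", "O2tm", "CO2t", "CO2tm",
                                            "ATPM", "LEAK"), ]
  expect_true(all(!is.na(enz$gpr)))
  expect_gte(glance(m)$n_genes, 55L)
  expect_equal(td$id[td$objective_coef != 0], "ATPM")
})

test_that("expression simulation reproduces the configured fold changes", {
  m <- make_toy_model()
  cfg <- cohort_config(seed = 5)
  sim <- simulate_expression(m, cfg)
  st <- sim$truth$gene_state
  down <- st$gene[st$down_regulated]
  stable_on <- st$gene[st$state == "on" & !st$down_regulated]
  expect_gte(length(down), 20L)

  g_mean <- function(genes, group) {
    cols <- names(sim$groups)[sim$groups == group]
    rowMeans(sim$expr$tpm[genes, cols, drop = FALSE])
  }
  # disease / control TPM ratio of down-regulated genes tracks disease_fold
  # (up to the compositional inflation TPM renormalisation applies to all
  # genes, which the stable-gene ratio estimates)
  infl <- median(g_mean(stable_on, "disease") / g_mean(stable_on, "control"))
  ratio <- median(g_mean(down, "disease") / g_mean(down, "control")) / infl
  expect_lt(abs(ratio - cfg$disease_fold) / cfg$disease_fold, 0.2)

  ratio_t <- median(g_mean(down, "treated") / g_mean(down, "control")) / infl
  expect_lt(abs(ratio_t - cfg$treated_fold) / cfg$treated_fold, 0.25)

  # genes outside the down-regulated subsystems are unchanged relative to
  # each other: their between-group ratios share one compositional factor
  expect_lt(stats::mad(log(g_mean(stable_on, "disease") /
                             g_mean(stable_on, "control"))), 0.35)
})

test_that("count noise approaches Poisson as dispersion vanishes", {
  m <- make_toy_model()
  cfg0 <- cohort_config(seed = 3, nb_dispersion = 0, n_per_group = 3L,
                        library_size_range = c(2e5, 2e5))
  sim0 <- simulate_expression(m, cfg0)
  counts <- sim0$expr$counts
  # variance/mean over replicate samples of the same group ~ 1 for Poisson
  ctrl <- counts[, grep("^control", colnames(counts))]
  keep <- rowMeans(ctrl) > 50
  vmr <- apply(ctrl[keep, ], 1, var) / rowMeans(ctrl[keep, ])
  # library-size variation inflates this; check it is near-Poisson scale,
  # far below the dispersed case
  cfg1 <- cohort_config(seed = 3, nb_dispersion = 0.5,
                        library_size_range = c(2e5, 2e5))
  sim1 <- simulate_expression(m, cfg1)
  ctrl1 <- sim1$expr$counts[, grep("^control", colnames(sim1$expr$counts))]
  keep1 <- rowMeans(ctrl1) > 50
  vmr1 <- apply(ctrl1[keep1, ], 1, var) / rowMeans(ctrl1[keep1, ])
  expect_lt(median(vmr), median(vmr1) / 5)
})

test_that("simulated expression is reproducible and respects the config contract", {
  m <- make_toy_model()
  a <- simulate_expression(m, cohort_config(seed = 12))
  b <- simulate_expression(m, cohort_config(seed = 12))
  expect_identical(a$expr$counts, b$expr$counts)
  expect_identical(a$groups, b$groups)
  expect_equal(length(a$groups), 9L)
  expect_error(cohort_config(disease_fold = 0.8, treated_fold = 0.5),
               "disease_fold")
  expect_error(cohort_config(n_per_group = 0), "n_per_group")
})

test_that("simulated respirometry orders groups by their fold factors", {
  cfg <- cohort_config(seed = 4, respirometry_noise_sd = 0)
  r <- simulate_respirometry(cfg)
  gm <- tapply(r$oxygen_flux, r$group, mean)
  expect_lt(gm[["disease"]], gm[["treated"]])
  expect_lt(gm[["treated"]], gm[["control"]])
  expect_equal(unname(gm[["control"]]), cfg$respirometry_base)

  expect_identical(simulate_respirometry(cfg), simulate_respirometry(cfg))

  # null configuration: all groups equal in expectation
  null_cfg <- cohort_config(seed = 4, disease_fold = 1, treated_fold = 1,
                            respirometry_noise_sd = 0)
  rn <- simulate_respirometry(null_cfg)
  expect_equal(unname(diff(range(tapply(rn$oxygen_flux, rn$group, mean)))), 0)
})

test_that("complex-I loss is compensated through complex II and the G3P shuttle", {
  m <- make_toy_model()
  m <- set_bounds(m, "DM_aa", lb = 0)
  for (r in c("EX_lac_e", "EX_pyr_e", "EX_ffa_e", "EX_gln_e")) {
    m <- set_bounds(m, r, lb = 0)
  }
  m <- set_bounds(m, "EX_glc_e", lb = -2)
  m <- set_bounds(m, "ATPM", lb = 30, ub = 30)
  base <- pfba(m, objective = c(ATPM = 1))
  ko <- pfba(set_bounds(m, "CPLX1", lb = 0, ub = 0), objective = c(ATPM = 1))
  expect_identical(ko$status, "optimal")   # ATP demand remains satisfiable
  expect_gte(ko$fluxes[["CPLX2"]], base$fluxes[["CPLX2"]] - 1e-9)
  expect_gt(ko$fluxes[["G3PSH"]], base$fluxes[["G3PSH"]])
})

test_that("random toy networks vary in size and include blocked reactions", {
  sizes <- integer(0); any_blocked <- FALSE
  for (seed in 1:15) {
    m <- make_random_toy_network(seed)
    sizes <- c(sizes, nrow(tidy(m)))
    cons <- fastcc_consistent(m)
    if (length(cons) < nrow(tidy(m))) any_blocked <- TRUE
  }
  expect_gt(length(unique(sizes)), 2L)
  expect_true(any_blocked)
})
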