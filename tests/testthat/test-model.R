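test_that("model construction assembles the stoichiometric matrix by definition", {
  m <- make_chain_model()
  S <- as.matrix(stoichiometric_matrix(m))
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(S["A", ], c(EX_a = 1, R1 = -1, EX_b = 0))
  expect_equal(S["B", ], c(EX_a = 0, R1 = 1, EX_b = -1))
  # repeated assembly is identical
  expect_identical(stoichiometric_matrix(m), stoichiometric_matrix(m))
  # a duplicated reversible copy of R1 duplicates its column
  m2 <- metabolic_model(
    "chain2", m$metabolites,
    dplyr::bind_rows(tidy(m)[1:7],
                     tibble::tibble(id = "R1b", name = "R1b", lb = -10, ub = 10,
                                    gpr = NA, subsystem = NA, objective_coef = 0)),
    dplyr::bind_rows(m$stoichiometry,
                     tibble::tibble(reaction = "R1b",
                                    metabolite = c("A", "B"), coef = c(-1, 1))),
    m$compartments)
  S2 <- as.matrix(stoichiometric_matrix(m2))
  expect_equal(unname(S2[, "R1b"]), unname(S2[, "R1"]))
})

test_that("construction rejects inconsistent input", {
  m <- make_chain_model()
  st_bad <- dplyr::bind_rows(m$stoichiometry,
                             tibble::tibble(reaction = "R1", metabolite = "X",
                                            coef = 1))
  expect_error(
    metabolic_model("bad", m$metabolites, m$reactions[names(m$reactions) != "is_exchange"],
                    st_bad, m$compartments),
    "X")
  r_bad <- tidy(m)[1:7]
  r_bad$lb[2] <- 5; r_bad$ub[2] <- 1
  expect_error(
    metabolic_model("bad", m$metabolites, r_bad, m$stoichiometry, m$compartments),
    "lb > ub")
})

test_that("validate_model reports dangling metabolites, dead ends and bound issues", {
  m <- make_chain_model()
  expect_equal(sum(validate_model(m)$severity == "error"), 0L)

  mets2 <- dplyr::bind_rows(m$metabolites,
                            tibble::tibble(id = "C", name = "C", compartment = "c",
                                           formula = NA_character_))
  m2 <- metabolic_model("dangling", mets2, tidy(m)[1:7], m$stoichiometry,
                        m$compartments)
  f <- validate_model(m2)
  expect_true(any(f$finding == "dangling" & f$id == "C"))

  m3 <- m
  m3$reactions$lb[2] <- 5
  m3$reactions$ub[2] <- 1
  f3 <- validate_model(m3)
  expect_true(any(f3$finding == "bounds" & f3$id == "R1"))
})

test_that("exchange reactions are identified structurally", {
  m <- make_toy_model()
  td <- tidy(m)
  expect_true(all(startsWith(td$id[td$is_exchange &
                                     grepl("^EX_", td$id)], "EX_")))
  expect_true(td$is_exchange[td$id == "DM_aa"])   # single-metabolite demand
  expect_false(td$is_exchange[td$id == "ATPM"])   # two-metabolite conversion
  expect_false(td$is_exchange[td$id == "CPLX1"])
})

test_that("JSON and SBML round trips preserve the model", {
  m <- make_toy_model()
  for (fmt in c("json", "sbml")) {
    path <- withr::local_tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    write_metabolic_model(m, path, format = fmt)
    m2 <- read_metabolic_model(path, format = fmt)
    t1 <- tidy(m); t2 <- tidy(m2)
    expect_equal(t2$id, t1$id)
    expect_equal(t2$lb, t1$lb)
    expect_equal(t2$ub, t1$ub)
    expect_equal(t2$subsystem, t1$subsystem)
    expect_equal(t2$objective_coef, t1$objective_coef)
    # GPR equivalence up to canonical serialisation
    for (i in seq_len(nrow(t1))) {
      if (is.na(t1$gpr[i])) {
        expect_true(is.na(t2$gpr[i]))
      } else {
        expect_identical(serialize_gpr(parse_gpr(t2$gpr[i])),
                         serialize_gpr(parse_gpr(t1$gpr[i])))
      }
    }
    expect_equal(as.matrix(stoichiometric_matrix(m2)),
                 as.matrix(stoichiometric_matrix(m)))
    expect_equal(m2$compartments[sort(names(m2$compartments))],
                 m$compartments[sort(names(m$compartments))])
  }
})

test_that("malformed model files raise informative errors", {
  bad_json <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites": [{"id": "A_c", "compartment": "c"}],
               "reactions": [{"id": "R1", "metabolites": {"X_c": -1},
                              "lower_bound": 0, "upper_bound": 10}],
               "compartments": {"c": "cytosol"}}', bad_json)
  expect_error(read_metabolic_model(bad_json), "X_c")

  old_sbml <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="old"/></sbml>', old_sbml)
  expect_error(read_metabolic_model(old_sbml), "Level 3")

  expect_error(read_metabolic_model("no_such_file.json"), "does not exist")
})

test_that("subset_model keeps only referenced metabolites and bounds edits validate", {
  m <- make_chain_model()
  sub <- subset_model(m, c("EX_a", "R1"))
  expect_setequal(tidy(sub)$id, c("EX_a", "R1"))
  expect_setequal(sub$metabolites$id, c("A", "B"))
  expect_error(subset_model(m, "nope"), "unknown reaction")
  expect_error(set_bounds(m, "R1", lb = 20, ub = 10), "lb > ub")
})

test_that("glance and tidy summarise models", {
  m <- make_toy_model()
  g <- glance(m)
  expect_equal(g$n_reactions, nrow(tidy(m)))
  expect_equal(g$n_compartments, 3L)
  expect_gt(g$n_genes, 50L)
})
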