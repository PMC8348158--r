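test_that("subsystem profiles sum absolute fluxes and normalise to one", {
  m <- metabolic_model(
    "p",
    tibble::tibble(id = c("A", "B", "C"), name = c("A", "B", "C"),
                   compartment = "c"),
    tibble::tibble(id = c("r1", "r2", "r3"), name = c("r1", "r2", "r3"),
                   lb = -10, ub = 10, gpr = NA,
                   subsystem = c("s1", "s1", "s2"), objective_coef = 0),
    tibble::tibble(reaction = c("r1", "r2", "r3"),
                   metabolite = c("A", "B", "C"), coef = 1),
    c(c = "c"))
  fd <- gemflux:::new_flux_distribution(
    c(r1 = 3, r2 = -4, r3 = 7), 0, "optimal", "pfba")
  pr <- subsystem_profile(fd, m, label = "x")
  expect_equal(sum(pr$value), 1)
  expect_equal(pr$value[pr$subsystem == "s1"], 0.5)   # |3| + |-4| = |7|
  expect_equal(pr$value[pr$subsystem == "s2"], 0.5)

  # scale invariance
  fd2 <- gemflux:::new_flux_distribution(
    c(r1 = 30, r2 = -40, r3 = 70), 0, "optimal", "pfba")
  expect_equal(subsystem_profile(fd2, m)$value, subsystem_profile(fd, m)$value)

  # all-zero flux is undefined
  fd0 <- gemflux:::new_flux_distribution(
    c(r1 = 0, r2 = 0, r3 = 0), 0, "optimal", "pfba")
  expect_error(subsystem_profile(fd0, m), "all-zero")

  # single subsystem: mass 1
  m1 <- m; m1$reactions$subsystem <- "only"
  expect_equal(subsystem_profile(fd, m1)$value, 1)
})

test_that("cosine similarity matches its definition and error contract", {
  s <- cosine_similarity(rbind(a = c(1, 0), b = c(0, 1), c = c(2, 0)))
  expect_equal(unclass(s)["a", "b"], 0)
  expect_equal(unclass(s)["a", "c"], 1)          # scale invariance
  expect_equal(diag(unclass(s)), c(a = 1, b = 1, c = 1))
  expect_equal(unclass(s), t(unclass(s)))
  expect_true(all(unclass(s) >= -1 - 1e-12 & unclass(s) <= 1 + 1e-12))
  expect_error(cosine_similarity(rbind(a = c(1, 1), z = c(0, 0))), "z")
})

test_that("clustering separates orthogonal profiles and handles ties", {
  m <- rbind(p1 = c(1, 0, 0), p2 = c(0.99, 0.01, 0), p3 = c(0, 0, 1))
  cl <- cluster_profiles(m, k = 2)
  expect_identical(cl$labels[["p1"]], cl$labels[["p2"]])
  expect_false(cl$labels[["p1"]] == cl$labels[["p3"]])
  # identical profiles collapse into one cluster at any low cut
  same <- rbind(a = c(1, 2), b = c(2, 4), c = c(4, 8))
  cs <- cluster_profiles(same, k = 1)
  expect_true(all(cs$labels == 1))
  expect_error(cluster_profiles(m[1, , drop = FALSE]), "at least 2")
})

test_that("PCA embedding reflects data rank and duplicates", {
  coll <- rbind(a = c(1, 1), b = c(2, 2), c = c(3, 3))
  emb <- embed_profiles(coll, method = "pca")
  expect_lt(max(abs(emb$dim2)), 1e-8)             # rank-1 data

  dup <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(0, 1))
  e2 <- embed_profiles(dup, method = "pca")
  expect_equal(e2[e2$label == "a", c("dim1", "dim2")],
               e2[e2$label == "b", c("dim1", "dim2")],
               ignore_attr = TRUE)
  expect_error(embed_profiles(coll[1:2, ]), "at least 3")
})

test_that("UMAP embedding works when available, PCA fallback otherwise", {
  m <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1), d = c(2, 1))
  if (requireNamespace("uwot", quietly = TRUE)) {
    emb <- embed_profiles(m, method = "umap", seed = 1)
    expect_true(all(is.finite(emb$dim1)) && all(is.finite(emb$dim2)))
    expect_identical(emb$label, rownames(m))
  } else {
    expect_warning(emb <- embed_profiles(m, method = "umap"), "PCA")
    expect_true(all(is.finite(emb$dim1)))
  }
})

test_that("group comparison reports medians, shifts, overlap and rank sums", {
  set.seed(8)
  base <- matrix(rnorm(500, 5, 1), 250, 2,
                 dimnames = list(NULL, c("rxn1", "rxn2")))
  identical_groups <- list(g1 = base, g2 = base)
  cmp <- compare_groups(identical_groups)
  expect_true(all(cmp$median_diff == 0))
  expect_true(all(cmp$overlap == 1))

  shifted <- base
  shifted[, "rxn1"] <- shifted[, "rxn1"] + 2
  cmp2 <- compare_groups(list(ref = base, up = shifted), reference = "ref")
  d <- cmp2$median_diff[cmp2$group == "up" & cmp2$reaction == "rxn1"]
  expect_equal(d, 2, tolerance = 0.2)
  expect_lt(cmp2$overlap[cmp2$group == "up" & cmp2$reaction == "rxn1"],
            cmp2$overlap[cmp2$group == "up" & cmp2$reaction == "rxn2"])

  # a reaction absent from one group is structurally zero and flagged
  missing_col <- base[, "rxn1", drop = FALSE]
  cmp3 <- compare_groups(list(ref = base, partial = missing_col))
  row <- cmp3[cmp3$group == "partial" & cmp3$reaction == "rxn2", ]
  expect_true(row$absent)
  expect_equal(row$median, 0)

  expect_error(compare_groups(list(only = base)), "at least 2")
})

test_that("flux matrices stack solutions with structural zeros", {
  s1 <- gemflux:::new_flux_distribution(c(a = 1, b = 2), 0, "optimal", "pfba")
  s2 <- gemflux:::new_flux_distribution(c(b = 3, c = 4), 0, "optimal", "pfba")
  fm <- flux_vector_matrix(list(x = s1, y = s2))
  expect_equal(fm["x", "c"], 0)
  expect_equal(fm["y", "a"], 0)
  expect_equal(fm["y", "b"], 3)
})
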