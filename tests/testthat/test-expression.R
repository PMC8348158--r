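test_that("TPM normalisation matches its defining formula", {
  # two genes, lengths 1 kb and 2 kb, equal counts: rates 10 and 5,
  # so TPM = (2/3, 1/3) * 1e6
  counts <- matrix(c(10L, 10L), ncol = 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  e <- tpm_from_counts(counts, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(e$tpm[, 1]), c(666666.6667, 333333.3333), tolerance = 1e-9)

  # one gene: normalisation forces 1e6 regardless of count
  e1 <- tpm_from_counts(matrix(7L, dimnames = list("g", "s")), c(g = 500))
  expect_equal(unname(e1$tpm[1, 1]), 1e6)

  # symmetry: equal counts and lengths split evenly
  e2 <- tpm_from_counts(matrix(c(5L, 5L), ncol = 1,
                               dimnames = list(c("a", "b"), "s")),
                        c(a = 800, b = 800))
  expect_equal(unname(e2$tpm[, 1]), c(5e5, 5e5))
})

test_that("TPM columns sum to 1e6 on random count matrices", {
  set.seed(11)
  for (rep in 1:5) {
    n_g <- sample(20:80, 1); n_s <- sample(2:5, 1)
    counts <- matrix(rnbinom(n_g * n_s, mu = 50, size = 2), n_g, n_s,
                     dimnames = list(paste0("g", 1:n_g), paste0("s", 1:n_s)))
    counts[1, ] <- pmax(counts[1, ], 1L)   # avoid an all-zero sample
    lens <- setNames(sample(200:3000, n_g), rownames(counts))
    e <- tpm_from_counts(counts, lens)
    expect_equal(unname(colSums(e$tpm)), rep(1e6, n_s), tolerance = 1e-9)
  }
})

test_that("TPM errors name the offending gene or sample", {
  counts <- matrix(c(1L, 2L), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_error(tpm_from_counts(counts, c(g1 = 1000)), "g2")
  z <- matrix(0L, 2, 1, dimnames = list(c("g1", "g2"), "empty_sample"))
  expect_error(tpm_from_counts(z, c(g1 = 1000, g2 = 1000)), "empty_sample")
})

test_that("the two-Gaussian fit recovers known generating components", {
  set.seed(42)
  x <- c(rnorm(500, 1, 0.5), rnorm(500, 6, 1))
  p <- fit_expression_mixture(x)
  expect_identical(p$method, "gmm")
  expect_gt(p$mu_low, 0.7); expect_lt(p$mu_low, 1.3)
  expect_gt(p$mu_high, 5.5); expect_lt(p$mu_high, 6.5)
  expect_lt(p$mu_low, p$mu_high)

  # mirror-symmetric bimodal sample: weights balance
  set.seed(7)
  y <- c(rnorm(1000, 2, 0.6), rnorm(1000, 8, 0.6))
  py <- fit_expression_mixture(y)
  expect_lt(abs(py$w_low - py$w_high), 0.05)
})

test_that("degenerate expression triggers the quantile fallback", {
  expect_warning(p <- fit_expression_mixture(rep(3.2, 100)), "degenerate")
  expect_identical(p$method, "quantile")
  expect_error(fit_expression_mixture(c(1, 2, 3), min_nonzero = 30),
               "at least 30")
})

test_that("discretisation thresholds behave at the component means", {
  tpm <- matrix(c(2^6 - 1, 2^1 - 1, 2^3.5 - 1, 0), ncol = 1,
                dimnames = list(c("hi", "lo", "mid", "zero"), "s"))
  tpm[, 1] <- tpm[, 1] / sum(tpm[, 1]) * 1e6   # rescale to valid TPM
  # construct params directly so thresholds are exact on the raw scale
  raw <- expression_matrix(tpm)
  sc <- log2(tpm[, 1] + 1)
  params <- structure(list(mu_low = sc[["lo"]], mu_high = sc[["hi"]],
                           sd_low = 0.5, sd_high = 0.5, w_low = .5,
                           w_high = .5, method = "gmm"),
                      class = "mixture_params")
  d <- discretize_genes(raw, "s", params, z_margin = 1)
  expect_identical(unname(d$category[c("hi", "lo", "zero")]), c(1L, -1L, -1L))
  # a gene strictly between the two thresholds is unknown
  mid_val <- sc[["mid"]]
  if (mid_val > params$mu_low + 0.5 && mid_val < params$mu_high - 0.5) {
    expect_identical(unname(d$category[["mid"]]), 0L)
  }
  # crossed thresholds: midpoint splits, nobody is unknown
  params2 <- params; params2$sd_low <- 10; params2$sd_high <- 10
  d2 <- discretize_genes(raw, "s", params2, z_margin = 1)
  expect_false(any(d2$category == 0L))
})

test_that("discretisation is monotone in TPM", {
  set.seed(5)
  base_tpm <- sort(exp(rnorm(60, 4, 2)))
  tpm <- matrix(base_tpm / sum(base_tpm) * 1e6, ncol = 1,
                dimnames = list(paste0("g", 1:60), "s"))
  e <- expression_matrix(tpm)
  p <- fit_expression_mixture(log2(tpm[tpm > 0] + 1))
  d <- discretize_genes(e, "s", p)
  # categories ordered by TPM must be non-decreasing
  expect_true(all(diff(d$category[order(tpm[, 1])]) >= 0))
})

test_that("cohort discretisation recovers simulated on/off labels", {
  model <- make_toy_model()
  sim <- simulate_expression(model, cohort_config(seed = 101))
  d <- discretize_cohort(sim$expr)
  st <- sim$truth$gene_state
  on <- st$gene[st$state == "on"]
  off <- st$gene[st$state == "off"]
  for (s in sim$expr$sample_ids) {
    expect_gte(mean(d[[s]]$category[off] == -1L), 0.9)
  }
  for (s in grep("^control", sim$expr$sample_ids, value = TRUE)) {
    expect_gte(mean(d[[s]]$category[on] == 1L), 0.9)
  }
})

test_that("gene tables round trip through TSV", {
  m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  gemflux:::write_gene_table(m, path)
  expect_equal(read_gene_table(path), m)
})

test_that("expression PCA returns finite sample coordinates", {
  model <- make_toy_model()
  sim <- simulate_expression(model, cohort_config(seed = 2))
  pc <- expression_pca(sim$expr)
  expect_equal(nrow(pc), length(sim$expr$sample_ids))
  expect_true(all(is.finite(pc$PC1)))
})
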