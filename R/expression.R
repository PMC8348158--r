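# Expression handling: TPM normalisation from raw counts + gene lengths,
# delimited I/O, two-Gaussian discretisation of log2(TPM+1) into
# expressed / unknown / unexpressed, and a small PCA helper for exploratory
# looks at a cohort.

#' Construct an expression matrix object
#'
#' @param tpm genes x samples numeric matrix of TPM values (rownames = gene
#'   ids, colnames = sample ids).
#' @param counts optional genes x samples integer count matrix.
#' @param gene_lengths_bp optional named vector of gene lengths (bp).
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(tpm, counts = NULL, gene_lengths_bp = NULL) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)), !is.null(colnames(tpm)))
  if (any(tpm < 0)) abort("TPM values must be non-negative")
  csums <- colSums(tpm)
  bad <- abs(csums - 1e6) / 1e6 > 1e-3
  if (any(bad)) {
    abort(paste0("TPM columns must sum to 1e6; offending sample(s): ",
                 paste(colnames(tpm)[bad], collapse = ", ")))
  }
  structure(
    list(
      gene_ids = rownames(tpm),
      sample_ids = colnames(tpm),
      tpm = tpm,
      counts = counts,
      gene_lengths_bp = gene_lengths_bp
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix>  %d genes x %d samples (TPM%s)\n",
              length(x$gene_ids), length(x$sample_ids),
              if (is.null(x$counts)) "" else " + counts"))
  invisible(x)
}

#' @export
tidy.expression_matrix <- function(x, ...) {
  as_tibble(x$tpm, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "tpm")
}

#' TPM normalisation of a count matrix
#'
#' Transcripts per kilobase million: per sample, each gene's count is divided
#' by its length in kb to give a rate, and rates are scaled to sum to 10^6.
#'
#' @param counts genes x samples non-negative integer matrix with rownames
#'   (gene ids) and colnames (sample ids), or a data frame whose first column
#'   is the gene id.
#' @param gene_lengths_bp named vector (or two-column data frame
#'   `gene_id`, `length_bp`) of positive gene lengths in base pairs.
#' @return an [expression_matrix()] whose TPM columns each sum to 10^6.
#' @export
tpm_from_counts <- function(counts, gene_lengths_bp) {
  if (is.data.frame(counts)) {
    ids <- as.character(counts[[1]])
    counts <- as.matrix(counts[, -1, drop = FALSE])
    rownames(counts) <- ids
  }
  if (is.data.frame(gene_lengths_bp)) {
    gene_lengths_bp <- setNames(as.numeric(gene_lengths_bp[[2]]),
                                as.character(gene_lengths_bp[[1]]))
  }
  if (any(counts < 0)) abort("counts must be non-negative")
  missing_len <- setdiff(rownames(counts)[rowSums(counts) > 0],
                         names(gene_lengths_bp))
  if (length(missing_len)) {
    abort(paste0("no gene length for gene(s) with non-zero counts: ",
                 paste(head(missing_len, 5), collapse = ", ")))
  }
  lens <- gene_lengths_bp[rownames(counts)]
  lens[is.na(lens)] <- 1   # genes with all-zero counts; value irrelevant
  if (any(lens <= 0)) abort("gene lengths must be positive")

  rate <- counts / (lens / 1000)
  totals <- colSums(rate)
  if (any(totals == 0)) {
    abort(paste0("zero total length-normalised rate in sample(s): ",
                 paste(colnames(counts)[totals == 0], collapse = ", ")))
  }
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  expression_matrix(tpm, counts = counts, gene_lengths_bp = gene_lengths_bp)
}

#' Fit a two-component Gaussian mixture to expression values
#'
#' The discretisation model: across all (non-zero) genes of a sample, the
#' log2(TPM+1) distribution is decomposed into a low-expression and a
#' high-expression Gaussian. Fitting is delegated to `mclust` (1-D,
#' unequal-variance, G = 2), whose model-based hierarchical initialisation is
#' deterministic. Degenerate fits (vanishing component weight or variance, or
#' indistinguishable means) fall back to quantile-based pseudo-components
#' with a warning.
#'
#' @param log2_tpm_values numeric vector of log2(TPM+1) values (zeros already
#'   excluded by the caller).
#' @param min_nonzero minimum number of values required for a mixture fit.
#' @return a list with class `mixture_params`: `mu_low`, `mu_high`,
#'   `sd_low`, `sd_high`, `w_low`, `w_high`, and `method` (`"gmm"` or
#'   `"quantile"`).
#' @export
fit_expression_mixture <- function(log2_tpm_values, min_nonzero = 30L) {
  x <- log2_tpm_values[is.finite(log2_tpm_values)]
  if (length(x) < min_nonzero) {
    abort(sprintf("need at least %d values for a mixture fit, got %d",
                  min_nonzero, length(x)))
  }
  # (near-)constant input cannot support a two-component fit and can hang
  # the EM backend; divert to the fallback directly
  fit <- if (length(unique(x)) < 3L || sd(x) < 1e-8) NULL else tryCatch(
    suppressWarnings(Mclust(x, G = 2, modelNames = "V", verbose = FALSE)),
    error = function(e) NULL
  )
  degenerate <- is.null(fit) ||
    any(fit$parameters$pro < 1e-3) ||
    any(sqrt(fit$parameters$variance$sigmasq) < 1e-6) ||
    diff(range(fit$parameters$mean)) < 1e-6
  if (degenerate) {
    warn("degenerate two-Gaussian fit; falling back to quantile thresholds")
    qs <- quantile(x, c(0.25, 0.75), names = FALSE)
    s <- max(sd(x), 1e-8)
    params <- list(mu_low = qs[1], mu_high = qs[2],
                   sd_low = s / 2, sd_high = s / 2,
                   w_low = 0.5, w_high = 0.5, method = "quantile")
  } else {
    ord <- order(fit$parameters$mean)
    mu <- fit$parameters$mean[ord]
    sig <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sig) == 1L) sig <- rep(sig, 2)   # equal-variance edge case
    sig <- sig[ord]
    w <- fit$parameters$pro[ord]
    params <- list(mu_low = unname(mu[1]), mu_high = unname(mu[2]),
                   sd_low = unname(sig[1]), sd_high = unname(sig[2]),
                   w_low = unname(w[1]), w_high = unname(w[2]),
                   method = "gmm")
  }
  structure(params, class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf(
    "<mixture_params %s>  low: N(%.2f, %.2f^2) w=%.2f | high: N(%.2f, %.2f^2) w=%.2f\n",
    x$method, x$mu_low, x$sd_low, x$w_low, x$mu_high, x$sd_high, x$w_high))
  invisible(x)
}

#' Discretise genes of one sample into expressed / unknown / unexpressed
#'
#' A gene is called expressed (+1) when its log2(TPM+1) lies within
#' `z_margin` standard deviations below the high component's mean or above,
#' unexpressed (-1) when within `z_margin` standard deviations above the low
#' component's mean or below, and unknown (0) in between. When the two
#' thresholds cross (strongly overlapping components), the midpoint of the
#' component means splits the calls and no gene is left unknown. Genes with
#' TPM = 0 are called unexpressed directly: the RNA-seq zero mass carries no
#' graded evidence and is excluded from the mixture fit upstream.
#'
#' @param expr an [expression_matrix()].
#' @param sample_id sample to discretise.
#' @param params [fit_expression_mixture()] output for this sample (or the
#'   pooled cohort).
#' @param z_margin width, in component standard deviations, of the margin
#'   defining the expressed / unexpressed calls (default 1).
#' @return an object of class `gene_discretization` with fields `sample_id`,
#'   `category` (named integer vector in -1/0/+1), `score` (named numeric,
#'   log2(TPM+1)), `params`, `thresholds`.
#' @export
discretize_genes <- function(expr, sample_id, params, z_margin = 1.0) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(params, "mixture_params"))
  if (!sample_id %in% expr$sample_ids) {
    abort(sprintf("unknown sample '%s'", sample_id))
  }
  tpm <- expr$tpm[, sample_id]
  score <- log2(tpm + 1)
  thr_hi <- params$mu_high - z_margin * params$sd_high
  thr_lo <- params$mu_low + z_margin * params$sd_low
  category <- integer(length(score))
  if (thr_hi < thr_lo) {
    mid <- (params$mu_low + params$mu_high) / 2
    category <- ifelse(score >= mid, 1L, -1L)
  } else {
    category <- ifelse(score >= thr_hi, 1L, ifelse(score <= thr_lo, -1L, 0L))
  }
  category[tpm == 0] <- -1L
  names(category) <- names(score) <- expr$gene_ids
  structure(
    list(sample_id = sample_id, category = category, score = score,
         params = params, thresholds = c(low = thr_lo, high = thr_hi),
         z_margin = z_margin),
    class = "gene_discretization"
  )
}

#' @export
print.gene_discretization <- function(x, ...) {
  tab <- table(factor(x$category, levels = c(-1, 0, 1)))
  cat(sprintf(
    "<gene_discretization '%s'>  expressed: %d, unknown: %d, unexpressed: %d\n",
    x$sample_id, tab[["1"]], tab[["0"]], tab[["-1"]]))
  invisible(x)
}

#' @export
tidy.gene_discretization <- function(x, ...) {
  tibble(gene = names(x$category), sample = x$sample_id,
         score = unname(x$score), category = unname(x$category))
}

#' Fit-and-discretise convenience for a whole cohort
#'
#' @param expr an [expression_matrix()].
#' @param z_margin see [discretize_genes()].
#' @param fit `"per_sample"` (default) fits one mixture per sample;
#'   `"pooled"` fits a single mixture on all samples' non-zero values and
#'   applies it to every sample.
#' @param min_nonzero see [fit_expression_mixture()].
#' @return named list of `gene_discretization`, one per sample.
#' @export
discretize_cohort <- function(expr, z_margin = 1.0,
                              fit = c("per_sample", "pooled"),
                              min_nonzero = 30L) {
  fit <- match.arg(fit)
  pooled_params <- NULL
  if (fit == "pooled") {
    vals <- log2(expr$tpm[expr$tpm > 0] + 1)
    pooled_params <- fit_expression_mixture(vals, min_nonzero)
  }
  out <- lapply(expr$sample_ids, function(s) {
    params <- pooled_params %||% {
      tpm <- expr$tpm[, s]
      fit_expression_mixture(log2(tpm[tpm > 0] + 1), min_nonzero)
    }
    discretize_genes(expr, s, params, z_margin)
  })
  setNames(out, expr$sample_ids)
}

#' Exploratory PCA of an expression cohort
#'
#' PCA on log2(TPM+1), samples as observations.
#'
#' @param expr an [expression_matrix()].
#' @param n_components number of principal components to keep.
#' @return tibble with `sample` and `PC1..PCk` columns.
#' @export
expression_pca <- function(expr, n_components = 2L) {
  x <- t(log2(expr$tpm + 1))
  keep <- apply(x, 2, function(col) sd(col) > 0)
  p <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  dplyr::bind_cols(tibble(sample = expr$sample_ids),
                   as_tibble(p$x[, seq_len(k), drop = FALSE]))
}

# --- delimited I/O ------------------------------------------------------

#' Read a gene x sample count (or TPM) table
#'
#' @param path TSV/CSV with a header row; first column gene id.
#' @return numeric matrix with gene rownames.
#' @export
read_gene_table <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read a gene-length table (`gene_id`, `length_bp`)
#'
#' @param path TSV with header.
#' @return named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

write_gene_table <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
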