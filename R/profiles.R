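# Flux-profile analytics: subsystem aggregation, cosine similarity,
# hierarchical clustering, 2-D embedding, and descriptive per-reaction
# comparison of sampled flux distributions between groups.

#' Subsystem flux profile of a flux distribution
#'
#' Absolute fluxes are summed per subsystem (reactions without a subsystem
#' pool into `"other"`) and the profile is normalised to sum to 1, making
#' profiles comparable across context models of different size and overall
#' flux scale.
#'
#' @param flux a `flux_distribution` (e.g. from [pfba()]).
#' @param model the model the fluxes live on (source of subsystem
#'   annotations).
#' @param label profile label (defaults to the model id).
#' @return a `subsystem_profile`: tibble with columns `label`, `subsystem`,
#'   `value`, values summing to 1.
#' @export
subsystem_profile <- function(flux, model, label = model$id) {
  v <- flux$fluxes[reaction_ids(model)]
  if (all(is.na(v))) abort("flux distribution has no solution")
  sub <- model$reactions$subsystem
  sub[is.na(sub)] <- "other"
  tot <- tapply(abs(v), sub, sum)
  if (sum(tot) == 0) abort("all-zero flux vector: profile undefined")
  out <- tibble(label = label, subsystem = names(tot),
                value = as.numeric(tot) / sum(tot))
  class(out) <- c("subsystem_profile", class(out))
  out
}

# Stack a list of profiles (or named vectors) into a labels x subsystems
# matrix, zero-filling subsystems absent from a profile (reactions absent
# from a context model contribute no flux).
profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  if (is.data.frame(profiles)) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (is.data.frame(p)) setNames(p$value, p$subsystem) else p
  })
  labs <- names(profiles) %||% vapply(profiles, function(p) {
    if (is.data.frame(p)) p$label[1] else NA_character_
  }, character(1))
  if (anyNA(labs)) labs <- paste0("profile", seq_along(rows))
  cols <- sort(unique(unlist(lapply(rows, names))))
  m <- matrix(0, length(rows), length(cols), dimnames = list(labs, cols))
  for (i in seq_along(rows)) m[i, names(rows[[i]])] <- rows[[i]]
  m
}

#' Cosine similarity matrix
#'
#' @param x a list of profiles / named flux vectors, or a numeric matrix
#'   with one observation per row.
#' @return a `similarity_matrix`: symmetric matrix with unit diagonal and
#'   entries `x_i . x_j / (|x_i| |x_j|)`.
#' @export
cosine_similarity <- function(x) {
  m <- profile_matrix(x)
  norms <- sqrt(rowSums(m^2))
  zero <- norms == 0
  if (any(zero)) {
    abort(paste0("zero vector(s) in cosine similarity: ",
                 paste(rownames(m)[zero], collapse = ", ")))
  }
  sim <- (m %*% t(m)) / outer(norms, norms)
  sim <- (sim + t(sim)) / 2     # enforce exact symmetry
  diag(sim) <- 1
  structure(sim, class = c("similarity_matrix", "matrix"))
}

#' @export
tidy.similarity_matrix <- function(x, ...) {
  m <- unclass(x)
  as_tibble(m, rownames = "from") |>
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "similarity")
}

#' Hierarchical clustering of flux profiles
#'
#' Agglomerative clustering on cosine distance (1 - cosine similarity).
#'
#' @param profiles as in [cosine_similarity()].
#' @param k optional number of flat clusters to cut.
#' @param linkage agglomeration method (default `"average"`).
#' @return a `profile_clustering`: list with the `hclust` tree, the
#'   similarity matrix, and (when `k` given) integer `labels`.
#' @export
cluster_profiles <- function(profiles, k = NULL, linkage = "average") {
  m <- profile_matrix(profiles)
  if (nrow(m) < 2) abort("need at least 2 profiles to cluster")
  sim <- cosine_similarity(m)
  d <- as.dist(pmax(1 - unclass(sim), 0))
  tree <- hclust(d, method = linkage)
  labels <- if (!is.null(k)) cutree(tree, k = k) else NULL
  structure(list(tree = tree, similarity = sim, labels = labels, k = k),
            class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("<profile_clustering>  %d profiles%s\n",
              length(x$tree$order),
              if (is.null(x$k)) "" else sprintf(", cut at k = %d", x$k)))
  invisible(x)
}

#' 2-D embedding of flux profiles
#'
#' @param profiles as in [cosine_similarity()].
#' @param method `"pca"` or `"umap"`. UMAP requires an optional dependency;
#'   when unavailable the function falls back to PCA with a warning.
#' @param seed seed for stochastic methods.
#' @return tibble with columns `label`, `dim1`, `dim2`.
#' @export
embed_profiles <- function(profiles, method = c("pca", "umap"), seed = 1L) {
  method <- match.arg(method)
  m <- profile_matrix(profiles)
  if (nrow(m) < 3) abort("need at least 3 profiles to embed")
  if (method == "umap") {
    if (!requireNamespace("uwot", quietly = TRUE)) {
      warn("UMAP backend not available; falling back to PCA")
      method <- "pca"
    }
  }
  if (method == "umap") {
    set.seed(seed)
    emb <- uwot::umap(m, n_neighbors = min(nrow(m) - 1L, 15L), n_components = 2)
  } else {
    keep <- apply(m, 2, function(col) sd(col) > 0)
    if (!any(keep)) {
      emb <- matrix(0, nrow(m), 2)
    } else {
      p <- prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
      emb <- cbind(p$x[, 1], if (ncol(p$x) >= 2) p$x[, 2] else 0)
    }
  }
  tibble(label = rownames(m), dim1 = emb[, 1], dim2 = emb[, 2])
}

#' Descriptive per-reaction comparison of sampled flux ensembles
#'
#' Compares the sampling distributions of each reaction across groups:
#' group medians, median difference against the reference group, overlap
#' coefficient of the sampled distributions, and the Wilcoxon rank-sum
#' statistic. Purely descriptive; no significance claims are attached.
#' Reactions absent from a group's context model are reported `absent` with
#' flux treated as structurally zero.
#'
#' @param ensembles named list of `sample_ensemble` (or bare sample
#'   matrices), one per group.
#' @param reactions reaction ids to compare (default: union across groups).
#' @param reference reference group (default: first).
#' @return tibble with one row per reaction x group.
#' @export
compare_groups <- function(ensembles, reactions = NULL, reference = NULL) {
  if (length(ensembles) < 2) abort("need at least 2 groups to compare")
  mats <- lapply(ensembles, function(e) {
    if (inherits(e, "sample_ensemble")) e$samples else as.matrix(e)
  })
  groups <- names(mats) %||% paste0("group", seq_along(mats))
  names(mats) <- groups
  reference <- reference %||% groups[1]
  if (!reference %in% groups) abort(sprintf("unknown reference group '%s'", reference))
  reactions <- reactions %||% sort(unique(unlist(lapply(mats, colnames))))

  col_or_zero <- function(m, r) {
    if (r %in% colnames(m)) m[, r] else rep(0, nrow(m))
  }
  out <- list()
  for (r in reactions) {
    ref_x <- col_or_zero(mats[[reference]], r)
    for (g in groups) {
      x <- col_or_zero(mats[[g]], r)
      absent <- !(r %in% colnames(mats[[g]]))
      out[[length(out) + 1L]] <- tibble(
        reaction = r, group = g, absent = absent,
        median = median(x),
        median_diff = median(x) - median(ref_x),
        overlap = overlap_coefficient(x, ref_x),
        rank_sum = rank_sum_statistic(x, ref_x)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "reference") <- reference
  class(res) <- c("group_comparison", class(res))
  res
}

# Overlap coefficient of two empirical distributions: integral of the
# pointwise minimum of their binned densities (1 = identical support and
# shape, 0 = disjoint).
overlap_coefficient <- function(x, y, n_bins = 50L) {
  rng <- range(c(x, y))
  if (diff(rng) == 0) return(1.0)     # both point masses at the same value
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  px <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) / length(x)
  py <- tabulate(findInterval(y, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) / length(y)
  sum(pmin(px, py))
}

# Wilcoxon rank-sum (Mann-Whitney U) statistic of x against y
rank_sum_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}
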