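# ggplot2 front-ends for the package's result types.

#' Plot subsystem flux profiles
#'
#' @param profiles a `subsystem_profile` tibble (one or many labels).
#' @return a ggplot.
#' @export
plot_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$label, y = .data$value,
                               fill = .data$subsystem)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "normalised |flux| share", fill = "subsystem") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.subsystem_profile <- function(object, ...) plot_profiles(object)

#' @export
autoplot.similarity_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$from, y = .data$to,
                               fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(min(object), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cosine") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a 2-D profile embedding
#'
#' @param embedding tibble from [embed_profiles()], optionally with a
#'   `group` column.
#' @return a ggplot.
#' @export
plot_embedding <- function(embedding) {
  aes <- if ("group" %in% names(embedding)) {
    ggplot2::aes(x = .data$dim1, y = .data$dim2, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$dim1, y = .data$dim2)
  }
  ggplot2::ggplot(embedding, aes) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.group_comparison <- function(object, reactions = NULL, ...) {
  df <- object
  if (!is.null(reactions)) df <- df[df$reaction %in% reactions, ]
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$reaction, y = .data$median,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "median sampled flux", fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Density plot of sampled fluxes for selected reactions
#'
#' @param ensembles named list of `sample_ensemble` (one per group).
#' @param reactions reaction ids to show.
#' @return a ggplot.
#' @export
plot_flux_samples <- function(ensembles, reactions) {
  df <- purrr::imap_dfr(ensembles, function(e, g) {
    m <- if (inherits(e, "sample_ensemble")) e$samples else as.matrix(e)
    keep <- intersect(reactions, colnames(m))
    purrr::map_dfr(keep, function(r) {
      tibble(group = g, reaction = r, flux = m[, r])
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flux, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(~reaction, scales = "free") +
    ggplot2::labs(x = "sampled flux", y = "density", fill = "group") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fva_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(y = stats::reorder(.data$reaction, .data$max))) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$min, xend = .data$max,
                                       yend = stats::reorder(.data$reaction,
                                                             .data$max)),
                          linewidth = 2, colour = "steelblue") +
    ggplot2::labs(x = "flux range", y = NULL) +
    ggplot2::theme_minimal()
}
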