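# Cohort-level orchestration: per-sample context building with E-Flux (and
# optional respirometry) caps, pFBA subsystem profiles, group-level pooled
# models for sampling, and the file-based simulate / build / analyze
# workflow the command-line wrapper drives.

#' Pool an expression cohort to one column per group
#'
#' Group-level TPM is the mean of the member samples' TPM columns (each
#' column of the result still sums to 10^6).
#'
#' @param expr an [expression_matrix()].
#' @param groups named character vector sample -> group.
#' @return an [expression_matrix()] with one column per group.
#' @export
pooled_expression <- function(expr, groups) {
  gs <- unique(unname(groups))
  tpm <- vapply(gs, function(g) {
    rowMeans(expr$tpm[, names(groups)[groups == g], drop = FALSE])
  }, numeric(length(expr$gene_ids)))
  expression_matrix(tpm)
}

#' Build one expression-constrained context model
#'
#' Composes context extraction ([build_context_model()]) with E-Flux bound
#' capping ([eflux_bounds()]) and, when a respirometry value is supplied,
#' the oxygen-uptake cap ([apply_respirometry()]).
#'
#' @param model parent [metabolic_model()].
#' @param expr an [expression_matrix()].
#' @param sample_id sample (or pooled group) column to use.
#' @param config an [extraction_config()].
#' @param v_max E-Flux cap for the top-scoring reaction.
#' @param or_mode GPR OR-semantics for scoring, see
#'   [reaction_activity_scores()].
#' @param oxygen_flux optional respirometry oxygen flux for this sample's
#'   group.
#' @param respirometry_scale conversion factor for `oxygen_flux`.
#' @param oxygen_exchange oxygen exchange reaction id.
#' @return a list: `context` (the `context_model`), `bounded` (the E-Flux
#'   capped `bounded_model`), `model` (the capped [metabolic_model()] ready
#'   to simulate).
#' @export
build_constrained_model <- function(model, expr, sample_id,
                                    config = extraction_config(),
                                    v_max = 1000, or_mode = "sum",
                                    oxygen_flux = NULL,
                                    respirometry_scale = 1,
                                    oxygen_exchange = "EX_o2_e") {
  ctx <- build_context_model(model, expr, sample_id, config)
  scores <- reaction_activity_scores(ctx$model, expr, sample_id,
                                     or_mode = or_mode)
  bounded <- eflux_bounds(ctx$model, scores, v_max = v_max)
  m <- bounded$model
  if (!is.null(oxygen_flux) &&
      oxygen_exchange %in% reaction_ids(m)) {
    bounded <- apply_respirometry(m, oxygen_flux, scale = respirometry_scale,
                                  oxygen_exchange = oxygen_exchange)
    m <- bounded$model
  }
  list(context = ctx, bounded = bounded, model = m)
}

#' Calibrate the respirometry conversion factor on the control group
#'
#' The conversion from measured oxygen flux (pmol O2/s/mg protein) to model
#' flux units is not identified by either data source, so it is fixed by
#' requiring the control group's cap to sit exactly at the control model's
#' unconstrained optimal oxygen uptake -- non-binding at the control
#' optimum, and proportionally tighter for groups with lower measured
#' respiration.
#'
#' @param control_model the control group's constrained model (pre-cap).
#' @param control_oxygen_flux the control group's measured oxygen flux.
#' @param oxygen_exchange oxygen exchange reaction id.
#' @return scale factor (flux units per measurement unit).
#' @export
calibrate_respirometry_scale <- function(control_model, control_oxygen_flux,
                                         oxygen_exchange = "EX_o2_e") {
  if (control_oxygen_flux <= 0) abort("control oxygen flux must be positive")
  sol <- pfba(control_model)
  if (sol$status != "optimal") abort("control model is not solvable")
  uptake <- max(0, -sol$fluxes[[oxygen_exchange]])
  uptake / control_oxygen_flux
}

#' Full cohort analysis in memory
#'
#' Per sample: context extraction, E-Flux capping, pFBA, subsystem profile.
#' Cohort level: cosine similarity, hierarchical clustering (k = number of
#' groups), PCA embedding, and (when `n_flux_samples > 0`) group-level
#' pooled models sampled with hit-and-run and compared per reaction.
#'
#' @param model parent [metabolic_model()].
#' @param expr an [expression_matrix()].
#' @param groups named character vector sample -> group.
#' @param config an [extraction_config()].
#' @param v_max E-Flux cap.
#' @param n_flux_samples hit-and-run samples per group model (0 = skip
#'   sampling).
#' @param seed seed for sampling.
#' @param respirometry optional tibble (`group`, `oxygen_flux`) of
#'   measurements; the conversion factor is calibrated on the control
#'   (first) group via [calibrate_respirometry_scale()].
#' @return list with `samples` (per-sample build results), `profiles`,
#'   `similarity`, `clustering`, `embedding`, `group_models`, `ensembles`,
#'   `comparison`.
#' @export
analyze_cohort <- function(model, expr, groups,
                           config = extraction_config(), v_max = 1000,
                           n_flux_samples = 0L, seed = 1L,
                           respirometry = NULL) {
  # when respirometry is supplied, calibrate its unit conversion on the
  # control (first) group's pooled model, then cap oxygen uptake per group
  resp_flux <- NULL
  resp_scale <- NULL
  gs_all <- unique(unname(groups))
  if (!is.null(respirometry)) {
    resp_flux <- tapply(respirometry$oxygen_flux, respirometry$group, mean)
    pooled0 <- pooled_expression(expr, groups)
    ctrl0 <- build_constrained_model(model, pooled0, gs_all[1], config, v_max)
    resp_scale <- calibrate_respirometry_scale(ctrl0$model,
                                               resp_flux[[gs_all[1]]])
  }

  builds <- lapply(names(groups), function(s) {
    build_constrained_model(
      model, expr, s, config, v_max,
      oxygen_flux = if (is.null(resp_flux)) NULL else resp_flux[[groups[[s]]]],
      respirometry_scale = resp_scale %||% 1)
  })
  names(builds) <- names(groups)

  solutions <- purrr::imap(builds, function(b, s) pfba(b$model))
  profiles <- purrr::imap(builds, function(b, s) {
    subsystem_profile(solutions[[s]], b$model, label = s)
  })
  profiles_tbl <- dplyr::bind_rows(profiles)
  fluxes <- flux_vector_matrix(solutions)

  # similarity, clustering and embedding operate on the reaction-level pFBA
  # flux vectors (the profile tibble is the aggregated view)
  sim <- cosine_similarity(fluxes)
  clust <- cluster_profiles(fluxes, k = length(unique(groups)))
  emb <- embed_profiles(fluxes, method = "pca") |>
    dplyr::mutate(group = unname(groups[.data$label]))

  group_models <- NULL
  ensembles <- NULL
  comparison <- NULL
  if (n_flux_samples > 0) {
    pooled <- pooled_expression(expr, groups)
    gs <- gs_all
    group_models <- lapply(gs, function(g) {
      build_constrained_model(
        model, pooled, g, config, v_max,
        oxygen_flux = if (is.null(resp_flux)) NULL else resp_flux[[g]],
        respirometry_scale = resp_scale %||% 1)
    })
    names(group_models) <- gs
    ensembles <- purrr::imap(group_models, function(b, g) {
      sample_fluxes(b$model, n_samples = n_flux_samples,
                    seed = seed + match(g, gs), thinning = 100L)
    })
    comparison <- compare_groups(ensembles, reference = gs[1])
  }

  list(samples = builds, solutions = solutions, fluxes = fluxes,
       profiles = profiles_tbl, similarity = sim,
       clustering = clust, embedding = emb, group_models = group_models,
       ensembles = ensembles, comparison = comparison)
}

#' Stack flux distributions into a samples x reactions matrix
#'
#' Reactions absent from a solution's model contribute structural zeros.
#'
#' @param solutions named list of `flux_distribution`.
#' @return numeric matrix, one row per solution.
#' @export
flux_vector_matrix <- function(solutions) {
  all_r <- sort(unique(unlist(lapply(solutions, function(s) names(s$fluxes)))))
  out <- t(vapply(solutions, function(s) {
    x <- setNames(rep(0, length(all_r)), all_r)
    v <- s$fluxes[!is.na(s$fluxes)]
    x[names(v)] <- v
    x
  }, numeric(length(all_r))))
  out
}

#' Down-regulation recovery check against simulation ground truth
#'
#' Evaluates the combined profile mass of the down-regulated subsystems per
#' group and checks the expected ordering disease < treated < control. The
#' combined mass is the meaningful read-out: normalised profiles are
#' compositional, so the down-regulation signal manifests as the
#' down-regulated subsystems jointly losing share to the unaffected ones.
#'
#' @param profiles profile tibble from [analyze_cohort()] (`label`,
#'   `subsystem`, `value`).
#' @param groups named character vector sample -> group.
#' @param truth `ground_truth` from [simulate_expression()].
#' @return one-row tibble with per-group combined mass and a `recovered`
#'   flag.
#' @export
directional_recovery <- function(profiles, groups, truth) {
  cfg <- truth$config
  gmass <- profiles |>
    dplyr::mutate(group = unname(groups[.data$label])) |>
    dplyr::filter(.data$subsystem %in% cfg$down_subsystems) |>
    dplyr::group_by(.data$group, .data$label) |>
    dplyr::summarise(mass = sum(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mass = mean(.data$mass), .groups = "drop")
  val <- function(g) {
    x <- gmass$mass[gmass$group == g]
    if (length(x)) x else 0
  }
  ctrl <- val(cfg$groups[1]); dis <- val(cfg$groups[2]); trt <- val(cfg$groups[3])
  tibble(subsystems = paste(cfg$down_subsystems, collapse = "+"),
         control = ctrl, disease = dis, treated = trt,
         recovered = dis < trt & trt < ctrl)
}

# --- file-based workflow ------------------------------------------------

#' Simulate a synthetic study to disk
#'
#' Writes the toy model and a simulated cohort in the same formats the
#' pipeline reads: `model.json`, `counts.tsv`, `lengths.tsv`, `groups.tsv`,
#' `respirometry.tsv`, `truth.json`.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [cohort_config()].
#' @return invisibly, the list of written paths.
#' @export
run_simulate <- function(out_dir, config = cohort_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create '%s'", out_dir))
  model <- make_toy_model()
  sim <- simulate_expression(model, config)
  resp <- simulate_respirometry(config)

  paths <- list(
    model = file.path(out_dir, "model.json"),
    counts = file.path(out_dir, "counts.tsv"),
    lengths = file.path(out_dir, "lengths.tsv"),
    groups = file.path(out_dir, "groups.tsv"),
    respirometry = file.path(out_dir, "respirometry.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_model_json(model, paths$model)
  write_gene_table(sim$expr$counts, paths$counts)
  utils::write.table(
    data.frame(gene_id = names(sim$expr$gene_lengths_bp),
               length_bp = unname(sim$expr$gene_lengths_bp)),
    paths$lengths, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(sample = names(sim$groups), group = unname(sim$groups)),
    paths$groups, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(resp), paths$respirometry, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(gene_state = sim$truth$gene_state,
         expected_direction = sim$truth$expected_direction,
         config = unclass(config)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

read_cohort_inputs <- function(data_dir) {
  need <- c(model = "model.json", counts = "counts.tsv",
            lengths = "lengths.tsv", groups = "groups.tsv")
  paths <- file.path(data_dir, need)
  names(paths) <- names(need)
  for (p in paths) {
    if (!file.exists(p)) abort(sprintf("required input file missing: %s", p))
  }
  groups_df <- utils::read.table(paths[["groups"]], header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  list(
    model = read_metabolic_model(paths[["model"]]),
    expr = tpm_from_counts(read_gene_table(paths[["counts"]]),
                           read_gene_lengths(paths[["lengths"]])),
    groups = setNames(groups_df$group, groups_df$sample)
  )
}

#' Build per-sample and per-group constrained context models to disk
#'
#' Reads a simulated (or real) cohort directory, builds an E-Flux-capped
#' context model per sample and per group (pooled expression), and writes
#' them as BiGG-style JSON plus a component-count summary table.
#'
#' @param data_dir directory with `model.json`, `counts.tsv`,
#'   `lengths.tsv`, `groups.tsv` (from [run_simulate()] or equivalent).
#' @param out_dir output directory (default `<data_dir>/build`).
#' @param config an [extraction_config()].
#' @param v_max E-Flux cap.
#' @return invisibly, the build summary tibble.
#' @export
run_build <- function(data_dir, out_dir = file.path(data_dir, "build"),
                      config = extraction_config(), v_max = 1000) {
  inp <- read_cohort_inputs(data_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list()
  for (s in names(inp$groups)) {
    b <- build_constrained_model(inp$model, inp$expr, s, config, v_max)
    write_model_json(b$model, file.path(out_dir, paste0("sample_", s, ".json")))
    g <- glance(b$context)
    g$sample <- s
    g$group <- unname(inp$groups[[s]])
    rows[[s]] <- g
  }
  pooled <- pooled_expression(inp$expr, inp$groups)
  for (g in unique(unname(inp$groups))) {
    b <- build_constrained_model(inp$model, pooled, g, config, v_max)
    write_model_json(b$model, file.path(out_dir, paste0("group_", g, ".json")))
  }
  summary <- dplyr::bind_rows(rows)
  utils::write.table(as.data.frame(summary),
                     file.path(out_dir, "build_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(summary)
}

#' Analyse a built cohort to disk
#'
#' pFBA subsystem profiles, cosine similarity, hierarchical clusters, PCA
#' embedding, group-level hit-and-run ensembles and per-reaction comparison,
#' written as TSV plus a provenance JSON; figures are written when a
#' graphics device is available.
#'
#' @param data_dir cohort directory (as in [run_build()]).
#' @param build_dir directory of built models (default `<data_dir>/build`).
#' @param out_dir output directory (default `<data_dir>/analysis`).
#' @param n_flux_samples hit-and-run samples per group model.
#' @param seed sampling seed.
#' @param check_ensembles verify steady state and bounds on every sampled
#'   flux vector before analysis.
#' @return invisibly, the list of result objects.
#' @export
run_analyze <- function(data_dir, build_dir = file.path(data_dir, "build"),
                        out_dir = file.path(data_dir, "analysis"),
                        n_flux_samples = 500L, seed = 1L,
                        check_ensembles = TRUE) {
  inp <- read_cohort_inputs(data_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sample_files <- file.path(build_dir, paste0("sample_", names(inp$groups), ".json"))
  missing <- sample_files[!file.exists(sample_files)]
  if (length(missing)) {
    abort(paste0("built model(s) missing, run run_build() first: ",
                 paste(missing, collapse = ", ")))
  }
  models <- lapply(sample_files, read_metabolic_model)
  names(models) <- names(inp$groups)

  solutions <- purrr::imap(models, function(m, s) pfba(m))
  profiles <- purrr::imap(models, function(m, s) {
    subsystem_profile(solutions[[s]], m, label = s)
  })
  profiles_tbl <- dplyr::bind_rows(profiles)
  fluxes <- flux_vector_matrix(solutions)
  sim <- cosine_similarity(fluxes)
  clust <- cluster_profiles(fluxes, k = length(unique(inp$groups)))
  emb <- embed_profiles(fluxes, method = "pca") |>
    dplyr::mutate(group = unname(inp$groups[.data$label]))

  gs <- unique(unname(inp$groups))
  ensembles <- list()
  for (g in gs) {
    gm <- read_metabolic_model(file.path(build_dir, paste0("group_", g, ".json")))
    ens <- sample_fluxes(gm, n_samples = n_flux_samples,
                         seed = seed + match(g, gs), thinning = 100L)
    if (check_ensembles) {
      chk <- check_ensemble(ens, gm)
      if (chk$max_steady_state_violation > 1e-6 || chk$max_bound_violation > 1e-9) {
        abort(sprintf("ensemble for group '%s' violates invariants", g))
      }
    }
    ensembles[[g]] <- ens
  }
  comparison <- compare_groups(ensembles, reference = gs[1])

  tsv <- function(x, name) {
    utils::write.table(as.data.frame(x), file.path(out_dir, name),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  tsv(profiles_tbl, "profiles.tsv")
  tsv(tidy(sim), "similarity.tsv")
  tsv(tibble(label = names(cutree(clust$tree, k = clust$k)),
             cluster = unname(cutree(clust$tree, k = clust$k))),
      "clusters.tsv")
  tsv(emb, "embedding.tsv")
  tsv(comparison, "comparison.tsv")
  jsonlite::write_json(
    list(seed = seed, n_flux_samples = n_flux_samples,
         package_version = as.character(utils::packageVersion("gemflux")),
         groups = as.list(inp$groups)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)

  try_figures(out_dir, profiles_tbl, sim, emb, comparison)

  invisible(list(profiles = profiles_tbl, similarity = sim,
                 clustering = clust, embedding = emb,
                 ensembles = ensembles, comparison = comparison))
}

try_figures <- function(out_dir, profiles_tbl, sim, emb, comparison) {
  save_fig <- function(plot, name) {
    tryCatch(
      suppressMessages(ggplot2::ggsave(
        file.path(out_dir, name), plot = plot,
        width = 7, height = 5, dpi = 120)),
      error = function(e) warn(sprintf("could not write figure %s: %s",
                                       name, conditionMessage(e)))
    )
  }
  save_fig(plot_profiles(profiles_tbl), "profiles.png")
  save_fig(autoplot(sim), "similarity.png")
  save_fig(plot_embedding(emb), "embedding.png")
  save_fig(autoplot(comparison), "comparison.png")
  invisible(NULL)
}
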