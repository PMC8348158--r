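# Expression-to-bounds translation (E-Flux) and respirometry-derived oxygen
# caps.  E-Flux maps each reaction's normalised expression evidence to a
# maximum flux: well-transcribed reactions keep wide bounds, poorly
# transcribed ones are throttled.

#' Continuous reaction activity scores from expression
#'
#' Evaluates each reaction's GPR rule on linear TPM values (`and` = min,
#' `or` = sum by default: isozymes add capacity). Reactions without a GPR
#' rule receive no score and are left untouched by [eflux_bounds()].
#'
#' @param model a [metabolic_model()].
#' @param expr an [expression_matrix()].
#' @param sample_id sample whose TPM column to use.
#' @param or_mode `"sum"` (default) or `"max"`; see [gpr_eval_continuous()].
#' @return named numeric vector of scores for reactions with a GPR.
#' @export
reaction_activity_scores <- function(model, expr, sample_id,
                                     or_mode = c("sum", "max")) {
  or_mode <- match.arg(or_mode)
  levels <- expr$tpm[, sample_id]
  has_gpr <- !is.na(model$reactions$gpr) & nzchar(model$reactions$gpr)
  ids <- model$reactions$id[has_gpr]
  scores <- vapply(model$reactions$gpr[has_gpr], function(rule) {
    gpr_eval_continuous(parse_gpr(rule), levels, or_mode = or_mode)
  }, numeric(1), USE.NAMES = FALSE)
  setNames(scores, ids)
}

#' E-Flux: cap flux bounds by normalised expression
#'
#' For each scored reaction the upper bound is capped at
#' `v_max * score / max(scores)` (and the lower bound at the negated cap for
#' reversible reactions); caps only ever tighten bounds. A score of zero
#' closes the reaction. Unscored reactions (no GPR) keep their bounds:
#' absence of evidence must not close transport or spontaneous reactions.
#'
#' @param model a [metabolic_model()].
#' @param reaction_scores named non-negative numeric vector from
#'   [reaction_activity_scores()] (ids must exist in the model).
#' @param v_max flux value assigned to the top-scoring reaction
#'   (default 1000, the default bound magnitude).
#' @return a `bounded_model`: list with the capped `model`,
#'   `normalization_max`, and an `applied_constraints` log tibble.
#' @export
eflux_bounds <- function(model, reaction_scores, v_max = 1000) {
  stopifnot(v_max > 0)
  if (any(reaction_scores < 0)) abort("reaction scores must be non-negative")
  bad <- setdiff(names(reaction_scores), reaction_ids(model))
  if (length(bad)) abort(paste0("scored reaction(s) not in model: ",
                                paste(bad, collapse = ", ")))
  norm <- max(reaction_scores)
  if (norm == 0) abort("all reaction scores are zero; cannot normalise")

  log_rows <- list()
  for (r in names(reaction_scores)) {
    i <- match(r, model$reactions$id)
    old_lb <- model$reactions$lb[i]
    old_ub <- model$reactions$ub[i]
    cap <- v_max * reaction_scores[[r]] / norm
    new_ub <- min(old_ub, cap)
    new_lb <- if (old_lb < 0) max(old_lb, -cap) else old_lb
    new_lb <- min(new_lb, new_ub)
    model$reactions$lb[i] <- new_lb
    model$reactions$ub[i] <- new_ub
    log_rows[[r]] <- tibble(reaction = r, score = reaction_scores[[r]],
                            old_lb = old_lb, old_ub = old_ub,
                            new_lb = new_lb, new_ub = new_ub)
  }
  structure(
    list(model = model, normalization_max = norm,
         applied_constraints = dplyr::bind_rows(log_rows)),
    class = "bounded_model"
  )
}

#' @export
print.bounded_model <- function(x, ...) {
  cat(sprintf("<bounded_model>  %d reaction bounds capped (max score %.3g)\n",
              nrow(x$applied_constraints), x$normalization_max))
  invisible(x)
}

#' A respirometry measurement
#'
#' High-resolution respirometry oxygen flux for one experimental group, in
#' pmol O2 / s / mg protein, at one titration state.
#'
#' @param group group label.
#' @param state titration state, one of `routine`, `oxphos`, `max_ox`,
#'   `atp_link`, `max_u`, `rox`.
#' @param oxygen_flux non-negative oxygen flux (residual-corrected).
#' @return a `respirometry_measurement`.
#' @export
respirometry_measurement <- function(group, state, oxygen_flux) {
  state <- match.arg(state, c("routine", "oxphos", "max_ox", "atp_link",
                              "max_u", "rox"))
  if (oxygen_flux < 0) abort("oxygen_flux must be non-negative")
  structure(list(group = group, state = state, oxygen_flux = oxygen_flux),
            class = "respirometry_measurement")
}

#' Cap oxygen uptake from a respirometry measurement
#'
#' Scales the measured oxygen flux (pmol O2 / s / mg protein) into model flux
#' units with a single configurable factor and caps the oxygen exchange's
#' uptake (its negative direction) at that value. Other bounds are untouched.
#'
#' @param model a [metabolic_model()] containing the oxygen exchange.
#' @param measurement a [respirometry_measurement()] (or a bare number,
#'   taken as the oxygen flux).
#' @param scale conversion factor from measurement units to flux units.
#' @param oxygen_exchange id of the oxygen exchange reaction.
#' @return a `bounded_model` with the capped model and constraint log.
#' @export
apply_respirometry <- function(model, measurement, scale = 1.0,
                               oxygen_exchange = "EX_o2_e") {
  flux <- if (inherits(measurement, "respirometry_measurement")) {
    measurement$oxygen_flux
  } else {
    as.numeric(measurement)
  }
  i <- match(oxygen_exchange, model$reactions$id)
  if (is.na(i)) {
    abort(sprintf("oxygen exchange reaction '%s' not found", oxygen_exchange))
  }
  old_lb <- model$reactions$lb[i]
  cap <- scale * flux
  new_lb <- max(old_lb, -cap)
  model$reactions$lb[i] <- min(new_lb, model$reactions$ub[i])
  structure(
    list(model = model, normalization_max = NA_real_,
         applied_constraints = tibble(
           reaction = oxygen_exchange, score = NA_real_,
           old_lb = old_lb, old_ub = model$reactions$ub[i],
           new_lb = model$reactions$lb[i], new_ub = model$reactions$ub[i])),
    class = "bounded_model"
  )
}

#' Read respirometry measurements from TSV
#'
#' Expected columns: `group`, `state`, `oxygen_flux`.
#'
#' @param path TSV file.
#' @return tibble of measurements.
#' @export
read_respirometry <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}
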