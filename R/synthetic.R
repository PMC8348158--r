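# Synthetic data with known ground truth: a hand-designed brain-energetics
# toy network, a three-group expression-cohort simulator, matched
# respirometry values, and a random toy-network generator for oracle tests.
#
# The toy network is designed, not sampled, so its ATP yields are auditable
# integers:
#   glucose, aerobic   : 26 ATP / glucose (10 NADH x 2, 2 CII-QH2 x 1,
#                        4 substrate-level)
#   glucose, anaerobic :  2 ATP / glucose (glycolysis + lactate export)
#   palmitate-like FFA : 83 ATP (62 from 31 NADH, 15 from QH2, 6 net
#                        substrate-level)
#   complex-I knockout : 16 ATP / glucose (all NADH rerouted through the
#                        reversible redox shuttle to the glycerol-3-phosphate
#                        shuttle at 1 ATP per NADH)
# Proton-motive accounting: complex I translocates 2 pmf per NADH, complexes
# III+IV 4 pmf per O2 (2 per QH2), ATP synthase makes 1 ATP per 2 pmf;
# complex II and the glycerol-3-phosphate shuttle feed the quinone pool
# without pumping.

#' The packaged brain-energetics toy model
#'
#' A deterministic ~40-reaction network over 3 compartments (extracellular,
#' cytosol, mitochondrion) with subsystems glycolysis, tca, oxphos (distinct
#' complex-I, complex-II, glycerol-3-phosphate-shuttle and ATP-synthase
#' reactions), fatty_acid_oxidation, transport, exchange and atp_demand.
#' Every enzymatic reaction carries a GPR rule over ~60 synthetic genes with
#' mouse-like symbols; the objective is the cytosolic ATP demand.
#'
#' @return a [metabolic_model()].
#' @export
make_toy_model <- function() {
  compartments <- c(e = "extracellular", c = "cytosol", m = "mitochondrion")

  met <- function(id, name) {
    comp <- sub(".*_([ecm])$", "\\1", id)
    tibble(id = id, name = name, compartment = comp, formula = NA_character_)
  }
  mets <- dplyr::bind_rows(
    met("glc_e", "glucose"), met("glc_c", "glucose"),
    met("lac_e", "lactate"), met("lac_c", "lactate"),
    met("pyr_e", "pyruvate"), met("pyr_c", "pyruvate"), met("pyr_m", "pyruvate"),
    met("triose_c", "triose phosphate"), met("pg_c", "phosphoglycerate"),
    met("nad_c", "NAD+"), met("nadh_c", "NADH"),
    met("atp_c", "ATP"), met("adp_c", "ADP"),
    met("o2_e", "oxygen"), met("o2_c", "oxygen"), met("o2_m", "oxygen"),
    met("co2_e", "CO2"), met("co2_c", "CO2"), met("co2_m", "CO2"),
    met("ffa_e", "fatty acid (palmitate-like)"), met("ffa_c", "fatty acid"),
    met("ffa_m", "fatty acid"),
    met("gln_e", "glutamine"), met("gln_c", "glutamine"), met("gln_m", "glutamine"),
    met("nad_m", "NAD+"), met("nadh_m", "NADH"),
    met("q_m", "ubiquinone"), met("qh2_m", "ubiquinol"),
    met("pmf_m", "proton-motive force"),
    met("atp_m", "ATP"), met("adp_m", "ADP"),
    met("accoa_m", "acetyl-CoA"), met("succ_m", "succinate"),
    met("fum_m", "fumarate"), met("oaa_m", "oxaloacetate"),
    met("aa_c", "amino-acid pool")
  )

  rx <- list()
  st <- list()
  add <- function(id, stoich, lb, ub, gpr, subsystem, name = id, obj = 0) {
    rx[[length(rx) + 1L]] <<- tibble(
      id = id, name = name, lb = lb, ub = ub,
      gpr = gpr %||% NA_character_, subsystem = subsystem,
      objective_coef = obj)
    st[[length(st) + 1L]] <<- tibble(
      reaction = id, metabolite = names(stoich), coef = as.numeric(stoich))
  }

  # exchanges (export positive, uptake negative); substrate availability is
  # deliberately generous so transcript-derived caps, not medium bounds,
  # limit flux in context models
  add("EX_glc_e", c(glc_e = -1), -100, 1000, NULL, "exchange")
  add("EX_o2_e",  c(o2_e = -1), -1000, 1000, NULL, "exchange")
  add("EX_lac_e", c(lac_e = -1), -100, 1000, NULL, "exchange")
  add("EX_pyr_e", c(pyr_e = -1), -100, 1000, NULL, "exchange")
  add("EX_co2_e", c(co2_e = -1), 0, 1000, NULL, "exchange")
  add("EX_ffa_e", c(ffa_e = -1), -100, 1000, NULL, "exchange")
  add("EX_gln_e", c(gln_e = -1), -100, 1000, NULL, "exchange")

  # transport
  add("GLCt", c(glc_e = -1, glc_c = 1), 0, 1000, "Slc2a1 or Slc2a3", "transport")
  add("O2t", c(o2_e = -1, o2_c = 1), 0, 1000, NULL, "transport")
  add("O2tm", c(o2_c = -1, o2_m = 1), 0, 1000, NULL, "transport")
  add("LACt", c(lac_c = -1, lac_e = 1), -1000, 1000, "Slc16a1 or Slc16a3", "transport")
  add("PYRt", c(pyr_c = -1, pyr_e = 1), 0, 1000, "Slc16a1", "transport")
  add("CO2tm", c(co2_m = -1, co2_c = 1), 0, 1000, NULL, "transport")
  add("CO2t", c(co2_c = -1, co2_e = 1), 0, 1000, NULL, "transport")
  add("FFAt", c(ffa_e = -1, ffa_c = 1), 0, 1000, "Cd36 or Slc27a1", "transport")
  add("GLNt", c(gln_e = -1, gln_c = 1), 0, 1000, "Slc1a5", "transport")
  add("GLNtm", c(gln_c = -1, gln_m = 1), 0, 1000, "Slc25a22", "transport")
  add("PYRtm", c(pyr_c = -1, pyr_m = 1), 0, 1000, "Mpc1 and Mpc2", "transport")
  add("ANT", c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1), 0, 1000,
      "Slc25a4 or Slc25a5", "transport", name = "adenine nucleotide translocase")
  # lumped malate-aspartate-style redox shuttle, reversible in the toy
  add("MAS", c(nadh_c = -1, nad_m = -1, nad_c = 1, nadh_m = 1), -1000, 1000,
      "Got1 and Got2 and Mdh1 and Mdh2", "transport", name = "redox shuttle")

  # glycolysis (lumped to three steps + LDH)
  add("HEX_PFK", c(glc_c = -1, atp_c = -2, triose_c = 2, adp_c = 2), 0, 1000,
      "(Hk1 or Hk2) and Gpi1 and (Pfkm or Pfkl)", "glycolysis",
      name = "upper glycolysis")
  add("GAPDH_PGK", c(triose_c = -1, nad_c = -1, adp_c = -1,
                     pg_c = 1, nadh_c = 1, atp_c = 1), 0, 1000,
      "Gapdh and (Pgk1 or Pgk2)", "glycolysis", name = "lower glycolysis I")
  add("ENO_PYK", c(pg_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1), 0, 1000,
      "Eno1 and (Pkm or Pklr)", "glycolysis", name = "lower glycolysis II")
  add("LDH", c(pyr_c = -1, nadh_c = -1, lac_c = 1, nad_c = 1), -1000, 1000,
      "Ldha or Ldhb", "glycolysis", name = "lactate dehydrogenase")

  # TCA cycle (two lumped halves around complex II) + anaplerosis
  add("PDH", c(pyr_m = -1, nad_m = -1, accoa_m = 1, nadh_m = 1, co2_m = 1),
      0, 1000, "Pdha1 and Pdhb and Dlat", "tca", name = "pyruvate dehydrogenase")
  add("CS_KGDH", c(accoa_m = -1, oaa_m = -1, nad_m = -2, adp_m = -1,
                   succ_m = 1, nadh_m = 2, atp_m = 1, co2_m = 2), 0, 1000,
      "Cs and Idh3a and Ogdh and Dlst and Sucla2", "tca",
      name = "citrate-to-succinate half-cycle")
  add("FUM_MDH", c(fum_m = -1, nad_m = -1, oaa_m = 1, nadh_m = 1), 0, 1000,
      "Fh1 and Mdh2", "tca", name = "fumarate-to-oxaloacetate half-cycle")
  add("ME", c(oaa_m = -1, pyr_m = 1, co2_m = 1), 0, 1000,
      "Me2 or Me3", "tca", name = "malic-enzyme cataplerosis")
  add("GLS_GDH", c(gln_m = -1, nad_m = -2, succ_m = 1, nadh_m = 2, co2_m = 1),
      0, 1000, "Gls and Glud1", "tca", name = "glutaminolysis entry")

  # oxidative phosphorylation
  add("CPLX1", c(nadh_m = -1, q_m = -1, nad_m = 1, qh2_m = 1, pmf_m = 2),
      0, 1000, "Ndufs1 and Ndufv1 and Ndufa1", "oxphos", name = "complex I")
  add("CPLX2", c(succ_m = -1, q_m = -1, fum_m = 1, qh2_m = 1), 0, 1000,
      "Sdha and Sdhb", "oxphos", name = "complex II")
  add("G3PSH", c(nadh_c = -1, q_m = -1, nad_c = 1, qh2_m = 1), 0, 1000,
      "Gpd1 and Gpd2", "oxphos", name = "glycerol-3-phosphate shuttle")
  add("CPLX34", c(qh2_m = -2, o2_m = -1, q_m = 2, pmf_m = 4), 0, 1000,
      "Uqcrc1 and Cyc1 and Cox4i1 and Cox5a", "oxphos", name = "complexes III+IV")
  add("ATPS", c(pmf_m = -2, adp_m = -1, atp_m = 1), 0, 1000,
      "Atp5a1 and Atp5b and Atp5c1", "oxphos", name = "ATP synthase")
  add("LEAK", c(pmf_m = -2), 0, 1000, NULL, "oxphos", name = "proton leak")

  # fatty-acid oxidation (lumped beta-oxidation, ETF feeding the Q pool)
  add("CPT", c(ffa_c = -1, ffa_m = 1), 0, 1000, "Cpt1a and Cpt2",
      "fatty_acid_oxidation", name = "carnitine shuttle")
  add("BOX", c(ffa_m = -1, nad_m = -7, q_m = -7, atp_m = -2,
               accoa_m = 8, nadh_m = 7, qh2_m = 7, adp_m = 2), 0, 1000,
      "Acadvl and Hadha and Hadhb", "fatty_acid_oxidation",
      name = "beta-oxidation (lumped)")

  # amino-acid turnover: an energy-independent material flux outside the
  # disease-regulated subsystems; its forced minimum emulates the
  # constitutive biosynthetic load tissues carry regardless of energetic
  # state (lumped, so no ATP coupling)
  add("GLN_AA", c(gln_c = -1, aa_c = 1), 0, 1000,
      "Asns or Glul", "amino_acid_metabolism", name = "amino-acid synthesis")
  add("DM_aa", c(aa_c = -1), 50, 1000, NULL, "amino_acid_metabolism",
      name = "amino-acid maintenance demand")

  # objective: cytosolic ATP demand
  add("ATPM", c(atp_c = -1, adp_c = 1), 0, 1000, NULL, "atp_demand",
      name = "ATP demand", obj = 1)

  metabolic_model(
    id = "toy_brain_energetics",
    metabolites = mets,
    reactions = dplyr::bind_rows(rx),
    stoichiometry = dplyr::bind_rows(st),
    compartments = compartments
  )
}

#' Packaged toy metabolic tasks
#'
#' Reads the ~10 brain-energetics feasibility tasks shipped with the package
#' (ATP from glucose aerobically / anaerobically, ATP from a palmitate-like
#' fatty acid, lactate-to-pyruvate NADH reoxidation, glutamine anaplerosis,
#' full oxidation to CO2, fermentation). ATP tasks are phrased as
#' ADP -> ATP conversion so the adenylate pool stays balanced.
#'
#' @return list of [task_definition()].
#' @export
toy_tasks <- function() {
  read_tasks(system.file("extdata", "tasks_brain.yaml", package = "gemflux"))
}

#' Cohort simulation configuration
#'
#' Defaults emulate a three-group design (control / disease / treated,
#' n = 3 each) in which the disease group down-regulates OXPHOS, glycolysis
#' and fatty-acid-oxidation genes to a quarter of their control expression
#' and treatment partially restores them (0.6-fold), with negative-binomial
#' counts and scaled-down library sizes.
#'
#' @param n_per_group samples per group.
#' @param groups group labels (control, disease, treated order).
#' @param down_subsystems subsystems whose genes are down-regulated in the
#'   disease group.
#' @param disease_fold expression fold retained in the disease group (0, 1].
#' @param treated_fold fold retained under treatment; must satisfy
#'   `disease_fold <= treated_fold <= 1`.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param library_size_range range of per-sample total read counts.
#' @param n_background number of non-pathway background genes spanning the
#'   low-to-mid expression continuum.
#' @param n_off number of silent genes (near-zero expression).
#' @param respirometry_base control-group oxygen flux, pmol O2/s/mg protein.
#' @param respirometry_noise_sd Gaussian noise on simulated oxygen fluxes.
#' @param seed integer seed.
#' @return a list with class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 3L,
                          groups = c("control", "disease", "treated"),
                          down_subsystems = c("oxphos", "glycolysis",
                                              "fatty_acid_oxidation"),
                          disease_fold = 0.25,
                          treated_fold = 0.6,
                          nb_dispersion = 0.05,
                          library_size_range = c(1e5, 1e6),
                          n_background = 150L,
                          n_off = 50L,
                          respirometry_base = 100,
                          respirometry_noise_sd = 5,
                          seed = 1L) {
  if (!(disease_fold > 0 && disease_fold <= treated_fold && treated_fold <= 1)) {
    abort("need 0 < disease_fold <= treated_fold <= 1")
  }
  if (n_per_group < 1) abort("n_per_group must be >= 1")
  if (length(groups) != 3) abort("exactly three group labels expected")
  structure(
    list(n_per_group = as.integer(n_per_group), groups = groups,
         down_subsystems = down_subsystems, disease_fold = disease_fold,
         treated_fold = treated_fold, nb_dispersion = nb_dispersion,
         library_size_range = library_size_range,
         n_background = as.integer(n_background), n_off = as.integer(n_off),
         respirometry_base = respirometry_base,
         respirometry_noise_sd = respirometry_noise_sd,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# genes attached (via GPR) to reactions of the given subsystems
subsystem_genes <- function(model, subsystems) {
  rows <- model$reactions$subsystem %in% subsystems &
    !is.na(model$reactions$gpr) & nzchar(model$reactions$gpr)
  sort(unique(unlist(lapply(model$reactions$gpr[rows],
                            function(r) gpr_genes(parse_gpr(r))))))
}

#' Simulate a three-group expression cohort on a model
#'
#' Per-gene baseline log2 expression targets are drawn once per cohort:
#' pathway genes from a high-expression component, background genes from a
#' broad low-to-mid continuum, and silent genes near zero. The disease group
#' multiplies the targets of genes in `down_subsystems` by `disease_fold`,
#' the treated group by `treated_fold`. Counts are negative-binomial around
#' length- and depth-scaled means; library sizes vary uniformly.
#'
#' @param model a [metabolic_model()] supplying the pathway genes.
#' @param config a [cohort_config()].
#' @return list with `expr` (an [expression_matrix()] with counts),
#'   `groups` (named character vector sample -> group), and `truth`
#'   (a `ground_truth`: `gene_state` and `expected_direction` tibbles).
#' @export
simulate_expression <- function(model, config = cohort_config()) {
  set.seed(config$seed)
  pathway_genes <- model_genes(model)
  down_genes <- subsystem_genes(model, config$down_subsystems)
  bg_genes <- sprintf("bg%03d", seq_len(config$n_background))
  off_genes <- sprintf("off%03d", seq_len(config$n_off))
  genes <- c(pathway_genes, bg_genes, off_genes)

  # baseline log2 expression targets, on an arbitrary relative scale:
  # pathway genes form the high mode; the background mixes a low-expression
  # anchor cluster with a sparser mid continuum (the shape real log-TPM
  # distributions show); designated-off genes sit low enough that most of
  # their counts are literally zero
  n_bg_low <- round(2 / 3 * config$n_background)
  n_bg_mid <- config$n_background - n_bg_low
  # pathway ("on") genes: sharp left edge + bounded exponential right tail,
  # the right-skew log-expression shape highly expressed genes show in
  # practice
  base_log2 <- c(
    7.2 + pmin(stats::rexp(length(pathway_genes), rate = 1 / 0.8), 3.3),
    rnorm(n_bg_low, mean = -1.5, sd = 1.0),
    rnorm(n_bg_mid, mean = 3.5, sd = 1.5),
    rnorm(config$n_off, mean = -7, sd = 1.0)
  )
  names(base_log2) <- genes
  # the adenine nucleotide translocase gene doubles as a stable
  # normalisation anchor: a ubiquitous top-expressed transporter outside the
  # down-regulated subsystems, so E-Flux's per-sample max score tracks the
  # same reaction in every group
  if ("Slc25a4" %in% genes) base_log2[["Slc25a4"]] <- 12
  # the glutamine transporter feeds the constitutive amino-acid turnover
  # demand; as for real abundant transporters its baseline sits safely in
  # the high tier so the forced demand is never throttled by chance
  if ("Slc1a5" %in% genes) base_log2[["Slc1a5"]] <- 9
  # glutamine synthetase is among the most abundant brain transcripts; its
  # high baseline keeps the amino-acid turnover pathway well above the
  # forced maintenance demand in every group
  if ("Glul" %in% genes) base_log2[["Glul"]] <- 10
  lengths_bp <- setNames(sample(500:3000, length(genes), replace = TRUE), genes)

  fold_for <- function(group) {
    f <- setNames(rep(1, length(genes)), genes)
    if (group == config$groups[2]) f[down_genes] <- config$disease_fold
    if (group == config$groups[3]) f[down_genes] <- config$treated_fold
    f
  }

  sample_ids <- as.vector(vapply(config$groups, function(g)
    paste(g, seq_len(config$n_per_group), sep = "_"),
    character(config$n_per_group)))
  groups <- setNames(rep(config$groups, each = config$n_per_group), sample_ids)

  # mean-dispersion trend: biological dispersion shrinks with expression
  # level, as bulk RNA-seq of inbred animals shows (highly expressed
  # housekeeping-type genes are the most stable); nb_dispersion is the
  # dispersion of low/mid-expressed genes, the trend floors at 5% of it for
  # the top tier
  disp_g <- config$nb_dispersion * (0.05 + 0.95 / (1 + 2^(base_log2 - 6)))

  counts <- matrix(0L, nrow = length(genes), ncol = length(sample_ids),
                   dimnames = list(genes, sample_ids))
  for (s in sample_ids) {
    f <- fold_for(groups[[s]])
    target <- 2^base_log2 * f
    lib <- runif(1, config$library_size_range[1], config$library_size_range[2])
    mu <- target * lengths_bp / sum(target * lengths_bp) * lib
    counts[, s] <- if (config$nb_dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / disp_g)
    } else {
      stats::rpois(length(mu), mu)
    }
  }

  gene_state <- dplyr::bind_rows(
    tibble(gene = pathway_genes, state = "on",
           down_regulated = pathway_genes %in% down_genes),
    tibble(gene = bg_genes, state = "background", down_regulated = FALSE),
    tibble(gene = off_genes, state = "off", down_regulated = FALSE)
  )
  expected_direction <- dplyr::bind_rows(
    tibble(group = config$groups[2], subsystem = config$down_subsystems,
           direction = "down", reference = config$groups[1]),
    tibble(group = config$groups[3], subsystem = config$down_subsystems,
           direction = "up", reference = config$groups[2])
  )
  truth <- structure(
    list(gene_state = gene_state, expected_direction = expected_direction,
         base_log2 = base_log2, config = config),
    class = "ground_truth")

  list(
    expr = tpm_from_counts(counts, lengths_bp),
    groups = groups,
    truth = truth
  )
}

#' Simulate group-level respirometry measurements
#'
#' Oxygen flux per group is the control base scaled by the group's expression
#' fold (control 1, disease `disease_fold`, treated `treated_fold`) plus
#' Gaussian noise, truncated at zero.
#'
#' @param config a [cohort_config()].
#' @return tibble with columns `group`, `state`, `oxygen_flux`, one row per
#'   sample.
#' @export
simulate_respirometry <- function(config = cohort_config()) {
  set.seed(config$seed + 1L)
  factors <- setNames(c(1, config$disease_fold, config$treated_fold),
                      config$groups)
  out <- lapply(config$groups, function(g) {
    flux <- config$respirometry_base * factors[[g]] +
      rnorm(config$n_per_group, 0, config$respirometry_noise_sd)
    tibble(group = g, state = "oxphos", oxygen_flux = pmax(flux, 0))
  })
  dplyr::bind_rows(out)
}

#' Random small metabolic network for oracle testing
#'
#' Generates a random chain-and-branch network of at most `n_reactions`
#' reactions: linear conversion chains between boundary metabolites with
#' random extra branches, random reversibility, and (optionally) orphan
#' reactions that can never carry steady-state flux. Intended for
#' brute-force cross-checks of consistency testing and extraction at toy
#' scale; no GPRs, no objective.
#'
#' @param seed integer seed.
#' @param n_reactions maximum number of reactions (default 12).
#' @param p_reversible probability an internal reaction is reversible.
#' @param p_orphan probability of appending a blocked orphan pair.
#' @return a [metabolic_model()].
#' @export
make_random_toy_network <- function(seed, n_reactions = 12L,
                                    p_reversible = 0.3, p_orphan = 0.5) {
  set.seed(seed)
  n_met <- sample(3:6, 1)
  mets <- sprintf("m%02d", seq_len(n_met))

  rx <- list()
  st <- list()
  add <- function(id, stoich, lb, ub) {
    rx[[length(rx) + 1L]] <<- tibble(id = id, name = id, lb = lb, ub = ub,
                                     gpr = NA_character_,
                                     subsystem = NA_character_,
                                     objective_coef = 0)
    st[[length(st) + 1L]] <<- tibble(reaction = id,
                                     metabolite = names(stoich),
                                     coef = as.numeric(stoich))
  }

  # a guaranteed spine: uptake -> chain across all metabolites -> secretion
  add("U1", setNames(1, mets[1]), 0, 10)
  for (i in seq_len(n_met - 1)) {
    rev <- runif(1) < p_reversible
    add(sprintf("C%02d", i), setNames(c(-1, 1), mets[c(i, i + 1)]),
        if (rev) -10 else 0, 10)
  }
  add("S1", setNames(-1, mets[n_met]), 0, 10)

  # random extra branches between metabolite pairs, some producing into or
  # consuming from the spine
  n_extra <- max(0L, n_reactions - length(rx) -
                   (if (runif(1) < p_orphan) 2L else 0L))
  for (k in seq_len(n_extra)) {
    pair <- sample(n_met, 2)
    rev <- runif(1) < p_reversible
    add(sprintf("B%02d", k), setNames(c(-1, 1), mets[pair]),
        if (rev) -10 else 0, 10)
  }

  # an orphan pair over fresh metabolites: consumes a metabolite nothing
  # produces, so both reactions are blocked
  if (length(rx) + 2L <= n_reactions + 2L && runif(1) < p_orphan) {
    mets <- c(mets, "x01", "x02")
    add("X01", c(x01 = -1, x02 = 1), 0, 10)
    add("X02", c(x02 = -1), 0, 10)
  }

  met_tbl <- tibble(id = mets, name = mets, compartment = "c",
                    formula = NA_character_)
  metabolic_model(
    id = sprintf("random_toy_%d", seed),
    metabolites = met_tbl,
    reactions = dplyr::bind_rows(rx),
    stoichiometry = dplyr::bind_rows(st),
    compartments = c(c = "cytosol")
  )
}
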