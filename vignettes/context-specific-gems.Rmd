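---
title: "Context-specific metabolic modelling from RNA-seq with gemflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific metabolic modelling from RNA-seq with gemflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemflux)
library(dplyr)
```

## The modelling problem

A genome-scale metabolic model (GEM) is a stoichiometric network: a matrix
$S$ whose rows are metabolites and columns are reactions, flux bounds
$l \le v \le u$, and gene–protein–reaction (GPR) rules linking each reaction
to the genes encoding its enzymes. Constraint-based analysis studies the
steady-state flux polytope

$$ P = \{ v : S v = 0,\; l \le v \le u \}. $$

A generic GEM describes what a genome *could* do. To describe what a
particular tissue in a particular condition *does*, gemflux integrates bulk
RNA-seq evidence in two complementary ways:

1. **Discrete integration (model extraction).** Genes are discretised into
   expressed / unknown / unexpressed; GPR rules lift those calls to
   reactions (core / noncore / inactive); inactive reactions are removed;
   the remaining network is pruned to its flux-consistent part (FASTCC);
   and a minimal flux-consistent subnetwork containing all core reactions
   is extracted (FASTCORE). The result is a context-specific model per
   sample.
2. **Continuous integration (E-Flux).** Linear expression levels are pushed
   through the GPR rules (`and` = min over complex subunits, `or` = sum
   over isozymes) to score each reaction, and scores are mapped to flux
   bound caps: $u_i' = v_{\max}\, s_i / \max_j s_j$. Well-transcribed
   reactions keep wide bounds; poorly transcribed ones are throttled.

Measured respirometry (oxygen flux per mg protein) additionally caps the
oxygen exchange per experimental group.

The constrained models are then simulated — parsimonious FBA for a
canonical flux state, flux variability analysis for per-reaction ranges,
hit-and-run sampling for flux distributions — and compared across groups
through subsystem profiles, cosine similarity, hierarchical clustering,
2-D embeddings and per-reaction sampling summaries.

## The discretisation model

For each sample the distribution of $\log_2(\mathrm{TPM}+1)$ over detected
genes is decomposed into two Gaussian components (low and high expression),
fitted with `mclust` (1-D, unequal variances, deterministic model-based
initialisation). A gene is called

* expressed (+1) if its value is at least $\mu_{high} - z\,\sigma_{high}$,
* unexpressed (−1) if at most $\mu_{low} + z\,\sigma_{low}$,
* unknown (0) in between,

with `z_margin` = 1 by default. Two special rules matter in practice:
genes with TPM = 0 are called unexpressed directly (the RNA-seq zero mass
carries no graded evidence and would distort the fit, so it is excluded
from it), and when the two thresholds cross — strongly overlapping
components — the midpoint of the component means splits the calls and no
gene is left unknown. Degenerate fits (vanishing weight or variance) fall
back to quantile thresholds with a warning.

Whether to fit one mixture per sample or one pooled mixture for a cohort is
not settled practice; gemflux fits per sample by default and offers
`discretize_cohort(fit = "pooled")` for the pooled variant.

## Tunable parameters

| Parameter | Default | Units / scale | Role |
|---|---|---|---|
| `epsilon` | 1e-4 | flux units | minimum magnitude counting as "carries flux" in consistency testing and extraction; bounds are of magnitude 1000, so this cleanly separates numerical zero from flux |
| `z_margin` | 1.0 | component SDs | width of the expressed/unexpressed margins |
| `v_max` | 1000 | flux units | E-Flux cap assigned to the top-scoring reaction |
| `or_mode` | sum (E-Flux), max (discrete) | — | isozyme semantics: capacities add for continuous scoring; any isozyme suffices for discrete calls |
| `fraction_of_optimum` | 1.0 | — | objective retention in pFBA / FVA |
| `n_samples`, `thinning` | 2000, 100 | — | hit-and-run ensemble size and chain thinning |

The respirometry-to-flux unit conversion is not identified by either data
source, so a single scale factor maps pmol O~2~ s^−1^ mg^−1^ into flux
units. `calibrate_respirometry_scale()` fixes it so the control group's cap
sits exactly at the control model's unconstrained optimal oxygen uptake —
non-binding for the control, proportionally tighter for groups that respire
less. Which titration state feeds the cap is configurable; the
OxPhos-capacity state is the default in the simulated data.

## The algorithms

**FASTCC.** A reaction is flux-consistent if some steady-state solution
gives it flux of magnitude at least `epsilon`. Rather than testing
reactions one at a time, blocks are certified together with the LP7 support
LP — maximise $\sum_i z_i$ subject to $S v = 0$, bounds, and
$0 \le z_i \le \varepsilon$, $z_i \le v_i$ — flipping the sign of
reversible reactions that fail in the forward orientation, and testing
stragglers singly. The unit tests and the acceptance suite verify the
result equals the brute-force per-reaction FVA answer on dozens of random
toy networks.

**FASTCORE.** Extraction alternates LP7 (how many unsatisfied core
reactions can reach $\varepsilon$ flux) with the LP10 sparsity LP
(minimise $\sum_{i \in P} |v_i|$ over the non-core penalty set while the
currently supported core carries flux), accumulating the support of each
sparse mode until every core reaction is covered. The L1 objective is a
surrogate for cardinality; on toy instances the tests compare the number of
added reactions against exhaustive search over all subnetworks. Reversible
core reactions unsatisfied forward are retried sign-flipped; a core
reaction unsupportable in the consistent model raises an error naming it.
Objective reactions are protected into the core by default
(`protect_objective`) so extracted models remain simulatable.

**pFBA.** Stage 1 maximises the objective; stage 2 splits $v = p - q$ with
$p, q \ge 0$ and minimises $\sum (p + q)$ subject to retaining the stage-1
optimum. Plain FBA optima are typically degenerate and solver-dependent;
the parsimonious solution is the canonical flux state reported throughout.

**Sampling.** Coordinate hit-and-run in null-space coordinates of $S$:
feasible points are $v_0 + N u$ with $S N = 0$, so only the box constraints
cut each chord. The chain starts at the centroid of the FVA extreme
solutions, draws a basis direction uniformly each step, recomputes the
feasible chord from the current point (so floating-point error cannot
accumulate), and keeps every `thinning`-th state. Every returned vector is
checked against $\|S v\|_\infty \le 10^{-6}$ and bounds within $10^{-9}$ by
`check_ensemble()`.

**LP kernel.** All of the above reduce to small dense LPs, solved by the
package's two-phase primal simplex (compiled, Bland's smallest-index rule,
so the often highly degenerate flux LPs cannot cycle). Feasibility uses a
$10^{-9}$ pivot tolerance, phase-1 feasibility is accepted below
$10^{-7}$, and equality comparisons in tests use $10^{-6}$. The test suite
cross-checks objective values against an independently implemented dense
simplex on every fixture.

## Flux profiles and group comparison

`subsystem_profile()` sums $|v_i|$ per subsystem and normalises the profile
to sum to 1 (L1). This makes profiles comparable across context models of
different size and flux scale — but it also makes them *compositional*: a
uniform down-scaling of every flux is invisible. Down-regulation of a set
of subsystems therefore manifests as those subsystems jointly losing share
to unaffected ones, which is how `directional_recovery()` evaluates it
(combined mass of the down-regulated subsystems per group). Per-model
z-scoring is applied only for heatmap display, never for analysis.

Cosine similarity, hierarchical clustering (average linkage on cosine
distance) and the 2-D embedding operate on the reaction-level pFBA flux
vectors of the cohort; the subsystem profile is the aggregated view. A UMAP
embedding is attempted when a UMAP backend is installed and falls back to
PCA with a warning otherwise.

`compare_groups()` is deliberately descriptive — group medians, median
differences against a reference group, overlap coefficients of the sampled
distributions, and rank-sum statistics. No significance claims are
attached: sampled flux values are not independent observations, and the
source analyses draw no formal flux-significance tests either.

## What the synthetic cohort emulates — and what it does not

`make_toy_model()` is a hand-designed brain-energetics network
(~40 reactions, 3 compartments, 8 subsystems, ~60 genes with mouse-like
symbols) rather than a sampled one, so its properties are auditable
integers fixed by construction:

* 26 ATP per glucose aerobically; 2 anaerobically (glycolysis + lactate
  export); 83 per palmitate-like fatty acid; 17 per glutamine;
* 16 ATP per glucose with complex I closed — all NADH rerouted through the
  reversible redox shuttle into the glycerol-3-phosphate shuttle at 1 ATP
  per NADH, keeping the ATP task feasible at reduced yield and pushing
  complex-II flux up per unit ATP (the compensation pattern the group
  comparisons probe);
* an amino-acid turnover demand (glutamine → amino-acid pool, forced
  minimum flux) outside the disease-regulated subsystems. Real GEMs carry
  many demand-driven non-energy pathways; this block is their minimal
  stand-in, and without it normalised profiles would be almost exactly
  scale-invariant between groups.

`simulate_expression()` draws per-gene baseline targets once per cohort:
a high tier for pathway genes with a sharp left edge and an exponential
right tail (the right-skew shape highly expressed genes show — and the
reason a $\mu_{high} - \sigma_{high}$ threshold can capture well over 90%
of them, which a symmetric Gaussian tier could not); a background
continuum with a low-expression anchor cluster and a sparser mid tier;
and near-silent "off" genes whose counts are mostly literal zeros. A few
transporters with stable, high baselines (the adenine nucleotide
translocase, the glutamine transporter, glutamine synthetase) play the
role abundant housekeeping transcripts play in real data; in particular
they keep E-Flux's per-sample max-score denominator anchored to the same
unchanged reaction in every group. Counts are negative-binomial with the
mean–dispersion trend bulk RNA-seq shows (dispersion 0.05 for low/mid
expression, shrinking to 5% of that for the top tier), library sizes are
uniform on 1e5–1e6 (scaled down from real depths; TPM is depth-normalised
so downstream logic is unaffected), and the disease / treated groups
multiply the targets of OXPHOS, glycolysis and fatty-acid-oxidation genes
by 0.25 / 0.6.

What passing the synthetic tests does **not** show: the cohort has no
batch effects, no outlier samples, no isoform-level effects, no correlated
gene–gene noise, and its network is three orders of magnitude smaller than
a real GEM. Results on this cohort validate the machinery, not the biology
of any particular tissue.

Two deliberate asymmetries are worth knowing about. First,
fatty-acid-oxidation genes are down-regulated in the simulated disease
group, but parsimonious solutions shun beta-oxidation whenever glucose
suffices (true of real pFBA too), so the FAO signal is visible in the
discretisation and the E-Flux caps but contributes no flux-share signal;
directional recovery is therefore assessed on the combined down-regulated
mass. Second, TPM renormalisation inflates unchanged genes when a large
expression mass is removed (a compositional effect real data shows); the
fold-recovery tests estimate that common factor from stable genes before
comparing ratios.

## Numerical and design choices

* Exchange reactions are identified structurally (single metabolite), with
  the `EX_` prefix as annotation fallback; default bounds when a file
  omits them are [0, 1000] / [−1000, 1000] (irreversible / reversible).
* SBML support targets Level 3 + FBC v2 (the profile BiGG exports use);
  older levels are rejected with a clear message rather than half-parsed.
* Inactive reactions are removed before extraction rather than merely
  closed, mirroring reduced models that exclude them outright.
* Ties between equally sparse supporting sets are broken by the
  deterministic pivoting rule and fixed reaction ordering, so extraction
  is reproducible bit-for-bit.
* Per-mouse models are built and aggregated downstream; pooled-expression
  group models (used for sampling) pool TPM by group mean.
* Problem sizes used by the test and acceptance workloads — 20 cohorts of
  9 samples on the ~40-reaction network, 500-sample ensembles per group
  model, 50 random networks for the consistency oracle, 20 instances for
  the extraction oracle — keep every check exhaustive or
  Monte-Carlo-stable at desk scale.

## A short tour

```{r tour, eval = FALSE}
model <- make_toy_model()
cfg <- cohort_config(seed = 1)
sim <- simulate_expression(model, cfg)
resp <- simulate_respirometry(cfg)

res <- analyze_cohort(model, sim$expr, sim$groups,
                      respirometry = resp, n_flux_samples = 500, seed = 1)

directional_recovery(res$profiles, sim$groups, sim$truth)
autoplot(res$similarity)
plot_embedding(res$embedding)
plot_flux_samples(res$ensembles, c("ATPS", "CPLX1", "CPLX2"))
```

The same workflow is available file-to-file through `run_simulate()`,
`run_build()` and `run_analyze()`, and from a shell via the thin wrapper in
`inst/scripts/gemflux.R`.

## Known limitations

* The LP kernel is a dense tableau simplex: right for networks up to a few
  hundred reactions, not for genome-scale matrices with tens of thousands
  of columns, which need a sparse revised simplex or interior-point solver.
* FASTCORE's L1 surrogate can in principle add more reactions than the
  cardinality minimum; the tests bound this only at toy scale.
* Discrete GPR semantics treat "unknown" as ordered between off and on;
  probabilistic semantics and gene-knockout simulation are out of scope.
* `compare_groups()` treats reactions absent from a context model as
  structural zeros, which conflates "absent" with "present but unused" in
  the summary statistics; the `absent` flag preserves the distinction.
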