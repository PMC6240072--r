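---
title: "Differential flux analysis, pathway DA scores and metabolite-set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential flux analysis, pathway DA scores and metabolite-set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxda)
```

`fluxda` has two arms. The *in silico* arm asks how a genome-scale-style
metabolic network redistributes flux when one input is forced up — here,
glucose entry — and summarises the answer per pathway. The *statistical*
arm analyses paired metabolomics measurements and tests KEGG pathway sets
against ranked metabolite lists. This vignette records the models behind
both arms, the parameters that matter, and the choices made where the
design was genuinely open.

## Constraint-based model and FBA

A metabolic network is a stoichiometric matrix `S` (metabolites x
reactions) with flux bounds `lb <= v <= ub`. Flux balance analysis assumes
steady state, `S v = 0`, and picks the flux vector optimising a linear
objective. The assumptions to keep in mind: no kinetics or metabolite
concentrations, no regulation, and thermodynamics only to the extent that
irreversibility is encoded in the bounds. Reversibility is encoded solely
by `lb < 0`; bounds are required to be finite (a "free" reaction uses a
large finite bound, 1000 by default in the toy network), so the LP is
never unbounded.

The solver is a dense two-phase bounded-variable revised simplex with
Bland's anti-cycling rule (`lp_simplex`). The basis system is re-solved
from the original data at every iteration, so no error accumulates in a
tableau; this costs a factor of the basis size per iteration and is the
right trade for the tens-of-reactions models this package targets.
Dependent rows of `S` (conserved moieties) are removed by QR before
solving, and the full residual is re-checked afterwards so row reduction
can never mask an inconsistency.

**Alternate optima.** FBA optima are typically degenerate: many flux
vectors achieve the same objective. Averages over objective sweeps are
only reproducible if each solve returns a *canonical* point, so after the
primary solve the objective is pinned at its optimum and the sum of
absolute fluxes is minimised (the parsimonious, pFBA-style secondary LP).
Splitting only reversible reactions keeps the secondary problem the same
size and shape as the primary. An earlier design used the minimum
Euclidean norm point instead — attractive because it is unique — but L2
spreads large fluxes across parallel dissipative routes (it will happily
run a substrate cycle to shave the square of a big flux), which corrupts
sign-based downstream scores; L1 parsimony suppresses exactly those
cycles.

**Numerical choices.** Feasibility tolerance `1e-9`; steady-state residual
checked to `1e-6`; reported fluxes below `1e-9` in magnitude are clamped
to zero so that solver noise cannot flip the sign-based DA scores
downstream. Ties in the simplex ratio test break toward the smallest
variable index (Bland), making repeated solves bitwise identical.

## Objective sweeps, differential fluxes, DA

Rather than committing to one biological objective, the average flux of
every reaction is taken across a sweep of objectives (ATP yield, lactate
export, palmitate export, a nucleotide-precursor demand, growth, and so
on), each maximised independently; objectives whose LP fails are skipped
and excluded from the mean denominator rather than zero-filled (zero
filling would bias means toward zero). With a shared feasible region
infeasibility is a model-level event, so in practice either all objectives
solve or none do.

Differential fluxes are `u_r = mean_perturbed[r] - mean_baseline[r]`. One
published description of this comparison states the subtraction in the
opposite order while its figure legend defines +1 as "all fluxes
increased"; since reaction ranking uses `|u_r|` only, the order affects
nothing but the sign of DA, and this package fixes the legend-consistent
convention: positive means increased under the perturbation.

The Differential Abundance score of a pathway `P` is

```
DA_P = sum_{r in P} u_r / sum_{r in P} |u_r|
```

bounded in `[-1, 1]`, equal to -1 exactly when every non-zero `u_r` in the
pathway decreased and +1 when every one increased. When all deltas vanish
the score is undefined and flagged (`defined = FALSE`), never reported as
0 — a pathway that did not move is not a pathway that moved both ways. No
statistical significance is attached to DA; it is a descriptive summary.

Metabolites are ranked by the incidence sum `sum |u_r|` over every
reaction touching them, transporters included. Compartmental instances are
distinct metabolites in the model; when building enrichment input they are
collapsed by KEGG id (summing scores), since pathway sets are keyed by
compound, not by compartment. The collapse rule is exposed
(`collapse_kegg`, `collapse =`) because the right choice depends on
whether the downstream sets distinguish compartments.

## PBEA: enrichment on ranked metabolite lists

Given a list `L` of `N` metabolites sorted by a metric (fold change for
measured data, the DFA incidence score for simulations) and a pathway set
`S` with `k` members in the list, a running sum starts at zero and, walking
down `L`, rises by `|metric_i|^p / sum_hits |metric|^p` at members and
falls by `1/(N - k)` at non-members. The enrichment score is the signed
value of maximum absolute deviation; the final value returns to zero by
construction. Only metabolites with a KEGG identifier enter the list —
unmapped compounds cannot belong to any set, and keeping them would
deflate every score.

Choices and defaults:

* `weight_p = 1` (GSEA-style weighting); `p = 0` gives the classical
  rank-only Kolmogorov–Smirnov statistic and is tested alongside.
* Permutation null: the metric-to-identifier assignment is permuted
  uniformly — equivalently, the member positions are redrawn uniformly
  without replacement, which is how it is implemented (an `O(k)` kernel
  per permutation instead of `O(N)`). Set-resampling nulls are deliberately
  not offered; they answer a different question.
* `p = #{|ES_perm| >= |ES_obs|} / n_perm` with `n_perm = 1000` by default,
  two-sided on `|ES|`; a signed option exists. There is no pseudocount by
  default (so `p = 0` is observable); `smoothed = TRUE` gives
  `(k+1)/(n+1)` when downstream FDR stability matters. An `exhaustive`
  mode enumerates all `choose(N, k)` placements for small lists.
* FDR across pathways is Benjamini–Hochberg by default (Bonferroni
  available); pathways with no member in the list are skipped with a
  warning, and the FDR is computed over the tested pathways only.
* Exact ties in the running-sum extreme (possible with symmetric metrics)
  resolve to the earliest list position, consistently between the full
  scorer and the streaming kernel, with a `1e-12` comparison tolerance.

Under a null list the permutation p-values are uniform on the grid
`{1/n_perm, ..., 1}`; the suite checks this with a chi-square
goodness-of-fit over 500 random pathways at 1000 permutations each, and
checks the scorer against a brute-force recomputation over *every*
placement of every set size for `N = 8`.

## Paired differential metabolomics

The design emulated throughout is litter-matched: each litter contributes
cystic and control animals, and litter is the pairing unit. Same-genotype
littermates are collapsed to their mean log abundance first, then a
classical two-sided paired t-test runs on per-litter differences. Working
on the log scale reflects the multiplicative error structure of
metabolomics intensities; fold changes are nevertheless reported on the
raw scale as `mean(cystic)/mean(control)`, with "absolute fold change
greater than t" meaning `FC > t` or `FC < 1/t`.

Zero-variance difference vectors yield `p = 1` plus a `degenerate` flag
instead of an error — batch runs over hundreds of metabolites should not
die on one flat feature — and degenerate rows are excluded from volcano
counts. Metabolites with missing values are excluded from testing and
flagged (`tested = FALSE`); no imputation is attempted. Adjustment is
Benjamini–Hochberg by default. Volcano classes: `up` when
`p_adj < alpha` and `FC > fc_threshold`, `down` when `p_adj < alpha` and
`FC < 1/fc_threshold`, `ns` otherwise, with `alpha = 0.05` and
`fc_threshold = 2`; `n_sig` counts significance regardless of fold
change. PCA (log, centred, SVD) and agglomerative clustering on euclidean
log-distances are provided as standard plumbing.

## Tracer arithmetic

Mass-isotopologue distributions are intensity fractions `raw/sum(raw)`.
Natural-abundance correction uses the standard binomial convolution
matrix: column `j` of `C` is the measured distribution generated by a
species with `j` tracer atoms when each remaining atom is heavy with
probability `a` (defaults: 0.0107 for carbon-13, 0.00364 for
nitrogen-15). Correction solves `C x = raw`, clamps small negative entries
caused by noise to zero and renormalises, raising a QC flag when the
clamped mass exceeds 1%. The forward model composed with the correction is
the identity to `1e-8`, which is the property the suite asserts. Dual
carbon/nitrogen labels are corrected sequentially per element — a
documented approximation adequate at natural-abundance magnitudes.
Consumption/release rates are `(spent - fresh)/(protein_t24 -
protein_t0)`: negative means net consumption; non-growing cultures are an
error because the normalisation is then meaningless.

## The synthetic toy network

The toy network (`make_toy_network`) is a hand-curated fixture, not a
random graph: directional claims about named pathways need a stable,
interpretable topology. It has three compartments (extracellular, cytosol,
mitochondrion), 33 metabolites and 42 reactions grouped into GLY, PPP,
TCA, OXPHOS, FAO, FAS, GLN, transport, exchange and demand, with every
internal reaction balancing tracked carbon (asserted at build time;
energy/redox carriers are untracked, and acetyl-CoA counts only its acyl
carbons).

Structural features that drive the behaviour under forced glucose uptake:

* Two tagged glucose transporters: a facilitated uniporter (capacity 2)
  and a sodium-coupled symporter whose sodium gradient is restored by an
  ATP-driven pump. The uniporter carries the uptake direction only:
  modelling it reversibly lets the LP exploit an ATP-dissipating
  import/export cycle whenever an objective is ATP-disposal-limited, a
  thermodynamically unrealistic artefact.
* The directionality constraints are built in: LDH runs pyruvate to
  lactate only, pyruvate transport is cytosol to mitochondrion only, and
  citrate transport is mitochondrion to cytosol only.
* Mitochondrial anaplerosis is glutamine-dependent — there is deliberately
  no pyruvate carboxylase — so any *net* citrate export for lipogenesis
  draws on glutamine. Reductive carboxylation (alpha-ketoglutarate + CO2
  to citrate) and an alanine transaminase (pyruvate + glutamate to alanine
  + alpha-ketoglutarate, alanine excreted) give glutamine-linked,
  NADH-neutral routes for lipogenic citrate and for pyruvate disposal;
  TCA NADH bookkeeping sits on PDH and the lumped AKGDH step. These routes
  are what let surplus glycolytic carbon flow into fatty acid synthesis
  without forcing respiration up.
* ATP demand and lactate export are capacity-limited. The ATP cap is the
  Warburg lever: glycolytic ATP from forced glucose displaces oxidative
  ATP production, so OXPHOS and the fat oxidation feeding it fall.
* OXPHOS is one lumped NADH + O2 to ATP proxy (P/O 2.5) rather than
  complexes I–V: sufficient for the direction of a DA score and keeps the
  LP small.

With the default nine objectives and the 1.6-fold forcing of both
transporters (the factor measured for glucose uptake in the tracing
experiments the perturbation mirrors), the sweep average shifts exactly in
the expected directions: DA = +1 for GLY and PPP, +1 for FAS, positive for
GLN, and -1 for both OXPHOS and FAO. The network was curated to make these
mechanisms available to the LP; the directions themselves emerge from the
optimisation, and the suite asserts signs only, never magnitudes.

What the toy network does *not* emulate: genome-scale coverage (42
reactions against thousands), kinetic or regulatory control, NADPH/redox
compartmentation, nitrogen balance (amide groups are untracked), or
realistic flux units. A directional agreement on the toy model shows the
algorithmic chain — sweep, canonicalisation, differencing, DA — behaves as
specified; it is not evidence about any real tissue.

## Metabolomics and null-list simulators

`simulate_metabolomics` draws per-metabolite baselines `N(10, 1)` on the
log scale, adds a litter random intercept (SD 0.05 — small, so pairing
helps but does not dominate), i.i.d. log-scale noise (SD 0.15, a
realistic within-litter CV of about 15%), and multiplies planted
metabolites by the effect fold change (2.5) up or down in cystic samples.
Defaults mirror the emulated study: 4 litters x (2 cystic + 2 control),
550 metabolites, 171 planted up, 213 planted down, 80% of metabolites
carrying a (synthetic) KEGG id. Everything is reproducible from one seed.
The generator does not emulate missingness, batch effects,
heteroscedastic intensity-dependent noise, or correlated metabolite
blocks, so recovery results here bound what real data would give from
above. `simulate_null_ranked_list` provides i.i.d. standard-normal metrics
over synthetic KEGG ids plus uniformly drawn pathway sets for calibration.

## Problem sizes used by the checks

The suite exercises: LP optima against brute-force vertex enumeration on
24 random networks of at most 12 reactions; the enrichment scorer against
exhaustive recomputation over all `2^8 - 2` member placements at `N = 8`;
permutation-null uniformity over 500 pathways at 1000 permutations;
type-I error on 2000 null metabolites; and volcano recovery on the full
550-metabolite design. These sizes keep each property statistically
meaningful while the whole suite stays fast enough to run on every change.

## Known limitations

* The simplex is dense and refactorises every iteration — appropriate up
  to a few hundred reactions, not for genome-scale models; swapping in a
  sparse LP backend behind `solve_fba` would not change any interface.
* DA carries no uncertainty; two pathways with DA 0.9 and 0.2 are ordered
  but not statistically distinguished.
* The enrichment null permutes the ranked list only; if pathway sets
  overlap heavily their p-values are dependent and BH is only
  heuristically calibrated across them.
* Sequential per-element natural-abundance correction ignores the joint
  carbon-nitrogen convolution; exact dual-label correction would need the
  tensor-product matrix.
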