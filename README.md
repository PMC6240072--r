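# fluxda

Dissecting metabolic reprogramming with differential flux balance analysis
and metabolite-set enrichment.

## The problem

Cystic kidney epithelia, like many proliferative tissues, shift their
central-carbon metabolism: glycolysis and lactate excretion rise while
respiration falls, glutamine is pulled into the TCA cycle and into de novo
fatty acid synthesis. Static metabolomics snapshots cannot by themselves say
which pathways moved in which direction. `fluxda` implements the
computational toolkit for that question:

* **FBA / DFA** — flux balance analysis (`solve_fba`) with parsimonious
  canonicalisation of alternate optima, averaged over a sweep of metabolic
  objectives (`objective_sweep`) for a baseline and a perturbed model
  (`apply_perturbation`, e.g. forcing glucose transporters to 1.6x their
  baseline average). Differential fluxes `u_r` are the per-reaction change
  of those averages (`differential_flux`).
* **Differential Abundance score** — for a pathway *P*,
  `DA_P = sum(u_r) / sum(|u_r|)` over `r in P` (`compute_da`,
  `pathway_da`). `DA = -1` means every non-zero flux in the pathway
  decreased, `+1` that every one increased.
* **PBEA** — pathway-based enrichment of a ranked metabolite list: a
  weighted Kolmogorov–Smirnov-like running-sum statistic
  (`enrichment_score`), permutation p-values (`permutation_pvalue`) and
  Benjamini–Hochberg FDR across KEGG pathway sets (`enrich_all`).
* **Paired differential metabolomics** — litter-matched paired t-tests on
  log abundances, fold changes, volcano classification
  (`differential_metabolomics`), plus PCA and hierarchical clustering.
* **Tracer arithmetic** — mass-isotopologue distributions, binomial
  natural-abundance correction, and consumption/release rates normalised to
  protein growth (`mid_fractions`, `natural_abundance_correct`,
  `consumption_release`).
* **Synthetic data** — a curated three-compartment central-carbon toy
  network (`make_toy_network`) and simulators for litter-paired
  metabolomics (`simulate_metabolomics`) and null ranked lists, so the
  whole pipeline runs and is tested without any external download.

## Worked example

Force the two tagged glucose transporters of the toy network to 1.6x their
wild-type sweep average and score every pathway:

```r
library(fluxda)

toy <- make_toy_network()
toy$model
#> metabolic_model: 33 metabolites, 42 reactions, 3 compartments, 10 pathways

wt   <- objective_sweep(toy$model, toy$objectives, condition_label = "wild-type")
pert <- apply_perturbation(toy$model, wt, toy$perturbation)
ko   <- objective_sweep(pert, toy$objectives, condition_label = "forced-glucose")
da   <- pathway_da(differential_flux(wt, ko), toy$model)
da[da$pathway %in% c("GLY", "PPP", "GLN", "FAS", "OXPHOS", "FAO", "TCA"), ]
#>   pathway     da n_reactions defined
#>       FAO -1.000           2    TRUE
#>       FAS  1.000           3    TRUE
#>       GLN  0.791           3    TRUE
#>       GLY  1.000           3    TRUE
#>    OXPHOS -1.000           2    TRUE
#>       PPP  1.000           1    TRUE
#>       TCA  0.239           5    TRUE
```

Increased glucose entry alone rewires the toy model the way the disease
tissue behaves: glycolysis, pentose phosphate, glutaminolysis and fatty
acid synthesis all carry more flux (DA > 0; GLY/PPP/FAS uniformly so),
while oxidative phosphorylation and fatty acid oxidation uniformly decrease
(DA = -1).

The metabolomics arm recovers planted ground truth. Simulating the default
4-litter design (550 metabolites, 171 planted up and 213 down at a
2.5-fold change):

```r
sim <- simulate_metabolomics(seed = 1)
dm  <- differential_metabolomics(sim$table)
attr(dm, "summary")
#> $n_sig  398
#> $n_up   171
#> $n_down 213
```

398 metabolites pass adjusted *P* < 0.05; applying the additional
|fold change| > 2 filter classifies exactly the planted 171 up and 213
down. `run_pipeline(pipeline_config(seed = 1), "out/")` executes both arms
end to end and writes every table plus a reproducibility manifest.

## Documentation

The methods vignette (`vignettes/differential-flux-enrichment.Rmd`)
describes the model and its assumptions, every tunable parameter with its
default and rationale, what the synthetic generators do and do not emulate,
and the package's numerical choices and limitations.
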