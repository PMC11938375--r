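# carma

Analysis toolkit for **CaRMA imaging** data — recordings in which the same
neurons are characterized both functionally (calcium imaging across labeled
behavioral states) and molecularly (quantitative multiplexed RNA-FISH of a
marker-gene panel). The package is for systems-neuroscience analysts who have
a cells × genes expression table, a neurons × time ΔF/F matrix, and a
behavioral-state schedule, and want to know:

* which **molecularly defined cell types (MCs)** the neurons form, and
  whether members of a type respond coherently;
* whether behavioral states are carried by dedicated **labeled-line** neurons
  or by **grouped ensembles** of cell types;
* how far **gene expression alone predicts function** — a neuron's
  activated/inhibited class and its full temporal response.

## The statistics at the core

* **t-auROC**: responses are quantified as `2·(auROC − ½) ∈ [−1, 1]`, where
  auROC = P(response sample > baseline sample) + ½·P(tie), computed by exact
  pair counting. Sign encodes activation vs. inhibition.
* **Linear purity and consistent-response**: within a cluster at a timebin,
  `purity = |Σᵢ rᵢ| / Σᵢ |rᵢ|` and `CR = purity × mean(r)`; the temporal
  maximum of |CR| per (cluster, state) gives the consistent-response map.
* **Labeled-line screen**: a neuron is a labeled-line for state *s* within a
  state subset iff it is responsive (vs. a circular-shift null) in *s* and in
  no other subset state; all `C(n, k)` subsets are screened with a max-min
  objective and Fisher-exact selectivity tests.
* **Grouped-ensemble decoding**: ridge multinomial logistic regression on
  trial features built from one neuron per cell type (resampled), with
  size-matched **dummy types** as the null.
* **SFFS / mSFFS**: greedy forward selection over per-gene feature triplets
  (linear, log, detection; z-scored) for predicting functional clusters,
  with shuffle-null significance; later rounds remove the top gene to expose
  redundant partners.
* **Youden-J thresholds** and per-timestamp **fraction of deviance explained
  (FDE)** models of responses from expression, with per-neuron
  predictability ranking.

A seeded synthetic-data generator (`generate_dataset()`) plants all of this
structure — 10 types dominated by one marker each, a "conductor"
receptor-like gene spanning several types whose expression level scales
response gain, coherent and incoherent types, ramp vs. fast kinetics — so
every stage is testable by parameter recovery.

## Worked example

```r
library(carma)

ds <- generate_dataset(synth_config(), seed = 1)
ds
#> <carma_dataset> 319 cells x 12 genes; traces 319 x 3690 (0.4-s steps); 11 states

# molecular typing (ARI vs the planted types: 0.964 on this seed)
norm <- normalize_expression(ds$expression)
mcs  <- name_clusters(cluster_cells(norm, n_clusters = 10), norm)
head(attr(mcs, "labels"), 3)
#>         1         2         3
#> "MC1-g08" "MC2-g02" "MC3-g03"

# responses, consistent-response map
resp <- response_traces(ds$traces, ds$schedule)
crm  <- cr_map(resp, mcs)
autoplot(crm)   # cluster x state heat map of max CR

# grouped-ensemble decoding vs size-matched dummy types
samp    <- build_samples(resp)
grouped <- decode_grouped(samp, mcs, n_resamples = 100, seed = 1)
dummy   <- decode_grouped(samp, dummy_types(mcs, seed = 1),
                          n_resamples = 100, seed = 1)
round(c(grouped = mean(grouped$accuracy), dummy = mean(dummy$accuracy)), 4)
#> grouped   dummy
#>  0.5942  0.5758
```

With 11 states, chance is ~9%: ten-neuron type ensembles decode the
behavioral state six-fold above chance, and ahead of the size-matched dummy
ensembles that scramble type identity. The formal paired-seed comparison
(Wilcoxon rank-sum over 100 resamples on the planted type assignment) is run
by the test suite and the acceptance script; on the default study conditions
it gives grouped 0.554 vs dummy 0.508, p = 0.0023.

The whole pipeline, file-based:

```r
carma_simulate("data/",  synth_config(), seed = 1)
rep <- carma_report("data/", out_dir = "out/", seed = 1)
str(rep$summary)   # also written to out/report.json
```

A thin CLI wrapper with `simulate` and `report` subcommands is installed at
`inst/scripts/carma.R`.

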