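---
title: "Methods: from multiplexed expression and calcium traces to grouped-ensemble coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multiplexed expression and calcium traces to grouped-ensemble coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`carma` analyzes datasets in which the same neurons are characterized twice:
once functionally, by calcium imaging across a series of labeled behavioral
states, and once molecularly, by quantitative multiplexed RNA-FISH of a
marker-gene panel. The pipeline asks whether molecularly defined cell types
respond coherently, whether behavioral states are carried by dedicated
"labeled-line" neurons or by combinations of cell types, and how far gene
expression alone predicts a neuron's functional responses. This vignette
records the models, the defaults and their units, and the design choices made
where the analysis is genuinely open.

## Data model

Three inputs define a dataset:

* an expression table (cells x genes) of continuous, non-negative FISH
  intensities;
* a trace matrix (neurons x time) of dF/F at a fixed sampling interval
  (0.4 s by default);
* a behavioral schedule: non-overlapping labeled epochs, half-open
  `[start_s, end_s)`, seconds, with optional stimulus events that must fall
  inside epochs.

All tabular results are tibbles; traces and per-timebin response arrays remain
dense numeric matrices/arrays, which is the natural container for regular
time series.

## The response statistic: t-auROC

Every downstream stage works on baseline-referenced responses rather than raw
dF/F. For a response window $W$ and baseline window $B$,

$$\mathrm{auROC} = \Pr(w > b) + \tfrac12 \Pr(w = b), \qquad
  \text{t-auROC} = 2(\mathrm{auROC} - \tfrac12) \in [-1, 1],$$

computed by exact pair counting (midranks). The sign encodes activation
versus inhibition and the statistic is invariant to monotone rescaling of the
fluorescence, which makes neurons with different indicator gains comparable.
Per-timebin response traces use a causal 2-s window (truncated at epoch
onset) against the 10 s of trace immediately preceding the epoch; whole-epoch
responses pool all epochs of a state against their pooled baselines. Both
windows are parameters (`window_s`, `baseline_s`). The exact window
conventions are a documented package choice: a standard auROC-versus-baseline
construction with the $[-1,1]$ transform.

## Purity and consistent-response

Within-type response coherence at a timebin is summarized by linear purity

$$\mathrm{purity}(r) = \frac{|\sum_i r_i|}{\sum_i |r_i|} \in [0, 1],$$

defined as 0 when the denominator falls below $10^{-9}$ (silent timebin),
and the consistent-response $\mathrm{CR}(t) = \mathrm{purity}(t) \cdot
\overline{r}(t)$, which always satisfies $|\mathrm{CR}| \le |\overline{r}|$.
A sign-fraction alternative $|n_+ - n_-|/n$ is available behind
`method = "sign"`. The linear form is a documented choice; both behave
identically on coherent clusters and differ only in how partial-magnitude
disagreement is weighted. Cluster-state pairs are summarized by the temporal
maximum of $|\mathrm{CR}|$ with its sign retained, together with the purity
and mean response at that timebin. Types with purity above 0.5 are read as
responding coherently. Clusters with fewer than 3 members are excluded from
cluster statistics.

## Molecular typing

Expression is normalized gene-wise as `log1p` followed by division by the
gene's maximum, preserving zeros and bounding every gene in $[0, 1]$
(z-scoring is deliberately avoided so the zero baseline stays meaningful).
Cells are clustered by agglomerative hierarchical clustering with correlation
distance and average linkage -- the standard choice for continuous expression
profiles; Euclidean distance and other linkages are exposed as options. The
dendrogram is stored so the tree can be re-cut at any cluster count without
re-clustering, supporting cluster-count sweeps. Clusters are named
`MC{i}-{gene}` after the gene with the highest cluster-mean normalized
expression, or `MC{i}-Low` when that mean is below 0.1; ties go to the lower
gene index and are logged. Cells with constant (all-zero) profiles have
undefined correlation; they are assigned unit distance to all other cells and
zero distance among themselves.

## Labeled-line screening

A neuron is responsive in a state when its pooled whole-epoch t-auROC falls
outside the central 95% of a circular-time-shift null (1000 shifts by
default, seeded); circular shifts preserve the trace's autocorrelation. A
labeled-line neuron for state $s$ within a state subset is responsive in $s$
and unresponsive in every other subset state. The screen enumerates all
$\binom{n}{k}$ subsets and, following the stopping logic of the analysis it
supports, selects the subset maximizing the **minimum** per-state
labeled-line count (a subset fails as soon as one of its states has no
dedicated neuron); a max-total objective is available. Per-state selectivity
is tested with a one-sided Fisher exact test against an expectation table
built by independently permuting each state's responsiveness column across
neurons (1000 permutations, averaged and rounded) -- a null that preserves
per-state rates while breaking cross-state dependence. No multiple-testing
correction is applied across states by default. States can be grouped into
state classes by clustering per-state ensemble mean-response vectors
(correlation distance, average linkage) and cutting at a threshold; the
screen then reruns on class pseudo-states.

## Behavioral-state decoding

Decoding features are per-trial vectors of mean-binned t-auROC values (10
bins over the first 20 s of each epoch by default; both knobs exposed).
Trials are the cross-validation unit, so no timebin leaks across folds.
The classifier is ridge-penalized multinomial logistic regression via glmnet
with the penalty fixed at 1 on the summed log-likelihood (glmnet
`lambda = 1/n`); a fixed penalty keeps results deterministic and avoids
tuning, and glmnet's symmetric multinomial parameterization provides
per-class coefficients for every state (needed by the decoding diagrams).
Folds are stratified by state and reduced, with a warning, when a state has
fewer trials than folds; at least 3 trials per state are required so every
training split retains 2 per class.

Single-neuron decoding fits one classifier per neuron and averages accuracy
within each molecular cluster (plus an `"All"` pseudo-type over every
neuron). Grouped-ensemble decoding draws one neuron per type (100 resamples
with replacement by default), concatenates their features, and reports the
accuracy distribution, the mean row-normalized confusion matrix, and
decoding weights: per state, the mean over resamples of the summed absolute
coefficients over each type's feature block, normalized to sum to one over
types. The dummy-type control permutes the neuron-to-type map (size spectrum
preserved) and is decoded with identical resample seeds for paired
comparison (Wilcoxon rank-sum). Per-type accuracies are compared with a
chi-squared test on correct/incorrect counts followed by the Marascuillo
procedure; per-state response amplitudes within a type use a one-way
repeated-measures ANOVA (neurons as subjects) with Tukey-Kramer pairwise
comparisons on the within-subject error term.

## Functional clusters and enrichment

For each state, neurons are clustered on their trial-averaged within-state
response profiles (correlation distance, average linkage) and the tree is
cut at two clusters -- activated (`Act-FC`, higher mean epoch response) and
inhibited (`Inh-FC`); deeper cuts are exploratory options. Differential
expression between FCs uses a two-sided Wilcoxon rank-sum test per gene
(robust to the strongly skewed intensities) plus the Act/Inh mean-expression
ratio; genes are ranked by $-\log_{10} p$ with no across-gene correction by
default. Cell-type enrichment in an FC uses a two-sided Fisher exact test on
the 2x2 membership table with its odds ratio.

## Predicting function from expression

Each gene contributes three normalized features per neuron -- max-scaled
linear expression, max-scaled `log1p` expression, and a detection indicator
-- all z-scored across neurons; the triplet is a documented package choice
that carries level, compressed-level and on/off information without
binarizing expression. Zero-variance features are dropped with a message.
FC prediction is ridge logistic regression under stratified 10-fold CV;
accuracy is the mean fold accuracy, the auROC comes from pooled out-of-fold
scores by exact pair counting, and coefficients are fold-averaged.

Sequential forward feature selection (SFFS) greedily adds whole gene blocks
while CV accuracy improves by more than 0.001 (a numeric floor for "no
longer increases" under CV noise), on a fold split fixed once per search;
ties go to the lower gene index and are logged. Multi-round SFFS removes the
first-selected gene of each prior round from the pool, exposing redundant
partners, and stops early when a round's accuracy falls to a supplied
significance level. Significance levels come from a shuffle null: the
neuron-to-label mapping is permuted (1000 times by default, at least 100),
the full-feature classifier is refit each time, and the 95th percentile of
shuffled accuracies is reported with the empirical p-value of the real
accuracy; shuffling labels rather than expression rows is equivalent here
and is the documented choice.

Per-gene expression thresholds use Youden's J on the ROC over candidate
cutpoints placed midway between consecutive observed values (ties toward the
lower threshold); the report compares precision and response purity of the
any-expression group against the above-optimal group.

Temporal prediction regresses each timestamp's per-neuron response on the
gene features (Gaussian deviance, as the responses are continuous t-auROC
values) and reports the fraction of deviance explained,
$\mathrm{FDE} = 1 - \mathrm{dev}_{\mathrm{model}} / \mathrm{dev}_{\mathrm{null}}$,
evaluated out-of-fold by default with the fold-training mean as the null
model (in-fold evaluation, where FDE equals $R^2$ exactly, is an option).
Models for all genes, an optimal gene set and the top-2 genes share the same
folds; the per-timestamp significance level is the 95th percentile of FDE
after permuting the feature-to-neuron mapping. Neurons are ranked by the FDE
of their predicted-versus-observed concatenated series, flagged significant
against per-neuron shuffle nulls, and split into predictability quartiles;
the top quartile is tested for gene-expression and cell-type enrichment
(one-sided rank-sum and Fisher tests).

## The synthetic-data generator

Because the pipeline's correctness claims are parameter-recovery claims, the
package ships a generator that plants known structure:

* **Expression** is zero-inflated log-normal: each gene is detected with a
  type-specific probability and, when detected, drawn as
  $\exp(\mathcal{N}(\mu_g, \sigma))$ with $\sigma = 0.8$ on the log scale --
  continuous, strictly positive, strongly right-skewed, high variance. A
  negative-binomial model would suit counts; FISH intensities are
  continuous.
* **Marker organization** is hierarchical: each of the 10 default types is
  dominated by one high-mean gene ($\mu = 3.0$, detection 0.99); genes that
  are dominant in no type act as class-level markers spanning contiguous
  blocks of types ($\mu = 2.0$, detection 0.85), the way class markers and
  pan-neuronal genes behave in real panels; off-type background expression
  is dim and sparse ($\mu = -1.0$, detection 0.12). With these defaults the
  per-cell expressed-gene count has its mode at 3 and ~80% of cells express
  more than two genes: for a non-conductor type the count is
  $1 + \mathrm{Bern}(0.85) + \mathrm{Binom}(10, 0.12)$, whose mode is 3.
* **The conductor gene** (the last gene by default) spans types 1-6 at
  detection 0.90 with log-mean 1.8 +/- 0.4 across member types. Its planted
  threshold is $e^{1.8}$: coherent member neurons above threshold follow
  their type kernel in the conductor-linked states with response gain
  increasing as (expression/threshold)^0.8; neurons below threshold respond
  with flipped sign there. This makes expression-level analyses (Youden
  cutpoints, FDE ranking) quantitatively meaningful rather than binary.
* **Traces**: each (type, state) kernel is
  $\mathrm{sign} \cdot A \, (1 - e^{-(t - t_0)/\tau_r})$ during the epoch
  and decays exponentially ($\tau_d$) after offset; onsets are 0.4-1.2 s and
  ramps alternate fast (0.8 s) and slow (6 s) across types so kinetic
  comparisons have planted structure. Every type responds strongly
  (1.6 dF/F) in its own signature state -- each state's dedicated driver
  type -- and weakly (0.4-1.0 dF/F) in a sparse set of other states (sign
  probabilities 0.20/0.15/0.65 for +/-/none). Secondary response patterns
  are shared within consecutive state pairs, planting state classes: paired
  states are distinguished mainly by their driver types, so decoding
  genuinely requires cell-type coverage (this is what makes grouped
  ensembles beat size-matched dummy ensembles, rather than every neuron
  being individually sufficient). A fraction `coherence` (0.95) of each
  type's members follow the type kernel; the rest -- and all members of the
  designated incoherent type (the last type, coherence 0) -- draw an
  independent random kernel per state *and per trial* (sign +/- 1 equally,
  half-normal amplitude). Per-trial draws are deliberate: with trial-stable
  random kernels an "incoherent" neuron would carry a unique, reliable
  tuning signature and become the most informative decoder in the ensemble,
  the opposite of the low-purity phenotype it emulates. Neurons get a
  log-normal gain (sdlog 0.15) and stationary AR(1) noise (coefficient 0.8
  at 0.4-s steps, sd 0.3 dF/F), matching the slow autocorrelation of
  calcium indicators without modeling spikes.
* **Schedule**: 11 states x 3 trials, 20-s stimulus epochs separated by
  24-s inter-trial intervals (deliberately compressed from experiment-scale
  ITIs of minutes to keep desk-scale; a config knob), 0.4-s sampling,
  319 cells.

What the generator does **not** emulate: imaging artifacts (motion, optical
aberration, segmentation errors), registration mismatches between the
functional and molecular measurements, spike-to-fluorescence nonlinearity,
trial-to-trial adaptation, and within-state behavioral variability. Passing
recovery tests therefore demonstrates that the analysis code is correct and
calibrated under its own statistical assumptions -- not that those
assumptions hold for any particular real dataset.

## Numerical choices and degenerate inputs

* t-auROC uses midranks, so ties contribute exactly one half; per-timebin
  values are clamped to $[-1, 1]$ against last-bit rounding.
* Correlation distance assigns constant profiles distance 1 to everything
  and 0 to each other; all-identical functional profiles are a hard error
  ("degenerate clustering").
* Purity uses an $\varepsilon = 10^{-9}$ denominator floor; expression
  ratios in enrichment are guarded the same way.
* CV folds are stratified and auto-reduced with a warning; ridge fits use a
  short decreasing lambda path ending at the target penalty (a single-value
  multinomial fit trips a coefficient-extraction bug in glmnet).
* The SFFS stopping tolerance is 0.001 accuracy; mSFFS removes only each
  round's first-selected gene, per its definition.
* Youden cutpoints between observed values use the midpoint; ties toward
  the lower threshold.
* All stochastic stages take explicit seeds; identical seeds give
  byte-identical pipeline outputs, and the caller's RNG state is never
  disturbed.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run the full method stack on
generated data at deliberate desk scale: the default 319-neuron, 11-state
session for the end-to-end and structural checks; 240 cells for the 8-type
clustering recovery; 100-run batches at n = 120-150 neurons for the
SFFS/mSFFS recovery rates; 200 response-free neurons for the responsiveness
false-positive calibration; and 100-200 shuffles/permutations for the
empirical nulls. The pipeline defaults (`carma_run_config()`) use 50
grouped-ensemble resamples, 100 circular shifts and every 10th timestamp for
temporal FDE; all are single-call knobs when more resolution is wanted.

## Known limitations

* The per-timestamp "optimal gene set" in the pipeline report is the SFFS
  selection for one state's functional clustering applied across all
  timestamps, not a per-timestamp re-selection -- a deliberate economy;
  `temporal_fde()` accepts arbitrary gene sets when per-timestamp selection
  is wanted.
* Responsiveness inference shares one set of circular shifts across neurons
  for speed; shift draws are seeded and the shared set slightly correlates
  neurons' null estimates without biasing individual rates.
* The grouped-ensemble/dummy comparison assumes every type has at least one
  imaged member.
* Labeled-line enumeration is exact and therefore exponential in the number
  of states; it is comfortable at 11 states and impractical far beyond.
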