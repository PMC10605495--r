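---
title: "Interpretable gene signatures and their transfer between single-cell datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable gene signatures and their transfer between single-cell datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigtransfer)
```

## The problem

Single-cell RNA-seq studies of the same disease rarely agree on a shared
measurement scale: protocol, tissue and cohort differences imprint
dataset-specific batch effects that defeat naive model transfer. Yet if a
cell type is annotated consistently across datasets, a *small* classifier of
per-cell disease state — two or three genes combined by elementary
arithmetic behind a logistic link — has a real chance of surviving the jump
from one dataset to another, and is interpretable enough to read off
biology. `sigtransfer` implements that full analysis: train per-cell-type
symbolic classifiers on one dataset, apply them to every other dataset
sharing the cell type, and quantify each transfer with a score that rewards
performance *and* consistency.

The disease context motivating the defaults is ulcerative colitis (UC):
samples (patients) carry a binary disease label which every cell inherits,
and per-cell-type disease fractions in real cohorts fall roughly in the
16–45% range.

## The model class

A `formula_model` is a binary expression tree over `{add, multiply}` with
1–3 gene leaves and a logistic output. Trees are kept in canonical
left-deep form: features $f_1,\dots,f_k$ are chained by operators
$o_1,\dots,o_{k-1}$ as

$$v_1 = w_1 f_1,\qquad v_j = v_{j-1} \;o_{j-1}\; (w_j f_j + b_{j-1}),
\qquad p = \sigma(v_k + b_0),$$

so each leaf carries a weight, each internal node a bias on its right
operand, and there is one output bias — at most $2k$ parameters. This is
the minimal class expressing the published model shapes (e.g. "add two
genes, then multiply by a third"). Left-deep canonicalization is a design
choice: it makes the structure space finite and enumerable without
restricting the expressible function families at this size. Whether
intermediate nodes should also carry a logistic link was an open question;
only the output link is implemented, since every model form we target is
expressible without inner links.

Parameters are fitted by minimizing mean binary cross-entropy with
multi-restart BFGS (analytic gradients; restarts drawn from
$\mathcal{N}(0, 0.5^2)$). A bias-only start — all weights zero, output
bias at the logit of the class prevalence — is always included, so the
fitted loss never exceeds the intercept-only loss. With at most six free
parameters this is robust and fast; no regularization is applied, because
complexity is controlled structurally (the 3-feature cap), matching the
stated preference for simplicity over penalization. Sign symmetries of
multiply nodes can create equal-loss optima; the first found under the
seeded restart order is kept.

## Structure search

`search_models()` explores structures with an evolutionary loop plus random
sampling: an initial population of randomly sampled structures (feature
count uniform on $[1,3]$, distinct genes, uniform operators) is fitted and
ranked by training loss; the elite half survives; the next generation is
filled with single-move mutants of the elites (swap one gene, flip one
operator, grow by one gene, shrink by one leaf) plus 20% fresh random
structures (immigration). Fits are cached per structure, so the cost is
proportional to the number of *distinct* structures explored. There is no
crossover operator. The gene pool defaults to the most variable genes of
the training slice (capped at 500) — whether the original analyses
restricted their pool is unstated, and a variance cap keeps exhaustive
oracles feasible; it is configurable to the full panel.

Gene identities in proposals (initial sampling, immigrants, and the
incoming gene of swap/grow moves) are drawn with probability proportional
to each gene's marginal label correlation plus a floor equal to the mean
correlation, rather than uniformly. This was a genuinely open design
point: purely uniform proposals were implemented first and proved
unreliable at assembling multi-gene signatures within desk-scale budgets —
pairing two specific informative genes out of a 100-gene pool by uniform
single-gene moves is a rare event — while correlation-weighted proposals
(standard roulette-style proposal biasing in evolutionary computation)
assemble them reliably at a fraction of the budget. The floor keeps every
pool gene proposable, so interaction-only genes with weak marginal signal
remain reachable, and the small-pool exhaustive-equivalence properties
are unaffected.

The search returns the 10 best structurally distinct models (purely
additive chains are treated as permutation-invariant in their features),
ranked by loss, then the complexity key (feature count, node count), then
the expression string. On small pools this provably converges to the
exhaustive optimum, which the test suite checks by brute-force enumeration
at 1 and 2 features.

## Metrics and the transfer score

Class imbalance makes precision–recall AUC the headline metric. `pr_auc()`
is step-wise average precision with tied scores grouped into a single
threshold — trapezoidal interpolation is deliberately avoided because it
over-estimates PR curves. `roc_auc()` is the normalized Mann–Whitney
statistic with half-credit for ties. Thresholded accuracy/precision/recall
at 0.5 complete the report.

The transferability-corrected performance score between training dataset X
and test dataset Y is

$$s_{XY} = \tfrac{1}{2}\,(\mathrm{AUC}_{PR,X} + \mathrm{AUC}_{PR,Y})
           - \lvert \mathrm{AUC}_{PR,X} - \mathrm{AUC}_{PR,Y} \rvert ,$$

algebraically $\min(a,b) - |a-b|/2$: it never exceeds the weaker AUC and
equals it only when the two agree. A 0.7/0.9 pair scores 0.6; a 0.8/0.8
pair scores 0.8.

```{r score}
transfer_score(0.7, 0.9)
transfer_score(0.8, 0.8)
round_half_up(transfer_score(0.95, 0.94), 2)
```

Reported tables round half-up to two decimals (0.935 prints as 0.94).

## Model selection and the transfer pipeline

`run_transfer()` enumerates every cell type shared by two or more
datasets, searches on each training slice, evaluates all candidates on
each test slice (features aligned by exact gene-symbol match; a candidate
whose gene is absent from the test panel is skipped rather than
zero-filled, because zero-filling silently changes the model's semantics),
and selects the reported model by the published strategy: discard
candidates whose training/test PR AUC gap is 0.10 or more — read as an
*absolute* difference in PR-AUC units, the simpler reading consistent with
the retained published rows; a relative-gap switch is provided — then
prefer fewest features, then purely additive trees, then the highest
score. When no candidate survives the gap filter, the highest-scoring one
is reported with a fallback flag. Selecting on test-set performance leaks
information by modern standards; it is implemented as stated because the
point is to reproduce the published protocol, and the criteria object
keeps the gap configurable for stricter designs.

Disease is the positive class (label 1) in every metric: published tables
report disease fractions and call disease "Class 1", and the one passage
suggesting the opposite encoding is treated as abandoned by the results;
a `positive_class` switch restores the other polarity, which changes PR
AUC values. "Dominant features" are the two genes present in the most of
the 10 candidate models (presence per model, not leaf multiplicity; ties
lexicographic). `summarize_transfers()` formats records with train/test
values "/"-joined, percentages for disease fractions, sorted by training
dataset then descending score.

## The synthetic cohort generator

Real accessions need downloads, so the package ships a generator whose
defaults *are* the emulated study conditions: at least two datasets with
distinct per-gene batch shifts, 20 samples per dataset, a disease fraction
of 0.4 (sample level; realized per-cell-type fractions then span the
16–45% band seen in real cohorts), a 200-gene panel, Poisson cell counts
per (sample, type) with mean 30, and negative-binomial counts via the
gamma–Poisson mixture — the standard scRNA-seq noise model; no generative
model was published, and NB keeps recovery tests honest. Counts for gene
$g$ in cell $c$ of dataset $d$ have mean
$\exp(\mathrm{base}_g + \mathrm{batch}_{d,g} + \mathrm{effect})$ with
dispersion (size) 10, where the effect $\log(2)\cdot\mathrm{lfc}_g$
applies only in diseased cells of a signed type. Baseline log-means are
uniform on $[-1, 2]$ (means of roughly 0.4–7 counts, the realistic range
for informative genes after UMI counting); batch shifts are normal with sd
0.3. Signature `interaction = "multiplicative"` couples the per-gene
effects through a shared per-cell lognormal activation (sd 0.25),
producing correlated effect sizes; the additive default applies fixed,
independent shifts and is what all calibration tests exercise.

What the generator does **not** emulate: read-level artifacts, UMI
collapsing, ambient RNA, dropout beyond NB sampling, cell-level label
noise, or the annotation step itself (cell types are taken as input
metadata, as in the original design). Inflamed and non-inflamed samples
are merged into one non-healthy class and never distinguished. Passing
recovery tests therefore demonstrates that the pipeline recovers planted
signal under realistic count noise and batch shifts — not that it would
survive every artifact of a real protocol.

Determinism: a config's seed makes cohorts bit-identical, searches are
reproducible under their seed (per-run seeds inside the pipeline are
derived from the search seed and the run index), and the end-to-end
summary TSV is byte-identical across repeated runs.

## Numerical choices and degenerate inputs

* Probabilities from `evaluate_model()` are clipped to
  $(10^{-12}, 1-10^{-12})$; losses use the stable
  $\max(z,0) - yz + \log(1+e^{-|z|})$ form, and non-finite tree values
  (possible under runaway multiply nodes) are penalized rather than
  propagated.
* Single-class slices are refused for training and skipped (with a logged
  reason) as test slices; single-class label vectors raise a classed error
  in ranking metrics rather than returning 0.
* Cells with zero total counts stay all-zero through normalization.
* A cell type that draws zero cells in a simulated dataset warns; a
  signature referencing a gene outside the panel is a configuration error.
* Equal-loss ties in search ranking break by complexity key then
  expression string, making orderings deterministic.

## Problem sizes used by the test suite

The calibration and recovery experiments run at deliberately compact
sizes chosen once as representative: recovery cohorts use two datasets,
20 samples each at disease fraction 0.5, a 100-gene panel with a planted
2-gene additive signature (log2 fold change 2.0 per gene, batch sd 0.2,
about 400 cells per class per dataset), and a search budget of population
48 for 12 generations, which saturates the candidate list with
signature-bearing structures. Twenty independent seeds feed the recovery
and permutation-null checks. Monte-Carlo calibration bands (e.g. the
disease/healthy mean-ratio interval for a planted log2 effect of 2) were
frozen from an independent simulation of the stated NB model before the
generator was tested against them.

## Known limitations

* The original symbolic-regression engine is proprietary; this package
  implements the minimal published model class and a standard evolutionary
  search, not the engine's undisclosed structure prior.
* Gene matching across datasets is exact string match on symbols; no alias
  resolution.
* No within-dataset cross-validation (training uses whole datasets, as in
  the published protocol) and no confidence intervals on AUCs.
* The generator's batch model is dataset-wide and per-gene; real batch
  effects can be cell-state dependent.
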