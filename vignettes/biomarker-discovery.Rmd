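---
title: "Model ensembles and classifier search for complication-specific biomarkers"
author: "netmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model ensembles and classifier search for complication-specific biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`netmark` implements an in silico biomarker-discovery pipeline for
complication subtypes of type 1 Gaucher disease (GD1), a lysosomal storage
disorder in which glucosylceramide-laden macrophages (Gaucher cells) drive
inflammation, iron accumulation and, in many patients, debilitating skeletal
disease. The pipeline has four stages:

1. a **signed, directed protein network** annotated with pathophysiological
   motifs (M1–M7), effector proteins, an expression signature and
   plasma/urine measurability;
2. **disease-model ensembles**: for each complication combination, an
   ensemble of constraint-satisfying signal-propagation solutions assigning
   every protein a predicted activity in $[-1, 1]$;
3. a **classifier search** over 1–3 protein tuples scored by
   cross-validated balanced accuracy;
4. a **filter cascade** that keeps only candidates that beat the best
   previously proposed biomarker, meet sensitivity/precision floors, are
   homogeneously modulated, and are *specific* to the skeletal comparison.

Because the original interactome, training compendium and pretrained models
are proprietary, the package ships a synthetic-data module that emulates
every input with known ground truth; all tests and the acceptance script
run without downloads.

## The network model

An `Interactome` holds proteins and directed signed edges
($+1$ activation, $-1$ inhibition, $0$ unknown). Design choices that the
rest of the package depends on:

* **Traversal is directed** — signal flows along edge direction; undirected
  database records should be loaded as two directed edges.
* **Unknown signs propagate as $+1$** but remain $0$ in the edge table, so
  connectivity is preserved while the uncertainty stays on record.
* **Gene symbols are exact, case-sensitive identifiers**; alias resolution
  is an input concern.
* Motif-to-motif connectivity is *distance-1 only*: two motifs count as
  connected exactly when a single edge links them, matching how initial
  pathological changes are related to downstream machinery.
* Enrichment of a signature within a protein set uses the upper-tail
  hypergeometric probability $P(X \ge k)$ — an over-representation test
  only.

Trigger analysis asks which effectors can signal the full
inflammation/iron machinery. A target counts as *covered* by an effector
when some directed path of length $\le 3$ with positive sign product
connects them (proximity positively correlated with activation); coverage
is normalized so full coverage is 100%. `selectTriggerSet()` then finds the
smallest effector subset whose united coverage reaches every target —
exactly for up to 20 candidates (subsets enumerated by size, ties broken
lexicographically), greedily beyond, with an explicit under-coverage flag
when 100% is unattainable. Whether the 100% criterion should be evaluated
per distance or cumulatively over distances 1–3 is an open question; the
cumulative reading is implemented. An effector counts as covering itself
when it is among the targets, since it is the stimulus.

## Model ensembles

A model is a `ModelConfig` with three parts: **stimulus** (trigger proteins
clamped to fixed activities), **restrictions** (signed activity
requirements, e.g. from the expression signature), and **response** (a
motif combination whose effectors must come out active). With base motifs
$\{M2, M3\}$ and complication motifs $\{M5, M6, M7\}$ (bone marrow, liver,
skeletal), the $2^3$ subsets give the canonical eight models.

The training internals of the commercial system this emulates are patented
and unpublished, so the sampler is a reconstruction, with every choice
exposed as an argument:

| parameter | default | meaning |
|---|---|---|
| `squash` | `tanh` | odd, bounded update nonlinearity |
| `steps` | 10 | synchronous propagation steps |
| `floor` | 0.1 | activity magnitude for a satisfied sign constraint |
| `tolerance` | 0.05 | hinge-loss level at which a solution is accepted |
| `n` | 250 | solutions per model |
| `maxIter` | 2000 | annealing iterations per solution (3 restarts) |
| `failLimit` | 0.1 | tolerated fraction of failed solutions |

Propagation is synchronous: activities start at zero, stimulus nodes are
re-clamped each step, and every other node updates as
$x_v \leftarrow \tanh\!\big(\sum_{e:\,u \to v} s_e w_e x_u\big)$ with
$s_e \in \{-1,+1\}$ and $w_e \in [0,1]$. Parallel edges between the same
pair sum their signed contributions. Nodes unreachable from the stimulus
stay at zero, and boundedness is automatic. The loss is a hinge over
constraints, $\sum_c \max(0, \mathrm{floor} - s_c x_c)$, zero exactly when
every constrained protein carries the required sign at meaningful
magnitude.

Each solution is an independent stochastic search over the edge-weight
vector: a signed breadth-first search from the stimulus finds, for every
constrained gene, a support path with the required sign product, and the
initial weights boost those paths while damping opposing in-edges of the
constrained genes; simulated annealing (geometric cooling, mixed random
perturbations and targeted repair moves on violated constraints) then
drives the loss to tolerance. Solutions differ by weights only — topology
subsampling is not used. Restrictions and response constraints enter the
same loss with equal weight, since no published weighting exists. Whether
an activity band around zero or exact zero defines "unmodulated"
downstream is likewise unpublished; a tolerance band (0.05) is used.

Per-solution seeds derive from the master seed by a fixed affine scheme,
`(seed + 104729 * i) mod (2^31 - 1)`, so an `ActivityMatrix` is
bit-reproducible from `(seed, n)`. A model whose constraints demand both
signs for one gene is rejected up front as infeasible; a model where more
than `failLimit` of searches stall is rejected with a diagnostic rather
than returned partially satisfied.

## Classifier search

Balanced accuracy is
$\mathrm{BACC} = (\mathrm{sensitivity} + \mathrm{specificity})/2$, with
sensitivity on the positive cohort and specificity on the negative one.
Cleaning removes zero-variance columns ("uninformative" is read strictly
as zero variance; near-constant filtering is deliberately not the
default). Single proteins use exhaustively optimized threshold rules —
one cut (direction auto-chosen) or two cuts (inside/outside interval) over
all midpoints between adjacent sorted observations, ties towards the
smaller cut. Pairs and triples use logistic regression, naive Bayes or a
small multilayer perceptron (one hidden layer of width 4, fixed-seed
initialization). The search is exhaustive for size 1; for sizes 2–3 it
enumerates the union of mRMR, ReliefF and Wilcoxon-with-correlation
shortlists unless exhaustive enumeration is requested, with a budget cap
that marks truncated results. A leave-one-out averaged threshold
(`looThreshold()`) reproduces the validation protocol used for univariate
biomarker evaluation.

Metrics come from stratified 10-fold cross-validation with pooled
out-of-fold predictions. The cross-validated p-value is the exact binomial
tail $P(X \ge \text{correct})$ under chance equal to the larger class
prior. A label-permutation alternative (`cvPValue(method =
"permutation")`) is provided. A caveat the calibration test quantifies:
out-of-fold predictions are not independent (folds share ~90% of training
data), so the binomial reference underestimates the variance of the
correct count; in the package's 200-run null calibration about 2.5% of
null candidates reach cv-p < 0.01 instead of the nominal $\le$ 1–2%. The
binomial definition is retained because it is the prescribed, reproducible
default; the permutation variant absorbs the dependence and should be
preferred when calibrated error rates matter.

## The filter cascade

Filters run in order and each rejection names the first failed filter:
(1) BACC strictly greater than the benchmark set by the best previously
proposed biomarker (default 0.5854, the published CCL4/MIP-1$\beta$
value — equality is not an improvement); (2) sensitivity $\ge$ 65% and
precision $\ge$ 65% (precision is positive-class precision); (3) no member
protein unmodulated ($|x| < 0.05$) in $\ge$ 75% of the solutions of either
cohort — a heterogeneity guard; (4) removal of candidates (identified by
their unordered protein tuple) that also passed filters 1–3 in the
bone-marrow or liver comparison. Filters 1–3 are pure predicates, so their
order affects only the attribution, never the survivor set — a property
the tests assert. Survivors are annotated against plasma/urine
measurability tables and ranked ascending by BACC, flagging panels whose
every member is blood-measurable.

`biomarkerDiscovery()` wires the stages together using the pooled
case-versus-rest reading of the three comparisons (all models containing
the motif versus all others); pairwise model contrasts can be built
manually from `cohortData()` if wanted.

## The synthetic-data module

Two tiers trade realism for speed:

* **Matrix tier** (`generateEnsembleDataset()`): clipped-Gaussian
  activities, planted markers shifted by $\delta$ in the positive cohort,
  null proteins identically distributed in both. Defaults are the study
  conditions: 250 solutions per cohort, $\sigma = 0.25$, $\delta = 0.5$
  (a $2\sigma$ gap), chosen so the Bayes-optimal BACC has the closed form
  $\Phi(\delta / 2\sigma) = \Phi(1) \approx 0.8413$ and classifier
  recovery can be tested against an exact oracle. The clipped-Gaussian
  model was chosen over a beta model for exactly this closed form.
* **Network tier** (`generateEndToEndDataset()`): a positive backbone tree
  of bounded depth grown from three trigger proteins (guaranteeing every
  constraint a satisfiable support path within the propagation budget),
  overlaid with preferential-attachment edges that are inhibitory with
  probability 0.2; motif sizes follow the canonical 6/24/12/21/43/85
  proportions unless given explicitly; a differential-expression table
  whose planted signature passes the inclusive thresholds (adjusted
  $p \le 0.05$, $|\log_2 FC| \ge 1$) by construction, plus decoy
  transcripts that map to no protein; random measurability flags; and the
  eight model configurations. Two planted markers define the ground truth
  of the cascade: `MK_SKEL` is restricted $+1$ in models whose response
  includes M7 and $-1$ otherwise (a clean skeletal-specific signal), and
  `MK_PAN` is restricted $+1$ when at least two complication motifs are in
  the response — a compounded-complication-burden signal that passes
  filters 1–3 in *all three* comparisons and must be removed by filter 4.
  Markers are backbone leaves (no effector may sit downstream of a protein
  whose required sign flips between models) and receive both an activating
  and an inhibiting route so both restriction signs are satisfiable.

What the generator does **not** emulate: real expression values and probe
structure, correlated activities along shared pathways, motif overlap
(generated motifs are disjoint), measurability databases, or the scale and
degree structure of the full human interactome. Passing tests therefore
demonstrate the machinery's correctness and calibration on controlled
truth, not performance on real GD1 data.

## Problem sizes and numerical choices

The test-suite and acceptance-script scales are the package's own choices:
planted-marker recovery uses 1 marker among 50 nulls at 250 solutions per
cohort over 20 seeds; null calibration uses 200 simulations of 5 proteins;
the end-to-end run uses a 200-protein network (motif sizes scaled to about
one third of the canonical proportions), 8 models × 50 solutions and a
size-1/2 search over the feature-selection shortlists. Exhaustive
enumeration at the full 423-protein scale (89,253 pairs, 12,525,171
triples) is supported through the budget flags and verified at the
counting level.

Degenerate inputs are defined errors, not silent results: empty motifs in
connectivity tests, conflicting duplicate expression records, classes
smaller than the fold count, all-constant feature matrices, weight vectors
naming non-existent edges, and infeasible constraint sets all raise with
the offending names. Ties are deterministic everywhere (smaller threshold,
lower column index, lexicographic gene order).

## Limitations

The sampler is a principled reconstruction, not the patented original; its
solution distribution (and hence absolute BACC values on real inputs) will
differ. The binomial cross-validated p-value is mildly anti-conservative,
as quantified above. Structural-mode trigger analysis ignores the
model-ensemble averaging that pretrained solutions would provide
(`signedCoverage` is graph-only; an ensemble mode can be emulated by
averaging coverage over an `ActivityMatrix`). Biological interpretation of
candidates — and any clinical use — requires in vitro / in vivo
validation, which is far outside this package's scope.
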