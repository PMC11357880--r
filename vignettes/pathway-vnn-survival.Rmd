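---
title: "Pathway-guided visible neural networks for survival modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-guided visible neural networks for survival modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`vnnsurv` fits a *visible* neural network to right-censored survival data
from binary gene-alteration profiles. Every neuron maps to a biological
entity — an input neuron to a gene alteration, a hidden neuron to a
pathway — and a connection exists only where the biology licenses it: a
gene connects to the pathways it belongs to, and a pathway connects to
its parent pathways in the hierarchy. The network's output, concatenated
with binary clinical covariates and passed through a two-layer dense
head, is a scalar risk score per patient.

Training minimizes the negative Cox partial log-likelihood,

$$-L(\theta) \;=\; -\sum_{i \in D}\Big(\hat r_\theta(X_i) -
\log \sum_{j \in R(t_i)} \exp \hat r_\theta(X_j)\Big),$$

where $D$ is the set of patients with an observed death and
$R(t_i) = \{j : t_j \ge t_i\}$ is the risk set at patient $i$'s event
time. Tied event times are kept in each other's risk sets (the Breslow
reading of "patients still alive at the time of death"). The sum is
computed with log-sum-exp stabilization, and during mini-batch training
the risk sets are formed *within* each batch; a batch that happens to
contain no events is skipped with a notice (full-cohort risk sets per
step are the special case `batch_size = n`).

Performance is summarized by the concordance index

$$C \;=\; \frac{1}{N_\mathrm{effect}} \sum_{i \in D}
\sum_{j \in R(t_i)} \mathbf{1}[\hat r_i > \hat r_j],$$

with the comparable pairs running over every event patient $i$ and every
other patient still at risk at $t_i$. Two conventions deserve note,
both exposed through the `ties` argument of `c_index()`. The indicator
above is *strict*: a tied pair of risk scores counts as discordant. We
keep strict as the default because it is the formula as printed, and
offer `ties = "half"` (0.5 credit) for comparability with other
survival toolkits — the distinction matters whenever risk scores take
few distinct values, e.g. for a score that is a weighted sum of a few
binary features. Second, because $j$ ranges over the whole risk set,
two events at the same time contribute a pair in *both* directions;
this follows the double sum literally and is deliberate.

## Compiling the architecture

`build_pathway_graph()` prunes the pathway universe to the nodes
reachable from the input gene panel (direct membership, then transitive
closure toward parents) — hierarchies are far larger than any given
panel touches. `assign_layers()` places each retained pathway at
`1 + (longest chain of children below it)`. The longest-path rule, not
shortest-path, is essential: real hierarchies are non-strict, and a
shortest-path layering can place a parent at or below one of its
children; longest-path layering guarantees `layer(child) <
layer(parent)` for every edge.

`build_masks()` then emits one binary mask per layer. Where a gene's
member pathway sits above layer 1, or an edge spans more than one
layer, or a parentless pathway's output must reach the root, the value
travels through *frozen identity skip-through channels*: unit-weight,
bias-free, activation-free copies. Freezing them (rather than making
them learnable) keeps the attribution of deep-entering genes
undistorted — the value a deep pathway receives is the gene's value,
not a rescaled proxy. Input genes that belong to no pathway are routed
directly to the root and flagged, so no input is silently discarded.

The root embedding defaults to the concatenation of all root-pathway
outputs plus orphan-gene channels (`root_mode = "concat"`), so its
width is emergent rather than chosen; a `dense` mode with a learnable
projection to a user-set width is available. Each pathway owns
`node_width` neurons (default 1). The masks are enforced structurally:
the forward pass multiplies weights by the mask, so a masked-out
position is absent whatever the dense storage holds, and the optimizer
additionally restores exact zeros after every update.

## Training defaults

All of these are unstated in the source material for this class of
model and are therefore declared package defaults, each configurable:
AdamW with decoupled weight decay (applied to weight matrices only, at
trainable positions only), `tanh` activation (bounded and stable for
sparse, narrow layers), head width 64, dropout 0.2 on pathway and head
units (inverted dropout; skip-through channels are never dropped, since
they are structure, not representation), and a default
cross-validation grid of learning rate {1e-2, 1e-3} x weight decay
{1e-2, 1e-4} x batch size {64, n} at 100 epochs. Folds are stratified
by event status so that no fold is event-free — without stratification
a small fold can make both the loss and the C-index undefined. Early
stopping is not used; epochs are a hyperparameter like any other.

Two baselines frame the masked model: `baseline_dense()` trains a fully
connected network with the same layer count and per-layer widths (so
its parameter count dominates the masked model's), and
`baseline_linear_ph()` fits the linear Cox model on the same columns
via `survival::coxph`, dropping constant columns with a notice.

## Attribution

`shap_values()` computes interventional Shapley values. The value of a
coalition is the model's mean output over hybrids of the explained
patient (coalition members) and a background sample (everything else).
Two scopes:

* **inputs** — players are the input columns (genetic and clinical).
  The empty coalition evaluates the model on the background alone, so
  the base value is a single scalar shared by all patients.
* **pathways** — players are the retained pathways. Intervening on a
  hidden entity needs a definition, and ours is activation clamping:
  for pathways outside the coalition, the forward pass overwrites their
  unit activations with the background's activations at the moment they
  are computed. Efficiency then gives additivity exactly:
  `base + sum(shap) = risk`. Because the patient's own gene values
  still travel the skip-through channels and the clinical columns stay
  the patient's, the empty-coalition value — the base — varies per
  patient in this scope; `shap_matrix$base_value` is accordingly a
  vector there and a scalar for inputs.

Exact mode enumerates all coalitions and is capped at 15 players;
sampling mode averages marginal contributions over seeded random
permutations (with coalition-value caching, so small player sets
converge to exact at modest budgets). The default background is a
seeded subsample of the cohort (100 patients); the all-zeros profile —
"no alterations, reference clinical state" — is available and is the
cheap default inside the elimination loop.

The per-feature summary is the altered-cases impact,
$\mathrm{Impact}_j = \frac{1}{N_j}\sum_{i \in C_j} s_{ij}$ with $C_j$
the carriers of alteration $j$. Averaging over carriers only, rather
than over everyone, keeps rare alterations visible: a feature altered
in 1% of patients can still carry a large per-carrier effect. A
never-altered feature has an undefined mean; we define its impact as 0
and flag it rather than erroring, since external panels routinely
include unobserved features.

`rank_and_eliminate()` iterates train → attribute → drop the `step`
features with the smallest `|impact|` → rebuild the architecture →
re-estimate CV performance. The magnitude ranks because protective and
harmful alterations are both informative; the sign is not a measure of
importance. The per-round CV estimate uses a single hyperparameter
setting (searching the grid at every round would multiply cost for
little ranking benefit).

In the Sankey export, node widths are mean |SHAP| across patients —
absolute values, because a node whose attribution is +0.2 for half the
cohort and −0.2 for the other half is important, not null; a signed
mean would draw it at width zero. Incoming edges split each target's
width proportionally to the source widths, so width is conserved at
every target before pruning; pruning then removes edges below a chosen
quantile of edge widths.

## Risk stratification and subtypes

The genetic prognostic index is
$\mathrm{score}_i = \sum_{j \in F_\mathrm{key}} f_{ij}\,
\mathrm{Impact}_j$, thresholded into levels I/II/III at $t_1 < t_2$
with boundary scores falling to the lower level. When thresholds are
not supplied, `optimize_thresholds()` searches a grid of ordered pairs,
requiring each level to hold at least `min_group` patients, and picks
the pair minimizing the *worst* of the three pairwise log-rank
p-values — "the groups differ significantly" is only as true as its
weakest comparison. Ties break toward balanced group sizes, then the
lexicographically smaller pair, so the search is deterministic.

Pairwise interaction analysis tests each unordered feature pair with a
two-sided Fisher exact test and Benjamini–Hochberg FDR (BH, not the
more conservative Benjamini–Yekutieli, as the standard reading of "FDR
correction"); labels require q below the level *and* an odds ratio on
the right side of 1. Degenerate 2x2 cells report the sample odds ratio
with the Inf/0 convention plus a Haldane-corrected column for plotting.
Patients carrying both high-risk and low-risk markers receive an
explicit `both` label rather than a silent precedence rule. The
anchor-feature sub-subtype uses competition ranking of per-patient
|SHAP| (ties share the better rank, so the assignment is
deterministic); rank within the top 5 maps to sub-subtype II, declared
here as the anchor-dominant, worse-prognosis convention.

## The synthetic generator

`simulate_cohort()` draws independent Bernoulli alteration columns at
stated marginal frequencies, exponential event times with hazard
$h_0 \exp(\sum_j \beta_j f_{ij} + \text{clinical effects})$, and
independent exponential censoring whose rate is calibrated by root
finding so the expected censored fraction hits the target. Exponential
survival is the simplest mechanism exactly compatible with
proportional hazards; a Gaussian-copula hook injects feature
correlation when co-occurrence structure is needed.

`planted_signal_study()` fixes the reference conditions used by the
package's end-to-end checks: 600 patients, 5 prognostic alterations at
$|\beta| = \log 2$ (three harmful, two protective) at frequency 0.4 —
the common-driver range — 15 null alterations at frequencies 0.1–0.4,
three clinical covariates with effects (+0.7 age > 60, −0.7 treatment,
−0.35 de-novo disease) in the range reported for strong clinical
prognostic factors, and ~30% censoring, with the gene panel routed
through a 12-pathway, 4-level hierarchy.

What the generator does *not* emulate — and hence what passing tests do
not establish about real cohorts: the long-tailed, mutually exclusive
mutation spectra of real tumors, non-proportional hazards, informative
censoring, covariate-dependent ascertainment, and panel heterogeneity
across centers. Results on synthetic data certify the machinery
(losses, gradients, masks, attributions, statistics), not clinical
performance.

## Numerical choices and problem sizes

Degenerate inputs are rejected early with located messages: non-binary
cells by row/column, non-positive times, event-free cohorts (the
partial likelihood is undefined), cyclic hierarchies (with the cycle
listed), constant columns in interaction tests (excluded with a
notice). Result tables are written at full precision and round-trip at
1e-10. Exact-vs-oracle tolerances in the test suite are 1e-10 for the
loss, exact equality for the C-index, 1e-5 relative for gradients
against central differences, and 0.02 for sampled-vs-exact Shapley at a
2^14 evaluation budget.

The shipped checks run on one CPU: cross-validation uses the
planted-signal cohort at n = 600 with a single default hyperparameter
setting, and the elimination study uses 5 seeds with 2-fold per-round
CV and the all-zeros attribution background; these sizes were chosen to
make the whole suite comfortably reproducible on a laptop while leaving
the conclusions (signal recovered, nulls eliminated first) unambiguous.

## Known limitations

The networks are small by design and trained in plain R; this is
adequate for panels of tens-to-hundreds of genes and hundreds-to-
thousands of patients, not for genome-wide inputs. Pathway-scope
Shapley values depend on the clamping definition of intervention;
other definitions (e.g. truncating gradient flow) would give different
hidden-layer attributions. The elimination procedure inherits the
variance of SHAP sampling at small budgets. No competing risks,
time-varying covariates, or transcriptomic inputs.
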