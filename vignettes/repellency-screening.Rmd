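---
title: "Scoring non-host plants for repellency: phylogenetic distance, odor similarity, and the behavioral assays that test them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring non-host plants for repellency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repelscore)
```

## The problem

Specialist herbivores find their hosts by recognizing a narrow set of
volatile cues — for a brassica specialist, the isothiocyanates released by
glucosinolate–myrosinase chemistry. A practical route to repellents is to
screen odors from *non-host* plants, but candidate selection is usually
guesswork. `repelscore` implements a systematic alternative: score each
candidate plant by

* **PD, phylogenetic distance** — how far the candidate sits from the focal
  host on a barcode-gene phylogeny, measured as the branch-length sum from
  the candidate's tip to its most recent common ancestor (MRCA) with the
  host; and
* **PS, physicochemical similarity** — how similar the candidate's volatile
  blend is to the host's kairomone compounds, measured with atom-pair
  fingerprints and the Tanimoto coefficient;

and then relate those two scores to behavioral assays (no-choice
oviposition, choice cages, y-tube olfactometer) with the statistics
appropriate to each design.

## The PD model

Per-gene alignments (e.g. *matK* and *rbcL*) are concatenated into a
supermatrix; a taxon missing a gene has that block gap-filled and is still
placed, its distances computed from the sites it does have (pairwise
deletion). Pairwise distances use the Jukes–Cantor correction

$$d = -\tfrac{3}{4}\,\log\!\left(1 - \tfrac{4p}{3}\right),$$

where $p$ is the proportion of differing sites among shared, ungapped,
non-`N` positions. A pair with $p \ge 0.75$ is reported as saturated rather
than silently truncated, and a pair sharing no sites is an error: both
indicate data inadequate for distance estimation.

The tree is built by neighbor-joining, which is exact on additive matrices —
the property the test suite verifies to $10^{-9}$ on random patristic
matrices. Negative branch-length estimates (a known NJ artifact on noisy
data) are clamped to zero and the total deficit reported. Because the
"first shared node" definition of PD presupposes a root, unrooted NJ trees
are rooted at the midpoint of the longest tip-to-tip path by default, with
outgroup rooting as an option; rooting never changes tip-to-tip path
lengths, only where the MRCA falls. An externally inferred tree (e.g. from
a Bayesian analysis) can be supplied as Newick and used verbatim — the
distance pipeline here is a deterministic, desk-scale stand-in for full
model-based inference, and PD is defined on whatever rooted tree you give
it. Consequently PD values from the NJ tree are estimates whose quality the
tests quantify (topology recovery, distance correlation), not re-creations
of any particular published tree.

The host's PD is identically 0 — one of the two identity anchors the
acceptance checks pin down.

## The PS model

Each compound is parsed from SMILES into a heavy-atom graph (hydrogens
implicit, charges ignored — essential-oil volatiles are small neutral
molecules). Every atom is typed by `(element, heavy-atom degree, pi
electrons)`, a Carhart-style descriptor: a double bond contributes one pi
electron per endpoint, a triple bond two, and aromatic atoms are assigned
exactly one regardless of their Kekulé form, which makes typing
deterministic from the parsed graph. The fingerprint of a molecule with $n$
heavy atoms is the multiset of $(type_a, type_b, d)$ triples over all
$n(n-1)/2$ unordered atom pairs, with $d$ the shortest bond-path length
(capped at 15 bonds; volatiles rarely approach that diameter, and the cap
bounds descriptor cardinality).

Similarity of two fingerprints is the count-preserving Tanimoto
$\sum_i \min(a_i, b_i) / \sum_i \max(a_i, b_i)$; a set-mode (Jaccard)
variant is available for sensitivity analysis, and its complement is a
metric — the triangle inequality is part of the property suite.

Blend-level PS aggregates compound similarities. The default,
`mean_of_max`, averages each blend compound's best match among the target
kairomones. This choice is deliberate: it is the only aggregator that
guarantees the host's own blend scores exactly 1 (the second identity
anchor), because every compound matches itself. The literal
all-pairs average (`mean_of_all_pairs`) is retained as an option, but it
scores even the host below 1 whenever the targets differ from one another.
Note that published PS values computed with other fingerprint families
(e.g. database substructure keys) will not be numerically reproduced by
atom pairs; rank order, not value equality, is the cross-implementation
contract, and the suite checks Spearman agreement with an independent
atom-pair implementation.

## Behavioral statistics

**QC filter.** Week blocks whose control plants averaged fewer than 5
larvae are discarded whole — low control oviposition means the assay failed
that week, and treated counts from the same week are uninterpretable.

**No-choice counts.** Larval counts are overdispersed, so the treatment
model is a log-link negative-binomial regression (variance
$\mu + \mu^2/k$; dispersion $k$ by maximum likelihood, with a
method-of-moments fallback that is flagged when ML fails). A treatment in
which every plant had zero larvae is a boundary case: its log-scale
coefficient is unbounded below, reported as $-\infty$ with a separation
flag rather than as a spuriously finite estimate.

**Choice cages.** Cage totals are not independent across the four plants,
so the preference test is a one-sample Hotelling $T^2$ on the per-cage
fraction of larvae on treated plants. The null is not 0.5: it is the
acceptability-weighted expectation $p_0 = \mu_t/(\mu_t + \mu_c)$ from the
no-choice means — if larvae distribute merely by how acceptable each plant
is without alternatives, the choice test should not fire. This
concretization of the weighting idea is the package's single largest
interpretive decision; a user-supplied $p_0$ is accepted wherever the
default is computed. On a univariate fraction, $T^2 = n(\bar x - p_0)^2 /
s^2$ equals the squared one-sample $t$ exactly, and $F = T^2$ with
$(1, n-1)$ degrees of freedom; the identity is verified numerically to
$10^{-9}$. Zero-variance cage sets short-circuit to $p = 1$ (all cages at
$p_0$) or a degenerate $p \to 0$ flag.

**Choice odds ratios.** The likelihood treats each larva's side as a
Bernoulli draw, so the intercept-only logit ML estimate is the closed-form
count ratio `total_treated / total_control`, with a Wald CI on the log
scale. A zero margin is complete separation and is reported as an
unbounded estimate with a flag, not a numeric overflow. Treating larvae as
independent ignores cage-level clustering; a chi-squared heterogeneity
flag marks treatments where that limitation bites.

**Olfactometer.** Replicates are classified as `chose_treated`,
`chose_control`, `no_choice`, or `stress`; the exact binomial test of the
arm split excludes both of the latter categories from $n$ (both represent
replicates in which no odor choice was expressed; an ambiguity in how the
exclusion could be read — stress only vs both — is resolved toward both,
and the four-way tally is always reported so either can be recomputed).
The two-sided p-value uses the minimum-likelihood rule — the sum of all
outcome probabilities no larger than the observed one — matching
`binom.test` and verified against brute-force pmf summation for every
$k, n \le 50$.

**Predictor regressions.** Across treatments, counts are regressed on PD
or PS with negative-binomial or Poisson log-linear models, olfactometer arm
choices with aggregated-binomial logistic regression, and linear fits
report $R^2$. No multiple-testing correction is applied anywhere, matching
the analysis style the package emulates; p-values across many treatments
should be read accordingly.

## The synthetic-data generator

The generator exists so that every stage can be tested against known
truth. Its defaults are fixed once, as the emulated study conditions:

* **Design sizes:** 19 taxa (one host + 18 candidates), 20 no-choice cages
  per treatment in two week blocks (10 treated + 5 control per week), 10
  choice cages, 30 olfactometer replicates, 6 phytotoxic treatments.
* **Sequences:** two gene blocks (900 + 700 sites, within the ~1.0–2.2 kb
  range typical of concatenated plant barcodes), evolved site-independently
  under JC69 on a random bifurcating tree with exponential branch lengths
  (mean 0.06 substitutions/site, which puts candidate PD values on the
  order of 0.05–0.5); one non-host taxon drops its second gene to exercise
  the missing-gene path.
* **Blends:** the host's blend is exactly the four packaged
  isothiocyanates; candidate blends are 8 compounds derived from random
  targets by 0–8 structural edits (element swaps and bond-order toggles,
  valence-checked). Edit count is the similarity ground truth: PS declines
  stochastically but monotonically in expectation with edits.
* **Behavior:** no-choice counts are negative binomial with
  $\log \mu = \beta_0 + \beta_{PD}\,PD + \beta_{PS}(PS-1)$, defaults
  $\beta_0 = 3$ (about 20 larvae on controls, comfortably above the QC
  threshold), $\beta_{PD} = -4$, $\beta_{PS} = 0$, $k = 2$; the $(PS-1)$
  centering makes the host score reproduce the control mean. Choice cages
  draw a Poisson total for the four plants and split it binomially at the
  no-choice-derived expected proportion. Olfactometer outcomes are
  four-category: stress (0.2) and no-choice (0.1) at fixed rates, the rest
  choosing the treated arm with probability
  $\mathrm{logit}^{-1}(\gamma_{PD}\,PD + \gamma_{PS}(PS-1))$, defaults
  $\gamma_{PD} = 0$, $\gamma_{PS} = -3$ (more host-like odors are avoided
  in the air stream, the direction the screening hypothesis predicts).

One global seed fans out to fixed per-stream child seeds (tree, sequences,
chemistry, behavior, phytotoxicity), so identical configurations produce
byte-identical output files while each stage stays independently
re-runnable.

What the generator deliberately does **not** emulate: real volatile
chemistry (terpenoid skeletons, blend co-occurrence structure), indels and
alignment error, among-site rate variation (no $\Gamma$; the simulator
matches the JC69 distance model by design), or within-cage spatial
structure of oviposition. Passing tests therefore demonstrate that the
*procedures* are correct and calibrated under the stated model — not that
real essential-oil data will satisfy that model.

## Numerical choices and edge cases

* NJ Q-matrix tie-breaking is delegated to the underlying `ape`
  implementation, which is deterministic; negative branch estimates are
  clamped at zero with the deficit logged.
* Topology-recovery checks use branch lengths bounded away from zero
  (uniform on 0.02–0.15): an internal edge of length ~0 is statistically
  unidentifiable at any finite sequence length, so including such edges
  would test the data, not the method.
* The discrete exact test's achieved size oscillates with $n$; calibration
  is evaluated at the design replicate count ($n = 30$, size 0.043), where
  the band check is meaningful for a discrete test.
* Degenerate inputs fail loudly and specifically: saturated distance
  pairs name the taxa, SMILES errors name the character position,
  separation is flagged rather than reported as a large finite number, and
  a choice test with $p_0 = 0$ warns that it has degenerated.
* Simulation problem sizes used by the test suite (e.g. 200 recovery
  replicates, 2000-replicate null calibrations, 500-molecule fingerprint
  panels, 100 additive matrices) were chosen as the smallest sizes at
  which the Monte-Carlo error is well below the property margins being
  checked.

## Known limitations

* PD from an NJ tree inherits NJ's estimation error; with an externally
  supplied tree the package computes but cannot validate its branch
  lengths.
* PS depends on the completeness of the supplied blend: compounds absent
  from the input simply do not contribute, and concentration/abundance is
  ignored (all compounds weigh equally).
* The per-larva odds-ratio likelihood understates uncertainty when cages
  are heterogeneous (flagged, not corrected).
* The weighted-null choice test assumes the no-choice means estimate
  acceptability without error; $p_0$ is plugged in, not propagated.
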