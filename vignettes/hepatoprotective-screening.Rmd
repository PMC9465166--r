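---
title: "Methods: two-level screening of TCMs for hepatoprotective activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-level screening of TCMs for hepatoprotective activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, the tunable parameters, the numerical
choices and the known limitations of the package — the things a
maintainer or reviewer would want to know before trusting a screen run
with it.

## The screening model

The package operationalises one idea at two levels. At the molecule
level, hepatoprotection is treated as a binary structure–activity
problem: ingredients reported to protect the liver are the positive
class, ingredients implicated in liver injury the negative class. At the
herb level, a TCM is treated as a plausible hepatoprotectant when two
independent lines of evidence agree: its *material basis* (it contains
many ingredients that are themselves hepatoprotective) and its *drug
property* (its nature/flavor/channel profile resembles that of known
hepatoprotective herbs more than that of non-hepatoprotective ones).
Neither line alone is treated as sufficient; the final screen is their
conjunction. Rule hits from the association-rule analysis are reported as
supporting evidence only and never gate the screen, because they are a
post-hoc consistency check, not an independent filter.

## Molecule level

### Data model and splitting

Compounds enter as `id, smiles, label` tables. Structures that Open Babel
cannot parse are never silently dropped: they go to a rejects table with
a reason, and the kept/rejected counts are logged, so a run is always
auditable against its input. Train/test splitting uses the Kennard–Stone
max–min procedure run *within each class* (the standard choice when the
two classes are strongly imbalanced and both must keep the 4:1 ratio).
Features are standardized to zero mean and unit variance before distances
are computed; the procedure itself is scale-sensitive and descriptor
magnitudes span orders of magnitude, so unstandardized Euclidean
distances would let a handful of large-scale descriptors dominate the
selection. Ties in the max–min step are broken by lowest input index,
which makes the split deterministic and permutation-stable whenever all
pairwise distances are distinct.

### Descriptors and feature selection

Descriptor computation is a *provider contract*: any function mapping a
parsed structure to a fixed-length named numeric vector qualifies. The
package ships a graph-based 2D provider (element, bond, ring and
branching statistics — about twenty features, deterministic, no external
program), a two-feature toy provider for examples, and a table adapter
(`descriptor_provider_table()`) that serves pre-computed descriptor files
from full-size external 2D descriptor programs. Sporadic provider
failures move the compound to the rejects table; sporadic missing values
are imputed with the feature median (and logged), keeping the matrix
rectangular without discarding compounds for single missing descriptors.

Relevance selection is a shadow-feature scheme: each iteration appends a
permuted copy of every feature, fits a random forest, and scores a hit
for every real feature whose z-scored permutation importance exceeds the
best shadow importance. Accumulated hits are tested two-sided binomially
at `alpha` (default 0.05) with a Bonferroni adjustment over the tested
features; features undecided after `max_iter` iterations (default 100)
are resolved by comparing their median importance to the median
best-shadow importance. The z-scored permutation importance and the
familywise adjustment were chosen after measuring that raw impurity
importance with unadjusted tests lets in about one spuriously confirmed
noise feature per run at n = 200: a feature whose *sample* correlation
with the labels happens to be large beats freshly permuted shadows
persistently, so the decision rule must demand strong, repeated evidence.
Even so, a lucky noise feature can carry genuine in-sample signal, and
occasional false confirms at small n are a property of any shadow scheme,
not a bug; the tests therefore assert a low rate, not an impossible zero.

Correlation pruning then walks the kept features in descending importance
and drops any feature correlated above `r_max` (default |r| > 0.90) with
an already-retained one, recording which feature it lost to. The greedy
order guarantees the retained set has all pairwise |r| ≤ `r_max`, which
the tests verify by brute force. Zero-variance features, whose
correlation is undefined, are dropped first under their own provenance
tag. Selection runs before pruning — relevance first, redundancy second —
so the pruned survivor of a correlated pair is always the more relevant
member.

### Classifiers

The seven base learners are functional analogues of a classic
workbench line-up, built on standard R fits: Gaussian naive Bayes
(e1071), a pruned CART tree (rpart) in place of a C4.5 tree, k-nearest
neighbour (class), a distance-weighted nearest neighbour with an
exponential kernel as the entropic-distance analogue (the bandwidth is
the `blend`-th percentile of training pairwise distances; this is
documented as an analogue, not a clone), a random forest, bagging over
knn, and discrete-SAMME AdaBoost over shallow trees. The voting
meta-learner averages the base models' active-class probabilities without
weights — the common default for probability-voting ensembles — and
labels a sample active at score ≥ 0.5, boundary inclusive. Class
imbalance is reported (SE and SP separately), not reweighted, matching
how such screens are read in practice.

Cross-validation is stratified, fold assignment is drawn once from the
seed, and metrics are pooled: one confusion matrix accumulated over all
out-of-fold predictions and one AUC from the pooled out-of-fold scores.
Pooling (rather than per-fold averaging) is the convention the
workbench-style tools report, and it makes the metrics exact functions of
the out-of-fold predictions. The AUC is computed as the Mann–Whitney pair
statistic, ties counted one half, so it is invariant under monotone
transforms of the scores. Grid search maximizes pooled CV accuracy and
breaks ties toward simpler models (fewer neighbours, fewer boosting
rounds, shallower or more heavily pruned trees), then grid order.

### Structural-alert mining

Fragments are generated by recursively cutting the acyclic single bonds
of each active molecule; rings are never opened. Contracting all
non-cuttable bonds (ring bonds, multiple bonds) collapses a molecule into
a tree of blocks, and the connected fragments are exactly the connected
subtrees of that tree, which the miner enumerates exhaustively with a cap
on heavy atoms (defaults 2–18, a desk-scale bound typical published
alert sizes fit comfortably inside). Each fragment is canonicalized through
Open Babel, so duplicates across molecules collapse.

Counting is substructure matching, not fragment-set membership: a
fragment counts for a compound if it embeds anywhere in it, and a
compound counts once however many times the fragment matches. Matching
runs through two provable shortcuts — a fragment cut from a molecule is
by construction contained in it, and a fragment whose element counts
exceed a molecule's cannot match — with the residual pairs decided by a
label-preserving subgraph monomorphism (igraph's LAD) on graphs whose
bonds are subdivision vertices labelled by bond order, aromatic ring
bonds sharing one label so that different kekulizations of the same ring
compare equal. The test suite checks this machinery against independent
Open Babel SMARTS counting on small sets, and `score_fragment()` always
uses the plain SMARTS route, so the two paths stay mutually auditable.

Alerts must pass `min_lr` and `min_freq` (both default 10). Infinite-LR
rules sort above all finite ones and among themselves by occurrence
count, matching how such tables are conventionally ordered. Two
extraction modes are provided because the upstream tool's mode is not
documented: `score_all` (default) scores everything and drops rules whose
matched active set is a subset of an already-accepted rule's — a pure
redundancy filter that keeps independent evidence — and `iterative_cover`
removes each accepted rule's matched actives and rescores, yielding a
covering set. Both modes are tested; they agree on which alerts exist and
differ only in the occurrence counts of later rules.

## Herb level

### Encoding and statistics

Drug properties are encoded on the fixed 24-term vocabulary (5 natures, 7
flavors, 12 channels) in a fixed order, so vectors are comparable across
runs. Unknown terms are rejected with the term and row named; a record
with no nature and no flavor is flagged invalid; a record without channel
terms is kept but flagged not clusterable, and the screen later reports
such herbs as unassessable instead of dropping them.

The chi-squared contrast is provided in two forms because the published
p = 0.042 could have come from either: an omnibus test on the 2 × 24
table of per-term possession counts (the default reading of "a
chi-squared test on the drug properties"), and 24 per-term 2 × 2 tests
with raw and Benjamini–Hochberg-adjusted p-values. Two caveats are
documented deliberately. First, the omnibus table is not a multinomial
contingency table — each herb contributes to several term columns — so
the chi-squared reference distribution makes the test *conservative*
under the null (measured: median null p ≈ 0.9, none of 60 null draws
below 0.05). It controls its level and detects genuine profile
differences, but its null p-values are not uniform; the tests assert
exactly that. Second, the per-term tests default to no continuity
correction (flag available), since the original software's setting is
unknowable; for a 50/50 all-vs-never split the statistic is 100
uncorrected and 96.04 Yates-corrected, both frozen in the tests.

### Association rules

Apriori runs with the consequent fixed to hepatoprotection, since every
published rule has that consequent and a general miner would spend its
budget on property–property rules of no interest here. The anti-monotone
pruning bound is applied to the joint (antecedent ∧ hepatoprotective)
support. Thresholds default to the published operating point — support
5%, confidence 65%, lift > 1 — and the antecedent is capped at 3 terms,
the deepest published rule. Reports round percentages to 2 dp; internal
arithmetic is unrounded, and the identities support ≤ confidence and
lift · prior = confidence hold exactly on every emitted rule. The miner
is checked against exhaustive subset enumeration on small vocabularies.

### Cluster classification

Candidates are clustered *jointly* with the reference herbs (Euclidean
distance, Ward's linkage `ward.D2`, tree cut into `k_cut = 2` branches by
default). Joint clustering was chosen over projecting candidates onto a
fixed reference tree because the published procedure put all herbs into
one cluster analysis. The verdict rule generalizes "clustered into the
same branch as the hepatoprotective herbs" to mixed branches: a branch is
hepatoprotective-like iff its fraction of hepatoprotective *reference*
herbs exceeds the global reference prior, so the verdict is a pure
function of branch composition, which is reported for audit. Ward on
binary vectors is stable and k = 2 matches the published dichotomy; both
are configurable. Determinism: for fixed input order the result is
deterministic; with tied distances (common for binary vectors) hclust's
ordering conventions make input order part of the tie-break, which is why
the screen fixes the candidate order before clustering.

### Networks and the screen

Edges are restricted to active (hepatoprotective) ingredients; herbs with
known hepatoprotective status form the hepatoprotective network and all
others the undetermined network, a partition the tests assert. The
material-basis filter is *inclusive* (degree ≥ 15): the published
candidate table contains eight herbs at exactly 15, so the table wins
over the accompanying prose ("greater than 15"). Ingredient identity is
the caller's id, normalized by lowercasing and trimming; cross-database
synonym resolution is out of scope by design and documented as the
caller's responsibility. Networks export to GraphML and GEXF with `role`
and `status` attributes.

`run_screen()` chains the stages, embeds every threshold and the seed in
the report provenance, reports unassessable candidates explicitly, and
computes `screened` as the conjunction of the degree filter and the
cluster verdict. Stage failures propagate with the stage name.

## Synthetic data: what it emulates and what it does not

The generators define the package's study conditions. Compounds are
assembled from a small concatenation-safe SMILES grammar (rings, chains,
common substituents; every piece starts and ends on an atom with a free
valence, so concatenation always parses), with planted alert motifs
appended to actives at a set penetrance and to inactives at a leak rate.
Defaults are ~700 actives and ~200 inactives with a trifluoromethyl motif
at penetrance 2/7, leak 0 — a class balance and alert prevalence in the
regime of the motivating data. Herb tables default to 250 reference herbs
at a hepatoprotective prior of 0.482 with a planted {sour} →
hepatoprotection rule at confidence 0.714; single-term rule confidences
are calibrated exactly through the conditional marginal
p(term | status), and multi-term associations emerge from the separated
property populations (signature flavors/channels enriched on each side,
gap controlled by `separation`). Edge lists plant ≥ 15 active ingredients
on designated candidate herbs against a low-degree background.

What passing these tests shows: every stage recovers the structure it is
designed to detect, at the stated tolerances, from data satisfying its
assumptions. What it does not show: performance on real compound
libraries (the grammar's chemistry is far simpler than natural products —
no stereochemistry, no charged groups, no fused-ring diversity), on real
herb annotations (real natures are mutually exclusive and real channel
sets are curated, while the generator draws bits independently given
status), or under database-driven ingredient synonymy. Scale is also
deliberate: the mining and screening tests run at 100–300 compounds and
150–200 herbs, and the acceptance script at the same desk scale, sizes
chosen so the full suite exercises every path in under a minute of
mining; statistical recovery checks (rule confidence at n = 5000) use
pure-R generation where large n is cheap.

## Numerical choices and degenerate inputs

* Likelihood ratio with fp = 0 is +Inf, printed as the literal `inf`;
  tp = fp = 0 is flagged undefined (NA), never 0 or 1.
* All-identical points in Kennard–Stone fall back to input order; the
  requested train size is clamped to [2, n−1] per class.
* The voting decision boundary counts 0.5 as active.
* Median imputation only ever fills sporadic descriptor failures; a
  provider that fails for a compound rejects the compound instead.
* Percentages are rounded only at the reporting edge (2 dp), never
  internally.
* Every stochastic step (fold draws, forests, generators) is seeded
  explicitly; identical seeds give identical results, which the tests
  assert down to serialized report bytes.

## Command-line use

The package's interface is its functions, scripts and this vignette;
`scripts/acceptance.R` is the runnable entry point that regenerates the
headline numbers (`--seed`, `--out`). The ingest/feature/train/screen
stages are plain functions designed to be scripted the same way.

## Known limitations

* Ingredient dose and content are ignored: a herb with fifteen trace
  ingredients screens identically to one with fifteen abundant ones.
* The alert miner's fragment space excludes ring-opened fragments by
  design; alerts that only exist as partial ring motifs will not be
  found.
* The entropic nearest-neighbour learner is an analogue, not a
  re-implementation, of the original entropic-distance method; its
  `blend` parameter is comparable in spirit but not numerically to the
  original's.
* The omnibus property contrast is conservative (see above); per-term
  tests with BH adjustment are the sharper instrument.
* Real screens hinge on curation quality (status labels, synonym
  resolution); the package validates formats and vocabularies but cannot
  validate curation.
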