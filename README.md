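# herbscreen

Screening traditional Chinese medicines (TCMs) for hepatoprotective
activity, at two levels:

* **Molecule level.** Given a table of ingredients labelled
  hepatoprotective / non-hepatoprotective (as SMILES), the package builds
  structure–activity models — molecular descriptors behind a pluggable
  provider, shadow-feature relevance selection, Pearson-correlation
  pruning, seven base learners combined by a probability-averaging voting
  ensemble, evaluated by stratified 5-fold cross-validation (ACC/SE/SP and
  the Mann–Whitney AUC) — and mines **structural alerts**: fragments
  obtained by cutting the acyclic single bonds of each active molecule,
  scored by the likelihood ratio

  LR = (tp / P) / (fp / N),

  where *tp*/*fp* are the numbers of active/inactive compounds containing
  the fragment and *P*/*N* the class totals. A fragment never seen in an
  inactive has LR = ∞; alerts must pass minimum LR and minimum frequency
  thresholds (both default 10).

* **Herb level.** Each TCM's drug properties — nature, flavor and channel
  tropism — are encoded as a 24-bit vector. The package contrasts
  hepatoprotective and non-hepatoprotective herbs by chi-squared tests,
  mines property → hepatoprotection association rules with a
  consequent-constrained Apriori (support, confidence, lift = confidence /
  prior), builds bipartite herb–ingredient networks split into a
  *hepatoprotective* and an *undetermined* network, and screens: a herb is
  nominated when it **contains many hepatoprotective ingredients**
  (network degree ≥ 15) **and** **has hepatoprotective-like drug
  properties** (hierarchical-cluster branch shared with the
  hepatoprotective reference herbs).

A synthetic-data module generates desk-scale compound tables, herb tables
and edge lists with planted alerts, planted rule confidences and planted
network enrichment, so every stage is testable end to end with no database
access.

The intended users are computational pharmacologists and cheminformatics
researchers who want a reproducible, testable re-implementation of this
screening workflow for their own compound and herb collections.

## Worked example

```r
library(herbscreen)

spec <- synthetic_spec(seed = 42, n_active = 80, n_inactive = 40,
                       n_herbs = 200, separation = 1)
compounds <- generate_compounds(spec)
compound_counts(compounds)
#>       n n_active n_inactive n_rejected
#> 1   120       80         40          0

alerts <- mine_alerts(compounds, miner_config(min_lr = 10, min_freq = 10))
alerts
#>      id pattern n_heavy_atoms    tp    fp    lr precision_pct
#> 1     1 CF                  2    25     0   Inf           100
```

The planted trifluoromethyl motif comes back as the single alert: 25 of
the 80 actives carry it, no inactive does, so its likelihood ratio is
infinite and its precision 100%.

```r
herbs <- generate_herbs(spec)
edges <- generate_edges(spec, compounds, herbs)
report <- run_screen(edges, compounds$id[compounds$label == "active"],
                     herbs, screen_config())
report[, c("herb", "n_active_ingredients", "verdict", "screened")]
#>   herb    n_active_ingredients verdict               screened
#> 1 cand_09                   20 hepatoprotective-like TRUE
#> 2 cand_03                   18 hepatoprotective-like TRUE
#> ...
#> 8 cand_01                   15 hepatoprotective-like TRUE
```

Exactly the eight herbs planted with ≥ 15 active ingredients *and*
hepatoprotective-like property vectors pass both filters; herbs that are
ingredient-rich but property-dissimilar (or vice versa) are reported with
`screened = FALSE`, and herbs without channel-tropism information are
reported as unassessable rather than dropped.

The package also ships the published screening tables as curated example
data: `reference_screen_rules()` (five drug-property rules such as
{sour} ⇒ hepatoprotection with support 5.88%, confidence 71.43%, lift
1.48) and `reference_screen_candidates()` (the 26 ingredient-rich
candidate TCMs, of which 12 passed the drug-property filter).

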