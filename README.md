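# opswatch

Regulatory-status modelling and composite toxicity watch lists for
organophosphorus pesticides (OPs).

OPs are acetylcholinesterase-inhibiting agrochemicals whose management
status differs across jurisdictions (China: banned / restricted /
unrestricted; EPA and EU: essentially binary), and many unrestricted
compounds — and their environmental transformation products — remain
highly toxic. `opswatch` is a screening toolkit for environmental
chemists and risk assessors that

- trains and evaluates **multi-class regulatory-status models** on
  molecular-descriptor tables (eight algorithm families, stratified 7:3
  split, confusion-matrix metric suite with support-weighted averaging,
  external validation, and application tallying),
- reduces descriptor tables by **missing-value deletion, Pearson
  redundancy pruning** (greedy scan in descending-variance order, |r|
  threshold 0.95 by default) and **random-forest importance ranking**
  with min-max relative importance,
- collapses a 24-indicator toxicity panel (20 probability endpoints + 4
  eco-endpoints: BCF, IGC50, LC50DM, LC50FM) into a comprehensive
  toxicity score by **entropy weighting + TOPSIS**,

  e_j = −(1/ln n) Σ_i p_ij ln p_ij,  w_j = (1 − e_j) / Σ_k (1 − e_k),
  C_i = D⁻_i / (D⁺_i + D⁻_i),

  with orientation-aware min-max normalization so larger always means
  more toxic, and aggregates parent compounds with their transformation
  products, and
- bins the scores into a four-level **special-attention watch list** by
  mean-centered standard-deviation intervals of width 1.85 δ
  (population SD), labels Special Focus / Focus / General Focus /
  Secondary Focus.

A synthetic-data generator (`synthetic_config()` and friends) emulates
all inputs — class-conditional descriptor signal with correlated
redundant blocks and missing columns, heterogeneous Beta/log-normal
indicator panels with plantable toxic tails, and parent-correlated
transformation products — so the whole pipeline is testable offline.
Reference tables (the 79-molecule Chinese management list, a
78-descriptor importance ranking, 170 application predictions, and 54
composite toxicity scores with their published attention levels) ship
as plain-CSV fixtures.

## Worked example

Score the packaged 54 unrestricted-class compounds and rebuild the
watch list:

```r
library(opswatch)
fx <- load_paper_fixtures()
md <- compute_delta(fx$composite_toxicity$composite_toxicity)
# mean 0.4228, delta 0.0458  (population SD of the 54 composite scores)
wl <- assign_levels(setNames(fx$composite_toxicity$composite_toxicity,
                             fx$composite_toxicity$name))
head(wl, 4)
#>                name composite_toxicity  deviation   level
#> 1 Tetrachlorvinphos             0.5886 0.16582963 special
#> 2   Chlorfenvinphos             0.5080 0.08522963 special
#> 3         Propaphos             0.5037 0.08092963   focus
#> 4        Naftalofos             0.4994 0.07662963   focus
table(wl$level)
#>   special     focus   general secondary
#>         2        24        26         2
```

Tetrachlorvinphos and chlorfenvinphos sit more than 1.85 δ above the
mean composite toxicity and land on the Special Focus level; malathion
and phenthoate fall below −1.85 δ into Secondary Focus. The recomputed
levels agree with the published assignment for all 54 molecules.

The classification arm, on a synthetic descriptor table with the
default planted signal:

```r
cfg <- synthetic_config(seed = 1)         # 79 molecules, 17/8/54 classes
g <- generate_descriptors(cfg)
X <- drop_unusable_descriptors(g$descriptors)   # 200 -> 190 usable columns
kept <- pearson_prune(X, 0.95)                  # 190 -> 118 non-redundant
sp <- split_dataset(g$labels, 0.7, seed = 1)    # 55 train / 24 test
m <- train_classifier("rf", X[sp$train, kept], g$labels[sp$train], seed = 1)
evaluate(predict(m, X[sp$test, kept]), g$labels[sp$test], m$classes)
#>               true
#> predicted      banned restricted unrestricted
#>   banned            5          0            0
#>   restricted        0          3            0
#>   unrestricted      0          0           16
#> accuracy 1.0000 | precision 1.0000 | recall 1.0000 | F1 1.0000 (weighted)
```

`reproduce_paper()` re-runs every packaged-table check (tallies,
dispersion, binning agreement, relative-importance rescaling) and
prints a pass/fail report.

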