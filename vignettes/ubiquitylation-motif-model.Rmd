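---
title: "Predicting ubiquitylation sites from substrate motifs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ubiquitylation sites from substrate motifs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubimotif)
```

## The problem

Ubiquitylation attaches ubiquitin to a substrate lysine through the
E1–E2–E3 enzyme cascade. E3 ligases recognise their substrates partly
through the local sequence context of the modified lysine, so the residues
flanking a lysine carry signal about whether it can be conjugated. Given a
protein sequence, `ubimotif` scores every lysine for its propensity to be
ubiquitylated and reports the substrate motif class the site most
resembles.

The modelling unit is the *peptide window*: the $2n+1$ residues centred on
a candidate lysine, with $n = 6$ by default (a 13-mer). Positions that
fall outside the protein are filled with the padding symbol `-`, which the
encoders treat as a 21st "non-existing residue". Windows centred on
experimentally confirmed sites are positives; all other lysine-centred
windows are negatives.

## Dataset construction

Training sets assembled from modification databases are redundant:
near-identical fragments inflate apparent performance. The `dataset`
functions reproduce the standard filtering contracts at the window level:

* `reduce_homology()` — greedy incremental clustering in input order at a
  30 % identity threshold (the CD-HIT contract). Identity between two
  equal-length windows is the fraction of exactly matching positions,
  padding included; the first retained window a candidate matches absorbs
  it, otherwise the candidate founds a new cluster.
* `cross_filter_negatives()` — removes every negative with ≥ 50 %
  identity to any positive, because unannotated lysines homologous to
  known sites are likely unlabelled positives.
* `sample_negatives()` — draws negatives at 2.33 per positive, the class
  balance of the published non-homologous ubiquitylation compendium
  (12,663 negatives to 5,438 positives) whose counts ship in
  `inst/extdata/reference_counts.tsv`.

A deliberate simplification: the filters run on 13-mer windows, not whole
proteins. Full-protein profile-based clustering is out of scope at this
scale; for fixed-length windows the identity denominator equals the
window length, which coincides with CD-HIT's shorter-sequence convention.

## Feature encodings

Seven representations, all in $[0,1]$ (`encode_windows()` is the registry;
`concat:a+b` concatenates):

| encoder | dim (n = 6) | content |
|---|---|---|
| `binary20` | 260 | one-hot per position, alphabetical residue order; padding is all-zero |
| `aac` | 21 | residue composition incl. padding, sums to 1 |
| `aapc` | 441 | adjacent ordered dipeptide composition over 21×21, sums to 1 |
| `pwm` | 13 | per-position occurrence rate of the window's own residue among training positives |
| `pssm` | 400 | profile window collapsed to 20×20 by residue type, scaled by $1/(2n+1)$, squashed by $1/(1+e^{-x})$ |
| `sasa` | 13 | per-position solvent accessibility, percent / 100 |
| `ss` | 39 | orthogonal helix/sheet/coil coding `100`/`010`/`001` |

Choices the formats leave open, fixed here once: "amino-acid pairs" are
adjacent ordered dipeptides (so the pair count is $2n$ and the composition
sums to 1); the PWM encoding is the per-position lookup (13 values), not a
flattened matrix; profile rows for padded positions contribute zero scores,
which after the logistic map is the neutral value 0.5; the centre lysine's
profile row is included in the type sums; matrix row order is alphabetical
single-letter with `-` last wherever a 21st slot exists. Profile files are
read in the PSI-BLAST ASCII dialect and the declared column-header order is
trusted rather than assumed.

## Motif discovery by maximal dependence decomposition

Aligned positive windows are recursively partitioned by the
(position, residue-group) split whose presence indicator has the strongest
summed chi-square dependence on the same group's presence at the other
flank positions. The statistic for one pair of positions is the closed-form
2×2 chi-square without continuity correction,

$$\chi^2 = \frac{N(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)},$$

and a pair contributes to a candidate's score only when it exceeds the
1-df critical value at $\alpha = 0.01$ ($\chi^2 \ge 6.63$). The residue
groups are the five disjoint physicochemical classes aromatic (F, Y, W),
acidic+amide (D, E, N, Q), basic (K, R, H), nonpolar-aliphatic
(A, G, I, L, V, M, P) and polar (S, T, C); the padding symbol belongs to
none. A branch stops when it is smaller than `max_cluster_size`
(default $\lceil N/6 \rceil$, exposed as a knob since the value behind the
published 12-subgroup tree is not recoverable) or when no candidate is
significant. Leaves are labelled `Ub1..Ubk` depth-first, with-group branch
first; ties between equal scores break toward the smaller absolute
position, then upstream, then scheme order, making the partition fully
deterministic for a given input order.

Two numerical points deserve emphasis:

* **Enrichment admissibility.** The 2×2 chi-square is invariant under
  complementing the group indicator, so "group depleted at $p$" scores
  exactly as high as "group present at $q$" for an associated pair. Raw
  maximisation therefore happily splits on the *absence* of a class at a
  position neighbouring a real motif. Since a substrate motif is the
  conserved presence of a residue class, a candidate $(p, g)$ is admitted
  only when $g$'s occurrence rate at $p$ exceeds its average rate across
  the node's flank positions. With this condition the decomposition of a
  planted two-class mixture splits first on a planted (position, group)
  pair in 10/10 seeded runs.
* **Purity ceiling.** After conditioning on one constraint of a planted
  class, a second constraint from a *different* group is a lone marker:
  enriched marginally but no longer pairwise-dependent on anything, so the
  recursion cannot shave off the background windows that passed the first
  constraint by chance (about 8 % for aromatic, 20 % for acidic+amide
  under a natural composition). Leaf *precision* for such classes
  plateaus around 0.8–0.87; leaf *cohesion* (the fraction of the class
  gathered in one leaf) is the quantity the tests assert at ≥ 0.9.

`describe_subgroup()` renders each leaf as its constraint path (e.g.
`+2 in {F,Y,W} AND +3 in {D,E,N,Q}`) plus a column-stochastic
residues × positions frequency matrix suitable for logo rendering;
`write_partition_json()` serialises the split tree.

## The two-layered SVM

All classifiers are radial-kernel SVMs with Platt-style probability
estimates (LIBSVM via `e1071`). Layer one holds one SVM per motif
subgroup, trained on the subgroup's positives against
`round(size × 2.33)` negatives drawn without replacement from the negative
pool — disjointly across subgroups while the pool lasts, falling back to
independent resampling once exhausted. Subgroups smaller than 10 windows
are merged into their preceding sibling. Layer two is an SVM over the
$k$-vector of first-layer probability estimates, trained on all positives
plus the full negative pool; a site is called when its second-layer
probability reaches the threshold (default 0.5), and the reported motif is
the subgroup with the maximal first-layer estimate.

Default hyperparameters: cost 1; gamma follows the variance-scale
heuristic $1/(d \cdot \overline{\mathrm{Var}})$ of the training matrix
rather than the fixed $1/d$, which is much too smooth for sparse one-hot
features (at $d = 260$ and one-hot variance ≈ 0.05 the fixed rule yields
an almost-linear kernel). `grid_search()` performs the conventional
powers-of-two exploration of (cost, gamma) by stratified CV with
deterministic tie-breaks toward the smaller values.

The combiner is trained by default on resubstitution scores — the final
first layer applied to its own training windows, the reading suggested by
the two-layer architecture itself. An out-of-fold mode
(`combiner_scores = "out_of_fold"`) retrains the first layer on inner
folds so the combiner sees honestly calibrated scores; on the synthetic
benchmark it changed accuracy by less than half a point in either
direction, so the cheaper default stands.

## Evaluation

`metrics()` computes sensitivity, specificity, accuracy and the Matthews
correlation coefficient from the four confusion counts, with MCC defined
as 0 whenever a denominator factor vanishes. `kfold_cv()` is stratified,
holds out every sample exactly once, and pools held-out predictions into
one confusion matrix by default (stabler at small $n$; per-fold averaging
is available). `two_sample_logo()` compares position-specific residue
frequencies between two window sets with a two-proportion z-test (pooled
variance, no continuity correction), flagging enrichment or depletion at
$p < 0.01$ per cell — uncorrected, matching the convention of the original
two-sample logo tool; apply `p.adjust` to its `p` column for a
multiplicity-adjusted view. `match_site_predictions()` does the set
arithmetic of site-level case studies; the bundled DMA2 list reproduces
the published 90.0 % precision.

## The synthetic proteome generator

`generate_proteome()` emulates exactly the structure the method assumes:
sequences drawn i.i.d. from a Swiss-Prot-like background composition; one
or two lysines per protein labelled as modified; each labelled site
assigned a motif class whose (position, residue-set) constraints are
planted into the flanks with an emission probability, 0.9 by default —
high enough to be discoverable, low enough to model the real-world
degeneracy of E3 recognition. The three default classes (aromatic at +2
with acidic/amide at +3; acidic/amide at −4 and −3; aromatic at −1 and
+1) mirror the kinds of subgroups reported for real ubiquitylation data.
Profile, accessibility and secondary-structure streams are generated in
the same file dialects the readers consume: profiles as match-scored
log-odds with integer noise, accessibility as smoothed noise around 30 %
raised by 15 points near modified sites (mirroring the observed exposure
tendency of real sites), structure as a sticky three-state chain.

What the generator does **not** emulate: overlapping domain structure,
compositional heterogeneity along the sequence, correlated flanks beyond
the planted constraints, and evolutionary profiles that differ from the
observed sequence. Passing tests therefore demonstrate that the machinery
recovers the statistical structure it is designed for — not that the
bundled defaults reach any particular accuracy on real proteomes.

Problem sizes used in the checked examples, chosen to keep a full run in
minutes on one CPU: the recovery and ordering benchmarks use 400 proteins
of 80–160 residues (≈ 600 positive and ≈ 1400 sampled negative windows
after the 1:2.33 draw); unit tests use 10–150 proteins. At ≈ 220
positives the motif subgroups become too small for stable per-subgroup
SVMs and the two-layer model loses its edge over a single SVM — the
architecture pays off only when each motif subgroup retains enough
training windows, which is worth knowing before applying it to small
site collections. The end-to-end accuracy bound (two-layer CV ≥ 0.85) is
checked under fully penetrant (probability 1.0) classes, i.e. genuinely
well-separated mixtures; under the default 0.9 emission the Bayes ceiling
of the generator itself is ≈ 0.89 and seeded runs land at 0.81–0.86.

## Reproducibility

Every stochastic step — proteome generation, negative sampling, fold
assignment, SVM probability calibration — draws from R's RNG under an
explicit seed argument, and `e1071`'s LIBSVM binding uses R's RNG too, so
identical inputs, configuration and seed give byte-identical prediction
tables. The command-line layer writes a `run_config.json` with an MD5
hash of the full configuration into every output directory and embeds the
hash as a `#` comment line in its TSV artifacts.

## Known limitations

* Homology reduction operates on windows, not whole proteins (see above).
* The exact residue grouping, significance cutoff and maximum-cluster-size
  behind the published 12-subgroup decomposition are not recoverable, so
  only the qualitative tree structure is reproduced.
* Leaf precision for multi-group motif classes is bounded by the purity
  ceiling described above.
* With `combiner_scores = "resubstitution"` the second layer sees
  optimistic scores; the out-of-fold mode exists for users who prefer the
  unbiased variant.
* The PWM encoder conditions only on positives; windows dominated by
  padding receive systematically low PWM values at padded positions.
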