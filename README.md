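# ubimotif

Sequence-based prediction of ubiquitylation sites. Ubiquitin is conjugated
to substrate lysines by E3 ligases that partly recognise the local sequence
context of the modified residue. `ubimotif` models that context: it
extracts the 13-residue peptide window centred on every lysine, discovers
*substrate motifs* — position-specific residue-group patterns — among the
known sites by maximal dependence decomposition (MDD), and classifies
candidate sites with a two-layered support-vector machine whose first layer
holds one RBF-kernel SVM per motif subgroup and whose second layer fuses
the per-motif probability estimates.

The package is aimed at proteomics groups who have a collection of
experimentally mapped ubiquitylation sites (e.g. from mass-spectrometry
ubiquitinome studies) and want to (i) characterise the motif classes in it
and (ii) score new proteins for candidate sites.

## The method in brief

For a window set aligned on the central lysine (position 0, flanks −6…+6):

* **MDD motif discovery.** For a candidate split (position *p*, residue
  group *g*), the dependence score is
  Σ<sub>q≠p</sub> χ²(g at p, g at q), where each 2×2 chi-square
  N(ad−bc)²/((a+b)(c+d)(a+c)(b+d)) contributes only if it exceeds the
  1-df critical value at α = 0.01. The window set is recursively split on
  the admissible candidate with the maximal score into with-/without-group
  subsets until subgroups fall below `max_cluster_size`. Residue groups:
  aromatic {F,Y,W}, acidic+amide {D,E,N,Q}, basic {K,R,H},
  nonpolar-aliphatic {A,G,I,L,V,M,P}, polar {S,T,C}.
* **Two-layer SVM.** Per subgroup, an RBF SVM
  (K(S<sub>i</sub>,S<sub>j</sub>) = exp(−γ‖S<sub>i</sub>−S<sub>j</sub>‖²))
  is trained on the subgroup's positives against negatives sampled at
  1:2.33 — the class balance of the published non-homologous training
  compendium (12,663 : 5,438). The k per-motif probability estimates form
  the input vector of the second-layer SVM, whose probability is the final
  site score (call threshold 0.5).
* **Evaluation.** Sn = TP/(TP+FN), Sp = TN/(TN+FP),
  Acc = (TP+TN)/total, and MCC = (TP·TN − FN·FP)/√((TP+FN)(TN+FP)(TP+FP)(TN+FN)),
  via stratified five-fold cross-validation in which every window is held
  out exactly once.

Seven window encodings are provided (one-hot `binary20`, compositions
`aac`/`aapc`, `pwm`, profile-based `pssm`, structural `sasa`/`ss`, and
`concat:` hybrids), plus CD-HIT-style greedy homology reduction, a
two-sample position-specific enrichment test, and a synthetic proteome
generator with planted motifs that makes the whole pipeline testable
without external data. See the vignette
(`vignettes/ubiquitylation-motif-model.Rmd`) for the full methods account.

## Worked example

Generate a synthetic proteome with three planted motif classes, discover
the motifs, train the two-layer model and score a protein:

```r
library(ubimotif)

spec    <- synthetic_spec(n_proteins = 150L, seed = 7L)
gen     <- generate_proteome(spec)
windows <- extract_windows(gen$proteins, n = 6)
pos <- windows[windows$label == "positive", ]                 # 221 windows
neg <- sample_negatives(windows[windows$label == "negative", ],
                        nrow(pos), seed = 7)                  # 515 windows

part <- mdd_partition(pos)
part
#> <mdd_partition> 8 subgroup(s), 221 windows
#>   Ub1   n=9     +1 in {F,Y,W} AND -2 in {K,R,H}
#>   Ub2   n=29    +1 in {F,Y,W} AND -2 not in {K,R,H} AND +3 in {A,G,I,L,V,M,P}
#>   Ub3   n=40    +1 in {F,Y,W} AND -2 not in {K,R,H} AND +3 not in {A,G,I,L,V,M,P}
#>   Ub4   n=10    +1 not in {F,Y,W} AND -4 in {D,E,N,Q} AND +4 in {K,R,H}
#>   Ub5   n=65    +1 not in {F,Y,W} AND -4 in {D,E,N,Q} AND +4 not in {K,R,H}
#>   ...

model <- train_two_layer(pos, neg, encoder = "binary20",
                         partition = part, seed = 7)
predict(model, gen$proteins[[3]])[, c("position", "probability", "call", "motif")]
#>   position probability  call motif
#> 1        9    7.26e-07 FALSE   Ub2
#> 2       26    7.09e-01  TRUE   Ub8
#> 3       41    3.62e-07 FALSE   Ub4
#> 4       51    1.51e-07 FALSE   Ub5
#> 5       64    6.86e-07 FALSE   Ub4
gen$proteins[[3]]$ub_sites
#> [1] 26
```

The subgroup constraints read as motif definitions: `Ub5` collects windows
with an acidic/amide residue at −4 and no aromatic at +1, the planted
upstream-acidic class. On this protein the single annotated site
(position 26) is the only lysine called, with probability 0.71; the other
four lysines score near zero. Real-data workflows start from
`read_fasta()` + `read_site_annotations()` instead of the generator, and
`build_dataset()` applies the 30 %/50 % homology filters first.

A command-line interface covers the same pipeline
(`synth | dataset | motifs | train | predict | evaluate`):

```sh
Rscript inst/cli/ubimotif.R synth   --out fix --n-proteins 150 --seed 7
Rscript inst/cli/ubimotif.R dataset --fasta fix/proteins.fasta --sites fix/sites.tsv --out ds
Rscript inst/cli/ubimotif.R train   --positives ds/positives.tsv --negatives ds/negatives.tsv --out run
Rscript inst/cli/ubimotif.R predict --fasta fix/proteins.fasta --model run/model.rds --out preds
```

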