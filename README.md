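# barcodeval

Evaluation of DNA-barcoding markers by four species-discrimination
criteria, with genetic-diversity summaries and a coalescent simulator
for ground-truthed benchmarking.

## The problem

Universal chloroplast markers (intergenic spacers such as *psbA–trnH*
and *atpI–atpH*, coding regions such as *matK* and *ycf1*) are the
workhorses of plant DNA barcoding, but in species-rich, recently
diverged groups — oaks being the canonical example — low plastid
mutation rates, incomplete lineage sorting (ILS) and chloroplast
capture through hybridisation blur species boundaries. Whether a
marker panel actually discriminates species has to be measured, and
the answer depends on the criterion used. `barcodeval` implements the
four standard criteria side by side, scores each with the strict
all-individuals species-success rule, and runs them over **every
combination** of the loaded markers (4 markers → 15 datasets). It is
aimed at systematists and molecular ecologists designing or auditing
a barcoding study.

## What it computes

For aligned marker FASTA files plus a sample table
(`individual_id`, `species`, `section`, `region`):

- **Distances & gap statistics** — pairwise *p*-distance (proportion
  of differing sites among comparable sites, pairwise deletion of
  `-`/`N`); per species θ (mean intraspecific *p*-distance) and
  coalescent depth (maximum intraspecific *p*-distance); dataset
  means; the barcoding gap flag (`min inter > max intra`); and the
  Mann–Whitney rank-sum test `W` between the intra- and interspecific
  multisets (exact enumeration at small *n*, tie- and
  continuity-corrected normal approximation otherwise).
- **Distance-based delimitation** — automatic barcode-gap detection
  (first spacing of the sorted distinct distances exceeding 1.5× the
  local mean spacing, above a prior *P*), single-linkage grouping
  below the threshold with recursive refinement, scanned over a
  geometric prior series (0.001–0.1, 10 steps) with modal-partition
  selection. A species is delimited when its individuals form exactly
  one pure group.
- **Similarity-based identification** — leave-one-out nearest
  neighbour under *p*-distance; a species succeeds when every
  individual's tied best matches are all conspecific.
- **Tree-based identification** — strict monophyly of each species on
  a supplied Newick tree (or a neighbour-joining tree built from the
  combination's distances); outgroup rooting supported.
- **Diagnostic method** — greedy mining of species-specific
  (position, nucleotide) conjunctions on a stratified 80/20
  train/test split; a species succeeds when all its train *and* test
  individuals classify back to it uniquely. The individual-level
  identification rate is reported separately.
- **Diversity & ordination** — haplotype count `Hn` and diversity
  `Hd = N/(N−1)(1−Σf²)`, nucleotide diversity π, segregating sites,
  deduplicated indel events, per-species/per-section tables, and
  principal coordinates analysis (PCoA) of the distance matrix.
- **Synthetic truth sets** — a multispecies-coalescent simulator with
  Jukes–Cantor substitution, per-marker relative rates, indels, and
  introgression modelled as chloroplast capture (lineage re-homing),
  so every statistic above can be validated against known truth.

## Worked example

A simulated panel in the difficult regime (shallow species tree,
height 3 coalescent units; 10% chloroplast capture) mirrors the
situation the package is built to diagnose:

```r
library(barcodeval)
cfg <- sim_config(n_species = 12, individuals_per_species = 4,
                  height = 3, theta_w = 0.005, introgression_prob = 0.1,
                  seed = 101)
ts  <- simulate_barcode_data(cfg)
rep <- run_evaluation(ts$alignments, ts$samples, seed = 101)
rep
#> resolution_report: 15 combination(s) x 4 method(s), seed 101
#>                               abgd tophit  tree  blog
#> atpI-atpH                        0   8.33  8.33 25.00
#> matK                             0  16.67 16.67 16.67
#> psbA-trnH                        0  16.67  8.33 33.33
#> ycf1                             0   8.33  8.33 16.67
#> ...
#> atpI-atpH+matK+psbA-trnH         0  25.00  8.33 41.67
#> ...
best_combination(rep)[, c("combination", "method", "rate")]
#>                combination method     rate
#> 32           matK+psbA-trnH   blog 41.66667
#> 44 atpI-atpH+matK+psbA-trnH   blog 41.67
```

Each cell is the percentage of species resolved by that method on
that marker combination (denominators for excluded singleton species
are carried in `rep$table`). Low single-marker rates that improve
with combination, and the absence of a barcoding gap, reproduce the
qualitative behaviour of real plastid panels in hybridising groups:

```r
g <- rep$gaps[["psbA-trnH"]]$dataset
#> gap_present = FALSE, max intra = 0.0487, min inter = 0.0000
#> rank-sum W = 19960, p = 1.4e-11   (intra still significantly lower)

group_stats(ts$alignments[["psbA-trnH"]], ts$samples, group_by = "section")
#>             group  N Ns  S         Pi Hn        Hd indel_events
#> 1          Cerris 12  3 47 0.02637791  9 0.9545455            2
#> 2 Cyclobalanopsis 12  3 50 0.02916943  9 0.9545455            2
#> ...
```

With introgression removed and divergence deepened
(`introgression_prob = 0`, `height` ≫ 1), every method reaches 100%
on every combination — the benchmark the test suite enforces.

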