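---
title: "Methods: species discrimination criteria, diversity statistics and the coalescent benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species discrimination criteria, diversity statistics and the coalescent benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

# Scope and model

`barcodeval` measures how well a panel of aligned barcoding markers
discriminates species. All statistics are built on the *p*-distance
— the proportion of mismatches among comparable sites — because it is
model-free and is what barcoding practice reports. Sites carrying `-`
or `N` in either sequence of a pair are excluded (pairwise deletion);
a complete-deletion mode (drop a column for everyone if anyone has a
gap) is available for sensitivity checks. A pair left with zero
comparable sites has an *undefined* distance that propagates as
missing and is excluded from every summary; it is never coerced to 0.
*p*-distances are not metric and no code relies on the triangle
inequality.

Species-level success is deliberately strict for all four criteria: a
species counts as resolved only when **every** sampled individual
satisfies the criterion. This is the hardest defensible reading and
makes rates comparable across methods.

# The four criteria

## Distance summaries and the barcoding gap

Per species we report θ, the mean intraspecific *p*-distance, and the
coalescent depth, the maximum intraspecific *p*-distance. The dataset
summary reports both the pooled mean over all intraspecific pairs and
the unweighted mean of per-species θ values; the two differ under
unequal sampling, and averaging θ across species removes the bias a
heavily sampled species would otherwise exert. Singleton species have
no intraspecific pairs; they are flagged and excluded from the
θ/coalescent-depth averages.

The barcoding gap flag is the strict inequality
`min(inter) > max(intra)`. Because intra- and interspecific sets are
unpaired samples, their locations are compared with the two-sample
Mann–Whitney rank-sum statistic in first-sample orientation
(`W` = number of (intra, inter) pairs with intra > inter, plus half
the ties). For small samples (total ≤ 16 values) the p-value is
computed by exact enumeration of the conditional rank assignments —
the normal approximation is off by far more than the enumeration cost
at such sizes — and otherwise by the normal approximation with tie
correction and a 0.5 continuity correction. Paired histograms over
shared bin edges on `[0, max observed]` (20 bins by default; purely
descriptive) are emitted for plotting.

## Automatic barcode-gap delimitation

The delimiter scans the ascending list of pairwise distances for the
barcode gap and partitions by single linkage below it:

1. Ties are collapsed to distinct values; tied distances otherwise
   dilute the local spacing scale to zero and every spacing becomes
   "significant".
2. A spacing `g_j = v[j+1] − v[j]` is **significant** when it exceeds
   `x` (default 1.5) times the mean of the preceding `window`
   spacings (default `max(10, n_pairs/20)` ranks). The first spacing
   has no preceding scale and is judged against the *following*
   window instead — this is what detects the gap when every
   within-group comparison is identical (distance 0), a common case
   for conserved markers.
3. The prior `P` is the assumed maximum intraspecific divergence:
   only spacings whose upper endpoint exceeds `P` qualify, i.e. the
   resulting threshold always exceeds the prior.
4. The first significant spacing yields a threshold at its midpoint;
   individuals are grouped by single-linkage connectivity at
   distances strictly below it (missing distances are non-edges), and
   the search recurses inside each group on its sub-matrix until no
   further gap is found. No threshold at the top level means one
   all-inclusive group.
5. The scan repeats over a geometric series of priors (0.001–0.1 in
   10 steps, mirroring the common web-tool defaults) and the **modal**
   partition — the grouping that recurs for the most priors — is
   selected, with ties broken toward the larger prior. Very small
   priors typically over-split (they admit thresholds inside the
   intraspecific distribution) and very large priors lump (the
   threshold is pushed past the gap), so the modal rule favours the
   stable middle of the series; it is also configurable because no
   single published selection rule exists.

This detector is a documented simplification of the published
slope-based heuristic: the local-mean-spacing test keeps its
"gap relative to local scale" idea in a form whose behaviour on
planted data can be verified exactly. Partition scoring: a species is
delimited when its individuals form exactly one group containing no
other species.

## Leave-one-out top-hit identification

Database similarity search over pre-aligned sequences reduces to
nearest-neighbour under *p*-distance: for each query, every other
individual is a reference, and the best-match set is the argmin. The
hit is conspecific only when *all* tied best matches are conspecific;
a tie mixing conspecific and heterospecific references is ambiguous
and fails (the conservative reading). Whether the alignment-score
machinery of a local-alignment search engine would rank references
differently is deliberately out of scope — on a fixed alignment the
distance order is the defensible emulation. Singleton species cannot
have a conspecific hit and are excluded from the denominator by
default (a switch counts them as failures; both denominators are
reported).

## Tree monophyly

A species passes when some node's descendant tip set equals its tips
exactly; polytomies count, support values are ignored (the criterion
is topological), singletons are trivially monophyletic and reported
separately. Trees are consumed from Newick; Bayesian inference is out
of scope. For self-contained evaluation a neighbour-joining tree can
be built from each combination's distance matrix — a deliberate,
documented stand-in, not a claim of equivalence to model-based trees.

## Diagnostic nucleotides

For each species a conjunction of (position, nucleotide) literals is
grown greedily from the positions where all conspecific training
sequences agree on one of A/C/G/T (gap and N never become literals):
each step adds the literal excluding the most remaining
heterospecific training sequences, ties broken toward the leftmost
position, stopping at a perfect rule, at `L_max = 5` literals, or
when no literal helps. Classification requires a *unique* perfect-rule
match; zero or multiple matches are `unknown`. The split is stratified
80/20 with every species of ≥ 2 individuals represented on both
sides, and is a deterministic function of the seed. Species success
requires every train **and** test individual to classify correctly;
the individual-level rate is reported independently because neither
rate bounds the other (a dataset can have high individual accuracy
yet fail most species on a single stray individual, which is exactly
why the two numbers are kept apart).

# Diversity statistics and ordination

Haplotype collapsing, nucleotide diversity π and segregating sites
use complete deletion by default (columns containing `-` or `N`
anywhere in the group are dropped), the convention of standard
polymorphism software; π can also be computed under pairwise
deletion. `Hd = N/(N−1)(1−Σf²)`. Indel events are maximal `-` runs
deduplicated by their (start, end) interval across rows — the
simple-gap coding; overlapping but non-identical runs count
separately. Groups of one individual have undefined diversity fields
and are flagged rather than zero-filled. PCoA is classical metric
scaling (Gower double-centering of squared distances,
eigendecomposition, coordinates scaled by the square root of each
positive eigenvalue); explained fractions are taken over positive
eigenvalues and the negative-eigenvalue mass (the non-Euclidean part
of a *p*-distance matrix) is reported rather than hidden.

# The coalescent benchmark generator

The simulator provides data with known truth, structured like a real
multi-marker plastid panel:

- **Species tree**: ultrametric, of height `height` in coalescent
  units (one unit = the expected pairwise coalescence time within a
  population), either a rescaled pure-birth topology or a balanced
  tree with evenly spaced split levels.
- **Genealogies**: the multispecies coalescent — lineages coalesce at
  pairwise rate 1 within each species-tree branch and merge at
  speciation nodes. ILS arises naturally whenever within-species
  coalescence outlasts an internode.
- **θ~w~** is the expected pairwise intraspecific diversity per site
  at relative rate 1, which fixes the substitution rate at
  `mu = theta_w × rate / 2` per site per unit time. `expected_pi()`
  returns `theta_w × rate` per marker for parameter-recovery checks.
- **Sequences**: Jukes–Cantor along each genealogy. The evaluation
  statistics are model-free *p*-distances, so a richer substitution
  model would add parameters without adding test surface.
- **Introgression** is chloroplast capture: with probability `m` an
  individual's lineage starts in a random other species' population
  before coalescing. Because the plastid is one maternally inherited,
  non-recombining molecule, the re-homing flag is drawn once per
  individual and shared by all markers; genealogies are nevertheless
  drawn independently per marker, so marker-to-marker variation in
  lineage sorting resembles that of unlinked loci — a deliberate
  compromise that slightly *understates* between-marker correlation
  relative to a single shared plastid genealogy.
- **Indels** are overlaid per tip sequence as Poisson-many maximal
  gap runs with geometric lengths, giving the indel-event counter a
  known ground truth.
- The default marker panel (1187, 691, 554, 796 bp; relative rates
  0.46, 0.48, 2.07, 0.98) and the default regime (~40 species, 1–15
  individuals each, height 5, θ~w~ = 0.005) reproduce the structure
  of a typical evergreen-oak plastid dataset: shallow intraspecific
  variation, overlapping intra/interspecific distributions, no
  barcoding gap, partial resolution improving with marker
  combination.

What the generator does **not** emulate: recombination (none in
plastids), selection and demographic change, alignment error and
PCR/sequencing dropout, and rate heterogeneity along sequences.
Passing the benchmark therefore shows the *evaluation machinery* is
correct under the stated model, not that any real marker panel will
resolve real species.

# Benchmark regimes and their design

Three regimes drive the end-to-end checks (sizes chosen as
representative working points):

- **Ideal regime** (40 species × 5 individuals, balanced tree,
  `height = 6e5`, `theta_w = 1e-6`, no introgression, no indels):
  internodes of 1e5 coalescent units make lineage sorting complete,
  and species are effectively fixed. Every method should — and the
  test suite requires it to — report 100% resolution on all 15
  combinations, with the barcoding gap present for every marker. The
  extremity is intentional and principled: because interspecific
  structure depends on the product `theta_w × height`, the regime
  keeps that product fixed while driving residual within-species
  polymorphism toward zero. Two stochastic artefacts otherwise
  contaminate the benchmark at rates proportional to θ~w~: (a)
  *p*-distances are quantised in steps of 1/L, and a missing step in
  the intraspecific tail can mimic a gap for small priors (with
  near-zero θ~w~ the intraspecific distances occupy consecutive
  multiples of 1/L, a uniform spacing sequence the detector provably
  never flags); (b) a held-out individual polymorphic at another
  species' single diagnostic site can match two perfect rules and
  classify `unknown`.
- **Degradation regime** (15 species × 4 individuals, two markers,
  height 120, `m ∈ {0, 0.1, 0.2, 0.3}`, 20 replicates on matched
  seeds): mean top-hit and monophyly rates must be non-increasing in
  `m`. Matched seeds couple the introgression indicators across `m`
  levels (the same uniform draws), so the affected-species sets are
  nested in expectation and the trend is not noise-limited.
- **Recovery regime** (1 species × 50 individuals, 100 independent
  500-bp loci, `theta_w = 0.005`): the mean simulated π must sit
  within three standard errors of `expected_pi`.

# Numerical and degenerate-case choices

- Undefined distances: excluded everywhere, with logged counts; a
  sub-matrix with no defined distance at all yields singleton groups
  with a warning.
- Rank-sum test: degenerate when every value in both samples is
  identical (`W = n1·n2/2`, `p = 1`, flagged). Exact-path cutoff at
  total `n = 16` keeps enumeration under `combn(16, 8)` subsets.
- Delimitation: thresholds compare strictly (`distance < threshold`);
  re-running on a group with no internal gap returns it unchanged, so
  recursion terminates.
- Haplotype collapsing with every column excluded is flagged
  degenerate (one haplotype) rather than failing.
- Greedy literal search breaks ties toward the leftmost alignment
  position, making rule sets reproducible.
- All stochastic stages (splits, simulation) are driven by explicit
  seeds; the pipeline derives per-combination seeds from its single
  global seed, and reports contain no timestamps, so a rerun is
  byte-identical.
- Rates are percentages; report files print them to two decimals
  while in-memory objects keep full precision.

# Known limitations

- The gap detector is a simplification of the published recursive
  slope heuristic; on heavily overlapping distributions the modal
  partition can collapse to one group or fragment to haplotypes,
  which is informative (no usable gap) but not identical to the
  original tool's output at any single prior.
- Which single partition the original tool's users score is not
  standardised; the modal rule here is one documented, configurable
  choice.
- Nearest-neighbour identification ignores alignment-score
  subtleties of database search engines (e-values, local alignment).
- The neighbour-joining fallback is not a substitute for model-based
  phylogenetics; it exists so the monophyly criterion is testable
  without external tree inference.
- Per-marker independent genealogies overstate the independence of
  plastid markers; treat multi-marker ILS variation as an
  unlinked-locus approximation.
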