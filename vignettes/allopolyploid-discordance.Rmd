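---
title: "Detecting allopolyploid origins from gene-tree discordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allopolyploid origins from gene-tree discordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roucela)
```

## The question

A cryptic polyploid — a lineage that genomic data separate cleanly from
its relatives while morphology does not — can arise either by
autopolyploidy within one species or by allopolyploidy, hybridization
between two species followed by genome doubling. The two histories leave
different genomic signatures: under allopolyploidy, different loci of the
hybrid genuinely trace back to different parents, so gene trees split
into two camps in proportions set by the inheritance probability γ.
Incomplete lineage sorting (ILS) also makes gene trees disagree, but
symmetrically around a single species tree. This package implements the
chain of analyses that separates the two signals for a focal system of
six lineages: an outgroup, *drabifolia*, *simulans*, *creutzburgii*, the
tetraploid *erinus* (erinus4x) and the octoploid *erinus* (erinus8x),
with the octoploid hypothesized to be an allopolyploid of erinus4x and
creutzburgii.

## Model and units

All branch lengths on the species side are in coalescent units: k
lineages coalesce at rate `k(k-1)/2` per unit (time in units of 2N
generations). One coalescent unit of internal branch leaves roughly 25%
of quartets discordant; 0.5 units roughly 40%.

The species history is a level-1 network, represented by its two
displayed trees (`species_network()`): the *major* tree attaches the
hybrid to the parent-1 (erinus4x) side and is inherited with probability
`1 - gamma`; the *minor* tree attaches it to creutzburgii and carries
`gamma`. This convention — γ is the creutzburgii-side weight — is fixed
throughout. Each locus of the hybrid is assumed to trace exactly one
parental path. That matches the data reality the pipeline consumes (one
consensus sequence per locus per sample) but deliberately ignores
homoeologs: simulating both subgenomes of the polyploid and their
assembly collapse is out of scope, and the hybrid behaves as a
diploid-like lineage whose loci are a γ-mixture.

Expected quartet concordance factors (CFs) follow the standard result
that, with one sample per lineage, a quartet whose unrooted restriction
on the species tree has internal path length `t` resolves concordantly
with probability `1 - (2/3) exp(-t)` and each discordant way with
`(1/3) exp(-t)`; on the network the triple is the γ-weighted mixture over
the two displayed trees (`expected_quartet_cf()`). For quartets not
involving the hybrid the two displayed trees agree and the mixture
collapses to the tree formula.

## The synthetic generator: what it emulates

`simulate_gene_trees()` draws, per locus, the hybrid's parental path
(`Bernoulli(gamma)`) and then runs the exact multispecies coalescent on
the chosen displayed tree, branch by branch, with multiple individuals
per lineage entering at the tips. Defaults define the stated synthetic
world used by the `analysis/` scripts:

* **130 loci** — the size of a complete target-enrichment matrix after
  filtering in this kind of study.
* **γ = 0.534 on the creutzburgii side** — the working value for the
  focal system.
* **`scale = 1`**: every internal edge one coalescent unit. The
  empirical system publishes no branch lengths or effective sizes, so
  this is a free modelling choice, picked to give substantial but not
  overwhelming ILS (≈ 25% discordance per internal edge); it is a
  default, not an estimate.
* **2 individuals per lineage** — enough to exercise monophyly logic
  without inflating runtimes; real studies sample more.
* **Support model**: an internal edge of length ℓ receives support
  `100/B * Binomial(B, 1 - exp(-l/lambda))` with `B = 100` and
  `lambda = 0.5`. This is a stand-in, not a bootstrap: it reproduces the
  two features the relaxed binning relies on (short branches get low,
  noisy support; long branches saturate at 100) and nothing else. With
  `lambda = 0.5`, a one-coalescent-unit edge averages ≈ 86 support, so
  the BS < 80 collapse threshold bites realistically.
* **Alignments** (optional): Jukes–Cantor only, `subst_scale`
  substitutions/site per coalescent unit. No rate variation, indels, or
  model misspecification — alignments exist to let the FASTA route be
  exercised end to end, not to benchmark tree inference.
* **Bracts** (`simulate_bracts()`): log-normal bract lengths (median
  8 mm), tooth = bract × ratio with Gaussian ratios, means 0.08 for both
  *erinus* cytotypes and 0.24 for *creutzburgii* (sd 0.02/0.05),
  truncated to `(0, bract)`. The 3× separation makes the long-toothed
  relative diagnosable while the cytotypes differ only by sampling
  noise.

What the generator does **not** emulate — and what a green test therefore
does not establish: homoeolog mis-assembly, paralog leakage past the QC
filter, rogue taxa, alignment or tree-estimation error feeding into gene
trees (simulated topologies are known exactly), substitution saturation,
and any geographic structure within lineages. Tests green on this world
certify the statistical machinery, not robustness to those artifacts.

## Locus QC

`flag_paralogs()` flags a (locus, taxon) pair when the taxon has ≥ 2
contigs each covering ≥ 75% of the bait length; the pair then loses the
locus. The interpretation is per-taxon: the dataset-wide removal of a
locus emerges through `completeness_filter()`, which keeps only loci
present for every required taxon — the two stages together reproduce the
usual reduction to a complete no-missing-data matrix. Fractions above 1
are legal (contigs extending into introns) and compare against the
threshold like any other value. A second, tree-inspection-based paralog
screen used in practice is not automated here; the binning audit trail is
the place where such loci surface.

## Binning

Strict calls (`classify_strict()`) restrict the tree to the samples of
H, P1, P2, O, root on the outgroup, and require H and a parent to each be
monophyletic *and* sisters. Sisterhood (not mere reciprocal monophyly) is
deliberate: it matches how the competing topologies are stated, and the
weaker reading would only move trees from OTHER into T1/T2. When the
outgroup samples are not monophyletic the tree is rooted on the edge
above their common ancestor — deterministic, and flagged per tree in the
audit trail.

Relaxed calls (`classify_relaxed()`) operationalize the manual judgment
"this weakly supported tree approximates topology X": collapse branches
with support `< 80` on the full tree (so supports keep their original
clade meaning), restrict, then resolve every one-sample-per-lineage
quartet (h, p1, p2, o) and take the strict majority between `h,p1|p2,o`
and `h,p2|p1,o`. Ties and all-unresolved trees are UNASSIGNED — never
arbitrarily assigned — which preserves mutual exclusivity of the reported
bins. Combinatorially large quartet sets are subsampled to 500 under a
fixed seed. The threshold (80), cap (500) and seed are all arguments.

Collapse itself (`collapse_low_support()`) contracts an edge when its
child node's support is present and below the threshold; unlabelled
edges are kept. Contraction preserves root-to-tip path lengths (child
edges absorb the contracted length), so quartet internal lengths stay
meaningful on collapsed trees.

## Concordance factors and the network fit

Observed CFs are **gene-tree frequencies**, not Bayesian concordance
factors: `quartet_cf_table()` lets each gene vote for its majority
resolution of each 4-lineage set (abstaining on ties), and
`clade_cf()` counts monophyly over informative trees. When gene trees
come from a Bayesian concordance analysis instead, numerical CFs will
differ; the package's fit consumes either, but its own estimates are
frequency-based by construction.

`fit_network()` maximizes the multinomial pseudolikelihood
`sum_q n_eff,q * sum_k cf_obs * log cf_exp` treating quartets as
independent (the standard pseudolikelihood simplification; no correction
for shared genes across quartets). Numerical choices:

* γ is optimized on the logit scale (bounded ±16) for stability and
  reported on [0, 1]; internal lengths are box-constrained to [0, 20] —
  beyond ~10 coalescent units CFs are numerically saturated anyway.
* Expected CFs are floored at 1e-12 inside logarithms.
* Because the candidate's edge lengths are linear in its parameters, the
  internal path length of every quartet is precomputed once as an affine
  map `t_q = c0 + a·t`; the optimizer then never touches tree
  structures. A test verifies this vectorized route agrees with the
  direct per-quartet computation to 1e-8.
* `L-BFGS-B` from 10 seeded random restarts; the best restart is
  reported with all convergence codes.

Identifiability caveat: with a single outgroup lineage, the root edge
length never lies on any quartet's internal path, so `t_root` is not
identifiable from quartet CFs and its estimate is meaningless noise; γ
and the other internal lengths are identified, and the self-consistency
test pins γ to 1e-3. Network *search* is intentionally absent: candidates
are user-supplied (`roucela_candidate()` being the default), because
the scientific question here is a fixed hypothesis test (tree vs
one-hybrid network via `compare_models()`), not topology discovery.
Pseudolikelihood values are comparable only within this package's scale —
only differences on the same CF table are interpreted, never absolute
values against other software.

One orientation quirk of this kind of data is worth stating: relaxed bin
frequencies and the fitted γ need not point the same way, because the bin
majority is a per-tree vote while γ weights quartet frequencies; the fit,
not the raw bin frequency, is the γ estimator.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → qc → bin → cf → fit → morph under a
single root seed split deterministically per stage; reruns with the same
configuration are byte-identical (timestamps are simply never written).
The configuration is an R list (`pipeline_config()`) serialized to
JSON in the report — YAML was dropped as a format since it would add a
dependency without adding structure.

## Morphology

`corrected_tooth()` divides bract-tooth length by total bract length,
removing plant- and bract-age effects; `lineage_comparison()` reports
per-lineage summaries, per-lineage regressions of raw tooth on bract
length, and two contrasts on the corrected ratio — tetraploid vs
octoploid (crypsis) and creutzburgii vs pooled erinus (diagnosability) —
each with Cohen's d and a Wilcoxon rank-sum p-value. The rank-sum test
is descriptive support, chosen for being distribution-free; no formal
delimitation test is implied. Bract area is read and stored but not
analysed. Both the ratio and d are scale-invariant, which the tests
assert.

## Known limitations

* The hybrid is one lineage with γ-mixed loci; homoeolog-aware analysis
  of polyploid subgenomes is out of scope.
* Gene trees are consumed as given; estimation error in empirical trees
  enters the CFs unmodelled (the relaxed binning's support collapse is
  the only concession).
* Only one hybrid node is supported, and only on user-supplied
  candidates.
* The simulator's substitution model is Jukes–Cantor only.
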