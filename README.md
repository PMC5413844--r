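# roucela

Gene-tree discordance and coalescent network analysis of allopolyploid
origins, built around the Mediterranean *Campanula* (Roucela) species
complex: a widespread annual harbouring a cryptic octoploid lineage that
genomic data separate cleanly from the tetraploid, while bract morphology
does not. The package implements the analysis chain used to ask whether
such a cryptic polyploid arose by allopolyploidy — hybridization between
two named parental lineages followed by genome doubling — from a
target-enrichment set of per-locus gene trees.

## Who this is for

Systematists with (i) a set of newick gene trees carrying bootstrap
supports, (ii) a sample-to-lineage table, and (iii) a concrete
hybridization hypothesis (hybrid H, candidate parents P1 and P2, outgroup
O), who want reproducible, scriptable versions of the usual manual steps:
locus QC, topology binning, concordance factors, and a fixed-network
inheritance-probability fit. A full synthetic generator means every stage
can also be exercised, and is tested, without any external data.

## The model

Gene trees disagree with the species history for two reasons this package
separates: incomplete lineage sorting (ILS) and hybridization. Under the
multispecies coalescent, a species-tree branch of length `t` in coalescent
units (k lineages coalesce at rate `k(k-1)/2`) leaves a 4-lineage set
resolved concordantly with probability

    CF_major = 1 - (2/3) exp(-t),   CF_minor = (1/3) exp(-t)  (each)

where `t` is the internal path length of the unrooted quartet. On a
level-1 network whose hybrid tip traces its parent-2 edge with inheritance
probability γ (gamma), the expected quartet concordance factors are the
γ-weighted mixture of the two displayed trees' CF triples. Observed CFs
are estimated as gene-tree frequencies; γ and the internal branch lengths
are then estimated by maximizing the multinomial pseudolikelihood

    sum_quartets n_eff * sum_k cf_obs,k * log cf_exp,k(γ, t)

over γ in [0,1] (logit-parameterized) and t in [0, 20], from multiple
seeded restarts, for the one-hybrid candidate and its γ = 0 tree
reduction. ILS alone cannot produce an asymmetric excess of the two
hybrid-adjacent resolutions; a pseudolikelihood gain with γ away from the
boundary is the allopolyploidy signal. Binning mirrors the classical
manual read of the same data: strict calls require monophyly and
sisterhood of H with one parent; relaxed calls first collapse branches
with bootstrap support below 80 and then take the quartet-majority vote.

## Worked example

The `analysis/` scripts run the whole chain on a synthetic 130-locus
dataset generated from the default six-lineage network (γ = 0.534 on the
creutzburgii side, every internal edge one coalescent unit, two
individuals per lineage):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc.R
Rscript analysis/03_binning.R
Rscript analysis/04_network.R
Rscript analysis/05_morphology.R
```

Stage 3 prints the topology bins:

```
Gene-tree bins over 130 trees (H = erinus8x, P1 = erinus4x, P2 = creutzburgii)
  strict : T1 33 (25.4%)  T2 45 (34.6%)  OTHER 52 (40.0%)
  relaxed (BS < 80 collapsed): T1 43 (33.1%)  T2 67 (51.5%)  unassigned 20 (15.4%)
```

— a majority of loci fall in neither strict class (ILS plus weak support),
but after collapsing weak branches nearly every tree approximates one of
the two candidate topologies, split close to the generating γ. Stage 4
fits the network:

```
Network pseudolikelihood fit (roucela_h1)
  gamma_hat = 0.6076
  pseudo-loglik = -1335.5825 (best of 10 restarts)
Tree vs one-hybrid network: hybrid edge supported (delta pseudo-loglik = 474.925, gamma_hat = 0.608)
```

so with 130 loci the creutzburgii-side inheritance probability is
recovered at 0.61 (truth 0.534; at this locus count the sampling error on
γ̂ is of order 0.1), and the one-hybrid network clearly beats the best
tree. Stage 5 prints the morphology report: corrected bract-tooth ratios
separate creutzburgii from both cytotypes (Cohen's d = 4.4, rank-sum
p ≈ 3e-23) while the two cytotypes remain indistinguishable (|d| = 0.32,
p = 0.10) — the cryptic-lineage pattern.

## Acceptance script

`scripts/acceptance.R` reruns the same end-to-end synthetic pipeline
(simulate → qc → bin → cf → fit → morph) against the installed package
under a caller-supplied seed and writes the acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — the package: simulator (`simulate_gene_trees()`,
  `attach_support()`, `simulate_alignment()`, `simulate_bracts()`), QC
  (`flag_paralogs()`, `completeness_filter()`), binning
  (`bin_gene_trees()`), concordance (`clade_cf()`, `quartet_cf_table()`),
  network fitting (`expected_quartet_cf()`, `fit_network()`,
  `compare_models()`), morphology (`lineage_comparison()`), and the
  orchestrating `run_pipeline()`.
- `analysis/` — the numbered narrative drivers shown above; outputs land
  under `results/`.
- `vignettes/allopolyploid-discordance.Rmd` — the methods vignette:
  model, assumptions, parameter choices, limitations.
- `inst/extdata/locus_assembly_synthetic.tsv` — small synthetic assembly
  summary with planted paralogs and missing cells for the QC stage.
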