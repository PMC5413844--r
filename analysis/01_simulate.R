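#!/usr/bin/env Rscript
# Stage 1: generate the synthetic Roucela-complex dataset.
#
# The generating world: six lineages with the octoploid (erinus8x) an
# allopolyploid between the tetraploid erinus and creutzburgii, inheritance
# probability gamma = 0.534 on the creutzburgii side, every internal edge
# one coalescent unit, two sampled individuals per lineage, 130 loci (the
# size of a complete target-enrichment matrix after filtering), bootstrap
# supports from the binomial length model, and 50 bract specimens per
# lineage with indistinguishable cytotypes.

suppressPackageStartupMessages(library(roucela))

seed <- 2026L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

net <- default_roucela_network(gamma = 0.534, scale = 1)
print(net)

cfg <- sim_config(n_genes = 130, samples_per_lineage = 2, seed = seed)
trees <- attach_support(simulate_gene_trees(net, cfg), cfg)
write_gene_trees(trees, file.path(out, "gene_trees.nwk"))
write_lineage_map(attr(trees, "lineage_map"),
                  file.path(out, "lineages.tsv"))
cat(sprintf("wrote %d gene trees (%d followed the creutzburgii path)\n",
            length(trees),
            sum(attr(trees, "parental_paths") == "minor")))

# one example alignment, to show the end-to-end FASTA route
aln <- simulate_alignment(trees[[1]], cfg)
write_alignment(aln, file.path(out, "locus001.fasta"))

bracts <- simulate_bracts(50, seed = seed + 1L)
write.table(bracts, file.path(out, "bracts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("wrote %d bract specimens\n", nrow(bracts)))
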