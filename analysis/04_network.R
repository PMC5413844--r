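#!/usr/bin/env Rscript
# Stage 4: concordance factors and the tree-vs-network pseudolikelihood fit.
#
# Clade CFs give the fraction of the genome supporting each candidate
# sister relationship of the octoploid; the quartet CF table feeds the
# coalescent network model, which estimates the inheritance probability
# gamma of the creutzburgii parent edge. A clear pseudolikelihood gain of
# the one-hybrid network over the best tree, with gamma away from 0/1, is
# the allopolyploidy signal.

suppressPackageStartupMessages(library(roucela))

out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

trees <- read_gene_trees("results/synthetic/gene_trees.nwk")
map <- read_lineage_map("results/synthetic/lineages.tsv")
samples_of <- function(lin) map$sample_id[map$lineage == lin]

cf_t2 <- clade_cf(trees, c(samples_of("erinus8x"),
                           samples_of("creutzburgii")))
cf_t1 <- clade_cf(trees, c(samples_of("erinus8x"), samples_of("erinus4x")))
print(cf_t2)
print(cf_t1)

cf_tab <- quartet_cf_table(trees, map, sort(unique(map$lineage)), seed = 7)
write_quartet_cf(cf_tab, file.path(out, "quartet_cf.tsv"))

fit_tree <- fit_network(cf_tab, gamma_fixed = 0, seed = 7)
fit_h1 <- fit_network(cf_tab, seed = 7)
print(fit_h1)
cmp <- compare_models(fit_tree, fit_h1)
print(cmp)

jsonlite::write_json(
  list(clade_cf_creutzburgii_side = cf_t2$cf,
       clade_cf_tetraploid_side = cf_t1$cf,
       gamma_hat = fit_h1$gamma_hat, t_hat = as.list(fit_h1$t_hat),
       loglik_h1 = fit_h1$loglik, loglik_tree = fit_tree$loglik,
       delta = cmp$delta, verdict = cmp$verdict),
  file.path(out, "fit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
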