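test_that("clade CFs are monophyly frequencies over informative trees", {
  trees <- list(
    ape::read.tree(text = "(((a,b),c),d);"),
    ape::read.tree(text = "(((a,c),b),d);"),
    ape::read.tree(text = "((a,b),(c,d));"),
    ape::read.tree(text = "(((a,b),d),c);"),
    ape::read.tree(text = "(((a,d),b),c);")
  )
  res <- clade_cf(trees, c("a", "b"))
  expect_equal(res$cf, 3 / 5)
  expect_identical(res$n_informative, 5L)
  expect_error(clade_cf(trees, character(0)), "clade")
  # degenerate: clade covering all taxa is uninformative
  expect_error(clade_cf(trees, c("a", "b", "c", "d")), "uninformative")
})

test_that("clade CF equals an independent per-tree monophyly scan", {
  set.seed(55)
  trees <- lapply(1:50, function(i) ape::rtree(8))
  clade <- c("t1", "t2", "t3")
  res <- clade_cf(trees, clade)
  oracle <- mean(vapply(trees, function(tr) {
    ape::is.monophyletic(tr, clade)
  }, logical(1)))
  expect_equal(res$cf, oracle)
})

test_that("observed quartet CFs normalize and recover unanimity", {
  map <- data.frame(sample_id = c("A_1", "B_1", "C_1", "D_1"),
                    lineage = c("A", "B", "C", "D"))
  tr <- ape::read.tree(text = "((A_1,B_1),(C_1,D_1));")
  tab <- quartet_cf_table(rep(list(tr), 10), map, c("A", "B", "C", "D"))
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$cf12_34, 1)
  expect_equal(tab$cf13_24 + tab$cf14_23, 0)
  expect_identical(tab$n_eff, 10L)
  expect_error(quartet_cf_table(list(tr), map, c("A", "B", "C", "E")), "E")
})

test_that("every observed CF triple sums to one on simulated data", {
  net <- default_roucela_network(gamma = 0.4, scale = 0.8)
  trees <- simulate_gene_trees(net, sim_config(n_genes = 200, seed = 6))
  map <- attr(trees, "lineage_map")
  tab <- quartet_cf_table(trees, map, sort(unique(map$lineage)))
  expect_identical(nrow(tab), 15L)
  sums <- tab$cf12_34 + tab$cf13_24 + tab$cf14_23
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("observed CFs equal exhaustive per-gene quartet counting", {
  set.seed(77)
  lineages <- c("A", "B", "C", "D")
  # two samples per lineage so the per-gene majority vote is exercised
  samples <- paste0(rep(lineages, each = 2), "_", 1:2)
  map <- data.frame(sample_id = samples,
                    lineage = rep(lineages, each = 2))
  trees <- lapply(1:200, function(i) {
    tr <- ape::rtree(8)
    tr$tip.label <- sample(samples)
    tr
  })
  tab <- quartet_cf_table(trees, map, lineages)
  votes <- c(0L, 0L, 0L)
  for (tr in trees) {
    tly <- c(0L, 0L, 0L)
    for (a in c("A_1", "A_2")) for (b in c("B_1", "B_2"))
      for (cc in c("C_1", "C_2")) for (d in c("D_1", "D_2")) {
        k <- oracle_quartet(tr, a, b, cc, d)
        if (k > 0L) tly[k] <- tly[k] + 1L
      }
    if (max(tly) > 0L && sum(tly == max(tly)) == 1L) {
      votes[which.max(tly)] <- votes[which.max(tly)] + 1L
    }
  }
  expect_identical(tab$n_eff, sum(votes))
  expect_equal(as.numeric(tab[1, c("cf12_34", "cf13_24", "cf14_23")]),
               votes / sum(votes))
})

test_that("expected quartet CFs follow the coalescent closed form", {
  net <- as_network(quartet_species_tree(1))
  cf <- expected_quartet_cf(net, c("a", "b", "c", "o"))
  expect_equal(unname(cf[1]), 1 - (2 / 3) * exp(-1))
  expect_equal(unname(cf[2]), exp(-1) / 3)
  expect_equal(sum(cf), 1)
  # t = 0: uniform; t large: degenerate
  cf0 <- expected_quartet_cf(as_network(quartet_species_tree(0)),
                             c("a", "b", "c", "o"))
  expect_equal(unname(cf0), rep(1 / 3, 3))
  cf50 <- expected_quartet_cf(as_network(quartet_species_tree(50)),
                              c("a", "b", "c", "o"))
  expect_equal(unname(cf50), c(1, 0, 0), tolerance = 1e-12)
  expect_error(expected_quartet_cf(net, c("a", "b", "c", "zz")), "zz")
})

test_that("hybrid quartets mix the two displayed trees by gamma", {
  major <- ape::read.tree(text = "(((h:1,p1:1):1,p2:2):1,o:3);")
  minor <- ape::read.tree(text = "(((h:1,p2:1):1,p1:2):1,o:3);")
  net <- species_network(major, minor, gamma = 0.5, hybrid = "h",
                        parents = c("p1", "p2"))
  cf <- expected_quartet_cf(net, c("h", "p1", "p2", "o"))
  # sorted quartet (h, o, p1, p2): h+p1 is 13|24, h+p2 is 14|23
  maj <- 1 - (2 / 3) * exp(-1)
  min_ <- exp(-1) / 3
  expect_equal(unname(cf["cf13_24"]), 0.5 * maj + 0.5 * min_)
  expect_equal(unname(cf["cf14_23"]), 0.5 * maj + 0.5 * min_)
  expect_equal(unname(cf["cf12_34"]), min_)
  expect_equal(unname(round(cf, 4)), c(0.1226, 0.4387, 0.4387))
  # gamma at the boundary reduces to the pure displayed tree
  net0 <- species_network(major, minor, gamma = 0, hybrid = "h",
                          parents = c("p1", "p2"))
  cfM <- expected_quartet_cf(net0, c("h", "p1", "p2", "o"))
  expect_equal(unname(cfM), c(min_, maj, min_))
})

test_that("pseudolikelihood matches hand arithmetic and is linear in n_eff", {
  net <- as_network(quartet_species_tree(1))
  tab <- data.frame(l1 = "a", l2 = "b", l3 = "c", l4 = "o",
                    cf12_34 = 1, cf13_24 = 0, cf14_23 = 0, n_eff = 100)
  pll <- network_pseudolik(net, tab)
  expect_equal(pll, 100 * log(1 - (2 / 3) * exp(-1)))
  tab2 <- tab
  tab2$n_eff <- 200
  expect_equal(network_pseudolik(net, tab2), 2 * pll)
})

test_that("the generating parameters maximize the pseudolikelihood", {
  # Gibbs: with cf_obs = cf_exp, any other (gamma, scale) scores lower
  truth <- default_roucela_network(gamma = 0.3, scale = 1)
  tab <- expected_cf_table(truth, n_eff = 100)
  at_truth <- network_pseudolik(truth, tab)
  for (g in c(0, 0.1, 0.6, 0.9)) {
    expect_lt(network_pseudolik(default_roucela_network(g, 1), tab),
              at_truth)
  }
  expect_lt(network_pseudolik(default_roucela_network(0.3, 2), tab),
            at_truth)
})

test_that("fitting an exact expected-CF table recovers gamma precisely", {
  tab <- expected_cf_table(default_roucela_network(gamma = 0.3, scale = 1),
                           n_eff = 1000)
  fit <- fit_network(tab, seed = 2)
  expect_lt(abs(fit$gamma_hat - 0.3), 1e-3)
  expect_true(fit$converged)
  # identifiable internal lengths recovered too
  expect_lt(abs(fit$t_hat[["t_attach"]] - 1), 0.01)
  expect_lt(abs(fit$t_hat[["t_clade"]] - 1), 0.01)
})

test_that("a tree-generated table drives gamma to the boundary", {
  tab <- expected_cf_table(default_roucela_network(gamma = 0, scale = 1),
                           n_eff = 500)
  fit <- fit_network(tab, seed = 4)
  expect_lt(fit$gamma_hat, 0.02)
})

test_that("the hybrid fit nests the tree fit", {
  tab <- expected_cf_table(default_roucela_network(gamma = 0.5, scale = 0.8),
                           n_eff = 300)
  fit_tree <- fit_network(tab, gamma_fixed = 0, seed = 6)
  fit_fixed <- fit_network(tab, gamma_fixed = 0, seed = 6)
  expect_identical(fit_fixed$loglik, fit_tree$loglik)
  # the optimizer's vectorized objective agrees with the per-quartet
  # expected-CF route at the optimum
  pll <- network_pseudolik(fit_tree$network, tab)
  expect_equal(pll, fit_tree$loglik, tolerance = 1e-8)
  fit_h1 <- fit_network(tab, seed = 6)
  cmp <- compare_models(fit_tree, fit_h1)
  expect_gte(cmp$delta, 0)
  expect_true(cmp$hybrid_supported)
  tab_other <- expected_cf_table(default_roucela_network(0.2, 1),
                                 n_eff = 300)
  fit_other <- fit_network(tab_other, seed = 6)
  expect_error(compare_models(fit_tree, fit_other), "different cf_tables")
})

test_that("gamma is recovered from simulated gene trees", {
  net <- default_roucela_network(gamma = 0.3, scale = 1)
  trees <- simulate_gene_trees(net, sim_config(n_genes = 3000, seed = 15))
  map <- attr(trees, "lineage_map")
  tab <- quartet_cf_table(trees, map, sort(unique(map$lineage)))
  fit <- fit_network(tab, seed = 15)
  expect_lt(abs(fit$gamma_hat - 0.3), 0.05)
})
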