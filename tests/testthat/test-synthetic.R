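test_that("default network validates gamma and stores the hybrid weights", {
  expect_error(default_roucela_network(gamma = 1.2), "gamma")
  expect_error(default_roucela_network(gamma = 0.5, scale = -1), "scale")
  net <- default_roucela_network(gamma = 0.534, scale = 1)
  expect_s3_class(net, "species_network")
  expect_equal(net$gamma, 0.534)
  expect_setequal(net$tips,
                  c("outgroup", "drabifolia", "erinus4x", "simulans",
                    "creutzburgii", "erinus8x"))
  w <- displayed_trees(net)$weights
  expect_equal(unname(w), c(1 - 0.534, 0.534))
})

test_that("degenerate gamma pins the hybrid to one parental path", {
  net0 <- default_roucela_network(gamma = 0, scale = 1)
  tr <- simulate_gene_trees(net0, sim_config(n_genes = 50, seed = 3))
  expect_true(all(attr(tr, "parental_paths") == "major"))
  net1 <- default_roucela_network(gamma = 1, scale = 1)
  tr1 <- simulate_gene_trees(net1, sim_config(n_genes = 50, seed = 3))
  expect_true(all(attr(tr1, "parental_paths") == "minor"))
})

test_that("parental paths at gamma = 0.5 are a fair coin over 10,000 draws", {
  net <- default_roucela_network(gamma = 0.5, scale = 1)
  tr <- simulate_gene_trees(net, sim_config(n_genes = 10000, seed = 17))
  n_minor <- sum(attr(tr, "parental_paths") == "minor")
  # within 4 binomial standard deviations of 5,000 (sd = 50)
  expect_lt(abs(n_minor - 5000), 200)
})

test_that("simulator returns the requested number of rooted gene trees", {
  net <- default_roucela_network(gamma = 0.5, scale = 1)
  trees <- simulate_gene_trees(net, sim_config(n_genes = 130, seed = 1))
  expect_length(trees, 130)
  expect_true(all(vapply(trees, ape::is.rooted, logical(1))))
  expect_true(all(vapply(trees, function(t) ape::is.binary(t), logical(1))))
  map <- attr(trees, "lineage_map")
  expect_setequal(trees[[1]]$tip.label, map$sample_id)
})

test_that("identical seeds give byte-identical newick output", {
  net <- default_roucela_network(gamma = 0.3, scale = 1)
  cfg <- sim_config(n_genes = 25, samples_per_lineage = 2, seed = 99)
  t1 <- attach_support(simulate_gene_trees(net, cfg), cfg)
  t2 <- attach_support(simulate_gene_trees(net, cfg), cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_gene_trees(t1, f1)
  write_gene_trees(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("empirical quartet frequencies match the coalescent closed form", {
  # 3-binomial-SE band around 1 - (2/3) exp(-t) for several internal lengths
  for (t in c(0.5, 1, 2)) {
    net <- as_network(quartet_species_tree(t))
    n <- 4000
    trees <- simulate_gene_trees(net, sim_config(n_genes = n,
                                                 seed = 300 + 10 * t))
    hit <- vapply(trees, function(tr) {
      pkg_quartet(tr, "a_1", "b_1", "c_1", "o_1") == 1L
    }, logical(1))
    p <- msc_major_prob(t)
    expect_lt(abs(mean(hit) - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("hybrid quartet resolutions are symmetric at gamma = 0.5", {
  net <- default_roucela_network(gamma = 0.5, scale = 1)
  n <- 4000
  trees <- simulate_gene_trees(net, sim_config(n_genes = n, seed = 23))
  res <- vapply(trees, function(tr) {
    pkg_quartet(tr, "erinus8x_1", "erinus4x_1", "creutzburgii_1",
                "outgroup_1")
  }, integer(1))
  f1 <- mean(res == 1L)  # hybrid with parent 1
  f2 <- mean(res == 2L)  # hybrid with parent 2
  expect_lt(abs(f1 - f2), 3 * sqrt(0.5 / n))
})

test_that("support model hits its binomial mean and its limits", {
  # one internal edge of length 0.1; lambda = 0.1 gives mean 100(1 - e^-1)
  base <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,c:0.2);")
  trees <- rep(list(base), 3000)
  cfg <- sim_config(n_genes = 1, lambda = 0.1, seed = 5)
  sup <- vapply(attach_support(trees, cfg), function(tr) {
    as.numeric(tr$node.label[2])
  }, numeric(1))
  expect_lt(abs(mean(sup) - 100 * (1 - exp(-1))), 1)

  zero <- ape::read.tree(text = "((a:1,b:1):0,c:1);")
  s0 <- attach_support(list(zero), cfg)[[1]]
  expect_identical(as.numeric(s0$node.label[2]), 0)

  long <- ape::read.tree(text = "((a:1,b:1):5,c:6);")
  sl <- attach_support(list(long), cfg)[[1]]  # l/lambda = 50: saturated
  expect_identical(as.numeric(sl$node.label[2]), 100)

  nolen <- ape::read.tree(text = "((a,b),c);")
  expect_error(attach_support(list(nolen), cfg), "tree 1")
})

test_that("Jukes-Cantor alignments have the expected divergence", {
  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  cfg <- sim_config(n_genes = 1, subst_scale = 1, n_sites = 10000, seed = 8)
  aln <- simulate_alignment(tr, cfg)
  expect_identical(dim(aln), c(2L, 10000L))
  p_diff <- mean(aln["a", ] != aln["b", ])
  expect_lt(abs(p_diff - 0.75 * (1 - exp(-4 * 0.3 / 3))), 0.01)

  cfg0 <- sim_config(n_genes = 1, subst_scale = 0, n_sites = 100, seed = 8)
  aln0 <- simulate_alignment(tr, cfg0)
  expect_identical(aln0["a", ], aln0["b", ])
  expect_error(sim_config(n_genes = 1, n_sites = 0), "n_sites")
})

test_that("bract simulator shapes the cryptic vs diagnosable contrast", {
  expect_error(simulate_bracts(0), "n_per_lineage")
  b <- simulate_bracts(100, seed = 12)
  expect_s3_class(b, "bract_records")
  expect_identical(nrow(b), 300L)
  expect_true(all(b$tooth_length_mm < b$bract_length_mm))
  rep <- lineage_comparison(b)
  d <- rep$contrasts
  expect_lt(abs(d$d[d$contrast == "erinus_4x_vs_8x"]), 0.2)
  expect_gt(abs(d$d[d$contrast == "creutzburgii_vs_erinus"]), 1)
})
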