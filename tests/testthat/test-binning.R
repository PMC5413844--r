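test_that("newick round-trips preserve supports and counts", {
  f <- tempfile(fileext = ".nwk")
  writeLines("((a,b)95,(c,d)80);", f)
  trees <- read_gene_trees(f)
  expect_length(trees, 1)
  expect_setequal(node_supports(trees[[1]]), c(NA, 95, 80))

  many <- rep("((a,b)100,(c,d)100);", 130)
  writeLines(many, f)
  trees <- read_gene_trees(f)
  expect_length(trees, 130)
  write_gene_trees(trees, f)
  expect_identical(readLines(f), many)
  expect_error(read_gene_trees(tempfile()), "no such")
})

test_that("low-support collapse contracts exactly the weak branches", {
  tr <- ape::read.tree(text = "(((a,b)50,c)90,(d,e)85);")
  expect_identical(ape::write.tree(collapse_low_support(tr, 80)),
                   "((a,b,c)90,(d,e)85);")
  # all strong: unchanged; all weak: star
  strong <- ape::read.tree(text = "(((a,b)100,c)100,(d,e)100);")
  expect_identical(ape::write.tree(collapse_low_support(strong, 80)),
                   ape::write.tree(strong))
  weak <- ape::read.tree(text = "(((a,b)10,c)10,(d,e)10);")
  expect_identical(collapse_low_support(weak, 80)$Nnode, 1L)
  # unlabelled edges are kept
  part <- ape::read.tree(text = "(((a,b),c)40,(d,e));")
  expect_identical(ape::write.tree(collapse_low_support(part, 80)),
                   "(c,(a,b),(d,e));")  # same multifurcation, rotated
  expect_error(collapse_low_support(tr, 150), "threshold")
})

test_that("collapse agrees with phangorn's pruneTree on labelled trees", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  for (i in 1:25) {
    tr <- ape::rtree(10)
    tr$node.label <- c("", as.character(sample(0:100, tr$Nnode - 1,
                                               replace = TRUE)))
    ours <- collapse_low_support(tr, 80)
    theirs <- phangorn::pruneTree(tr, 80)
    expect_true(ape::dist.topo(ape::unroot(ours),
                               ape::unroot(theirs)) == 0)
  }
})

test_that("collapse is monotone in the threshold", {
  set.seed(31)
  tr <- ape::rtree(15)
  tr$node.label <- c("", as.character(sample(0:100, tr$Nnode - 1,
                                             replace = TRUE)))
  sizes <- vapply(c(0, 30, 60, 90, 100), function(th) {
    collapse_low_support(tr, th)$Nnode
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("strict classification hits the three reference cases", {
  map <- toy_map()
  hyp <- toy_hyp()
  t1 <- ape::read.tree(text = "(((h1,h2),(p1a,p1b)),((p2a,p2b),(o1,o2)));")
  expect_identical(as.character(classify_strict(t1, hyp, map)), "T1")
  t2 <- ape::read.tree(text = "((((h1,h2),p2a),(p1a,p1b)),(o1,o2));")
  expect_identical(as.character(classify_strict(t2, hyp, map)), "T2")
  other <- ape::read.tree(text = "((((h1,p1a),p1b),(h2,p2a)),(o1,o2));")
  expect_identical(as.character(classify_strict(other, hyp, map)), "OTHER")
  # missing lineage is an error naming it
  nop2 <- ape::read.tree(text = "(((h1,h2),(p1a,p1b)),(o1,o2));")
  expect_error(classify_strict(nop2, hyp, map), "P2")
})

test_that("strict calls ignore sample labels within a lineage", {
  map <- toy_map()
  hyp <- toy_hyp()
  t1 <- ape::read.tree(text = "(((h1,h2),(p1a,p1b)),((p2a,p2b),(o1,o2)));")
  swapped <- t1
  swapped$tip.label[match(c("p1a", "p1b"), swapped$tip.label)] <-
    c("p1b", "p1a")
  expect_identical(as.character(classify_strict(t1, hyp, map)),
                   as.character(classify_strict(swapped, hyp, map)))
})

test_that("relaxed classification follows the quartet majority", {
  map <- toy_map()
  hyp <- toy_hyp()
  # fully resolved strict-T1 tree: relaxed refines strict
  t1 <- ape::read.tree(text = "(((h1,h2)100,(p1a,p1b)100)100,((p2a,p2b)100,(o1,o2)100)100);")
  r <- classify_relaxed(t1, hyp, map)
  expect_identical(as.character(r), "T1")
  # star after collapse: unassigned
  weak <- ape::read.tree(text = "(((h1,h2)10,(p1a,p1b)10)10,((p2a,p2b)10,(o1,o2)10)10);")
  expect_identical(as.character(classify_relaxed(weak, hyp, map)),
                   "UNASSIGNED")
  # mixed trees: the call must follow the exhaustive keep.tip oracle's
  # quartet majority, including the tie -> UNASSIGNED rule
  mixes <- c(
    "((((h1,p1a)100,p1b)100,((h2,p2a)100,p2b)100)100,(o1,o2)100);",
    "((((h1,h2)100,(p1a,p1b)100)100,(p2a,p2b)100)100,(o1,o2)100);",
    "(((h1,(h2,p2a)100)100,((p1a,p1b)100,p2b)100)100,(o1,o2)100);"
  )
  for (nwk in mixes) {
    mix <- ape::read.tree(text = nwk)
    rm <- classify_relaxed(mix, hyp, map)
    oracle <- c(0L, 0L, 0L, 0L)
    for (h in c("h1", "h2")) for (p1 in c("p1a", "p1b"))
      for (p2 in c("p2a", "p2b")) for (o in c("o1", "o2")) {
        k <- oracle_quartet(mix, h, p1, p2, o)
        oracle[if (k == 0L) 4L else k] <- oracle[if (k == 0L) 4L else k] + 1L
      }
    expect_identical(unname(attr(rm, "tally")), oracle)
    want <- if (oracle[1] > oracle[2]) "T1"
            else if (oracle[2] > oracle[1]) "T2" else "UNASSIGNED"
    expect_identical(as.character(rm), want)
  }
})

test_that("quartet classifier equals the exhaustive oracle on random trees", {
  set.seed(101)
  for (i in 1:100) {
    tr <- ape::rtree(12)
    tips <- sample(tr$tip.label, 4)
    expect_identical(pkg_quartet(tr, tips[1], tips[2], tips[3], tips[4]),
                     oracle_quartet(tr, tips[1], tips[2], tips[3], tips[4]))
  }
})

test_that("binning conserves counts and reports an audit trail", {
  map <- toy_map()
  hyp <- toy_hyp()
  t1 <- ape::read.tree(text = "(((h1,h2),(p1a,p1b)),((p2a,p2b),(o1,o2)));")
  bins <- bin_gene_trees(rep(list(t1), 10), hyp, map)
  expect_identical(unname(bins$strict), c(10L, 0L, 0L))
  expect_identical(unname(bins$strict_freq), c(1, 0, 0))
  expect_identical(sum(bins$strict), bins$n_trees)
  expect_identical(sum(bins$relaxed), bins$n_trees)
  expect_identical(nrow(bins$audit), 10L)
  expect_true(all(bins$audit$strict == "T1"))
})

test_that("strict T2 dominates when gamma = 1 with long branches", {
  net <- default_roucela_network(gamma = 1, scale = 10)
  trees <- simulate_gene_trees(net, sim_config(n_genes = 100, seed = 2))
  map <- attr(trees, "lineage_map")
  hyp <- hypothesis_spec("erinus8x", "erinus4x", "creutzburgii", "outgroup")
  bins <- bin_gene_trees(trees, hyp, map)
  expect_identical(unname(bins$strict["T1"]), 0L)
  expect_gt(bins$strict_freq["T2"], 0.95)
})
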