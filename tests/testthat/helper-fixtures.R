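# shared fixtures and independent oracles

# four-lineage species tree with one internal edge of length `t` between the
# (a,b) cherry and the rest; used for closed-form coalescent checks
quartet_species_tree <- function(t = 1) {
  ape::read.tree(text = sprintf("(((a:1,b:1):%g,c:%g):1,o:%g);",
                                t, 1 + t, 2 + t))
}

# wrap a plain species tree as a degenerate one-hybrid network (gamma = 0)
as_network <- function(phy) {
  species_network(phy, phy, gamma = 0, hybrid = phy$tip.label[1],
                  parents = phy$tip.label[c(2, 2)])
}

# closed-form MSC probability that a quartet with internal length t is
# concordant with the species tree
msc_major_prob <- function(t) 1 - (2 / 3) * exp(-t)

# independent quartet oracle: restrict with keep.tip and compare the
# unrooted restriction against the three reference quartet topologies by
# Robinson-Foulds distance (ape::dist.topo); no shared code with the
# package's mrca-walk classifier
oracle_quartet <- function(tree, a, b, c, d) {
  tips <- c(a, b, c, d)
  sub <- ape::unroot(ape::keep.tip(tree, tips))
  sub$edge.length <- NULL
  refs <- c(
    sprintf("((%s,%s),%s,%s);", a, b, c, d),
    sprintf("((%s,%s),%s,%s);", a, c, b, d),
    sprintf("((%s,%s),%s,%s);", a, d, b, c)
  )
  for (k in 1:3) {
    ref <- ape::unroot(ape::read.tree(text = refs[k]))
    if (ape::dist.topo(sub, ref) == 0) return(k)
  }
  0L
}

# package-side quartet resolution by tip label, via the exported audit path
pkg_quartet <- function(tree, a, b, c, d) {
  par <- roucela:::parent_vec(tree)
  dep <- roucela:::depth_vec(tree, par)
  i <- match(c(a, b, c, d), tree$tip.label)
  roucela:::quartet_resolution(par, dep, i[1], i[2], i[3], i[4])
}

# toy lineage map for hand-built binning trees
toy_map <- function() {
  data.frame(
    sample_id = c("h1", "h2", "p1a", "p1b", "p2a", "p2b", "o1", "o2"),
    lineage = c("H", "H", "P1", "P1", "P2", "P2", "O", "O"),
    stringsAsFactors = FALSE
  )
}

toy_hyp <- function(threshold = 80) {
  hypothesis_spec("H", "P1", "P2", "O", support_threshold = threshold)
}

qc_fixture_path <- function() {
  system.file("extdata", "locus_assembly_synthetic.tsv", package = "roucela")
}
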