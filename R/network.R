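#' Build a level-1 species network from its two displayed trees
#'
#' A level-1 network with a single hybrid node is represented by the two
#' rooted trees it displays: the `major` tree, in which the hybrid tip is
#' attached to the parent-1 side (inherited with probability `1 - gamma`),
#' and the `minor` tree, in which it is attached to the parent-2 side
#' (probability `gamma`). Both trees carry branch lengths in coalescent
#' units (k lineages coalesce at rate k(k-1)/2 per unit).
#'
#' @param major,minor rooted `phylo` objects on the same tip set, with
#'   non-negative branch lengths.
#' @param gamma inheritance probability of the `minor` (parent-2) path,
#'   in `[0, 1]`.
#' @param hybrid tip label of the hybrid lineage.
#' @param parents character vector of length 2: the parent-1 and parent-2
#'   lineage labels (the lineages whose edges the hybrid attaches to in
#'   `major` and `minor` respectively).
#' @return an object of class `species_network`.
#' @seealso [default_roucela_network()]
#' @export
species_network <- function(major, minor, gamma, hybrid, parents) {
  if (!is_prob(gamma)) abort("gamma must be a single value in [0, 1], got %s",
                             format(gamma)[1])
  for (nm in c("major", "minor")) {
    phy <- if (nm == "major") major else minor
    if (!inherits(phy, "phylo")) abort("%s must be a 'phylo' object", nm)
    if (!ape::is.rooted(phy)) abort("%s displayed tree must be rooted", nm)
    if (is.null(phy$edge.length) || any(phy$edge.length < 0)) {
      abort("%s displayed tree must have non-negative branch lengths", nm)
    }
    if (anyDuplicated(phy$tip.label)) abort("tip labels must be unique")
  }
  if (!setequal(major$tip.label, minor$tip.label)) {
    abort("displayed trees must share one tip set")
  }
  if (!hybrid %in% major$tip.label) abort("hybrid '%s' is not a tip", hybrid)
  if (length(parents) != 2L || !all(parents %in% major$tip.label)) {
    abort("parents must name two tips of the network")
  }
  structure(
    list(major = major, minor = minor, gamma = gamma,
         hybrid = hybrid, parents = parents,
         tips = sort(major$tip.label)),
    class = "species_network"
  )
}

#' @export
print.species_network <- function(x, ...) {
  cat("Level-1 species network (", length(x$tips), " lineages)\n", sep = "")
  cat("  hybrid:", x$hybrid, "\n")
  cat(sprintf("  parent edges: %s (1 - gamma = %.4g), %s (gamma = %.4g)\n",
              x$parents[1], 1 - x$gamma, x$parents[2], x$gamma))
  cat("  major displayed tree:",
      ape::write.tree(ape::compute.brlen(x$major, 1)), "\n")
  invisible(x)
}

#' Displayed trees of a species network
#'
#' @param network a [species_network()].
#' @return a list with elements `major` and `minor` (`phylo` objects) and
#'   their inheritance weights.
#' @export
displayed_trees <- function(network) {
  stopifnot(inherits(network, "species_network"))
  list(major = network$major, minor = network$minor,
       weights = c(major = 1 - network$gamma, minor = network$gamma))
}

# lineage names of the default Roucela-complex network
roucela_lineages <- function() {
  c("outgroup", "drabifolia", "erinus4x", "simulans", "creutzburgii",
    "erinus8x")
}

#' Default six-lineage hybridization network for the Roucela complex
#'
#' The backbone is `(outgroup,((drabifolia,erinus4x),(simulans,creutzburgii)))`
#' and the octoploid lineage `erinus8x` is a hybrid whose two parent edges
#' attach to the `erinus4x` and `creutzburgii` terminal edges with weights
#' `1 - gamma` and `gamma`. The network is ultrametric with the hybrid
#' attachment points at height `scale`, the two ingroup cherries at
#' `2 * scale`, the ingroup root at `3 * scale` and the root at `4 * scale`,
#' so every internal edge has length `scale` (coalescent units).
#'
#' @param gamma inheritance probability of the `creutzburgii` parent edge.
#' @param scale internal edge length in coalescent units; small values mean
#'   much incomplete lineage sorting, large values almost none.
#' @return a [species_network()].
#' @examples
#' net <- default_roucela_network(gamma = 0.534, scale = 1)
#' displayed_trees(net)$weights
#' @export
default_roucela_network <- function(gamma = 0.534, scale = 1) {
  if (!is_prob(gamma)) abort("gamma must be in [0, 1], got %s",
                             format(gamma)[1])
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    abort("scale must be a single positive number")
  }
  s <- scale
  build_roucela_heights(gamma, a = s, h2 = 2 * s, h3 = 3 * s, h4 = 4 * s)
}

# Roucela network from node heights (coalescent units above the tips):
# hybrid attachment points at `a`, ingroup cherries at `h2`, ingroup root at
# `h3`, root at `h4`; requires 0 < a <= h2 <= h3 <= h4
build_roucela_heights <- function(gamma, a, h2, h3, h4) {
  if (!(a > 0 && a <= h2 && h2 <= h3 && h3 <= h4)) {
    abort("heights must satisfy 0 < a <= h2 <= h3 <= h4")
  }
  fmt <- function(x) format(x, digits = 15)
  major <- sprintf(
    "(outgroup:%s,((drabifolia:%s,(erinus4x:%s,erinus8x:%s):%s):%s,(simulans:%s,creutzburgii:%s):%s):%s);",
    fmt(h4), fmt(h2), fmt(a), fmt(a), fmt(h2 - a), fmt(h3 - h2), fmt(h2),
    fmt(h2), fmt(h3 - h2), fmt(h4 - h3))
  minor <- sprintf(
    "(outgroup:%s,((drabifolia:%s,erinus4x:%s):%s,(simulans:%s,(creutzburgii:%s,erinus8x:%s):%s):%s):%s);",
    fmt(h4), fmt(h2), fmt(h2), fmt(h3 - h2), fmt(h2), fmt(a), fmt(a),
    fmt(h2 - a), fmt(h3 - h2), fmt(h4 - h3))
  species_network(
    major = ape::read.tree(text = major),
    minor = ape::read.tree(text = minor),
    gamma = gamma,
    hybrid = "erinus8x",
    parents = c("erinus4x", "creutzburgii")
  )
}
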