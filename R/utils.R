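# internal helpers shared across modules

# stop without the call, sprintf-style
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# run `code` under a temporary seed when `seed` is non-NULL, leaving the
# caller's RNG stream untouched; with seed = NULL the current stream is used
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# parent lookup vector (0 for root) from a phylo edge matrix
parent_vec <- function(phy) {
  n_all <- length(phy$tip.label) + phy$Nnode
  par <- integer(n_all)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

# topological node depths (root = 0) from a parent vector
depth_vec <- function(phy, par = parent_vec(phy)) {
  n_all <- length(par)
  dep <- integer(n_all)
  eo <- reorder_preorder(phy)
  for (i in seq_len(nrow(eo))) dep[eo[i, 2L]] <- dep[eo[i, 1L]] + 1L
  dep
}

# cumulative edge-length depths (root = 0); NULL when tree has no lengths
depthlen_vec <- function(phy, par = parent_vec(phy)) {
  if (is.null(phy$edge.length)) return(NULL)
  n_all <- length(par)
  dep <- numeric(n_all)
  eo <- reorder_preorder(phy, lengths = TRUE)
  for (i in seq_len(nrow(eo$edge))) {
    dep[eo$edge[i, 2L]] <- dep[eo$edge[i, 1L]] + eo$len[i]
  }
  dep
}

# edge matrix in an order where parents precede children
reorder_preorder <- function(phy, lengths = FALSE) {
  ph <- ape::reorder.phylo(phy, "cladewise")
  if (lengths) list(edge = ph$edge, len = ph$edge.length) else ph$edge
}

# most recent common ancestor of two nodes via upward walks
mrca2 <- function(par, dep, a, b) {
  while (dep[a] > dep[b]) a <- par[a]
  while (dep[b] > dep[a]) b <- par[b]
  while (a != b) {
    a <- par[a]
    b <- par[b]
  }
  a
}

# Resolution of the quartet (a, b, c, d) embedded in a tree given by parent
# and depth vectors. Returns 1 for ab|cd, 2 for ac|bd, 3 for ad|bc, 0 when
# the restricted quartet is unresolved (polytomy). The pairing whose two
# pair-MRCAs have the strictly greatest total depth is the induced unrooted
# quartet; ties mean the four paths meet in a single node.
quartet_resolution <- function(par, dep, a, b, c, d) {
  s1 <- dep[mrca2(par, dep, a, b)] + dep[mrca2(par, dep, c, d)]
  s2 <- dep[mrca2(par, dep, a, c)] + dep[mrca2(par, dep, b, d)]
  s3 <- dep[mrca2(par, dep, a, d)] + dep[mrca2(par, dep, b, c)]
  s <- c(s1, s2, s3)
  top <- max(s)
  if (sum(s == top) > 1L) 0L else which.max(s)
}

# number of tips descending from each node
n_desc_tips <- function(phy, par = parent_vec(phy)) {
  n <- length(phy$tip.label)
  n_all <- n + phy$Nnode
  cnt <- integer(n_all)
  cnt[seq_len(n)] <- 1L
  eo <- reorder_preorder(phy)
  for (i in rev(seq_len(nrow(eo)))) {
    cnt[eo[i, 1L]] <- cnt[eo[i, 1L]] + cnt[eo[i, 2L]]
  }
  cnt
}
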