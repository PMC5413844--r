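# gene-tree utilities: supports, low-support collapse, quartet machinery

#' Numeric support values of a gene tree's internal nodes
#'
#' @param tree a `phylo`; supports are expected as internal node labels on
#'   the 0-100 bootstrap scale (RAxML dialect). Missing or non-numeric
#'   labels give `NA`.
#' @return numeric vector of length `tree$Nnode` (node `Ntip + i` at
#'   position `i`).
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Collapse weakly supported branches into polytomies
#'
#' Every internal edge whose child node carries a support value below
#' `threshold` is contracted: the node's children are reattached to its
#' parent, with branch lengths accumulated so root-to-tip path lengths are
#' preserved. Edges without a support value, and supports at or above the
#' threshold, are left alone; the leaf set never changes. This mirrors the
#' usual practice of treating branches with bootstrap support below 80 as
#' unresolved before interpreting gene-tree conflict.
#'
#' @param tree a `phylo` with supports as internal node labels.
#' @param threshold support threshold in `[0, 100]`; strictly smaller
#'   supports are collapsed.
#' @return the collapsed `phylo` (possibly multifurcating).
#' @examples
#' tr <- ape::read.tree(text = "(((a,b)50,c)90,(d,e)85);")
#' ape::write.tree(collapse_low_support(tr, 80))
#' @export
collapse_low_support <- function(tree, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 100) {
    abort("threshold must be a single value in [0, 100]")
  }
  s <- node_supports(tree)
  n <- length(tree$tip.label)
  root <- n + 1L
  drop <- n + which(!is.na(s) & s < threshold)
  drop <- setdiff(drop, root)
  if (length(drop) == 0L) return(tree)
  par <- parent_vec(tree)
  dl <- depthlen_vec(tree, par)
  has_len <- !is.null(dl)
  labs <- if (is.null(tree$node.label)) rep("", tree$Nnode) else tree$node.label
  dropped <- logical(n + tree$Nnode)
  dropped[drop] <- TRUE
  # children after contraction: each surviving non-root node hangs from its
  # nearest non-dropped ancestor
  kids <- vector("list", n + tree$Nnode)
  for (v in seq_len(n + tree$Nnode)) {
    if (v == root || dropped[v]) next
    p <- par[v]
    while (dropped[p]) p <- par[p]
    kids[[p]] <- c(kids[[p]], v)
  }
  render <- function(v) {
    if (v <= n) {
      tree$tip.label[v]
    } else {
      inner <- paste(vapply(kids[[v]], render_child, character(1)),
                     collapse = ",")
      paste0("(", inner, ")", labs[v - n])
    }
  }
  render_child <- function(v) {
    body <- render(v)
    if (has_len) {
      p <- par[v]
      while (dropped[p]) p <- par[p]
      paste0(body, ":", format(dl[v] - dl[p], digits = 15))
    } else {
      body
    }
  }
  ape::read.tree(text = paste0(render(root), ";"))
}

# index tips by label; errors on absent labels
tip_index <- function(tree, labels) {
  idx <- match(labels, tree$tip.label)
  if (anyNA(idx)) {
    abort("samples not in tree: %s",
          paste(labels[is.na(idx)], collapse = ", "))
  }
  idx
}

# is `tips` (integer indices) a clade of the rooted tree?
is_clade <- function(tree, tips, par = parent_vec(tree),
                     dep = depth_vec(tree, par),
                     ndesc = n_desc_tips(tree, par)) {
  if (length(tips) <= 1L) return(TRUE)
  m <- tips[1L]
  for (t in tips[-1L]) m <- mrca2(par, dep, m, t)
  ndesc[m] == length(tips)
}
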