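#' Hybridization hypothesis for gene-tree binning
#'
#' Names the hybrid lineage (H), its two candidate parents (P1, P2) and the
#' outgroup (O), plus the bootstrap threshold below which branches are
#' treated as unresolved in the relaxed classification.
#'
#' @param hybrid,parent1,parent2,outgroup four distinct lineage ids.
#' @param support_threshold bootstrap threshold in `[0, 100]`; default 80.
#' @return a list of class `hypothesis_spec`.
#' @export
hypothesis_spec <- function(hybrid, parent1, parent2, outgroup,
                            support_threshold = 80) {
  lin <- c(hybrid, parent1, parent2, outgroup)
  if (length(lin) != 4L || anyDuplicated(lin)) {
    abort("hybrid, parent1, parent2, outgroup must be four distinct lineages")
  }
  if (!is.numeric(support_threshold) || support_threshold < 0 ||
      support_threshold > 100) {
    abort("support_threshold must be in [0, 100]")
  }
  structure(list(hybrid = hybrid, parent1 = parent1, parent2 = parent2,
                 outgroup = outgroup,
                 support_threshold = support_threshold),
            class = "hypothesis_spec")
}

# samples of each hypothesis lineage present in the tree; errors when a
# lineage has no sample in the tree
hyp_samples <- function(tree, hyp, map) {
  lookup <- setNames(map$lineage, map$sample_id)
  roles <- c(H = hyp$hybrid, P1 = hyp$parent1, P2 = hyp$parent2,
             O = hyp$outgroup)
  out <- lapply(roles, function(lin) {
    s <- tree$tip.label[lookup[tree$tip.label] %in% lin]
    s[!is.na(s)]
  })
  empty <- names(roles)[vapply(out, length, integer(1)) == 0L]
  if (length(empty)) {
    abort("no samples of lineage(s) %s in tree",
          paste(roles[empty], collapse = ", "))
  }
  out
}

# restrict to the hypothesis samples and root on the outgroup; returns the
# rooted tree plus a flag for outgroup monophyly
restrict_and_root <- function(tree, samples) {
  keep <- unlist(samples, use.names = FALSE)
  sub <- ape::keep.tip(tree, keep)
  o <- samples$O
  o_mono <- length(o) == 1L || ape::is.monophyletic(sub, o)
  sub <- if (o_mono) {
    ape::root(sub, outgroup = o, resolve.root = TRUE)
  } else {
    # root on the edge above the outgroup samples' common ancestor
    m <- ape::getMRCA(sub, o)
    if (m == length(sub$tip.label) + 1L) sub else
      ape::root(sub, node = m, resolve.root = TRUE)
  }
  list(tree = sub, outgroup_monophyletic = o_mono)
}

#' Strict topology classification of one gene tree
#'
#' The tree is restricted to the samples of the four hypothesis lineages and
#' rooted on the outgroup (on the edge above the outgroup samples' common
#' ancestor when they are not monophyletic). The call is `T1` when the
#' hybrid's and parent-1's samples are each monophyletic and sister to each
#' other, `T2` for hybrid plus parent-2, and `OTHER` otherwise. `T1` and
#' `T2` are mutually exclusive.
#'
#' @param tree a `phylo` containing at least one sample of each lineage.
#' @param hyp a [hypothesis_spec()].
#' @param map lineage map data.frame (`sample_id`, `lineage`).
#' @return `"T1"`, `"T2"` or `"OTHER"`, with attribute
#'   `outgroup_monophyletic`.
#' @export
classify_strict <- function(tree, hyp, map) {
  samples <- hyp_samples(tree, hyp, map)
  rr <- restrict_and_root(tree, samples)
  sub <- rr$tree
  par <- parent_vec(sub)
  dep <- depth_vec(sub, par)
  ndesc <- n_desc_tips(sub, par)
  idx <- lapply(samples, function(s) tip_index(sub, s))
  mono <- function(tips) is_clade(sub, tips, par, dep, ndesc)
  call <- "OTHER"
  if (mono(idx$H)) {
    if (mono(idx$P1) && mono(c(idx$H, idx$P1))) {
      call <- "T1"
    } else if (mono(idx$P2) && mono(c(idx$H, idx$P2))) {
      call <- "T2"
    }
  }
  structure(call, outgroup_monophyletic = rr$outgroup_monophyletic)
}

#' Support-relaxed topology classification of one gene tree
#'
#' Branches with support below the hypothesis threshold are collapsed, the
#' tree is restricted to the hypothesis samples, and every quartet of one
#' sample per lineage (hybrid h, parents p1/p2, outgroup o) is resolved in
#' the collapsed tree. The call is `T1` when strictly more quartets resolve
#' `h,p1 | p2,o` than `h,p2 | p1,o`, `T2` when strictly fewer, and
#' `UNASSIGNED` on a tie or when no quartet resolves. This is a
#' reproducible surrogate for judging that a weakly resolved gene tree
#' "approximates" one of the two candidate topologies.
#'
#' @inheritParams classify_strict
#' @param max_quartets cap on sampled quartets when the one-per-lineage
#'   combinations exceed it (subsampled deterministically under `seed`).
#' @param seed seed for quartet subsampling only.
#' @return `"T1"`, `"T2"` or `"UNASSIGNED"`, with attribute `tally`
#'   (counts of T1/T2/hybrid-outgroup/unresolved quartets).
#' @export
classify_relaxed <- function(tree, hyp, map, max_quartets = 500L, seed = 1L) {
  samples <- hyp_samples(tree, hyp, map)
  collapsed <- collapse_low_support(tree, hyp$support_threshold)
  sub <- ape::keep.tip(collapsed, unlist(samples, use.names = FALSE))
  par <- parent_vec(sub)
  dep <- depth_vec(sub, par)
  idx <- lapply(samples, function(s) tip_index(sub, s))
  combos <- expand.grid(h = idx$H, p1 = idx$P1, p2 = idx$P2, o = idx$O,
                        KEEP.OUT.ATTRS = FALSE)
  if (nrow(combos) > max_quartets) {
    rows <- with_seed_if(seed, sample.int(nrow(combos), max_quartets))
    combos <- combos[rows, , drop = FALSE]
  }
  tally <- c(T1 = 0L, T2 = 0L, HO = 0L, unresolved = 0L)
  for (i in seq_len(nrow(combos))) {
    # resolutions of (h, p1, p2, o): 1 = hp1|p2o, 2 = hp2|p1o, 3 = ho|p1p2
    r <- quartet_resolution(par, dep, combos$h[i], combos$p1[i],
                            combos$p2[i], combos$o[i])
    tally[if (r == 0L) 4L else r] <- tally[if (r == 0L) 4L else r] + 1L
  }
  call <- if (tally["T1"] > tally["T2"]) "T1"
          else if (tally["T2"] > tally["T1"]) "T2"
          else "UNASSIGNED"
  structure(call, tally = tally)
}

#' Bin a set of gene trees into competing topology classes
#'
#' Applies [classify_strict()] and [classify_relaxed()] to every tree and
#' tallies the calls; a per-tree audit trail records both calls, the quartet
#' tallies and whether the outgroup was monophyletic.
#'
#' @param trees list of `phylo` objects.
#' @param hyp a [hypothesis_spec()].
#' @param map lineage map data.frame.
#' @inheritParams classify_relaxed
#' @return a list of class `bin_counts`: `strict` and `relaxed` named count
#'   vectors, `strict_freq`/`relaxed_freq`, `n_trees`, and `audit`
#'   (data.frame).
#' @export
bin_gene_trees <- function(trees, hyp, map, max_quartets = 500L, seed = 1L) {
  if (length(trees) < 1L) abort("need at least one gene tree")
  n <- length(trees)
  strict <- character(n)
  relaxed <- character(n)
  o_mono <- logical(n)
  tallies <- matrix(0L, n, 4L,
                    dimnames = list(NULL, c("q_T1", "q_T2", "q_HO",
                                            "q_unresolved")))
  for (i in seq_len(n)) {
    s <- tryCatch(classify_strict(trees[[i]], hyp, map),
                  error = function(e) abort("tree %d: %s", i,
                                            conditionMessage(e)))
    r <- classify_relaxed(trees[[i]], hyp, map, max_quartets, seed)
    strict[i] <- as.character(s)
    o_mono[i] <- attr(s, "outgroup_monophyletic")
    relaxed[i] <- as.character(r)
    tallies[i, ] <- attr(r, "tally")
  }
  strict_counts <- c(T1 = sum(strict == "T1"), T2 = sum(strict == "T2"),
                     OTHER = sum(strict == "OTHER"))
  relaxed_counts <- c(T1 = sum(relaxed == "T1"), T2 = sum(relaxed == "T2"),
                      UNASSIGNED = sum(relaxed == "UNASSIGNED"))
  audit <- data.frame(tree = seq_len(n), strict = strict, relaxed = relaxed,
                      outgroup_monophyletic = o_mono, tallies,
                      stringsAsFactors = FALSE)
  structure(
    list(strict = strict_counts, relaxed = relaxed_counts,
         strict_freq = strict_counts / n, relaxed_freq = relaxed_counts / n,
         n_trees = n, hypothesis = hyp, audit = audit),
    class = "bin_counts"
  )
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("Gene-tree bins over %d trees (H = %s, P1 = %s, P2 = %s)\n",
              x$n_trees, x$hypothesis$hybrid, x$hypothesis$parent1,
              x$hypothesis$parent2))
  cat(sprintf("  strict : T1 %d (%.1f%%)  T2 %d (%.1f%%)  OTHER %d (%.1f%%)\n",
              x$strict["T1"], 100 * x$strict_freq["T1"],
              x$strict["T2"], 100 * x$strict_freq["T2"],
              x$strict["OTHER"], 100 * x$strict_freq["OTHER"]))
  cat(sprintf("  relaxed (BS < %g collapsed): T1 %d (%.1f%%)  T2 %d (%.1f%%)  unassigned %d (%.1f%%)\n",
              x$hypothesis$support_threshold,
              x$relaxed["T1"], 100 * x$relaxed_freq["T1"],
              x$relaxed["T2"], 100 * x$relaxed_freq["T2"],
              x$relaxed["UNASSIGNED"], 100 * x$relaxed_freq["UNASSIGNED"]))
  invisible(x)
}
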