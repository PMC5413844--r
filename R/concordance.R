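#' Clade concordance factor from gene-tree frequencies
#'
#' The concordance factor of a clade is the proportion of the genome for
#' which the clade is true, estimated here as the fraction of informative
#' gene trees in which the clade's samples are monophyletic. A tree is
#' informative for the clade when it contains every clade member and at
#' least one non-member.
#'
#' @param trees list of rooted `phylo` objects.
#' @param clade character vector of tip labels (>= 1).
#' @return a list of class `clade_cf`: `clade`, `cf`, `n_informative`,
#'   `n_concordant`.
#' @export
clade_cf <- function(trees, clade) {
  if (length(clade) < 1L) abort("clade must contain at least one taxon")
  n_inf <- 0L
  n_con <- 0L
  for (tr in trees) {
    if (!all(clade %in% tr$tip.label)) next
    if (length(setdiff(tr$tip.label, clade)) == 0L) next
    n_inf <- n_inf + 1L
    if (is_clade(tr, match(clade, tr$tip.label))) n_con <- n_con + 1L
  }
  if (n_inf == 0L) {
    abort("clade {%s} is uninformative: no tree has all members plus an outsider",
          paste(clade, collapse = ", "))
  }
  structure(list(clade = clade, cf = n_con / n_inf, n_informative = n_inf,
                 n_concordant = n_con),
            class = "clade_cf")
}

#' @export
print.clade_cf <- function(x, ...) {
  cat(sprintf("CF = %.3f for clade {%s} (%d/%d informative trees)\n",
              x$cf, paste(x$clade, collapse = ", "), x$n_concordant,
              x$n_informative))
  invisible(x)
}

# canonical resolution index of a lineage quartet (l1 < l2 < l3 < l4):
# 1 = l1l2|l3l4, 2 = l1l3|l2l4, 3 = l1l4|l2l3

#' Observed quartet concordance factors across gene trees
#'
#' For every 4-subset of `lineages` and every gene tree, the one-sample-
#' per-lineage quartets (capped at `max_quartets`, subsampled under `seed`)
#' are resolved in the tree; the gene votes for its majority resolution and
#' abstains on a tie or when nothing resolves. Concordance factors are the
#' vote fractions over voting genes. Lineages are sorted within each
#' quartet, so `cf12_34` is the resolution pairing the two alphabetically
#' first lineages, etc.
#'
#' @param trees list of `phylo` objects.
#' @param map lineage map data.frame (`sample_id`, `lineage`).
#' @param lineages lineage ids to analyse (>= 4).
#' @param max_quartets per-gene cap on sampled quartets per 4-subset.
#' @param seed seed for quartet subsampling only.
#' @return a data.frame of class `quartet_cf`: columns `l1..l4`,
#'   `cf12_34`, `cf13_24`, `cf14_23`, `n_eff`.
#' @export
quartet_cf_table <- function(trees, map, lineages, max_quartets = 500L,
                             seed = 1L) {
  if (length(lineages) < 4L) abort("need at least four lineages")
  lookup <- setNames(map$lineage, map$sample_id)
  seen <- unique(lookup[unlist(lapply(trees, `[[`, "tip.label"),
                               use.names = FALSE)])
  missing <- setdiff(lineages, seen)
  if (length(missing)) {
    abort("lineage(s) absent from all trees: %s",
          paste(missing, collapse = ", "))
  }
  sets <- combn(sort(lineages), 4L)
  # per-tree structures computed once
  prepped <- lapply(trees, function(tr) {
    par <- parent_vec(tr)
    list(par = par, dep = depth_vec(tr, par),
         of_lineage = split(seq_along(tr$tip.label),
                            lookup[tr$tip.label]))
  })
  rows <- vector("list", ncol(sets))
  for (q in seq_len(ncol(sets))) {
    lins <- sets[, q]
    votes <- c(0L, 0L, 0L)
    for (pt in prepped) {
      tips <- pt$of_lineage[lins]
      if (any(vapply(tips, is.null, logical(1)))) next
      combos <- expand.grid(a = tips[[1]], b = tips[[2]], c = tips[[3]],
                            d = tips[[4]], KEEP.OUT.ATTRS = FALSE)
      if (nrow(combos) > max_quartets) {
        rws <- with_seed_if(seed, sample.int(nrow(combos), max_quartets))
        combos <- combos[rws, , drop = FALSE]
      }
      tly <- c(0L, 0L, 0L)
      for (i in seq_len(nrow(combos))) {
        r <- quartet_resolution(pt$par, pt$dep, combos$a[i], combos$b[i],
                                combos$c[i], combos$d[i])
        if (r > 0L) tly[r] <- tly[r] + 1L
      }
      top <- max(tly)
      if (top > 0L && sum(tly == top) == 1L) {
        votes[which.max(tly)] <- votes[which.max(tly)] + 1L
      }
    }
    n_eff <- sum(votes)
    cf <- if (n_eff > 0L) votes / n_eff else c(NA_real_, NA_real_, NA_real_)
    rows[[q]] <- data.frame(l1 = lins[1], l2 = lins[2], l3 = lins[3],
                            l4 = lins[4], cf12_34 = cf[1], cf13_24 = cf[2],
                            cf14_23 = cf[3], n_eff = n_eff,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("quartet_cf", "data.frame")
  out
}

#' Write or read a quartet concordance-factor table
#'
#' @param cf_table data.frame from [quartet_cf_table()].
#' @param path TSV path.
#' @return `read_quartet_cf()`: the table; `write_quartet_cf()`: `path`,
#'   invisibly.
#' @export
write_quartet_cf <- function(cf_table, path) {
  utils::write.table(cf_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_quartet_cf
#' @export
read_quartet_cf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("l1", "l2", "l3", "l4", "cf12_34", "cf13_24", "cf14_23",
            "n_eff")
  if (!all(need %in% names(df))) {
    abort("quartet CF table %s must have columns %s", path,
          paste(need, collapse = ", "))
  }
  class(df) <- c("quartet_cf", "data.frame")
  df
}
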