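#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator. Branch lengths are in
#' coalescent units; `lambda` is the length scale of the bootstrap-support
#' model (an internal edge of length `l` receives support drawn from
#' `Binomial(B, 1 - exp(-l/lambda))`, rescaled to 0-100); `subst_scale`
#' converts coalescent units to expected substitutions/site for optional
#' Jukes-Cantor alignments.
#'
#' @param n_genes number of unlinked loci to simulate (>= 1).
#' @param samples_per_lineage a single count applied to every lineage, or a
#'   named integer vector mapping lineage -> number of sampled individuals.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param lambda support-model length scale (> 0, coalescent units).
#' @param B support-model pseudoreplicates (default 100, like a standard
#'   bootstrap).
#' @param subst_scale substitutions/site per coalescent unit for
#'   [simulate_alignment()].
#' @param n_sites alignment length for [simulate_alignment()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes, samples_per_lineage = 1L, seed = NULL,
                       lambda = 0.5, B = 100L, subst_scale = 0.02,
                       n_sites = 500L) {
  if (!is_count(n_genes)) abort("n_genes must be a count >= 1")
  if (!is.numeric(samples_per_lineage) || any(samples_per_lineage < 1) ||
      any(samples_per_lineage != floor(samples_per_lineage))) {
    abort("samples_per_lineage must be counts >= 1")
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    abort("lambda must be a single positive number")
  }
  if (!is_count(B)) abort("B must be a count >= 1")
  if (!is_count(n_sites)) abort("n_sites must be a count >= 1")
  if (!is.numeric(subst_scale) || subst_scale < 0) {
    abort("subst_scale must be >= 0")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         samples_per_lineage = samples_per_lineage,
         seed = seed, lambda = lambda, B = as.integer(B),
         subst_scale = subst_scale, n_sites = as.integer(n_sites)),
    class = "sim_config"
  )
}

# precompute per displayed tree the tables the coalescent sweep needs:
# parent vector, node times (tip-ward heights), postorder node sequence
prep_species_tree <- function(phy) {
  n <- length(phy$tip.label)
  n_all <- n + phy$Nnode
  par <- parent_vec(phy)
  dl <- depthlen_vec(phy, par)
  tme <- max(dl[seq_len(n)]) - dl
  po <- ape::reorder.phylo(phy, "postorder")$edge
  nodes <- c(po[, 2L], n + 1L)  # children before parents, root last
  nodes <- nodes[!duplicated(nodes)]
  nodes <- c(nodes[nodes <= n], nodes[nodes > n])  # tips need no ordering
  ch <- vector("list", n_all)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    ch[[p]] <- c(ch[[p]], phy$edge[i, 2L])
  }
  list(n = n, n_all = n_all, par = par, tme = tme, nodes = nodes,
       children = ch, tip_label = phy$tip.label)
}

# one multispecies-coalescent gene tree on a prepped species tree;
# tip_ids: list per species tip of gene-tip indices; returns a phylo
sim_msc_one <- function(prep, tip_ids, tip_labels) {
  n_sp <- prep$n
  N <- length(tip_labels)
  act <- vector("list", prep$n_all)
  ch1 <- integer(N - 1L)
  ch2 <- integer(N - 1L)
  itime <- numeric(N - 1L)
  nint <- 0L
  for (v in prep$nodes) {
    lin <- if (v <= n_sp) tip_ids[[v]] else unlist(act[prep$children[[v]]],
                                                   use.names = FALSE)
    k <- length(lin)
    if (k >= 2L) {
      t0 <- prep$tme[v]
      p <- prep$par[v]
      t1 <- if (p == 0L) Inf else prep$tme[p]
      t <- t0
      while (k >= 2L) {
        t <- t + rexp(1L, k * (k - 1L) / 2)
        if (t >= t1) break
        ij <- sample.int(k, 2L)
        nint <- nint + 1L
        ch1[nint] <- lin[ij[1L]]
        ch2[nint] <- lin[ij[2L]]
        itime[nint] <- t
        lin <- c(lin[-ij], N + nint)
        k <- k - 1L
      }
    }
    act[[v]] <- lin
  }
  build_gene_phylo(N, ch1, ch2, itime, tip_labels)
}

# assemble an ape phylo (cladewise, root = N+1) from merge records
build_gene_phylo <- function(N, ch1, ch2, itime, tip_labels) {
  M <- N - 1L
  time_of <- c(numeric(N), itime)
  root_old <- N + M
  n_edge <- 2L * M
  edge <- matrix(0L, n_edge, 2L)
  elen <- numeric(n_edge)
  new_id <- integer(N + M)
  # iterative depth-first walk; stacks hold (old id, new parent id)
  st_node <- integer(N + M)
  st_par <- integer(N + M)
  sp <- 1L
  st_node[1L] <- root_old
  st_par[1L] <- 0L
  next_int <- N + 1L
  eidx <- 0L
  while (sp > 0L) {
    v <- st_node[sp]
    pnew <- st_par[sp]
    sp <- sp - 1L
    if (v <= N) {
      vnew <- v
    } else {
      vnew <- next_int
      next_int <- next_int + 1L
    }
    new_id[v] <- vnew
    if (pnew > 0L) {
      eidx <- eidx + 1L
      edge[eidx, 1L] <- pnew
      edge[eidx, 2L] <- vnew
    }
    if (v > N) {
      i <- v - N
      sp <- sp + 1L
      st_node[sp] <- ch2[i]
      st_par[sp] <- vnew
      sp <- sp + 1L
      st_node[sp] <- ch1[i]
      st_par[sp] <- vnew
    }
  }
  # lengths: parent time minus child time, in the same edge order
  old_of_new <- integer(N + M)
  old_of_new[new_id] <- seq_len(N + M)
  for (i in seq_len(n_edge)) {
    elen[i] <- time_of[old_of_new[edge[i, 1L]]] -
      time_of[old_of_new[edge[i, 2L]]]
  }
  structure(
    list(edge = edge, edge.length = elen, Nnode = M, tip.label = tip_labels),
    class = "phylo", order = "cladewise"
  )
}

#' Simulate gene trees under the network multispecies coalescent
#'
#' For each locus independently, the hybrid lineage's parental path is drawn
#' (`Bernoulli(gamma)` for the parent-2/minor path) and the standard
#' multispecies coalescent is run on the resulting displayed tree: within
#' each species-tree branch of length `t`, while `k >= 2` gene lineages
#' remain, an exponential waiting time with rate `k(k-1)/2` is drawn and a
#' uniformly chosen pair merged if the event falls within the branch;
#' surviving lineages enter the parent branch, and everything coalesces
#' above the root. Gene trees are rooted, with coalescent-unit branch
#' lengths; each carries the chosen path in `attr(tree, "parental_path")`.
#'
#' @param network a [species_network()].
#' @param config a [sim_config()]; `samples_per_lineage` individuals are
#'   sampled per lineage, labelled `<lineage>_<i>`.
#' @return a list of `n_genes` `phylo` objects with attributes
#'   `lineage_map` (data.frame sample_id, lineage) and `parental_paths`.
#' @examples
#' net <- default_roucela_network(gamma = 0.5, scale = 1)
#' trees <- simulate_gene_trees(net, sim_config(n_genes = 5, seed = 1))
#' length(trees)
#' @export
simulate_gene_trees <- function(network, config) {
  stopifnot(inherits(network, "species_network"))
  stopifnot(inherits(config, "sim_config"))
  disp <- displayed_trees(network)
  lineages <- disp$major$tip.label
  spl <- config$samples_per_lineage
  if (length(spl) == 1L && is.null(names(spl))) {
    spl <- setNames(rep(as.integer(spl), length(lineages)), lineages)
  }
  if (!all(lineages %in% names(spl))) {
    abort("samples_per_lineage must cover every lineage (missing: %s)",
          paste(setdiff(lineages, names(spl)), collapse = ", "))
  }
  spl <- as.integer(spl[lineages])
  # global sample ids grouped by lineage, in major-tree tip order
  tip_labels <- unlist(lapply(seq_along(lineages), function(i) {
    paste0(lineages[i], "_", seq_len(spl[i]))
  }), use.names = FALSE)
  ids_of_lineage <- split(seq_along(tip_labels),
                          rep(lineages, spl))[lineages]
  preps <- lapply(list(disp$major, disp$minor), prep_species_tree)
  tip_ids <- lapply(preps, function(p) ids_of_lineage[p$tip_label])
  with_seed_if(config$seed, {
    path <- rbinom(config$n_genes, 1L, network$gamma)  # 1 = minor
    trees <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      w <- path[g] + 1L
      tr <- sim_msc_one(preps[[w]], tip_ids[[w]], tip_labels)
      attr(tr, "parental_path") <- c("major", "minor")[w]
      trees[[g]] <- tr
    }
    attr(trees, "parental_paths") <- c("major", "minor")[path + 1L]
    attr(trees, "lineage_map") <- data.frame(
      sample_id = tip_labels,
      lineage = rep(lineages, spl),
      stringsAsFactors = FALSE
    )
    trees
  })
}

#' Attach bootstrap-like support values to simulated gene trees
#'
#' Each internal edge of length `l` (the edge above an internal node)
#' receives a support value drawn from `Binomial(B, 1 - exp(-l / lambda))`,
#' rescaled to the 0-100 bootstrap scale and stored as the node's label
#' (RAxML newick dialect). The root, having no parent edge, gets an empty
#' label. Longer edges therefore saturate at 100 while near-zero edges get
#' near-zero support, mimicking how bootstrap support tracks branch length.
#'
#' @param trees list of `phylo` objects with branch lengths.
#' @param config a [sim_config()] supplying `lambda`, `B` and `seed`.
#' @return the list of trees with `node.label` set.
#' @export
attach_support <- function(trees, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, {
    out <- vector("list", length(trees))
    for (i in seq_along(trees)) {
      tr <- trees[[i]]
      if (is.null(tr$edge.length)) {
        abort("tree %d has no branch lengths; supports need them", i)
      }
      n <- length(tr$tip.label)
      lab <- character(tr$Nnode)
      for (j in seq_len(tr$Nnode)) {
        v <- n + j
        row <- which(tr$edge[, 2L] == v)
        if (length(row) == 0L) {
          lab[j] <- ""  # root
        } else {
          p <- 1 - exp(-tr$edge.length[row] / config$lambda)
          x <- rbinom(1L, config$B, p)
          lab[j] <- format(100 * x / config$B)
        }
      }
      tr$node.label <- lab
      out[[i]] <- tr
    }
    for (a in names(attributes(trees))) {
      if (!a %in% c("names")) attr(out, a) <- attr(trees, a)
    }
    out
  })
}

#' Simulate a Jukes-Cantor alignment along a gene tree
#'
#' Sites evolve independently under the Jukes-Cantor model with branch
#' lengths `l * subst_scale` expected substitutions/site. The root sequence
#' is uniform over the four bases.
#'
#' @param tree a `phylo` with branch lengths (coalescent units).
#' @param config a [sim_config()] supplying `subst_scale`, `n_sites`, `seed`.
#' @return a character matrix (tips x sites) of bases `a/c/g/t`, writable
#'   with [write_alignment()].
#' @export
simulate_alignment <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  bases <- c("a", "c", "g", "t")
  n <- length(tree$tip.label)
  n_all <- n + tree$Nnode
  L <- config$n_sites
  with_seed_if(config$seed, {
    seqs <- matrix(0L, n_all, L)
    root <- n + 1L
    seqs[root, ] <- sample.int(4L, L, replace = TRUE)
    eo <- reorder_preorder(tree, lengths = TRUE)
    for (i in seq_len(nrow(eo$edge))) {
      d <- eo$len[i] * config$subst_scale
      p_change <- 0.75 * (1 - exp(-4 * d / 3))
      parent_seq <- seqs[eo$edge[i, 1L], ]
      child_seq <- parent_seq
      hit <- which(runif(L) < p_change)
      if (length(hit)) {
        # uniform among the three other bases
        child_seq[hit] <- ((parent_seq[hit] - 1L +
                              sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
      }
      seqs[eo$edge[i, 2L], ] <- child_seq
    }
    out <- matrix(bases[seqs[seq_len(n), , drop = FALSE]], n, L)
    rownames(out) <- tree$tip.label
    out
  })
}

#' Write an alignment to FASTA
#'
#' @param aln character matrix from [simulate_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ape::write.FASTA(ape::as.DNAbin(aln), path)
  invisible(path)
}

#' Write and read gene trees in newick format
#'
#' Supports are written as internal node labels; one tree per line.
#'
#' @param trees list of `phylo` objects.
#' @param path newick file (one tree per line).
#' @return `write_gene_trees()`: `path`, invisibly. `read_gene_trees()`: a
#'   list of `phylo` objects (node labels preserved as character supports).
#' @export
write_gene_trees <- function(trees, path) {
  txt <- vapply(trees, function(tr) ape::write.tree(tr), character(1))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_gene_trees
#' @export
read_gene_trees <- function(path) {
  if (!file.exists(path)) abort("no such tree file: %s", path)
  trees <- tryCatch(ape::read.tree(path),
                    error = function(e) abort("malformed newick in %s: %s",
                                              path, conditionMessage(e)))
  if (is.null(trees)) abort("no trees found in %s", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- NULL
  trees
}

#' Read and write a sample-to-lineage map
#'
#' A two-column TSV (`sample_id`, `lineage`) assigning each sequenced
#' individual to a lineage.
#'
#' @param path TSV file.
#' @param map data.frame with columns `sample_id` and `lineage`.
#' @return `read_lineage_map()`: the data.frame; `write_lineage_map()`:
#'   `path`, invisibly.
#' @export
read_lineage_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "lineage") %in% names(df))) {
    abort("lineage map %s must have columns sample_id, lineage", path)
  }
  if (anyDuplicated(df$sample_id)) {
    abort("duplicate sample_id in lineage map %s", path)
  }
  df
}

#' @rdname read_lineage_map
#' @export
write_lineage_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
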