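# expected quartet CFs on a level-1 network, pseudolikelihood, gamma fitting

# pairing index and internal path length of a 4-lineage set on one rooted
# displayed tree; pairing: 1 = q1q2|q3q4, 2 = q1q3|q2q4, 3 = q1q4|q2q3
# (q sorted), 0 when the restriction is unresolved
displayed_quartet_stats <- function(phy, q) {
  sub <- ape::unroot(ape::keep.tip(phy, q))
  n <- length(sub$tip.label)
  internal <- sub$edge[, 2L] > n
  t <- if (is.null(sub$edge.length)) 0 else sum(sub$edge.length[internal])
  if (!any(internal)) return(list(pairing = 0L, t = 0))
  # the single internal non-root node subtends one pair of tips
  v <- sub$edge[internal, 2L][1L]
  pair <- sub$tip.label[sub$edge[sub$edge[, 1L] == v, 2L]]
  if (!q[1L] %in% pair) pair <- setdiff(q, pair)
  partner <- setdiff(pair, q[1L])
  list(pairing = match(partner, q[-1L]), t = t)
}

# CF triple of a quartet with internal length t and major pairing k
tree_cf_triple <- function(pairing, t) {
  minor <- exp(-t) / 3
  out <- rep(minor, 3L)
  if (pairing == 0L) return(rep(1 / 3, 3L))
  out[pairing] <- 1 - 2 * minor
  out
}

#' Expected quartet concordance factors on a species network
#'
#' Under the multispecies coalescent, a 4-lineage set whose unrooted
#' restriction on a species tree has internal path length `t` (coalescent
#' units) yields the concordant resolution with probability
#' `1 - (2/3) exp(-t)` and each discordant resolution with probability
#' `(1/3) exp(-t)`. On a one-hybrid network the expected triple is the
#' gamma-weighted mixture of the triples on the two displayed trees; for
#' quartets that do not involve the hybrid the two displayed trees agree
#' and the mixture reduces to the tree formula.
#'
#' @param network a [species_network()].
#' @param quartet four lineage (tip) labels.
#' @return named numeric vector `(cf12_34, cf13_24, cf14_23)` relative to
#'   the alphabetically sorted quartet; sums to 1.
#' @examples
#' net <- default_roucela_network(gamma = 0.5, scale = 1)
#' expected_quartet_cf(net, c("outgroup", "drabifolia", "erinus4x",
#'                            "creutzburgii"))
#' @export
expected_quartet_cf <- function(network, quartet) {
  stopifnot(inherits(network, "species_network"))
  if (length(quartet) != 4L || anyDuplicated(quartet)) {
    abort("quartet must be four distinct lineages")
  }
  unknown <- setdiff(quartet, network$major$tip.label)
  if (length(unknown)) {
    abort("unknown lineage(s): %s", paste(unknown, collapse = ", "))
  }
  q <- sort(quartet)
  sM <- displayed_quartet_stats(network$major, q)
  sm <- displayed_quartet_stats(network$minor, q)
  cf <- (1 - network$gamma) * tree_cf_triple(sM$pairing, sM$t) +
    network$gamma * tree_cf_triple(sm$pairing, sm$t)
  setNames(cf, c("cf12_34", "cf13_24", "cf14_23"))
}

#' Expected quartet CF table for a whole network
#'
#' @param network a [species_network()].
#' @param lineages lineages to include (default: all tips).
#' @param n_eff effective gene count recorded per quartet (used as
#'   multinomial weight by [network_pseudolik()]).
#' @return a `quartet_cf` data.frame like [quartet_cf_table()]'s.
#' @export
expected_cf_table <- function(network, lineages = network$tips,
                              n_eff = 100L) {
  sets <- combn(sort(lineages), 4L)
  rows <- lapply(seq_len(ncol(sets)), function(q) {
    lins <- sets[, q]
    cf <- expected_quartet_cf(network, lins)
    data.frame(l1 = lins[1], l2 = lins[2], l3 = lins[3], l4 = lins[4],
               cf12_34 = cf[1], cf13_24 = cf[2], cf14_23 = cf[3],
               n_eff = n_eff, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("quartet_cf", "data.frame")
  out
}

check_cf_table <- function(cf_table) {
  need <- c("l1", "l2", "l3", "l4", "cf12_34", "cf13_24", "cf14_23",
            "n_eff")
  if (!all(need %in% names(cf_table))) {
    abort("cf_table must have columns %s", paste(need, collapse = ", "))
  }
  srt <- apply(as.matrix(cf_table[, c("l1", "l2", "l3", "l4")]), 1L,
               function(r) all(r == sort(r)))
  if (!all(srt)) abort("cf_table lineages must be sorted within each row")
  invisible(cf_table)
}

#' Multinomial pseudo-log-likelihood of a network given observed quartet CFs
#'
#' Each quartet contributes `n_eff * sum_k cf_obs_k * log(cf_exp_k)` with
#' expected CFs floored at 1e-12 inside the log; quartets are treated as
#' independent. Higher is better. Rows with `n_eff = 0` or missing observed
#' CFs are ignored.
#'
#' @param network a [species_network()].
#' @param cf_table observed table from [quartet_cf_table()].
#' @return the pseudo-log-likelihood (a single number).
#' @export
network_pseudolik <- function(network, cf_table) {
  check_cf_table(cf_table)
  total <- 0
  for (i in seq_len(nrow(cf_table))) {
    ne <- cf_table$n_eff[i]
    obs <- as.numeric(cf_table[i, c("cf12_34", "cf13_24", "cf14_23")])
    if (is.na(ne) || ne <= 0 || anyNA(obs)) next
    expd <- expected_quartet_cf(network, as.character(
      cf_table[i, c("l1", "l2", "l3", "l4")]))
    total <- total + ne * sum(obs * log(pmax(expd, 1e-12)))
  }
  total
}

#' Candidate network: the Roucela hybridization topology
#'
#' The fixed candidate used for fitting: backbone
#' `(outgroup,((drabifolia,erinus4x),(simulans,creutzburgii)))` with the
#' octoploid hybrid attached to the `erinus4x`/`creutzburgii` terminal
#' edges. Three free internal lengths (coalescent units): `t_attach` from
#' the hybrid attachment points up to the ingroup cherries, `t_clade` from
#' each cherry to the ingroup root, `t_root` from the ingroup root to the
#' root.
#'
#' @return a list of class `network_candidate` with elements `build(gamma,
#'   t)`, `n_t`, `t_names` and `name`, consumable by [fit_network()].
#' @export
roucela_candidate <- function() {
  structure(
    list(
      build = function(gamma, t) {
        build_roucela_heights(gamma, a = 1, h2 = 1 + t[1L],
                              h3 = 1 + t[1L] + t[2L],
                              h4 = 1 + t[1L] + t[2L] + t[3L])
      },
      n_t = 3L,
      t_names = c("t_attach", "t_clade", "t_root"),
      name = "roucela_h1"
    ),
    class = "network_candidate"
  )
}

# linearize the internal path lengths of every quartet in the candidate's
# parameters: t_q(t) = c0 + A %*% t (edge lengths are linear in t by
# construction); pairings are fixed by the topology
precompute_candidate <- function(cf_table, candidate) {
  qs <- as.matrix(cf_table[, c("l1", "l2", "l3", "l4")])
  nq <- nrow(qs)
  n_t <- candidate$n_t
  ref <- candidate$build(0.5, rep(1, n_t))
  basis <- lapply(seq_len(n_t), function(i) {
    e <- rep(1, n_t)
    e[i] <- 2
    candidate$build(0.5, e)
  })
  out <- list()
  for (side in c("major", "minor")) {
    pairing <- integer(nq)
    c0 <- numeric(nq)
    A <- matrix(0, nq, n_t)
    for (q in seq_len(nq)) {
      s_ref <- displayed_quartet_stats(ref[[side]], qs[q, ])
      pairing[q] <- s_ref$pairing
      tb <- vapply(basis, function(net) {
        displayed_quartet_stats(net[[side]], qs[q, ])$t
      }, numeric(1))
      A[q, ] <- tb - s_ref$t
      c0[q] <- s_ref$t - sum(A[q, ])  # value at t = 0 extrapolated
    }
    out[[side]] <- list(pairing = pairing, c0 = c0, A = A)
  }
  out
}

# expected CF matrix (nq x 3) for one displayed side at parameters t
expected_side_cf <- function(side_pre, t) {
  tq <- pmax(side_pre$c0 + as.vector(side_pre$A %*% t), 0)
  minor <- exp(-tq) / 3
  m <- matrix(minor, length(tq), 3L)
  for (k in 1:3) {
    sel <- side_pre$pairing == k
    m[sel, k] <- 1 - 2 * minor[sel]
  }
  unres <- side_pre$pairing == 0L
  if (any(unres)) m[unres, ] <- 1 / 3
  m
}

#' Fit a candidate network to observed quartet concordance factors
#'
#' Maximizes the multinomial pseudolikelihood over the inheritance
#' probability `gamma` (on the logit scale internally) and the candidate's
#' internal branch lengths `t` in `[0, t_max]`, by bounded quasi-Newton
#' (`L-BFGS-B`) from `n_restarts` seeded random starts. The candidate
#' topology is fixed; no network search is performed.
#'
#' @param cf_table observed quartet CFs ([quartet_cf_table()] or
#'   [read_quartet_cf()]).
#' @param candidate a [roucela_candidate()]-style candidate (list with
#'   `build(gamma, t)` and `n_t`).
#' @param gamma_fixed fix gamma at this value instead of estimating it
#'   (e.g. 0 for the no-hybridization tree model).
#' @param n_restarts number of random restarts (>= 1; default 10).
#' @param seed seed for the restart draws.
#' @param t_max upper bound on internal branch lengths (coalescent units).
#' @return a list of class `network_fit`: `gamma_hat`, `t_hat`, `loglik`
#'   (pseudo-log-likelihood, higher is better), `network` (the fitted
#'   [species_network()]), `convergence` (per-restart optim codes),
#'   `converged`, `restart_values`, and the `cf_table` used.
#' @export
fit_network <- function(cf_table, candidate = roucela_candidate(),
                        gamma_fixed = NULL, n_restarts = 10L, seed = 1L,
                        t_max = 20) {
  check_cf_table(cf_table)
  if (nrow(cf_table) < 1L) abort("cf_table must have at least one quartet")
  if (!is.null(gamma_fixed) && !is_prob(gamma_fixed)) {
    abort("gamma_fixed must be in [0, 1]")
  }
  if (!is_count(n_restarts)) abort("n_restarts must be a count >= 1")
  keep <- !is.na(cf_table$n_eff) & cf_table$n_eff > 0 &
    !is.na(cf_table$cf12_34)
  used <- cf_table[keep, , drop = FALSE]
  pre <- precompute_candidate(used, candidate)
  obs <- as.matrix(used[, c("cf12_34", "cf13_24", "cf14_23")])
  ne <- used$n_eff
  n_t <- candidate$n_t
  free_gamma <- is.null(gamma_fixed)
  pll <- function(gamma, t) {
    m <- (1 - gamma) * expected_side_cf(pre$major, t) +
      gamma * expected_side_cf(pre$minor, t)
    sum(ne * rowSums(obs * log(pmax(m, 1e-12))))
  }
  unpack <- function(par) {
    if (free_gamma) list(gamma = plogis(par[1L]), t = par[-1L])
    else list(gamma = gamma_fixed, t = par)
  }
  obj <- function(par) {
    p <- unpack(par)
    -pll(p$gamma, p$t)
  }
  lower <- c(if (free_gamma) -16, rep(0, n_t))
  upper <- c(if (free_gamma) 16, rep(t_max, n_t))
  starts <- with_seed_if(seed, {
    lapply(seq_len(n_restarts), function(i) {
      c(if (free_gamma) qlogis(runif(1, 0.02, 0.98)),
        runif(n_t, 0.05, 3))
    })
  })
  fits <- lapply(starts, function(p0) {
    tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) list(value = Inf, par = p0, convergence = 99L)
    )
  })
  values <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(values)]]
  p <- unpack(best$par)
  t_hat <- setNames(p$t, candidate$t_names %||% paste0("t", seq_len(n_t)))
  structure(
    list(gamma_hat = p$gamma, t_hat = t_hat, loglik = -best$value,
         network = candidate$build(p$gamma, p$t),
         gamma_fixed = gamma_fixed,
         convergence = vapply(fits, `[[`, numeric(1), "convergence"),
         converged = any(vapply(fits, `[[`, numeric(1),
                                "convergence") == 0),
         restart_values = -values, candidate_name = candidate$name,
         cf_table = cf_table),
    class = "network_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.network_fit <- function(x, ...) {
  cat("Network pseudolikelihood fit (", x$candidate_name, ")\n", sep = "")
  if (is.null(x$gamma_fixed)) {
    cat(sprintf("  gamma_hat = %.4f\n", x$gamma_hat))
  } else {
    cat(sprintf("  gamma fixed at %.4f\n", x$gamma_fixed))
  }
  cat("  t_hat =", paste(sprintf("%s %.3f", names(x$t_hat), x$t_hat),
                         collapse = ", "), "\n")
  cat(sprintf("  pseudo-loglik = %.4f (best of %d restarts%s)\n",
              x$loglik, length(x$restart_values),
              if (x$converged) "" else "; WARNING: no restart converged"))
  invisible(x)
}

#' Compare the no-hybridization tree fit with the one-hybrid network fit
#'
#' Reports the pseudolikelihood improvement of allowing one hybrid edge
#' (`delta = loglik(h1) - loglik(tree)`), the fitted gamma, and a
#' plain-language verdict: the hybrid edge is called supported when `delta`
#' exceeds `margin`. A gamma estimate near 0 or 1 with `delta ~ 0` means
#' the reticulation is not needed to explain the quartet CFs.
#'
#' @param fit_tree a [fit_network()] result with `gamma_fixed = 0`.
#' @param fit_h1 a [fit_network()] result with free gamma, on the same
#'   `cf_table`.
#' @param margin improvement required to call the hybrid edge supported.
#' @return a list of class `model_comparison`: `delta`, `gamma_hat`,
#'   `hybrid_supported`, `verdict`.
#' @export
compare_models <- function(fit_tree, fit_h1, margin = 0) {
  stopifnot(inherits(fit_tree, "network_fit"),
            inherits(fit_h1, "network_fit"))
  if (!isTRUE(all.equal(fit_tree$cf_table, fit_h1$cf_table,
                        check.attributes = FALSE))) {
    abort("the two fits were computed on different cf_tables")
  }
  delta <- fit_h1$loglik - fit_tree$loglik
  supported <- delta > margin
  boundary <- fit_h1$gamma_hat < 0.02 || fit_h1$gamma_hat > 0.98
  verdict <- if (supported && !boundary) {
    sprintf("hybrid edge supported (delta pseudo-loglik = %.3f, gamma_hat = %.3f)",
            delta, fit_h1$gamma_hat)
  } else if (boundary) {
    sprintf("no support for hybridization: gamma_hat = %.3f at the boundary (delta = %.3f)",
            fit_h1$gamma_hat, delta)
  } else {
    sprintf("no improvement from the hybrid edge (delta pseudo-loglik = %.3f)",
            delta)
  }
  structure(list(delta = delta, gamma_hat = fit_h1$gamma_hat,
                 hybrid_supported = supported && !boundary,
                 margin = margin, verdict = verdict),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Tree vs one-hybrid network:", x$verdict, "\n")
  invisible(x)
}
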