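#' Read per-locus assembly summaries
#'
#' One row per (locus, taxon, contig) with the fraction of the bait length
#' the contig covers. Fractions may exceed 1 when contigs extend into
#' flanking (e.g. intronic) regions.
#'
#' @param path TSV with columns `locus_id`, `taxon_id`, `contig_id`,
#'   `fraction`.
#' @return a data.frame.
#' @export
read_locus_assemblies <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "taxon_id", "contig_id", "fraction")
  if (!all(need %in% names(df))) {
    abort("assembly table %s must have columns %s", path,
          paste(need, collapse = ", "))
  }
  validate_assemblies(df)
  df
}

validate_assemblies <- function(assemblies) {
  bad <- which(!is.finite(assemblies$fraction) | assemblies$fraction < 0)
  if (length(bad)) {
    abort("negative or non-finite fraction for (locus %s, taxon %s, contig %s)",
          assemblies$locus_id[bad[1]], assemblies$taxon_id[bad[1]],
          assemblies$contig_id[bad[1]])
  }
  key <- paste(assemblies$locus_id, assemblies$taxon_id,
               assemblies$contig_id)
  if (anyDuplicated(key)) {
    abort("duplicate (locus, taxon, contig) record: %s",
          key[anyDuplicated(key)])
  }
  invisible(assemblies)
}

#' Flag putative paralogs by bait-coverage fraction
#'
#' A (locus, taxon) pair is flagged when the taxon assembled two or more
#' contigs for the locus, each covering at least `min_fraction` of the bait
#' length: multiple long contigs for a single-copy target indicate the bait
#' captured more than one gene copy. Flagged pairs lose the locus for that
#' taxon (all copies removed).
#'
#' @param assemblies data.frame as from [read_locus_assemblies()].
#' @param min_fraction flagging threshold on the bait-length fraction, in
#'   `(0, 1]`; default 0.75.
#' @return a data.frame of flagged pairs (`locus_id`, `taxon_id`,
#'   `n_long_contigs`).
#' @examples
#' a <- data.frame(locus_id = "L1", taxon_id = "t1",
#'                 contig_id = c("c1", "c2"), fraction = c(0.9, 0.8))
#' flag_paralogs(a)  # flagged: two contigs >= 0.75
#' @export
flag_paralogs <- function(assemblies, min_fraction = 0.75) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1) {
    abort("min_fraction must be in (0, 1]")
  }
  validate_assemblies(assemblies)
  long <- assemblies[assemblies$fraction >= min_fraction, , drop = FALSE]
  if (nrow(long) == 0L) {
    return(data.frame(locus_id = character(), taxon_id = character(),
                      n_long_contigs = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(contig_id ~ locus_id + taxon_id, data = long,
                          FUN = length)
  names(agg)[3] <- "n_long_contigs"
  out <- agg[agg$n_long_contigs >= 2L, , drop = FALSE]
  out <- out[order(out$locus_id, out$taxon_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Presence/absence matrix of loci across taxa
#'
#' A locus is present for a taxon when at least one contig was assembled and
#' the (locus, taxon) pair was not paralog-flagged.
#'
#' @param assemblies data.frame as from [read_locus_assemblies()].
#' @param flags flagged pairs from [flag_paralogs()] (may have zero rows).
#' @param loci,taxa optional declared locus/taxon universe (defaults to
#'   those observed in `assemblies`), fixing matrix dimensions and order.
#' @return a logical matrix, loci in rows, taxa in columns.
#' @export
presence_matrix <- function(assemblies, flags = NULL, loci = NULL,
                            taxa = NULL) {
  validate_assemblies(assemblies)
  if (is.null(loci)) loci <- unique(assemblies$locus_id)
  if (is.null(taxa)) taxa <- unique(assemblies$taxon_id)
  m <- matrix(FALSE, length(loci), length(taxa),
              dimnames = list(loci, taxa))
  keep <- assemblies$locus_id %in% loci & assemblies$taxon_id %in% taxa
  m[cbind(assemblies$locus_id[keep], assemblies$taxon_id[keep])] <- TRUE
  if (!is.null(flags) && nrow(flags)) {
    fl <- flags$locus_id %in% loci & flags$taxon_id %in% taxa
    m[cbind(flags$locus_id[fl], flags$taxon_id[fl])] <- FALSE
  }
  m
}

#' Keep loci recovered for every required taxon
#'
#' The no-missing-data filter: a locus survives only if it is present
#' (recovered and not paralog-flagged) for every required taxon.
#'
#' @param matrix logical presence matrix from [presence_matrix()].
#' @param required_taxa taxa that must all be present; defaults to every
#'   column of the matrix.
#' @return character vector of kept loci, in the matrix's row order.
#' @export
completeness_filter <- function(matrix, required_taxa = colnames(matrix)) {
  unknown <- setdiff(required_taxa, colnames(matrix))
  if (length(unknown)) {
    abort("unknown taxa in required_taxa: %s",
          paste(unknown, collapse = ", "))
  }
  rn <- rownames(matrix)
  if (is.null(rn)) rn <- character(0)
  if (length(required_taxa) == 0L) return(rn)
  keep <- rowSums(!matrix[, required_taxa, drop = FALSE]) == 0L
  rn[keep]
}
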