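#' Read a bract morphometry table
#'
#' @param path TSV with columns `specimen_id`, `lineage`,
#'   `bract_length_mm`, `tooth_length_mm` and optionally `bract_area_mm2`.
#' @return a validated data.frame of class `bract_records`.
#' @export
read_bract_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "lineage", "bract_length_mm", "tooth_length_mm")
  if (!all(need %in% names(df))) {
    abort("bract table %s must have columns %s", path,
          paste(need, collapse = ", "))
  }
  validate_bracts(df)
  class(df) <- c("bract_records", "data.frame")
  df
}

validate_bracts <- function(records) {
  bad <- which(!is.finite(records$bract_length_mm) |
                 records$bract_length_mm <= 0)
  if (length(bad)) {
    abort("specimen %s: bract length must be > 0",
          records$specimen_id[bad[1]])
  }
  bad <- which(!is.finite(records$tooth_length_mm) |
                 records$tooth_length_mm < 0 |
                 records$tooth_length_mm > records$bract_length_mm)
  if (length(bad)) {
    abort("specimen %s: tooth length must lie in [0, bract length]",
          records$specimen_id[bad[1]])
  }
  invisible(records)
}

#' Bract-tooth length corrected for bract length
#'
#' Tooth length divided by the length of the entire bract, removing
#' variation due to plant or bract age; the resulting ratio is the
#' diagnostic trait for separating the long-toothed relative from the two
#' cryptic cytotypes.
#'
#' @param records a `bract_records` data.frame.
#' @return numeric vector of ratios in `[0, 1]`, named by specimen.
#' @export
corrected_tooth <- function(records) {
  validate_bracts(records)
  setNames(records$tooth_length_mm / records$bract_length_mm,
           records$specimen_id)
}

cohens_d <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  if (sp2 == 0) return(0)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Compare bract-tooth morphology across lineages
#'
#' Summarizes the corrected tooth ratio per lineage (n, mean, sd), fits a
#' per-lineage least-squares regression of tooth length on bract length,
#' and reports two pairwise contrasts on the corrected ratio: tetraploid vs
#' octoploid cytotype (the crypsis check) and creutzburgii vs the pooled
#' cytotypes (the diagnosability check), each with Cohen's d and a
#' Wilcoxon rank-sum p-value. The rank-sum test is descriptive support
#' only, not a formal delimitation test.
#'
#' @param records a `bract_records` data.frame; lineages with fewer than 2
#'   records are excluded with a warning.
#' @return a list of class `morph_report`: `summary` (per-lineage
#'   data.frame with regression slope/intercept), `contrasts` (data.frame
#'   with `d` and `p_ranksum`), and `flags`.
#' @export
lineage_comparison <- function(records) {
  validate_bracts(records)
  counts <- table(records$lineage)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("excluding lineage(s) with < 2 records: ",
            paste(small, collapse = ", "), call. = FALSE)
    records <- records[!records$lineage %in% small, , drop = FALSE]
  }
  if (nrow(records) == 0L) abort("no lineage has >= 2 records")
  ratio <- corrected_tooth(records)
  lineages <- sort(unique(records$lineage))
  flags <- character(0)
  summ <- do.call(rbind, lapply(lineages, function(lin) {
    sel <- records$lineage == lin
    r <- ratio[sel]
    if (stats::var(records$bract_length_mm[sel]) > 0) {
      fit <- coef(lm(tooth_length_mm ~ bract_length_mm,
                     data = records[sel, ]))
      slope <- unname(fit[2])
      intercept <- unname(fit[1])
    } else {
      slope <- NA_real_
      intercept <- NA_real_
      flags <<- c(flags, sprintf(
        "lineage %s: bract lengths do not vary; regression undefined", lin))
    }
    data.frame(lineage = lin, n = sum(sel), mean_ratio = mean(r),
               sd_ratio = sd(r), slope = slope, intercept = intercept,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  contrast <- function(label, x, y) {
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
    data.frame(contrast = label, d = cohens_d(x, y), p_ranksum = p,
               n1 = length(x), n2 = length(y), stringsAsFactors = FALSE)
  }
  r_of <- function(lin) ratio[records$lineage %in% lin]
  contrasts <- rbind(
    contrast("erinus_4x_vs_8x", r_of("erinus_4x"), r_of("erinus_8x")),
    contrast("creutzburgii_vs_erinus", r_of("creutzburgii"),
             r_of(c("erinus_4x", "erinus_8x")))
  )
  structure(list(summary = summ, contrasts = contrasts, flags = flags),
            class = "morph_report")
}

#' @export
print.morph_report <- function(x, ...) {
  cat("Bract-tooth morphology (corrected ratio = tooth / bract)\n")
  print(x$summary, row.names = FALSE, digits = 3)
  if (!is.null(x$contrasts)) {
    cat("contrasts:\n")
    print(x$contrasts, row.names = FALSE, digits = 3)
  }
  for (f in x$flags) cat("note:", f, "\n")
  invisible(x)
}
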