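#' Pipeline configuration
#'
#' One configuration object driving the whole chain
#' simulate -> qc -> bin -> cf -> fit -> morph. Stages can be toggled off;
#' disabled downstream stages are skipped. All randomness flows from the
#' root `seed`, split deterministically per stage.
#'
#' @param out_dir output directory (created if needed).
#' @param seed root integer seed.
#' @param stages character subset of
#'   `c("simulate", "qc", "bin", "cf", "fit", "morph")`.
#' @param gamma,scale network parameters for the simulation stage.
#' @param n_genes,samples_per_lineage simulation sizes.
#' @param n_bracts bract specimens per lineage for the morphology stage.
#' @param support_threshold bootstrap threshold for relaxed binning.
#' @param min_fraction paralog-flagging threshold for the qc stage.
#' @param trees_file,map_file,assembly_file,bract_file optional paths to
#'   empirical inputs; when `NULL` the simulate stage's outputs are used.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "qc", "bin", "cf",
                                       "fit", "morph"),
                            gamma = 0.534, scale = 1, n_genes = 130L,
                            samples_per_lineage = 2L, n_bracts = 50L,
                            support_threshold = 80, min_fraction = 0.75,
                            trees_file = NULL, map_file = NULL,
                            assembly_file = NULL, bract_file = NULL) {
  known <- c("simulate", "qc", "bin", "cf", "fit", "morph")
  if (!all(stages %in% known)) {
    abort("unknown stage(s): %s",
          paste(setdiff(stages, known), collapse = ", "))
  }
  if (!is_count(seed)) abort("seed must be a count >= 1")
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
         gamma = gamma, scale = scale, n_genes = n_genes,
         samples_per_lineage = samples_per_lineage, n_bracts = n_bracts,
         support_threshold = support_threshold,
         min_fraction = min_fraction, trees_file = trees_file,
         map_file = map_file, assembly_file = assembly_file,
         bract_file = bract_file),
    class = "pipeline_config"
  )
}

# deterministic per-stage seeds derived from the root seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, qc = 211L, bin = 307L, cf = 401L, fit = 503L,
            morph = 601L)
  (seed * 977L + offs[[stage]]) %% 2147483647L
}

#' Run the full discordance-analysis pipeline
#'
#' Executes the enabled stages in order and writes per-stage outputs plus an
#' aggregated `report.json` under `config$out_dir`. With the simulate stage
#' enabled, gene trees with supports, the lineage map and a bract table are
#' generated from [default_roucela_network()]; otherwise the configured
#' input files are used. The report aggregates bin counts, clade CFs for
#' the two focal sister relationships, the quartet CF table summary, the
#' tree-vs-network comparison and the morphology report, along with seed
#' and threshold provenance. Identical configurations yield byte-identical
#' reports.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("roucela")),
      seed = config$seed,
      support_threshold = config$support_threshold,
      min_fraction = config$min_fraction,
      stages = config$stages
    )
  )
  on <- function(stage) stage %in% config$stages
  trees <- NULL
  map <- NULL

  if (on("simulate")) {
    log_stage("simulate", sprintf("%d genes on the default network (gamma = %g)",
                                  config$n_genes, config$gamma))
    net <- default_roucela_network(config$gamma, config$scale)
    cfg <- sim_config(n_genes = config$n_genes,
                      samples_per_lineage = config$samples_per_lineage,
                      seed = stage_seed(config$seed, "simulate"))
    trees <- simulate_gene_trees(net, cfg)
    trees <- attach_support(trees, cfg)
    map <- attr(trees, "lineage_map")
    write_gene_trees(trees, file.path(config$out_dir, "gene_trees.nwk"))
    write_lineage_map(map, file.path(config$out_dir, "lineages.tsv"))
    bracts <- simulate_bracts(config$n_bracts,
                              seed = stage_seed(config$seed, "morph"))
    utils::write.table(bracts, file.path(config$out_dir, "bracts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$simulate <- list(n_genes = length(trees),
                            gamma_true = config$gamma,
                            scale = config$scale,
                            parental_path_minor_frac =
                              mean(attr(trees, "parental_paths") == "minor"))
  } else {
    if (is.null(config$trees_file) || is.null(config$map_file)) {
      abort("without the simulate stage, trees_file and map_file are required")
    }
    trees <- read_gene_trees(config$trees_file)
    map <- read_lineage_map(config$map_file)
  }

  if (on("qc") && !is.null(config$assembly_file)) {
    log_stage("qc", sprintf("paralog flagging at fraction >= %g",
                            config$min_fraction))
    asm <- read_locus_assemblies(config$assembly_file)
    flags <- flag_paralogs(asm, config$min_fraction)
    pm <- presence_matrix(asm, flags)
    kept <- completeness_filter(pm)
    utils::write.table(flags, file.path(config$out_dir, "paralog_flags.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(kept, file.path(config$out_dir, "kept_loci.txt"))
    report$qc <- list(n_flagged_pairs = nrow(flags),
                      n_loci_in = nrow(pm), n_loci_kept = length(kept))
  }

  hyp <- hypothesis_spec(hybrid = "erinus8x", parent1 = "erinus4x",
                         parent2 = "creutzburgii", outgroup = "outgroup",
                         support_threshold = config$support_threshold)

  if (on("bin")) {
    log_stage("bin", sprintf("%d gene trees", length(trees)))
    bins <- bin_gene_trees(trees, hyp, map,
                           seed = stage_seed(config$seed, "bin"))
    utils::write.table(bins$audit,
                       file.path(config$out_dir, "per_tree_bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$bins <- list(strict = as.list(bins$strict),
                        strict_freq = as.list(bins$strict_freq),
                        relaxed = as.list(bins$relaxed),
                        relaxed_freq = as.list(bins$relaxed_freq))
  }

  cf_tab <- NULL
  if (on("cf")) {
    log_stage("cf", "clade and quartet concordance factors")
    lineages <- sort(unique(map$lineage))
    samples_of <- function(lin) map$sample_id[map$lineage == lin]
    cf_t2 <- clade_cf(trees, c(samples_of("erinus8x"),
                               samples_of("creutzburgii")))
    cf_t1 <- clade_cf(trees, c(samples_of("erinus8x"),
                               samples_of("erinus4x")))
    cf_tab <- quartet_cf_table(trees, map, lineages,
                               seed = stage_seed(config$seed, "cf"))
    write_quartet_cf(cf_tab, file.path(config$out_dir, "quartet_cf.tsv"))
    report$concordance <- list(
      clade_cf_hybrid_parent2 = cf_t2$cf,
      clade_cf_hybrid_parent1 = cf_t1$cf,
      n_quartets = nrow(cf_tab)
    )
  }

  if (on("fit")) {
    if (is.null(cf_tab)) abort("fit stage needs the cf stage")
    log_stage("fit", "tree vs one-hybrid network pseudolikelihood")
    fseed <- stage_seed(config$seed, "fit")
    fit_tree <- fit_network(cf_tab, gamma_fixed = 0, seed = fseed)
    fit_h1 <- fit_network(cf_tab, seed = fseed)
    cmp <- compare_models(fit_tree, fit_h1)
    report$fit <- list(
      gamma_hat = fit_h1$gamma_hat,
      t_hat = as.list(fit_h1$t_hat),
      loglik_h1 = fit_h1$loglik,
      loglik_tree = fit_tree$loglik,
      delta = cmp$delta,
      hybrid_supported = cmp$hybrid_supported,
      verdict = cmp$verdict
    )
    jsonlite::write_json(report$fit, file.path(config$out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (on("morph")) {
    log_stage("morph", "bract-tooth comparison")
    bract_path <- config$bract_file %||%
      file.path(config$out_dir, "bracts.tsv")
    if (file.exists(bract_path)) {
      morph <- lineage_comparison(read_bract_table(bract_path))
      report$morphology <- list(
        summary = morph$summary,
        contrasts = morph$contrasts,
        flags = morph$flags
      )
      jsonlite::write_json(report$morphology,
                           file.path(config$out_dir, "morph_report.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(report)
}
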