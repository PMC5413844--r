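#!/usr/bin/env Rscript
# Stage 5: the bract-tooth morphometric comparison behind the "cryptic"
# claim: tooth length corrected by bract length should separate the
# long-toothed creutzburgii from both erinus cytotypes while leaving the
# tetraploid and octoploid indistinguishable.

suppressPackageStartupMessages(library(roucela))

out <- "results/morphology"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

bracts <- read_bract_table("results/synthetic/bracts.tsv")
report <- lineage_comparison(bracts)
print(report)

jsonlite::write_json(
  list(summary = report$summary, contrasts = report$contrasts,
       flags = report$flags),
  file.path(out, "morph_report.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "rows", pretty = TRUE)
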