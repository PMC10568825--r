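#!/usr/bin/env Rscript
# Stage 3: per-variant meta-analysis of the harmonized panel.
#
# Combines the harmonized studies with both the inverse-variance
# fixed-effects method and the sample-size-weighted z-score method and
# writes one results table per method under results/meta/.

library(bovmeta)

stopifnot(dir.exists("results/qc"))
hfiles <- list.files("results/qc", "_harmonized\\.tsv$", full.names = TRUE)
ids <- sub("_harmonized\\.tsv$", "", basename(hfiles))
studies <- lapply(hfiles, read_sumstats)
names(studies) <- ids

panel <- build_common_panel(studies)
panel <- align_effect_alleles(panel)

dir.create("results/meta", showWarnings = FALSE, recursive = TRUE)
for (mm in c("fixed", "zscore")) {
  res <- run_meta(panel, method = mm)
  write_meta_results(res, file.path("results/meta", paste0(mm, ".tsv")))
  top <- head(res[order(-res$mlogp), ], 5)
  cat(sprintf("\n%s meta-analysis: %d variants combined (%d skipped); top signals:\n",
              mm, nrow(res), attr(res, "n_skipped")))
  print(top[, c("chrom", "pos", "direction", "k_studies", "z", "mlogp")],
        row.names = FALSE)
}
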