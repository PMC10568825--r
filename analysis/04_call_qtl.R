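#!/usr/bin/env Rscript
# Stage 4: QTL calling and cross-analysis comparison.
#
# Applies the genome-wide threshold (-log10 p = 8.7, i.e. 5% Bonferroni
# for ~25M tests) and the upper-third +/- 2 Mb confidence-interval rule
# to each within-population scan and to both meta-analyses, then
# tabulates how the QTL sets compare.  Writes QTL tables and BED
# exports under results/qtl/ and the comparison under results/.

library(bovmeta)

stopifnot(dir.exists("results/meta"), dir.exists("results/qc"))
sets <- list()
for (f in list.files("results/qc", "_harmonized\\.tsv$", full.names = TRUE)) {
  id <- sub("_harmonized\\.tsv$", "", basename(f))
  sets[[id]] <- detect_qtl(read_sumstats(f))
}
for (mm in c("fixed", "zscore")) {
  sets[[mm]] <- detect_qtl(
    read_meta_results(file.path("results/meta", paste0(mm, ".tsv"))))
}

dir.create("results/qtl", showWarnings = FALSE, recursive = TRUE)
for (nm in names(sets)) {
  tab <- sets[[nm]]
  utils::write.table(
    data.frame(CHR = tab$chrom, LEAD_POS = tab$lead_pos,
               LEAD_REF = tab$lead_ref, LEAD_ALT = tab$lead_alt,
               LEAD_MLOG10P = tab$lead_mlogp, CI_START = tab$ci_start,
               CI_END = tab$ci_end, N_CI_VARIANTS = tab$n_ci_variants,
               CI_SIZE_KB = tab$ci_size_kb),
    file.path("results/qtl", paste0(nm, "_qtl.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(tab) > 0) {
    write_qtl_bed(tab, file.path("results/qtl", paste0(nm, "_ci.bed")))
  }
}

cmp <- compare_analyses(sets)
utils::write.table(cmp$per_set, "results/qtl_comparison_per_set.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cmp$pairwise, "results/qtl_comparison_pairwise.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("QTL per analysis:\n")
print(cmp$per_set, row.names = FALSE)
cat("\npairwise region matching (inclusive CI overlap):\n")
print(cmp$pairwise, row.names = FALSE)
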