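#!/usr/bin/env Rscript
# Stage 2: quality control and harmonization of the per-population
# summary statistics written by stage 1.
#
# Standardizes effects to genetic-SD units, applies the MAF (>= 0.005)
# and imputation-R2 (>= 0.20) filters, removes |beta| > 5 SD outliers,
# keeps variants carried concordantly by at least two populations, and
# aligns every effect to the canonical ALT allele.  Writes harmonized
# per-study tables and a QC report under results/qc/.

library(bovmeta)
library(yaml)

stopifnot(dir.exists("results/sim"))
ss_files <- list.files("results/sim", "_sumstats\\.tsv$", full.names = TRUE)
ids <- sub("_sumstats\\.tsv$", "", basename(ss_files))
records <- lapply(ss_files, read_sumstats)
metas <- lapply(file.path("results/sim", paste0(ids, "_meta.yml")),
                read_study_meta)
names(records) <- names(metas) <- ids

panel <- harmonize_studies(records, metas)
print(panel)

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
for (id in ids) {
  write_sumstats(panel$studies[[id]],
                 file.path("results/qc", paste0(id, "_harmonized.tsv")))
}
rep <- panel$qc_report
write_yaml(list(n_sites_seen = rep$n_sites_seen,
                n_single_study = rep$n_single_study,
                n_discordant = rep$n_discordant,
                n_retained = rep$n_retained,
                per_study_kept = as.list(rep$per_study_kept),
                per_study_filters = lapply(rep$per_study_filters, as.list)),
           "results/qc/qc_report.yml")

for (id in ids) {
  f <- rep$per_study_filters[[id]]
  cat(sprintf("%s: %d in, %d MAF-removed, %d R2-removed, %d outliers, %d kept\n",
              id, f["n_input"], f["removed_maf"], f["removed_info"],
              f["removed_outlier"], f["n_final"]))
}
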