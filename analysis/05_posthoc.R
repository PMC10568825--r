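#!/usr/bin/env Rscript
# Stage 5: post-GWAS annotation, enrichment and colocalization.
#
# Builds SYNTHETIC annotation resources keyed to the simulated
# coordinate space (a consequence table with realistic category
# proportions, a QTL-interval database in which meat/carcass records
# cluster near the planted loci, and an e/sQTL table with regulatory
# hits at the causal variants), then runs the three post-GWAS
# summaries on the fixed-effects QTL: consequence distribution of CI
# variants, interval-database enrichment with BH-FDR < 0.05, and
# GWAS x eQTL colocalization (pan-tissue, lowest nominal p per
# variant).  Outputs under results/posthoc/.

library(bovmeta)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
set.seed(seed + 50000L)

stopifnot(dir.exists("results/meta"), dir.exists("results/sim"))
res <- read_meta_results("results/meta/fixed.tsv")
qtl <- detect_qtl(res)
truth <- read.delim("results/sim/truth.tsv")

dir.create("results/posthoc", showWarnings = FALSE, recursive = TRUE)

## ---- synthetic consequence table (all panel variants) --------------------
vocab <- setdiff(consequence_vocabulary(), "other")
weights <- c(58, 28, 6, 5, 0.6, 0.5, 0.4, 0.25,
             rep(0.1, length(vocab) - 8))
cons <- data.frame(CHR = res$chrom, POS = res$pos, REF = res$ref,
                   ALT = res$alt,
                   CONSEQUENCE = sample(vocab, nrow(res), TRUE,
                                        prob = weights / sum(weights)))
write.table(cons, "results/posthoc/synthetic_consequences.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cons_tab <- read_consequences("results/posthoc/synthetic_consequences.tsv")

ci_variants <- unique(unlist(qtl$members))
if (length(ci_variants) > 0) {
  pct <- consequence_distribution(ci_variants, cons_tab)
  write.table(data.frame(CATEGORY = names(pct), PERCENT = pct),
              "results/posthoc/consequence_distribution.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("consequence distribution of", length(ci_variants),
      "CI variants (top):\n")
  print(round(head(sort(pct, decreasing = TRUE), 5), 2))
}

## ---- synthetic interval database: meat/carcass records cluster at QTL ----
cats <- c("Milk", "Production", "Meat_and_Carcass", "Reproduction",
          "Health", "Exterior")
n_bg <- 120
db <- data.frame(
  CHR = "1",
  START = sample.int(max(res$pos), n_bg),
  CATEGORY = sample(cats, n_bg, TRUE, prob = c(.45, .2, .1, .1, .1, .05)),
  stringsAsFactors = FALSE)
db$END <- db$START + sample(2e4:2e5, n_bg, TRUE)
near <- data.frame(
  CHR = "1",
  START = rep(pmax(1, truth$POS - 5e4), each = 2),
  CATEGORY = "Meat_and_Carcass")
near$END <- near$START + 1e5
db <- rbind(db, near)
db$NAME <- sprintf("QTLdb_%03d", seq_len(nrow(db)))
write.table(db[, c("CHR", "START", "END", "CATEGORY", "NAME")],
            "results/posthoc/synthetic_qtldb.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

enr <- region_enrichment(qtl, read_intervals("results/posthoc/synthetic_qtldb.tsv"))
write.table(enr, "results/posthoc/enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nQTL-type enrichment (FDR < 0.05 flagged):\n")
print(enr, row.names = FALSE)

## ---- synthetic e/sQTL table: regulatory hits at the causal variants ------
bg <- res[sample.int(nrow(res), 150), ]
mk_eqtl <- function(d, gene, tissue, kind, p, p_adj) {
  data.frame(CHR = d$chrom, POS = d$pos, REF = d$ref, ALT = d$alt,
             GENE = gene, TISSUE = tissue, KIND = kind, P = p,
             P_ADJ = p_adj, stringsAsFactors = FALSE)
}
eq <- rbind(
  mk_eqtl(bg, sprintf("GENE%03d", seq_len(nrow(bg))),
          sample(c("Muscle", "Liver", "Adipose", "Pituitary"), nrow(bg), TRUE),
          sample(c("eQTL", "sQTL"), nrow(bg), TRUE),
          runif(nrow(bg), 1e-4, 1), runif(nrow(bg), 0.05, 1)),
  mk_eqtl(res[res$pos %in% truth$POS, ], "CAUSAL_GENE",
          "Muscle_taurus", "eQTL", 1e-8, 0.01))
write.table(eq, "results/posthoc/synthetic_eqtl.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cs <- coloc_summary(res, read_eqtl("results/posthoc/synthetic_eqtl.tsv"))
print(cs)
write.table(cs$joint, "results/posthoc/coloc_joint.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cs$counts, "results/posthoc/coloc_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(cs$enrichment, r = cs$correlation$r),
            "results/posthoc/coloc_enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
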