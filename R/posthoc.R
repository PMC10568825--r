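#' Consequence-category distribution of CI variants
#'
#' Tabulates the functional-consequence categories of the variants lying
#' in QTL confidence intervals, as percentages over all supplied
#' variants, in the fixed vocabulary order (see
#' \code{\link{consequence_vocabulary}}).  Variants absent from the
#' consequence table are counted as \code{"other"} with a warning.
#'
#' @param ci_variants Character vector of variant ids
#'   (\code{chrom:pos:ref:alt}), e.g. unlisted \code{members} of a
#'   \code{\link{detect_qtl}} table.
#' @param table Consequence table from \code{\link{read_consequences}}.
#' @return Named numeric vector of percentages (one entry per vocabulary
#'   category, summing to 100).
#' @export
consequence_distribution <- function(ci_variants, table) {
  if (length(ci_variants) == 0) {
    stop("no CI variants supplied", call. = FALSE)
  }
  key <- variant_id(table$chrom, table$pos, table$ref, table$alt)
  idx <- match(ci_variants, key)
  cons <- table$consequence[idx]
  if (anyNA(idx)) {
    warning(sprintf("%d CI variant(s) absent from the consequence table; counted as 'other'",
                    sum(is.na(idx))), call. = FALSE)
    cons[is.na(idx)] <- "other"
  }
  counts <- table(factor(cons, levels = .consequence_vocab))
  setNames(100 * as.vector(counts) / length(ci_variants),
           .consequence_vocab)
}

#' QTL-type enrichment against an interval database
#'
#' For each trait-type category of an interval database (e.g. a cattle
#' QTL database export), tests whether database records of that category
#' are over-represented among records overlapping any QTL confidence
#' interval.  Overlap means any base-pair intersection between a
#' database interval and a CI (both 1-based inclusive).  The null is
#' hypergeometric over database records: with \code{N} records in
#' total, \code{K} of the category, \code{n} overlapping any CI and
#' \code{k} of the category overlapping, the upper-tail p-value is
#' \eqn{P(X \ge k)} for \eqn{X \sim}
#' Hypergeometric\eqn{(N, K, n)}.  P-values are Benjamini-Hochberg
#' adjusted across categories and a category is flagged enriched iff
#' its FDR is strictly below \code{fdr_cutoff}.
#'
#' @param regions QTL table from \code{\link{detect_qtl}}.
#' @param db Interval database from \code{\link{read_intervals}}.
#' @param fdr_cutoff Enrichment retention cutoff (default 0.05, strict).
#' @return \code{data.frame}: \code{category, observed, expected, p,
#'   fdr, enriched}, ordered by increasing p.
#' @export
region_enrichment <- function(regions, db, fdr_cutoff = 0.05) {
  if (nrow(db) == 0) stop("interval database is empty", call. = FALSE)
  hit <- vapply(seq_len(nrow(db)), function(i) {
    any(regions$chrom == db$chrom[i] &
          regions$ci_start <= db$end[i] &
          regions$ci_end >= db$start[i])
  }, logical(1))
  N <- nrow(db)
  n <- sum(hit)
  cats <- sort(unique(db$category))
  K <- vapply(cats, function(cc) sum(db$category == cc), numeric(1))
  k <- vapply(cats, function(cc) sum(hit & db$category == cc), numeric(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(
    category = cats, observed = as.integer(k),
    expected = n * K / N, p = p,
    fdr = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$enriched <- res$fdr < fdr_cutoff
  res <- res[order(res$p, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' GWAS x e/sQTL colocalization summary
#'
#' Overlap-based colocalization between meta-analysis results and
#' cis-e/sQTL records sharing the variant coordinate space.  A variant
#' counts as colocalized iff its meta-analysis p-value is strictly below
#' \code{gwas_nominal_p} (default 2e-9, i.e. Bonferroni-adjusted
#' p < 0.05 for ~25 million tests) and it carries an e/sQTL record with
#' adjusted p strictly below \code{eqtl_adj_p} (default 0.05; the
#' adjusted p is taken as given from the input table).  In
#' \code{pan_tissue} mode all tissues are considered and, when a
#' variant has records in several tissues, the record with the lowest
#' nominal p is retained; \code{multi_tissue} mode first restricts to
#' the supplied \code{tissues} and then retains the lowest-p record
#' within them.  Separately per QTL kind (eQTL, sQTL) the summary
#' reports colocalized counts per tissue, a two-sided Fisher exact test
#' for over-representation of regulatory variants among
#' meta-significant variants (2x2 over all meta-analyzed variants), and
#' the Pearson correlation of \eqn{-\log_{10} p} between the two
#' analyses over jointly tested variants.
#'
#' @param results Meta-analysis results (see \code{\link{run_meta}}).
#' @param eqtl e/sQTL table from \code{\link{read_eqtl}}.
#' @param gwas_nominal_p GWAS nominal significance threshold.
#' @param eqtl_adj_p e/sQTL adjusted-p threshold.
#' @param mode \code{"pan_tissue"} or \code{"multi_tissue"}.
#' @param tissues Tissue subset, required for \code{multi_tissue} mode.
#' @return An object of class \code{"coloc_summary"}: list with
#'   \code{counts} (tissue x kind colocalized counts),
#'   \code{enrichment} (per kind: 2x2 cells and Fisher p),
#'   \code{correlation} (per kind: joint-variant count and Pearson r),
#'   and \code{joint} (scatter-ready per-variant table with
#'   \code{mlogp_meta} and \code{mlogp_eqtl}).
#' @export
coloc_summary <- function(results, eqtl, gwas_nominal_p = 2e-9,
                          eqtl_adj_p = 0.05,
                          mode = c("pan_tissue", "multi_tissue"),
                          tissues = NULL) {
  mode <- match.arg(mode)
  stopifnot(gwas_nominal_p > 0, gwas_nominal_p < 1,
            eqtl_adj_p > 0, eqtl_adj_p <= 1)
  if (mode == "multi_tissue") {
    if (is.null(tissues)) {
      stop("multi_tissue mode needs a tissue subset", call. = FALSE)
    }
    eqtl <- eqtl[eqtl$tissue %in% tissues, , drop = FALSE]
  }
  gwas_thr_mlogp <- -log10(gwas_nominal_p)
  rid <- variant_id(results$chrom, results$pos, results$ref, results$alt)
  meta_sig <- results$mlogp > gwas_thr_mlogp

  kinds <- c("eQTL", "sQTL")
  counts <- enr <- corr <- joint <- list()
  for (kd in kinds) {
    e <- eqtl[eqtl$kind == kd, , drop = FALSE]
    eid <- variant_id(e$chrom, e$pos, e$ref, e$alt)
    # retain the most significant record (lowest nominal p) per variant
    if (nrow(e) > 0) {
      ord <- order(eid, e$p)
      e <- e[ord, , drop = FALSE]
      eid <- eid[ord]
      first <- !duplicated(eid)
      e <- e[first, , drop = FALSE]
      eid <- eid[first]
    }
    idx <- match(rid, eid)
    has_reg <- !is.na(idx) & e$p_adj[idx] < eqtl_adj_p
    has_reg[is.na(has_reg)] <- FALSE
    both <- meta_sig & has_reg

    sel <- which(!is.na(idx))
    jt <- data.frame(
      variant = rid[sel],
      tissue = e$tissue[idx[sel]],
      kind = rep(kd, length(sel)),
      gene = e$gene[idx[sel]],
      mlogp_meta = results$mlogp[sel],
      mlogp_eqtl = -log10(e$p[idx[sel]]),
      eqtl_p_adj = e$p_adj[idx[sel]],
      meta_significant = meta_sig[sel],
      colocalized = both[sel],
      stringsAsFactors = FALSE
    )
    joint[[kd]] <- jt

    if (any(both)) {
      tb <- table(e$tissue[idx[both]])
      counts[[kd]] <- data.frame(tissue = names(tb), kind = kd,
                                 n_colocalized = as.integer(tb),
                                 stringsAsFactors = FALSE)
    }
    n11 <- sum(meta_sig & has_reg); n10 <- sum(meta_sig & !has_reg)
    n01 <- sum(!meta_sig & has_reg); n00 <- sum(!meta_sig & !has_reg)
    pf <- if (sum(n11, n10, n01, n00) > 0) {
      fisher.test(matrix(c(n11, n01, n10, n00), nrow = 2))$p.value
    } else NA_real_
    enr[[kd]] <- data.frame(kind = kd, n_sig_reg = n11, n_sig_only = n10,
                            n_reg_only = n01, n_neither = n00,
                            fisher_p = pf, stringsAsFactors = FALSE)
    r <- if (nrow(jt) >= 2 && sd(jt$mlogp_meta) > 0 &&
             sd(jt$mlogp_eqtl) > 0) {
      cor(jt$mlogp_meta, jt$mlogp_eqtl)
    } else NA_real_
    corr[[kd]] <- data.frame(kind = kd, n_joint = nrow(jt), r = r,
                             stringsAsFactors = FALSE)
  }
  counts <- if (length(counts)) do.call(rbind, counts) else
    data.frame(tissue = character(0), kind = character(0),
               n_colocalized = integer(0))
  rownames(counts) <- NULL
  structure(list(
    counts = counts,
    enrichment = do.call(rbind, enr),
    correlation = do.call(rbind, corr),
    joint = do.call(rbind, joint),
    mode = mode,
    gwas_nominal_p = gwas_nominal_p,
    eqtl_adj_p = eqtl_adj_p
  ), class = "coloc_summary")
}

#' @export
print.coloc_summary <- function(x, ...) {
  cat(sprintf("colocalization summary (%s mode, GWAS p < %g, e/sQTL adj p < %g)\n",
              x$mode, x$gwas_nominal_p, x$eqtl_adj_p))
  for (kd in c("eQTL", "sQTL")) {
    e <- x$enrichment[x$enrichment$kind == kd, ]
    r <- x$correlation[x$correlation$kind == kd, ]
    cat(sprintf("  %s: %d colocalized, Fisher p = %s, r(-log10 p) = %s over %d joint variants\n",
                kd, e$n_sig_reg,
                format(e$fisher_p, digits = 3),
                format(r$r, digits = 3), r$n_joint))
  }
  invisible(x)
}
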