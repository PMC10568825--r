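#' Standardize variant effects to genetic-standard-deviation units
#'
#' Divides each study's effect estimates and standard errors by the
#' trait's genetic standard deviation so that effects are comparable
#' across populations measuring the trait in different units or with
#' different variability.  P-values are untouched (the Wald statistic is
#' scale-invariant).
#'
#' @param records Summary-statistics \code{data.frame}.
#' @param genetic_sd Genetic standard deviation in trait units (> 0).
#' @return The records with \code{beta} and \code{se} rescaled.
#' @export
standardize_effects <- function(records, genetic_sd) {
  if (!is.numeric(genetic_sd) || length(genetic_sd) != 1L ||
      !is.finite(genetic_sd) || genetic_sd <= 0) {
    stop("genetic_sd must be a single positive number", call. = FALSE)
  }
  records$beta <- records$beta / genetic_sd
  records$se <- records$se / genetic_sd
  records
}

#' Filter variants on minor allele frequency and imputation accuracy
#'
#' Keeps a variant iff \code{maf >= maf_min} and \code{info_r2 >=
#' info_min} (both inclusive, mirroring the ">=" filter rules).  A
#' missing MAF or INFO_R2 fails its criterion.  The report counts, per
#' criterion, how many rows failed it (a row failing both is counted
#' under both), plus the total removed.
#'
#' @param records Summary-statistics \code{data.frame}.
#' @param maf_min MAF threshold in (0, 0.5); 0.005 for large cohorts,
#'   0.02 for small ones.
#' @param info_min Imputation-R² threshold in [0, 1]; default 0.20.
#' @return \code{list(kept = <records>, report = <named counts>)}.
#' @export
filter_variants <- function(records, maf_min = 0.005, info_min = 0.20) {
  stopifnot(maf_min > 0, maf_min < 0.5, info_min >= 0, info_min <= 1)
  ok_maf <- !is.na(records$maf) & records$maf >= maf_min
  ok_info <- !is.na(records$info_r2) & records$info_r2 >= info_min
  keep <- ok_maf & ok_info
  list(
    kept = records[keep, , drop = FALSE],
    report = c(n_input = nrow(records),
               removed_maf = sum(!ok_maf),
               removed_info = sum(!ok_info),
               removed_total = sum(!keep),
               n_kept = sum(keep))
  )
}

#' Remove outlier effects
#'
#' Drops markers whose absolute standardized effect exceeds \code{k}
#' genetic standard deviations (such effects are overwhelmingly seen for
#' very rare, poorly imputed variants).  Records must already be on the
#' standardized (genetic-SD) scale.
#'
#' @param records Standardized summary-statistics \code{data.frame}.
#' @param k Threshold in genetic-SD units; default 5.
#' @return \code{list(kept = <records>, removed = <records>)}.
#' @export
remove_outliers <- function(records, k = 5) {
  stopifnot(is.numeric(k), length(k) == 1L, k > 0)
  out <- abs(records$beta) > k
  list(kept = records[!out, , drop = FALSE],
       removed = records[out, , drop = FALSE])
}

# internal: site id and unordered allele-pair key per record
.site_id <- function(df) {
  paste(df$chrom, format(df$pos, scientific = FALSE, trim = TRUE),
        sep = ":")
}
.pair_key <- function(df) {
  paste(pmin(df$ref, df$alt), pmax(df$ref, df$alt), sep = "/")
}

#' Build the cross-study harmonized panel
#'
#' Applies the two-partner retention rule: a variant site is kept iff it
#' is present in at least two studies and every study carrying it
#' reports the identical unordered \{REF, ALT\} allele pair.  Studies
#' whose REF/ALT labels are swapped relative to the first study carrying
#' the site are reconciled to that first-seen canonical orientation
#' (label rewrite only; effects still refer to the recorded effect
#' allele until \code{\link{align_effect_alleles}} is applied).  Sites
#' with discordant allele pairs — including strand-ambiguous
#' re-labellings beyond a REF/ALT swap, and sites duplicated within one
#' study — are dropped.
#'
#' @param studies Named list (>= 2) of per-study summary-statistics
#'   \code{data.frame}s, in input order.
#' @return An object of class \code{"harmonized_panel"}: a list with
#'   \code{variants} (canonical \code{chrom,pos,ref,alt} table in
#'   genome order), \code{studies} (per-study records restricted to
#'   retained sites, REF/ALT rewritten to canonical), and
#'   \code{qc_report} (site-level retention counts).
#' @export
build_common_panel <- function(studies) {
  if (!is.list(studies) || length(studies) < 2L) {
    stop("need at least two studies to build a panel", call. = FALSE)
  }
  if (is.null(names(studies)) || anyDuplicated(names(studies))) {
    stop("studies must be a uniquely named list", call. = FALSE)
  }
  per <- lapply(studies, function(df) {
    data.frame(site = .site_id(df), pair = .pair_key(df),
               stringsAsFactors = FALSE)
  })
  all_sites <- unlist(lapply(per, `[[`, "site"), use.names = FALSE)
  all_pairs <- unlist(lapply(per, `[[`, "pair"), use.names = FALSE)

  carriers <- table(all_sites)
  n_pairs <- tapply(all_pairs, all_sites, function(x) length(unique(x)))
  dup_within <- unique(unlist(lapply(per, function(x)
    x$site[duplicated(x$site)]), use.names = FALSE))

  concordant <- names(n_pairs)[n_pairs == 1L]
  concordant <- setdiff(concordant, dup_within)
  multi <- names(carriers)[carriers >= 2L]
  retained <- intersect(concordant, multi)

  # canonical orientation: first study (input order) carrying the site
  canon <- NULL
  remaining <- retained
  for (df in studies) {
    if (length(remaining) == 0) break
    sites <- .site_id(df)
    hit <- sites %in% remaining & !duplicated(sites)
    if (any(hit)) {
      canon <- rbind(canon, df[hit, c("chrom", "pos", "ref", "alt")])
      remaining <- setdiff(remaining, sites[hit])
    }
  }
  lev <- chrom_levels(canon$chrom)
  canon <- canon[order(match(canon$chrom, lev), canon$pos), , drop = FALSE]
  rownames(canon) <- NULL
  canon_site <- .site_id(canon)

  aligned <- lapply(studies, function(df) {
    sites <- .site_id(df)
    keep <- sites %in% retained
    sub <- df[keep, , drop = FALSE]
    idx <- match(.site_id(sub), canon_site)
    # rewrite swapped REF/ALT labels to the canonical orientation
    sub$ref <- canon$ref[idx]
    sub$alt <- canon$alt[idx]
    rownames(sub) <- NULL
    sub
  })

  structure(list(
    variants = canon,
    studies = aligned,
    qc_report = list(
      n_sites_seen = length(carriers),
      n_single_study = sum(!(names(carriers) %in% multi)),
      n_discordant = length(setdiff(names(carriers)[carriers >= 2L],
                                    retained)),
      n_retained = length(retained),
      per_study_kept = vapply(aligned, nrow, integer(1))
    )
  ), class = "harmonized_panel")
}

#' @export
print.harmonized_panel <- function(x, ...) {
  cat(sprintf("harmonized panel: %d variants x %d studies\n",
              nrow(x$variants), length(x$studies)))
  cat(sprintf("  sites seen %d | single-study %d | discordant %d | retained %d\n",
              x$qc_report$n_sites_seen, x$qc_report$n_single_study,
              x$qc_report$n_discordant, x$qc_report$n_retained))
  invisible(x)
}

#' Align effect alleles to the canonical ALT
#'
#' For every retained record, checks that the allele whose dose the
#' effect refers to equals the panel's canonical ALT; where it equals
#' the canonical REF instead, the effect direction is flipped
#' (\code{beta} negated) and the effect allele rewritten.  SE, p-value,
#' MAF and INFO_R2 are unchanged.
#'
#' @param panel A \code{\link{build_common_panel}} result.
#' @return The panel with every study's \code{effect_allele} equal to the
#'   canonical ALT.
#' @export
align_effect_alleles <- function(panel) {
  stopifnot(inherits(panel, "harmonized_panel"))
  canon_site <- .site_id(panel$variants)
  panel$studies <- lapply(seq_along(panel$studies), function(i) {
    df <- panel$studies[[i]]
    if (nrow(df) == 0) return(df)
    idx <- match(.site_id(df), canon_site)
    on_alt <- df$effect_allele == panel$variants$alt[idx]
    on_ref <- df$effect_allele == panel$variants$ref[idx]
    bad <- !(on_alt | on_ref)
    if (any(bad)) {
      j <- which(bad)[1]
      stop(sprintf(
        "study %s: effect allele %s at %s:%s matches neither canonical allele %s/%s",
        names(panel$studies)[i], df$effect_allele[j], df$chrom[j],
        format(df$pos[j], scientific = FALSE), panel$variants$ref[idx[j]],
        panel$variants$alt[idx[j]]), call. = FALSE)
    }
    df$beta[on_ref] <- -df$beta[on_ref]
    df$effect_allele[on_ref] <- panel$variants$alt[idx[on_ref]]
    df
  })
  names(panel$studies) <- names(panel$qc_report$per_study_kept)
  panel
}

#' Full summary-statistics quality control and harmonization
#'
#' Runs the whole per-study QC chain and panel construction:
#' standardization to genetic-SD units, MAF and imputation-R² filtering
#' (per-study MAF threshold from the study metadata), outlier removal
#' (absolute standardized effect > \code{outlier_k}), the two-partner
#' concordance rule, and effect-allele alignment.
#'
#' @param study_records Named list of summary-statistics
#'   \code{data.frame}s (one per study).
#' @param study_metas Named list of \code{\link{study_meta}} objects,
#'   same names.
#' @param info_min Imputation-R² threshold (default 0.20).
#' @param outlier_k Outlier threshold in genetic-SD units (default 5).
#' @return An allele-aligned \code{"harmonized_panel"} whose
#'   \code{qc_report} also carries the per-study filter counts.
#' @export
harmonize_studies <- function(study_records, study_metas,
                              info_min = 0.20, outlier_k = 5) {
  stopifnot(length(study_records) >= 2L,
            identical(names(study_records), names(study_metas)))
  reports <- list()
  cleaned <- lapply(names(study_records), function(id) {
    meta <- study_metas[[id]]
    rec <- standardize_effects(study_records[[id]], meta$genetic_sd)
    flt <- filter_variants(rec, maf_min = meta$maf_threshold,
                           info_min = info_min)
    out <- remove_outliers(flt$kept, k = outlier_k)
    reports[[id]] <<- c(flt$report, removed_outlier = nrow(out$removed),
                        n_final = nrow(out$kept))
    out$kept
  })
  names(cleaned) <- names(study_records)
  panel <- build_common_panel(cleaned)
  panel <- align_effect_alleles(panel)
  panel$qc_report$per_study_filters <- reports
  panel
}
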