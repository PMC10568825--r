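#' Detect QTL by iterative lead-variant selection
#'
#' Scans an association profile chromosome by chromosome.  Repeatedly:
#' (1) the unmasked variant with the largest \eqn{-\log_{10} p} at or
#' above the genome-wide threshold becomes the lead (ties broken by
#' smallest position, then lexicographic REF/ALT); (2) the QTL members
#' are the unmasked variants within \code{window_bp} of the lead whose
#' \eqn{-\log_{10} p} reaches the upper \code{peak_fraction} of the
#' peak, i.e. \eqn{\ge (1 - \code{peak_fraction}) \cdot}
#' lead \eqn{-\log_{10} p}; (3) the confidence interval spans the most
#' distant members; (4) every variant within \code{window_bp} of the
#' lead is masked, so leads of distinct QTL on one chromosome are more
#' than one window apart.  Defaults reproduce the usual sequence-GWAS
#' rule: threshold 8.7 (5\% genome-wide Bonferroni for ~25 million
#' variants), \eqn{\pm} 2 Mb window, upper third of the peak.
#'
#' @param results \code{data.frame} with columns \code{chrom, pos, ref,
#'   alt} and either \code{mlogp} or \code{p} (meta-analysis results or
#'   single-study summary statistics).
#' @param threshold_mlogp Detection threshold on the \eqn{-\log_{10} p}
#'   scale; default \code{genomewide_threshold(0.05, 25e6)} = 8.69897.
#' @param window_bp Half-window around the lead in bp (default 2e6).
#' @param peak_fraction Fraction of the peak that defines CI membership
#'   (default 1/3: the upper third).
#' @return \code{data.frame} of regions in decreasing lead significance:
#'   \code{chrom, lead_pos, lead_ref, lead_alt, lead_mlogp, ci_start,
#'   ci_end, n_ci_variants, ci_size_kb}, plus a \code{members}
#'   list-column of member variant ids (\code{chrom:pos:ref:alt}).
#' @export
detect_qtl <- function(results, threshold_mlogp = genomewide_threshold(),
                       window_bp = 2e6, peak_fraction = 1/3) {
  stopifnot(threshold_mlogp > 0, window_bp > 0,
            peak_fraction > 0, peak_fraction < 1)
  if (is.null(results$mlogp)) {
    if (is.null(results$p)) {
      stop("results need an 'mlogp' or 'p' column", call. = FALSE)
    }
    results$mlogp <- -log10(results$p)
  }
  out <- list()
  for (chr in chrom_levels(results$chrom)) {
    d <- results[results$chrom == chr, , drop = FALSE]
    pos <- d$pos; mlogp <- d$mlogp
    unmasked <- rep(TRUE, nrow(d))
    repeat {
      cand <- which(unmasked & mlogp >= threshold_mlogp)
      if (length(cand) == 0) break
      lead <- cand[order(-mlogp[cand], pos[cand], d$ref[cand],
                         d$alt[cand])][1]
      near <- unmasked & abs(pos - pos[lead]) <= window_bp
      member <- near & mlogp >= (1 - peak_fraction) * mlogp[lead]
      ci <- range(pos[member])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, lead_pos = pos[lead], lead_ref = d$ref[lead],
        lead_alt = d$alt[lead], lead_mlogp = mlogp[lead],
        ci_start = ci[1], ci_end = ci[2],
        n_ci_variants = sum(member),
        ci_size_kb = (ci[2] - ci[1]) / 1000,
        members = I(list(variant_id(chr, pos[member], d$ref[member],
                                    d$alt[member]))),
        stringsAsFactors = FALSE
      )
      unmasked[near] <- FALSE
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), lead_pos = numeric(0),
                      lead_ref = character(0), lead_alt = character(0),
                      lead_mlogp = numeric(0), ci_start = numeric(0),
                      ci_end = numeric(0), n_ci_variants = integer(0),
                      ci_size_kb = numeric(0),
                      members = I(list()), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$lead_mlogp, match(res$chrom, chrom_levels(res$chrom)),
                   res$lead_pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Match QTL between two analyses
#'
#' Two regions match iff they lie on the same chromosome and their
#' confidence intervals overlap (1-based inclusive, so intervals that
#' merely touch match).  Matching is greedy in decreasing lead
#' significance of \code{a}; each region is used at most once.  Among
#' several overlapping candidates the most significant (then
#' left-most) \code{b} region is taken.
#'
#' @param a,b QTL tables from \code{\link{detect_qtl}}.
#' @return \code{list(pairs, unmatched_a, unmatched_b)} where
#'   \code{pairs} is a \code{data.frame} of row indices \code{(a, b)}
#'   into the two inputs.
#' @export
match_qtl <- function(a, b) {
  order_a <- order(-a$lead_mlogp)
  taken_b <- rep(FALSE, nrow(b))
  pairs <- list()
  for (i in order_a) {
    cand <- which(!taken_b & b$chrom == a$chrom[i] &
                    b$ci_start <= a$ci_end[i] & b$ci_end >= a$ci_start[i])
    if (length(cand) == 0) next
    j <- cand[order(-b$lead_mlogp[cand], b$ci_start[cand])][1]
    taken_b[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(a = i, b = j)
  }
  pairs <- if (length(pairs)) {
    as.data.frame(do.call(rbind, pairs))
  } else {
    data.frame(a = integer(0), b = integer(0))
  }
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(nrow(a)), pairs$a),
       unmatched_b = setdiff(seq_len(nrow(b)), pairs$b))
}

#' Summarize a QTL table
#'
#' Count plus mean/min/max of the number of CI variants and of the CI
#' size in kb — the per-analysis summary used to compare
#' within-population GWAS against meta-analyses.
#'
#' @param regions QTL table from \code{\link{detect_qtl}}.
#' @return One-row \code{data.frame}: \code{n_qtl},
#'   \code{{mean,min,max}_ci_variants}, \code{{mean,min,max}_ci_kb}
#'   (NA with zero regions).
#' @export
summarize_qtl <- function(regions) {
  if (nrow(regions) == 0) {
    return(data.frame(n_qtl = 0L, mean_ci_variants = NA_real_,
                      min_ci_variants = NA_real_, max_ci_variants = NA_real_,
                      mean_ci_kb = NA_real_, min_ci_kb = NA_real_,
                      max_ci_kb = NA_real_))
  }
  data.frame(
    n_qtl = nrow(regions),
    mean_ci_variants = mean(regions$n_ci_variants),
    min_ci_variants = min(regions$n_ci_variants),
    max_ci_variants = max(regions$n_ci_variants),
    mean_ci_kb = mean(regions$ci_size_kb),
    min_ci_kb = min(regions$ci_size_kb),
    max_ci_kb = max(regions$ci_size_kb)
  )
}
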