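#' Signed z-statistic from a two-sided p-value
#'
#' Converts a two-sided p-value and an effect direction into a signed
#' standard-normal statistic, \eqn{z = \Phi^{-1}(1 - p/2) \cdot d},
#' computed on the log scale so it stays accurate for p-values down to
#' \eqn{10^{-300}}.
#'
#' @param p Two-sided p-value(s) in (0, 1].
#' @param direction Effect direction(s), +1 or -1.
#' @return Signed z-statistic(s).
#' @examples
#' z_from_p(0.05, 1)   # 1.959964
#' z_from_p(1, -1)     # 0
#' @export
z_from_p <- function(p, direction) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must be in (0, 1]", call. = FALSE)
  }
  if (!all(direction %in% c(-1, 1))) {
    stop("direction must be +1 or -1", call. = FALSE)
  }
  qnorm(log(p) - log(2), lower.tail = FALSE, log.p = TRUE) * direction
}

# internal: signed z from -log10 p (exact for arbitrarily large mlogp)
.z_from_mlogp <- function(mlogp, direction) {
  qnorm(-mlogp * log(10) - log(2), lower.tail = FALSE, log.p = TRUE) *
    direction
}

#' Two-sided -log10 p from a z-statistic
#'
#' \eqn{-\log_{10}(2\,\Phi(-|z|))}, computed on the log scale: never
#' underflows, so meta-analysis peaks with \eqn{-\log_{10} p} in the
#' hundreds keep exact significance values.
#'
#' @param z z-statistic(s).
#' @return \eqn{-\log_{10}} of the two-sided p-value(s).
#' @export
mlogp_from_z <- function(z) {
  -(log(2) + pnorm(-abs(z), log.p = TRUE)) / log(10)
}

#' Genome-wide Bonferroni significance threshold
#'
#' \eqn{-\log_{10}(\alpha/m)}: the genome-wide threshold on the
#' \eqn{-\log_{10} p} scale after Bonferroni correction for \code{m}
#' tests.  With \eqn{\alpha = 0.05} and \eqn{m = 25} million
#' sequence variants this is 8.69897, the usual "8.7" threshold of
#' sequence-level cattle GWAS.
#'
#' @param alpha Genome-wide significance level in (0, 1); default 0.05.
#' @param m Number of tests (>= 1); default 25 million.
#' @return Threshold on the \eqn{-\log_{10} p} scale.
#' @export
genomewide_threshold <- function(alpha = 0.05, m = 25e6) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  log10(m) - log10(alpha)
}

#' Sample-size-weighted z-score meta-analysis of one variant
#'
#' Combines per-study two-sided p-values and effect directions into
#' \eqn{Z = \sum_i z_i w_i / \sqrt{\sum_i w_i^2}} with
#' \eqn{w_i = \sqrt{n_i}} and \eqn{z_i = \Phi^{-1}(1 - p_i/2)\,d_i}.
#' The \eqn{\sqrt{\sum w_i^2}} denominator makes Z standard normal under
#' the null, which the package's null-calibration tests verify
#' empirically.
#'
#' @param p Per-study two-sided p-values (length k >= 2).
#' @param direction Per-study effect directions, +1/-1.
#' @param n Per-study sample sizes (>= 1).
#' @return \code{list(z, mlogp, k_studies, n_total)}.
#' @export
meta_zscore <- function(p, direction, n) {
  k <- length(p)
  if (k < 2L) stop("need at least two studies", call. = FALSE)
  stopifnot(length(direction) == k, length(n) == k, all(n >= 1))
  zi <- z_from_p(p, direction)
  z <- sum(zi * sqrt(n)) / sqrt(sum(n))
  list(z = z, mlogp = mlogp_from_z(z), k_studies = k, n_total = sum(n))
}

#' Inverse-variance fixed-effects meta-analysis of one variant
#'
#' Assumes one true allele effect across studies and combines estimates
#' with inverse-variance weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\hat\beta = \sum w_i \beta_i / \sum w_i},
#' \eqn{se = 1/\sqrt{\sum w_i}}, \eqn{Z = \hat\beta/se}.
#'
#' @param beta Per-study effects in a common (genetic-SD) unit
#'   (length k >= 2).
#' @param se Per-study standard errors (> 0).
#' @return \code{list(beta_meta, se_meta, z, mlogp, k_studies)}.
#' @export
meta_fixed <- function(beta, se) {
  k <- length(beta)
  if (k < 2L) stop("need at least two studies", call. = FALSE)
  if (length(se) != k || any(is.na(se)) || any(se <= 0)) {
    stop("se must be positive for every study", call. = FALSE)
  }
  w <- 1 / se^2
  beta_meta <- sum(w * beta) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  z <- beta_meta / se_meta
  list(beta_meta = beta_meta, se_meta = se_meta, z = z,
       mlogp = mlogp_from_z(z), k_studies = k)
}

#' Run a meta-analysis over a harmonized panel
#'
#' Applies \code{\link{meta_fixed}} or \code{\link{meta_zscore}} (in
#' vectorized form) to every panel variant carried by at least
#' \code{min_studies} studies.  Variants with fewer carriers are skipped
#' and counted in the \code{"n_skipped"} attribute.  The per-variant
#' direction string has one character per panel study in panel order:
#' \code{"+"}/\code{"-"} for the sign of the aligned effect,
#' \code{"?"} where the study does not carry the variant.
#'
#' @param panel Allele-aligned \code{"harmonized_panel"} (see
#'   \code{\link{harmonize_studies}}).
#' @param method \code{"fixed"} or \code{"zscore"}.
#' @param min_studies Minimum carrying studies per combined variant
#'   (default 2, mirroring the two-partner retention rule).
#' @return \code{data.frame} with one row per combined variant:
#'   \code{chrom, pos, ref, alt, effect_allele, method, k_studies,
#'   n_total, direction, beta_meta, se_meta, z, mlogp}, in panel
#'   (genome) order.  \code{beta_meta}/\code{se_meta} are \code{NA} for
#'   the z-score method.
#' @export
run_meta <- function(panel, method = c("fixed", "zscore"),
                     min_studies = 2L) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "harmonized_panel"), min_studies >= 2L)
  canon <- panel$variants
  nv <- nrow(canon)
  ns <- length(panel$studies)
  canon_site <- .site_id(canon)

  B <- SE <- P <- N <- matrix(NA_real_, nrow = nv, ncol = ns)
  for (j in seq_len(ns)) {
    df <- panel$studies[[j]]
    if (nrow(df) == 0) next
    if (!all(df$effect_allele == df$alt)) {
      stop("panel is not allele-aligned; run align_effect_alleles() first",
           call. = FALSE)
    }
    idx <- match(.site_id(df), canon_site)
    B[idx, j] <- df$beta
    SE[idx, j] <- df$se
    P[idx, j] <- df$p
    N[idx, j] <- df$n
  }
  present <- !is.na(B)
  k_studies <- rowSums(present)
  keep <- k_studies >= min_studies
  n_skipped <- sum(!keep & k_studies > 0)

  dir_chr <- matrix("?", nrow = nv, ncol = ns)
  dir_chr[present & B < 0] <- "-"
  dir_chr[present & B >= 0] <- "+"
  direction <- do.call(paste0, as.data.frame(dir_chr))

  n_total <- rowSums(N, na.rm = TRUE)
  if (method == "fixed") {
    W <- 1 / SE^2
    sw <- rowSums(W, na.rm = TRUE)
    beta_meta <- rowSums(W * B, na.rm = TRUE) / sw
    se_meta <- 1 / sqrt(sw)
    z <- beta_meta / se_meta
  } else {
    Zi <- matrix(NA_real_, nrow = nv, ncol = ns)
    ok <- !is.na(P)
    Zi[ok] <- z_from_p(P[ok], ifelse(B[ok] >= 0, 1, -1))
    z <- rowSums(Zi * sqrt(N), na.rm = TRUE) / sqrt(n_total)
    beta_meta <- se_meta <- rep(NA_real_, nv)
  }
  res <- data.frame(
    chrom = canon$chrom, pos = canon$pos, ref = canon$ref,
    alt = canon$alt, effect_allele = canon$alt, method = method,
    k_studies = as.integer(k_studies), n_total = n_total,
    direction = direction, beta_meta = beta_meta, se_meta = se_meta,
    z = z, mlogp = mlogp_from_z(z), stringsAsFactors = FALSE
  )
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}
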