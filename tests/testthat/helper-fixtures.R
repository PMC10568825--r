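# fixture builders shared across the suite; everything is generated in
# code so tests carry no data files

sumstat_header <- paste(c("CHR", "POS", "REF", "ALT", "EA", "BETA", "SE",
                          "P", "MAF", "INFO_R2", "N"), collapse = "\t")

# a valid in-memory summary-statistics table
make_sumstats <- function(n = 5, chrom = "1", pos = seq_len(n) * 1000,
                          ref = "A", alt = "G", effect_allele = alt,
                          beta = 0.1, se = 0.05, p = NULL, maf = 0.25,
                          info_r2 = 0.9, nn = 1000) {
  beta <- rep_len(beta, n); se <- rep_len(se, n)
  if (is.null(p)) p <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             effect_allele = rep_len(effect_allele, n),
             beta = beta, se = se, p = rep_len(p, n),
             maf = rep_len(maf, n), info_r2 = rep_len(info_r2, n),
             n = rep_len(nn, n), stringsAsFactors = FALSE)
}

# random per-study record sets over a common variant space, for
# harmonization and meta-analysis property tests
random_studies <- function(n_studies = 3, n_variants = 40, seed = 1,
                           present_prob = 0.8) {
  set.seed(seed)
  base <- make_sumstats(n_variants,
                        ref = sample(c("A", "C"), n_variants, TRUE),
                        alt = sample(c("G", "T"), n_variants, TRUE))
  out <- lapply(seq_len(n_studies), function(i) {
    # study 1 carries everything, so it is always the orientation donor
    keep <- if (i == 1) rep(TRUE, n_variants) else
      runif(n_variants) < present_prob
    df <- base[keep, , drop = FALSE]
    m <- nrow(df)
    df$beta <- rnorm(m, 0, 0.2)
    df$se <- runif(m, 0.02, 0.2)
    df$p <- pmax(2 * pnorm(-abs(df$beta / df$se)), 1e-300)
    df$n <- sample(500:5000, 1)
    rownames(df) <- NULL
    df
  })
  names(out) <- paste0("S", seq_len(n_studies))
  out
}

# swap REF/ALT labels of chosen rows of one study, re-expressing the same
# association (effect allele string is untouched; labels only)
swap_orientation <- function(df, rows = seq_len(nrow(df))) {
  tmp <- df$ref[rows]
  df$ref[rows] <- df$alt[rows]
  df$alt[rows] <- tmp
  df
}

# re-encode a study on the opposite effect allele: equivalent information
flip_effect_allele <- function(df, rows = seq_len(nrow(df))) {
  other <- ifelse(df$effect_allele[rows] == df$alt[rows],
                  df$ref[rows], df$alt[rows])
  df$effect_allele[rows] <- other
  df$beta[rows] <- -df$beta[rows]
  df
}

default_metas <- function(studies, genetic_sd = 1) {
  metas <- lapply(names(studies), function(id) {
    study_meta(study_id = id, n = studies[[id]]$n[1] %||% 1000,
               genetic_sd = genetic_sd)
  })
  names(metas) <- names(studies)
  metas
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# random association profile for QTL-caller tests: background noise plus
# a few planted peaks with decaying shoulders
random_profile <- function(n = 500, n_peaks = 3, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(20e6, n))
  mlogp <- abs(rnorm(n, 2, 1.5))
  for (i in seq_len(n_peaks)) {
    centre <- sample.int(20e6, 1)
    height <- runif(1, 9, 40)
    d <- abs(pos - centre)
    mlogp <- pmax(mlogp, height * pmax(0, 1 - d / runif(1, 3e5, 3e6)))
  }
  data.frame(chrom = "1", pos = pos,
             ref = sample(c("A", "C", "G", "T"), n, TRUE),
             alt = sample(c("A", "C", "G", "T"), n, TRUE),
             mlogp = mlogp, stringsAsFactors = FALSE)
}

# independent brute-force QTL caller used as oracle: literal re-scan
# after each masking step, no shared code with detect_qtl
oracle_qtl <- function(d, thr = 8.7, window = 2e6, frac = 1/3) {
  regions <- list()
  for (chr in unique(d$chrom)) {
    dd <- d[d$chrom == chr, ]
    dd <- dd[order(dd$pos), ]
    alive <- rep(TRUE, nrow(dd))
    repeat {
      best <- NULL
      for (i in which(alive)) {
        if (dd$mlogp[i] < thr) next
        if (is.null(best)) best <- i
        else if (dd$mlogp[i] > dd$mlogp[best]) best <- i
        else if (dd$mlogp[i] == dd$mlogp[best]) {
          if (dd$pos[i] < dd$pos[best]) best <- i
          else if (dd$pos[i] == dd$pos[best]) {
            if (dd$ref[i] < dd$ref[best] ||
                (dd$ref[i] == dd$ref[best] && dd$alt[i] < dd$alt[best])) {
              best <- i
            }
          }
        }
      }
      if (is.null(best)) break
      inwin <- alive & abs(dd$pos - dd$pos[best]) <= window
      memb <- inwin & dd$mlogp >= (1 - frac) * dd$mlogp[best]
      regions[[length(regions) + 1L]] <- list(
        chrom = chr, lead_pos = dd$pos[best],
        lead_mlogp = dd$mlogp[best],
        ci_start = min(dd$pos[memb]), ci_end = max(dd$pos[memb]),
        n_members = sum(memb))
      alive[inwin] <- FALSE
    }
  }
  regions
}

# brute-force Benjamini-Hochberg: sort, p * N / rank, cumulative min
# from the largest p down, restore input order
oracle_bh <- function(p) {
  N <- length(p)
  o <- order(p)
  adj <- p[o] * N / seq_len(N)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(N)
  out[o] <- adj
  out
}
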