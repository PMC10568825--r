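test_that("standardization divides effects and SEs by the genetic SD", {
  ss <- make_sumstats(3, beta = 0.5, se = 0.2, p = 0.0124)
  out <- standardize_effects(ss, 2)
  expect_equal(out$beta, rep(0.25, 3))
  expect_equal(out$se, rep(0.1, 3))
  expect_equal(out$p, ss$p)             # p untouched
  expect_equal(standardize_effects(ss, 1), ss)
  expect_error(standardize_effects(ss, 0), "positive")
})

test_that("MAF and R2 filters are inclusive at the threshold", {
  ss <- make_sumstats(5, maf = c(0.004, 0.005, 0.3, 0.3, 0.3),
                      info_r2 = c(0.9, 0.9, 0.19, 0.20, 0.9))
  out <- filter_variants(ss, maf_min = 0.005, info_min = 0.20)
  expect_equal(out$kept$pos, c(2000, 4000, 5000))
  expect_equal(unname(out$report["removed_maf"]), 1)
  expect_equal(unname(out$report["removed_info"]), 1)
  expect_equal(unname(out$report["n_kept"]), 3)
  # empty input passes through
  empty <- filter_variants(ss[0, ])
  expect_equal(nrow(empty$kept), 0L)
})

test_that("outlier rule removes |standardized beta| above k", {
  ss <- make_sumstats(3, beta = c(5.1, -4.9, 0))
  out <- remove_outliers(ss, k = 5)
  expect_equal(out$kept$beta, c(-4.9, 0))
  expect_equal(out$removed$beta, 5.1)
  zero <- remove_outliers(make_sumstats(4, beta = 0))
  expect_equal(nrow(zero$removed), 0L)
})

test_that("two-partner rule keeps concordant multi-study sites only", {
  s1 <- make_sumstats(3, pos = c(100, 200, 300), ref = "A", alt = "C")
  s2 <- make_sumstats(2, pos = c(100, 200), ref = "A",
                      alt = c("C", "G"))              # 200 discordant
  s3 <- make_sumstats(1, pos = 400, ref = "T", alt = "G")  # single study
  panel <- build_common_panel(list(a = s1, b = s2, c = s3))
  expect_equal(panel$variants$pos, 100)
  expect_equal(panel$qc_report$n_discordant, 1)
  expect_equal(panel$qc_report$n_single_study, 2)  # 300 (s1), 400 (s3)
  expect_error(build_common_panel(list(a = s1)), "two studies")
})

test_that("swapped REF/ALT labels are reconciled to first-seen orientation", {
  s1 <- make_sumstats(2, pos = c(100, 200), ref = "A", alt = "C",
                      effect_allele = "C", beta = 0.3)
  s2 <- swap_orientation(
    make_sumstats(2, pos = c(100, 200), ref = "A", alt = "C",
                  effect_allele = "C", beta = 0.3))
  panel <- build_common_panel(list(a = s1, b = s2))
  expect_equal(nrow(panel$variants), 2L)
  expect_equal(panel$variants$ref, c("A", "A"))      # canonical = study a
  expect_equal(panel$studies$b$ref, c("A", "A"))     # labels rewritten
  expect_equal(panel$studies$b$effect_allele, c("C", "C"))
})

test_that("variant present concordantly in 3 of 5 studies is kept", {
  base <- make_sumstats(1, pos = 7777, ref = "G", alt = "T")
  other <- make_sumstats(1, pos = 1, ref = "A", alt = "C")
  studies <- list(a = base, b = base, c = base, d = other, e = other)
  panel <- build_common_panel(studies)
  expect_true(7777 %in% panel$variants$pos)
  expect_equal(sum(vapply(panel$studies, function(s) 7777 %in% s$pos,
                          logical(1))), 3L)
})

test_that("two-partner rule matches a brute-force enumeration oracle", {
  for (seed in 1:5) {
    studies <- random_studies(n_studies = 5, n_variants = 100, seed = seed,
                              present_prob = 0.5)
    # corrupt some allele pairs to create discordance
    set.seed(seed + 100)
    for (j in seq_along(studies)) {
      rows <- which(runif(nrow(studies[[j]])) < 0.05)
      studies[[j]]$alt[rows] <- ifelse(studies[[j]]$alt[rows] == "G",
                                       "T", "G")
    }
    panel <- build_common_panel(studies)
    # oracle: enumerate all (site, study) pairs directly
    tab <- do.call(rbind, lapply(studies, function(s) {
      data.frame(site = paste(s$chrom, s$pos), pair = paste(
        pmin(s$ref, s$alt), pmax(s$ref, s$alt)))
    }))
    keep <- vapply(unique(tab$site), function(sid) {
      sub <- tab[tab$site == sid, ]
      nrow(sub) >= 2 && length(unique(sub$pair)) == 1
    }, logical(1))
    expect_setequal(paste(panel$variants$chrom, panel$variants$pos),
                    unique(tab$site)[keep])
  }
})

test_that("effect alleles align to the canonical ALT with direction flips", {
  s1 <- make_sumstats(2, pos = c(10, 20), ref = "A", alt = "G",
                      effect_allele = "G", beta = 0.3)
  s2 <- flip_effect_allele(
    make_sumstats(2, pos = c(10, 20), ref = "A", alt = "G",
                  effect_allele = "G", beta = 0.3))
  expect_equal(s2$effect_allele, c("A", "A"))
  panel <- align_effect_alleles(build_common_panel(list(a = s1, b = s2)))
  expect_equal(panel$studies$b$effect_allele, c("G", "G"))
  expect_equal(panel$studies$b$beta, c(0.3, 0.3))   # flipped back
  expect_equal(panel$studies$a$beta, c(0.3, 0.3))   # untouched

  s2$effect_allele <- "T"                            # foreign allele
  expect_error(align_effect_alleles(build_common_panel(list(a = s1, b = s2))),
               "study b.*matches neither")
})

test_that("re-encoding one study leaves the panel and meta results identical", {
  studies <- random_studies(n_studies = 3, n_variants = 50, seed = 11)
  metas <- default_metas(studies)
  base <- harmonize_studies(studies, metas)
  base_fixed <- run_meta(base, "fixed")
  base_z <- run_meta(base, "zscore")

  # flip study 2 (not the orientation donor): exact identity expected
  flipped <- studies
  flipped$S2 <- flip_effect_allele(swap_orientation(studies$S2))
  alt <- harmonize_studies(flipped, metas)
  expect_equal(alt$variants, base$variants)
  expect_equal(run_meta(alt, "fixed"), base_fixed)
  expect_equal(run_meta(alt, "zscore"), base_z)

  # flip study 1 (the donor): labels may swap, significance must not move
  flipped1 <- studies
  flipped1$S1 <- flip_effect_allele(swap_orientation(studies$S1))
  alt1 <- harmonize_studies(flipped1, metas)
  f1 <- run_meta(alt1, "fixed")
  expect_equal(f1$mlogp, base_fixed$mlogp)
  expect_equal(abs(f1$beta_meta), abs(base_fixed$beta_meta))
})

test_that("row-local filters compose in any order", {
  set.seed(3)
  ss <- make_sumstats(200, beta = rnorm(200, 0, 3),
                      maf = runif(200, 0, 0.5),
                      info_r2 = runif(200))
  a <- remove_outliers(filter_variants(ss, 0.01, 0.3)$kept, 5)$kept
  b <- filter_variants(remove_outliers(ss, 5)$kept, 0.01, 0.3)$kept
  c1 <- filter_variants(remove_outliers(
    filter_variants(ss, 0.01, 0)$kept, 5)$kept, 0.01, 0.3)$kept
  expect_equal(a[order(a$pos), ], b[order(b$pos), ])
  expect_equal(a[order(a$pos), ], c1[order(c1$pos), ])
})
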