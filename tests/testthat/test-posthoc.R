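cons_table <- function() {
  data.frame(
    chrom = "1", pos = c(100, 200, 300, 400), ref = "A", alt = "G",
    consequence = c("Intergenic_region", "Intergenic_region",
                    "Intron_variant", "Missense_variant"),
    stringsAsFactors = FALSE)
}

test_that("consequence distribution gives vocabulary-ordered percentages", {
  ids <- paste("1", c(100, 200, 300, 400), "A", "G", sep = ":")
  pct <- consequence_distribution(ids, cons_table())
  expect_equal(names(pct), consequence_vocabulary())
  expect_equal(unname(pct["Intergenic_region"]), 50)
  expect_equal(unname(pct["Intron_variant"]), 25)
  expect_equal(unname(pct["Missense_variant"]), 25)
  expect_equal(sum(pct), 100, tolerance = 0.01)

  # all one category
  pct1 <- consequence_distribution(ids[1:2], cons_table())
  expect_equal(unname(pct1["Intergenic_region"]), 100)

  # unknown variant -> 'other', with a warning; still sums to 100
  expect_warning(pct2 <- consequence_distribution(
    c(ids, "9:9:A:G"), cons_table()), "other")
  expect_equal(unname(pct2["other"]), 20)
  expect_equal(sum(pct2), 100, tolerance = 0.01)

  expect_error(consequence_distribution(character(0), cons_table()),
               "no CI variants")
})

test_that("percentages sum to 100 on random inputs", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(3:50, 1)
    tab <- data.frame(chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
                      consequence = sample(consequence_vocabulary(), n,
                                           replace = TRUE))
    ids <- paste("1", seq_len(n), "A", "G", sep = ":")
    expect_equal(sum(consequence_distribution(ids, tab)), 100,
                 tolerance = 0.01)
  }
})

region_fixture <- function(ci = cbind(c(1e6, 8e6), c(2e6, 9e6))) {
  data.frame(chrom = "1", lead_pos = rowMeans(ci), lead_ref = "A",
             lead_alt = "G", lead_mlogp = 12, ci_start = ci[, 1],
             ci_end = ci[, 2], n_ci_variants = 5L,
             ci_size_kb = (ci[, 2] - ci[, 1]) / 1000,
             stringsAsFactors = FALSE)
}

test_that("interval enrichment uses the upper-tail hypergeometric null", {
  # db: category X concentrated in the CIs, category Y outside
  db <- data.frame(
    chrom = "1",
    start = c(seq(1e6, 1.9e6, length.out = 5), seq(20e6, 24e6, length.out = 15)),
    end = c(seq(1e6, 1.9e6, length.out = 5) + 1e4,
            seq(20e6, 24e6, length.out = 15) + 1e4),
    category = rep(c("X", "Y"), c(5, 15)),
    name = paste0("r", 1:20), stringsAsFactors = FALSE)
  # arrange overlaps: all 5 X plus 3 Y inside CIs
  db$start[6:8] <- 8.1e6; db$end[6:8] <- 8.2e6
  res <- region_enrichment(region_fixture(), db)
  x <- res[res$category == "X", ]
  # N = 20, K = 5, n = 8, k = 5: exact combinatorial oracle
  p_exact <- sum(vapply(5:5, function(i)
    choose(5, i) * choose(15, 8 - i) / choose(20, 8), numeric(1)))
  expect_equal(x$p, p_exact, tolerance = 1e-12)
  expect_equal(x$observed, 5L)
  expect_equal(x$expected, 8 * 5 / 20)
  expect_equal(res$enriched, res$fdr < 0.05)

  # single category, everything overlapping: no enrichment possible
  db1 <- db; db1$category <- "X"
  res1 <- region_enrichment(region_fixture(cbind(0, 30e6)), db1)
  expect_equal(res1$p, 1)
  expect_false(any(res1$enriched))

  # no overlap at all: p = 1 everywhere
  far <- region_fixture(cbind(40e6, 41e6))
  res2 <- region_enrichment(far, db)
  expect_true(all(res2$p == 1))
  expect_false(any(res2$enriched))

  expect_error(region_enrichment(region_fixture(), db[0, ]), "empty")
})

test_that("enrichment p-values match exact summation on small instances", {
  set.seed(31)
  for (i in 1:10) {
    N <- sample(10:30, 1)
    db <- data.frame(chrom = "1",
                     start = sample.int(1e6, N), category = sample(c("A", "B", "C"), N, TRUE),
                     name = paste0("x", 1:N), stringsAsFactors = FALSE)
    db$end <- db$start + 100
    regions <- region_fixture(cbind(1, sample.int(1e6, 1)))
    res <- region_enrichment(regions, db)
    hit <- db$end >= regions$ci_start[1] & db$start <= regions$ci_end[1]
    n <- sum(hit)
    for (j in seq_len(nrow(res))) {
      K <- sum(db$category == res$category[j])
      k <- res$observed[j]
      exact <- sum(vapply(k:min(K, n), function(i)
        choose(K, i) * choose(N - K, n - i) / choose(N, n), numeric(1)))
      expect_equal(res$p[j], exact, tolerance = 1e-10)
    }
  }
})

test_that("BH adjustment matches a brute-force implementation", {
  set.seed(13)
  for (i in 1:8) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

coloc_fixture <- function() {
  res <- data.frame(
    chrom = "6", pos = c(1, 2, 3, 4) * 1e6, ref = "A", alt = "G",
    effect_allele = "G", method = "fixed", k_studies = 3L,
    n_total = 6000, direction = "+++",
    beta_meta = 0.4, se_meta = 0.05,
    z = c(8, 7, 3, 1),
    mlogp = c(15, 10, 2.5, 0.4), stringsAsFactors = FALSE)
  eq <- data.frame(
    chrom = "6", pos = c(1e6, 1e6, 2e6, 3e6), ref = "A", alt = "G",
    gene = c("MED28", "MED28", "SLIT2", "LCORL"),
    tissue = c("Liver", "Muscle", "Muscle", "Adipose"),
    kind = "eQTL",
    p = c(1e-4, 1e-6, 1e-3, 1e-5),
    p_adj = c(0.01, 0.02, 0.01, 0.06), stringsAsFactors = FALSE)
  list(res = res, eq = eq)
}

test_that("colocalization counts joint-significant variants per tissue", {
  fx <- coloc_fixture()
  cs <- coloc_summary(fx$res, fx$eq)
  # variant 1e6: meta mlogp 15 > 8.7 and pan-tissue record = Muscle (1e-6)
  # variant 2e6: meta 10 > 8.7, p_adj 0.01 -> counted (Muscle)
  # variant 3e6: not meta-significant
  expect_equal(sum(cs$counts$n_colocalized), 2L)
  expect_equal(cs$counts$tissue, "Muscle")
  expect_equal(cs$counts$n_colocalized, 2L)
  jt <- cs$joint[cs$joint$kind == "eQTL", ]
  expect_equal(jt$tissue[jt$variant == "6:1000000:A:G"], "Muscle")

  # boundary: adjusted p exactly at the cutoff is not significant
  eq2 <- fx$eq; eq2$p_adj <- 0.05
  cs2 <- coloc_summary(fx$res, eq2)
  expect_equal(sum(cs2$counts$n_colocalized), 0L)

  # multi-tissue mode restricts the candidate records
  cs3 <- coloc_summary(fx$res, fx$eq, mode = "multi_tissue",
                       tissues = "Liver")
  expect_equal(sum(cs3$counts$n_colocalized), 1L)
  expect_equal(cs3$counts$tissue, "Liver")

  # empty e/sQTL table: zero counts, undefined correlation
  cs4 <- coloc_summary(fx$res, fx$eq[0, ])
  expect_equal(nrow(cs4$counts), 0L)
  expect_true(all(is.na(cs4$correlation$r)))
})

test_that("variant ids format positions without scientific notation", {
  fx <- coloc_fixture()
  cs <- coloc_summary(fx$res, fx$eq)
  expect_true(all(grepl("^6:[0-9]+:", cs$joint$variant)))
})

test_that("coloc counts shrink as either threshold tightens", {
  fx <- coloc_fixture()
  n_at <- function(gp, ep) {
    cs <- coloc_summary(fx$res, fx$eq, gwas_nominal_p = gp,
                        eqtl_adj_p = ep)
    sum(cs$counts$n_colocalized)
  }
  base <- n_at(2e-9, 0.05)
  expect_lte(n_at(1e-12, 0.05), base)
  expect_lte(n_at(2e-9, 0.015), base)
  expect_gte(n_at(1e-3, 0.1), base)
})

test_that("correlation uses jointly tested variants on the -log10 scale", {
  fx <- coloc_fixture()
  cs <- coloc_summary(fx$res, fx$eq)
  jt <- cs$joint
  expect_equal(cs$correlation$r[cs$correlation$kind == "eQTL"],
               cor(jt$mlogp_meta, jt$mlogp_eqtl))
  expect_true(abs(cs$correlation$r[1]) <= 1)
})
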