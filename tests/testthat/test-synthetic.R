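small_cfg <- function(seed = 202, ...) {
  sim_config(n_pops = 3, n_per_pop = c(400, 300, 250), n_variants = 300,
             block_size = 30, seed = seed, ...)
}

test_that("simulation is deterministic under the seed", {
  cfg <- small_cfg()
  a <- simulate_populations(cfg)
  b <- simulate_populations(cfg)
  expect_identical(a, b)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- make_study_set(cfg, d1)
  f2 <- make_study_set(cfg, d2)
  for (id in names(f1$sumstats)) {
    expect_identical(readLines(f1$sumstats[[id]]),
                     readLines(f2$sumstats[[id]]))
  }
  expect_identical(readLines(f1$truth), readLines(f2$truth))
  # a different seed changes the data
  f3 <- make_study_set(small_cfg(seed = 203), tempfile())
  expect_false(identical(readLines(f1$sumstats[[1]]),
                         readLines(f3$sumstats[[1]])))
})

test_that("blockwise streaming generation equals the in-memory panels", {
  cfg <- small_cfg()
  pan <- simulate_populations(cfg)
  sim <- simulate_studies(cfg)
  # recompute study 1's scan directly from the full panel
  ph <- simulate_phenotypes(
    pan$pops[[1]]$dosage_true[, cfg$causal$index, drop = FALSE], cfg, 1)
  direct <- run_single_variant_gwas(pan$pops[[1]]$dosage, ph$y, ph$weights,
                                    variants = pan$variants,
                                    info_r2 = pan$pops[[1]]$info_r2)
  expect_equal(sim$records$POP1, direct, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero divergence keeps population frequencies at the ancestral", {
  cfg <- small_cfg(fst = 0)
  pan <- simulate_populations(cfg)
  expect_equal(pan$pops[[1]]$freq, pan$pops[[2]]$freq)
  # and with divergence they differ
  pan2 <- simulate_populations(small_cfg(fst = 0.2))
  expect_gt(mean(abs(pan2$pops[[1]]$freq - pan2$pops[[2]]$freq)), 0.01)
})

test_that("rho = 0 leaves adjacent dosages essentially uncorrelated", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 2000, n_variants = 200,
                    block_size = 50, rho = 0, fst = 0, seed = 5,
                    info_r2_range = c(1, 1))
  pan <- simulate_populations(cfg)
  X <- pan$pops[[1]]$dosage
  adj <- vapply(seq_len(ncol(X) - 1), function(j)
    abs(cor(X[, j], X[, j + 1])), numeric(1))
  expect_lt(mean(adj), 0.05)
  # and with rho = 0.9 adjacent variants are strongly correlated
  cfg2 <- sim_config(n_pops = 2, n_per_pop = 2000, n_variants = 200,
                     block_size = 50, rho = 0.9, fst = 0, seed = 5,
                     info_r2_range = c(1, 1))
  X2 <- simulate_populations(cfg2)$pops[[1]]$dosage
  adj2 <- vapply(seq_len(50)[-50], function(j)
    cor(X2[, j], X2[, j + 1]), numeric(1))
  expect_gt(mean(adj2), 0.5)
})

test_that("imputation noise hits the target dosage R2", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 4000, n_variants = 100,
                    block_size = 25, rho = 0.5, info_r2_range = c(0.3, 0.9),
                    seed = 77)
  pan <- simulate_populations(cfg)
  p1 <- pan$pops[[1]]
  r2 <- vapply(seq_len(100), function(j)
    cor(p1$dosage[, j], p1$dosage_true[, j])^2, numeric(1))
  expect_lt(mean(abs(r2 - p1$info_r2)), 0.03)
})

test_that("degenerate configurations are refused", {
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(fst = 0.5), "fst")
  expect_error(sim_config(h2_poly = 1), "h2_poly")
  expect_error(sim_config(ancestral_maf_range = c(0, 0.5)))
  expect_error(small_cfg(causal = data.frame(index = 1)), "missing column")
  expect_error(small_cfg(causal = data.frame(index = 1e6, shared = TRUE,
                                             beta_1 = 1, beta_2 = 1,
                                             beta_3 = 1)),
               "out of range")
})

test_that("association scan is calibrated under the null", {
  # no causal variants, no polygenic term: y independent of all dosages
  cfg <- sim_config(n_pops = 2, n_per_pop = 1500, n_variants = 400,
                    block_size = 40, h2_poly = 0, rho = 0.2,
                    causal = data.frame(index = 1L, shared = TRUE,
                                        beta_1 = 0, beta_2 = 0),
                    seed = 31)
  reps <- lapply(1:30, function(i) {
    cfg$seed <- 31L + i
    sim <- simulate_studies(cfg)
    sim$records$POP1$p
  })
  p <- unlist(reps)
  expect_gt(length(p), 10000)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
  expect_lt(abs(mean(p < 0.01) - 0.01), 0.005)
})

test_that("planted effects are recovered without bias", {
  # b = 0.5 genetic-SD at a common variant, n = 2000
  cfg0 <- sim_config(n_pops = 2, n_per_pop = 2000, n_variants = 40,
                     block_size = 10, fst = 0, rho = 0.5,
                     ancestral_maf_range = c(0.3, 0.3),
                     info_r2_range = c(1, 1),
                     causal = data.frame(index = 20L, shared = TRUE,
                                         beta_1 = 0.5, beta_2 = 0.5),
                     seed = 1)
  est <- vapply(1:60, function(i) {
    cfg0$seed <- 1000L + i
    sim <- simulate_studies(cfg0)
    r <- sim$records$POP1
    r$beta[r$pos == sim$truth$pos[1]]
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 3 * mc_se)

  # realized variant-explained variance matches 2 p (1-p) b^2 of the
  # genetic variance (closed-form decomposition), within MC error
  exp_frac <- 2 * 0.3 * 0.7 * 0.25
  sim <- simulate_studies(cfg0)
  frac <- 2 * sim$truth$freq_1 * (1 - sim$truth$freq_1) * 0.25
  expect_equal(frac, exp_frac, tolerance = 0.1)
})

test_that("monomorphic variants are excluded and counted", {
  set.seed(2)
  X <- cbind(rbinom(200, 2, 0.3), rep(2, 200), rbinom(200, 2, 0.4))
  y <- rnorm(200)
  out <- run_single_variant_gwas(X, y)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_monomorphic"), 1)
  expect_error(run_single_variant_gwas(X, rep(1, 200)), "constant")
})

test_that("study sets produce one file trio per population plus truth", {
  cfg <- small_cfg()
  d <- tempfile()
  files <- make_study_set(cfg, d)
  expect_length(files$sumstats, 3L)
  expect_length(files$meta, 3L)
  expect_true(file.exists(files$truth))
  m <- read_study_meta(files$meta[["POP2"]])
  expect_equal(m$n, 300)
  expect_equal(m$phenotype_kind, "DYD")
  # sumstats files are readable and validated
  ss <- read_sumstats(files$sumstats[["POP1"]])
  expect_gt(nrow(ss), 250)
})

test_that("opposite-sign population effects attenuate the fixed-effects MA", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 3000, n_variants = 60,
                    block_size = 15, fst = 0.02, rho = 0.3,
                    ancestral_maf_range = c(0.3, 0.4),
                    info_r2_range = c(0.95, 1),
                    causal = data.frame(index = 30L, shared = FALSE,
                                        beta_1 = 0.5, beta_2 = -0.5),
                    seed = 55)
  sim <- simulate_studies(cfg)
  panel <- harmonize_studies(sim$records, sim$metas)
  res <- run_meta(panel, "fixed")
  at <- res[res$pos == sim$truth$pos[1], ]
  per_study <- vapply(sim$records, function(r)
    -log10(r$p[r$pos == sim$truth$pos[1]]), numeric(1))
  expect_true(all(per_study > genomewide_threshold()))
  expect_lt(at$mlogp, min(per_study))     # MA weakens the signal
  expect_lt(abs(at$beta_meta), 0.25)      # shrunk toward zero
})

test_that("weights are heteroscedastic only for DYD/DRP phenotypes", {
  cfg <- small_cfg()
  nc <- nrow(cfg$causal)
  ph1 <- simulate_phenotypes(matrix(0, 400, nc), cfg, 1)  # YD
  ph2 <- simulate_phenotypes(matrix(0, 300, nc), cfg, 2)  # DYD
  expect_true(all(ph1$weights == 1))
  expect_gt(sd(ph2$weights), 0.1)
})
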