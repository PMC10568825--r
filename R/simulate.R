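#' Simulation configuration for multi-population study sets
#'
#' Describes the synthetic multi-population design used to exercise the
#' whole pipeline with known ground truth: several cattle-like
#' populations with Balding-Nichols allele-frequency divergence,
#' blockwise linkage disequilibrium (LD) whose block boundaries and
#' correlation may differ between populations, planted shared and
#' population-specific causal variants in genetic-standard-deviation
#' units, a polygenic background, heteroscedastic phenotype accuracies
#' (YD/DYD/DRP), and imputation noise reported through the INFO_R2
#' column.
#'
#' @param n_pops Number of populations (2-10).
#' @param n_per_pop Per-population sample sizes (recycled).
#' @param n_variants Number of variants on the simulated chromosome.
#' @param block_size Variants per LD block (the number of blocks follows).
#' @param rho Within-block latent correlation between adjacent variants,
#'   in [0, 1); scalar or per-population.
#' @param block_offset Per-population shift (in variants) of the LD block
#'   boundaries; differing offsets emulate population-divergent LD.
#'   Default: population i shifted by (i-1) * block_size / 4.
#' @param fst Balding-Nichols divergence parameter in [0, 0.5).
#' @param ancestral_maf_range Range of ancestral ALT-allele frequencies,
#'   within (0, 0.5].
#' @param causal \code{data.frame} with columns \code{index} (variant
#'   index), \code{shared} (logical) and \code{beta_1..beta_K}
#'   (per-population true effects in genetic-SD units).  \code{NULL}
#'   installs the default plan: four shared effects of 0.45 genetic SD
#'   plus two population-specific effects of 0.6 — the size of the
#'   major growth/muscularity QTL that sequence-level cattle studies
#'   detect.
#' @param h2_poly Polygenic fraction of phenotypic variance in [0, 1).
#' @param info_r2_range Range of per-variant imputation accuracies,
#'   within (0, 1].
#' @param phenotype_kind Per-population phenotype construction
#'   (\code{"YD"}, \code{"DYD"}, \code{"DRP"}; recycled).
#' @param weight_dispersion Coefficient of variation of the per-record
#'   accuracy weights for DYD/DRP phenotypes.
#' @param genetic_sd Per-population genetic SD in trait units (recycled;
#'   1 makes standardization the identity).
#' @param bp_spacing Base pairs between adjacent variants.
#' @param chrom Chromosome label.
#' @param seed Master seed; all per-population streams derive from it.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_pops = 3,
                       n_per_pop = c(3000, 2000, 1200),
                       n_variants = 5000,
                       block_size = 100,
                       rho = 0.9,
                       block_offset = NULL,
                       fst = 0.1,
                       ancestral_maf_range = c(0.05, 0.5),
                       causal = NULL,
                       h2_poly = 0.3,
                       info_r2_range = c(0.15, 1),
                       phenotype_kind = c("YD", "DYD", "DRP"),
                       weight_dispersion = 0.3,
                       genetic_sd = 1,
                       bp_spacing = 3000,
                       chrom = "1",
                       seed = 1L) {
  stopifnot(n_pops >= 2, n_pops <= 10, n_variants >= 2, block_size >= 1)
  if (any(rho < 0) || any(rho >= 1)) {
    stop("rho must be in [0, 1)", call. = FALSE)
  }
  if (fst < 0 || fst >= 0.5) stop("fst must be in [0, 0.5)", call. = FALSE)
  stopifnot(length(ancestral_maf_range) == 2,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
            ancestral_maf_range[1] <= ancestral_maf_range[2])
  stopifnot(h2_poly >= 0, h2_poly < 1)
  stopifnot(length(info_r2_range) == 2, info_r2_range[1] > 0,
            info_r2_range[2] <= 1,
            info_r2_range[1] <= info_r2_range[2])
  stopifnot(weight_dispersion >= 0, bp_spacing >= 1, seed == round(seed))
  cfg <- list(
    n_pops = as.integer(n_pops),
    n_per_pop = as.integer(rep_len(n_per_pop, n_pops)),
    n_variants = as.integer(n_variants),
    block_size = as.integer(block_size),
    rho = rep_len(rho, n_pops),
    block_offset = if (is.null(block_offset)) {
      as.integer((seq_len(n_pops) - 1) * max(1, block_size %/% 4))
    } else as.integer(rep_len(block_offset, n_pops)),
    fst = fst,
    ancestral_maf_range = ancestral_maf_range,
    h2_poly = h2_poly,
    info_r2_range = info_r2_range,
    phenotype_kind = rep_len(match.arg(phenotype_kind,
                                       c("YD", "DYD", "DRP"),
                                       several.ok = TRUE),
                             n_pops),
    weight_dispersion = weight_dispersion,
    genetic_sd = rep_len(genetic_sd, n_pops),
    bp_spacing = as.integer(bp_spacing),
    chrom = as.character(chrom),
    seed = as.integer(seed)
  )
  cfg$causal <- if (is.null(causal)) .default_causal(cfg) else {
    .check_causal(causal, cfg)
  }
  structure(cfg, class = "sim_config")
}

# default plan: four shared causal variants of moderate effect spread
# along the chromosome, plus two population-specific ones
.default_causal <- function(cfg) {
  m <- cfg$n_variants
  idx_shared <- unique(pmax(1L, as.integer(round(m * c(.15, .35, .55, .75)))))
  idx_spec <- unique(pmax(1L, as.integer(round(m * c(.25, .90)))))
  idx_spec <- setdiff(idx_spec, idx_shared)
  K <- cfg$n_pops
  betas <- rbind(
    matrix(0.45, nrow = length(idx_shared), ncol = K),
    t(vapply(seq_along(idx_spec), function(i) {
      b <- rep(0, K); b[1 + (i - 1) %% K] <- 0.6; b
    }, numeric(K)))
  )
  df <- data.frame(index = c(idx_shared, idx_spec),
                   shared = rep(c(TRUE, FALSE),
                                c(length(idx_shared), length(idx_spec))))
  colnames(betas) <- paste0("beta_", seq_len(K))
  cbind(df, betas)
}

.check_causal <- function(causal, cfg) {
  K <- cfg$n_pops
  need <- c("index", "shared", paste0("beta_", seq_len(K)))
  missing <- setdiff(need, names(causal))
  if (length(missing)) {
    stop("causal plan missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(causal$index < 1 | causal$index > cfg$n_variants)) {
    stop("causal index out of range", call. = FALSE)
  }
  causal
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d populations (n = %s), %d variants, blocks of %d, rho = %s, Fst = %g\n",
              x$n_pops, paste(x$n_per_pop, collapse = "/"), x$n_variants,
              x$block_size, paste(format(x$rho), collapse = "/"), x$fst))
  cat(sprintf("  %d causal variants (%d shared), h2_poly = %g, info R2 in [%g, %g], seed %d\n",
              nrow(x$causal), sum(x$causal$shared), x$h2_poly,
              x$info_r2_range[1], x$info_r2_range[2], x$seed))
  invisible(x)
}

# ---- seeded stream splitting ---------------------------------------------
# One stream per (population, block), plus reserved per-population streams
# for frequencies/accuracies, phenotype noise and weights, all derived
# from the master seed; adding a population never perturbs existing ones.
.STREAM_FREQ <- 104500L
.STREAM_PHENO <- 104600L
.STREAM_WEIGHT <- 104650L

.stream_seed <- function(master, pop, block) {
  s <- (as.double(master %% 1000003L) * 1009 + pop * 104729 + block) %%
    2147483647
  as.integer(s) + 1L
}

# ---- variant map (shared across populations) ------------------------------

# internal: chromosome, positions and ref/alt alleles, drawn once from the
# master seed so all populations share one coordinate space
.variant_map <- function(cfg) {
  set.seed(.stream_seed(cfg$seed, 0L, 0L))
  m <- cfg$n_variants
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, m, replace = TRUE)
  alt_i <- (ref_i - 1L + sample.int(3L, m, replace = TRUE)) %% 4L + 1L
  data.frame(chrom = cfg$chrom, pos = as.numeric(seq_len(m)) * cfg$bp_spacing,
             ref = bases[ref_i], alt = bases[alt_i],
             stringsAsFactors = FALSE)
}

# internal: ancestral ALT frequencies (shared) and per-population
# Balding-Nichols frequencies + target imputation accuracies
.pop_freqs <- function(cfg, pop) {
  set.seed(.stream_seed(cfg$seed, 0L, 1L))
  anc <- runif(cfg$n_variants, cfg$ancestral_maf_range[1],
               cfg$ancestral_maf_range[2])
  set.seed(.stream_seed(cfg$seed, pop, .STREAM_FREQ))
  freq <- if (cfg$fst == 0) anc else {
    a <- (1 - cfg$fst) / cfg$fst
    rbeta(cfg$n_variants, anc * a, (1 - anc) * a)
  }
  info <- runif(cfg$n_variants, cfg$info_r2_range[1], cfg$info_r2_range[2])
  list(ancestral = anc, freq = freq, info_r2 = info)
}

# internal: per-population LD block id of every variant
.block_ids <- function(cfg, pop) {
  (seq_len(cfg$n_variants) - 1L + cfg$block_offset[pop]) %/% cfg$block_size
}

# internal: regenerate one LD block of true and observed dosages for one
# population.  Gaussian-threshold haplotypes with AR(1) latent correlation
# rho within the block; imputation noise degrades the true dosage to the
# target R2 in the classic shrink-toward-the-mean (BLUP dosage) form:
# x_obs = m + R2 (x - m) + e with Var(e) = R2 (1 - R2) Var(x), so that
# cor(x_obs, x)^2 = R2 and regression of y on x_obs stays unbiased.
.gen_block <- function(cfg, pop, block, cols, freq, info) {
  n <- cfg$n_per_pop[pop]
  v <- length(cols)
  rho <- cfg$rho[pop]
  set.seed(.stream_seed(cfg$seed, pop, block + 2L))
  E <- matrix(rnorm(2L * n * v), nrow = 2L * n, ncol = v)
  if (rho > 0 && v > 1) {
    a <- sqrt(1 - rho^2)
    for (j in 2:v) E[, j] <- rho * E[, j - 1] + a * E[, j]
  }
  thr <- qnorm(freq[cols])
  A <- sweep(E, 2, thr, `<`)
  X <- A[seq_len(n), , drop = FALSE] + A[n + seq_len(n), , drop = FALSE]
  storage.mode(X) <- "double"
  r2 <- info[cols]
  mu <- colMeans(X)
  vx <- apply(X, 2, var)
  noise_sd <- sqrt(pmax(0, r2 * (1 - r2) * vx))
  Xo <- sweep(sweep(X, 2, mu), 2, r2, `*`)
  Xo <- sweep(Xo, 2, mu, `+`) +
    matrix(rnorm(n * v), nrow = n) * rep(noise_sd, each = n)
  list(true = X, obs = Xo)
}

#' Simulate per-population dosage panels
#'
#' Draws ancestral allele frequencies, diverges them per population with
#' the Balding-Nichols model, generates blockwise-correlated haplotypes
#' by Gaussian thresholding, and degrades the dosages with imputation
#' noise to a per-variant target R².  Fully deterministic under the
#' configured seed.  For configurations whose dosage matrices would be
#' impractically large, \code{\link{simulate_studies}} runs the same
#' generation blockwise without materializing the panels.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{variants} (shared variant map) and
#'   \code{pops}: per population a list of \code{dosage} (observed,
#'   n x m), \code{dosage_true}, \code{freq} (Balding-Nichols target
#'   ALT frequency), \code{freq_realized}, and \code{info_r2}.
#' @export
simulate_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  vm <- .variant_map(config)
  pops <- lapply(seq_len(config$n_pops), function(pop) {
    fr <- .pop_freqs(config, pop)
    bid <- .block_ids(config, pop)
    n <- config$n_per_pop[pop]
    Xo <- Xt <- matrix(0, nrow = n, ncol = config$n_variants)
    for (b in unique(bid)) {
      cols <- which(bid == b)
      g <- .gen_block(config, pop, b, cols, fr$freq, fr$info_r2)
      Xt[, cols] <- g$true
      Xo[, cols] <- g$obs
    }
    list(dosage = Xo, dosage_true = Xt, freq = fr$freq,
         freq_realized = colMeans(Xt) / 2, info_r2 = fr$info_r2)
  })
  list(variants = vm, pops = pops)
}

# internal: per-population true causal effect vector
.causal_beta <- function(cfg, pop) cfg$causal[[paste0("beta_", pop)]]

#' Simulate phenotypes for one population
#'
#' Builds \code{y = causal genetic value + polygenic surrogate +
#' heteroscedastic residual} on a scale where the total genetic standard
#' deviation is exactly one, then multiplies by the population's
#' \code{genetic_sd} to express the trait in its own units.  Causal
#' effects act through the \emph{true} dosages; the polygenic term is an
#' independent Gaussian surrogate (simulated individuals are unrelated,
#' so a relationship-matrix term would be indistinguishable from it)
#' with variance \code{h2_poly} of the phenotypic variance; residuals
#' have variance \eqn{\sigma_e^2 / w_r} with per-record accuracy weights
#' \eqn{w_r} equal to 1 for YD phenotypes and gamma-dispersed around 1
#' for DYD/DRP.
#'
#' @param dosage_true True causal-variant dosage matrix (n x n_causal),
#'   columns in the order of \code{config$causal}.
#' @param config A \code{\link{sim_config}}.
#' @param pop Population index.
#' @return \code{list(y, weights, var_causal, var_poly, var_error)} with
#'   variances on the genetic-SD = 1 scale.
#' @export
simulate_phenotypes <- function(dosage_true, config, pop = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_per_pop[pop]
  beta <- .causal_beta(config, pop)
  gc <- if (length(beta) > 0 && any(beta != 0)) {
    as.vector(dosage_true %*% beta)
  } else {
    rep(0, n)
  }
  var_c <- if (all(gc == 0)) 0 else var(gc)
  if (var_c >= 1) {
    stop("causal effects explain >= 100% of the genetic variance; ",
         "reduce the planted betas", call. = FALSE)
  }
  var_poly <- 1 - var_c
  if (config$h2_poly > 0) {
    var_y <- var_poly / config$h2_poly
    var_e <- var_y - 1
    if (var_e <= 0) {
      stop("h2_poly too large for the planted causal variance",
           call. = FALSE)
    }
  } else {
    # no polygenic background: residual variance set to the (unit)
    # genetic variance, giving a heritability of one half
    var_poly <- 0
    var_e <- 1
  }
  set.seed(.stream_seed(config$seed, pop, .STREAM_WEIGHT))
  w <- if (config$phenotype_kind[pop] == "YD" ||
           config$weight_dispersion == 0) {
    rep(1, n)
  } else {
    shape <- 1 / config$weight_dispersion^2
    rgamma(n, shape = shape, rate = shape)
  }
  set.seed(.stream_seed(config$seed, pop, .STREAM_PHENO))
  g_poly <- if (var_poly > 0) rnorm(n, sd = sqrt(var_poly)) else rep(0, n)
  e <- rnorm(n, sd = sqrt(var_e / w))
  y <- (gc + g_poly + e) * config$genetic_sd[pop]
  list(y = y, weights = w, var_causal = var_c, var_poly = var_poly,
       var_error = var_e)
}

#' Per-variant weighted least-squares association scan
#'
#' Marginal single-variant regression of the phenotype on allele dosage
#' with an intercept, weighted by the per-record accuracy weights (the
#' diagonal of the residual covariance is \eqn{\sigma_e^2/w_r}); the
#' polygenic adjustment of a mixed-model scan is unnecessary for
#' unrelated simulated individuals.  Two-sided p-values come from the
#' t distribution with n - 2 degrees of freedom.  Monomorphic variants
#' are excluded from the output and counted in the
#' \code{"n_monomorphic"} attribute.
#'
#' @param dosage Dosage matrix (n individuals x m variants).
#' @param y Phenotype vector.
#' @param weights Positive per-record weights (default all 1).
#' @param variants Variant map (\code{chrom,pos,ref,alt}) for the
#'   columns; optional.
#' @param info_r2 Per-variant imputation accuracy to report; optional.
#' @return Summary-statistics \code{data.frame} in \link{sumstats-format}
#'   column layout.
#' @export
run_single_variant_gwas <- function(dosage, y, weights = NULL,
                                    variants = NULL, info_r2 = NULL) {
  n <- length(y)
  stopifnot(nrow(dosage) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  if (var(y) == 0) stop("phenotype is constant", call. = FALSE)
  m <- ncol(dosage)
  sw <- sum(weights)
  wy <- weights * y
  ybar <- sum(wy) / sw
  xbar <- colSums(weights * dosage) / sw
  Sxx <- colSums(weights * dosage^2) - sw * xbar^2
  Sxy <- colSums(dosage * wy) - sw * xbar * ybar
  Syy <- sum(wy * y) - sw * ybar^2
  mono <- Sxx <= n * 1e-12
  beta <- Sxy / Sxx
  rss <- pmax(0, Syy - beta * Sxy)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / Sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)
  f <- pmin(1, pmax(0, colMeans(dosage) / 2))
  maf <- pmin(f, 1 - f)
  if (is.null(variants)) {
    variants <- data.frame(chrom = "1", pos = as.numeric(seq_len(m)),
                           ref = "A", alt = "G",
                           stringsAsFactors = FALSE)
  }
  out <- data.frame(
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    alt = variants$alt, effect_allele = variants$alt,
    beta = beta, se = se, p = p, maf = maf,
    info_r2 = if (is.null(info_r2)) rep(NA_real_, m) else info_r2,
    n = n, stringsAsFactors = FALSE
  )
  out <- out[!mono, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_monomorphic") <- sum(mono)
  out
}

#' Simulate a full multi-population study set in memory
#'
#' End-to-end generation: for each population, blockwise dosage
#' generation (never materializing the full panel), phenotype
#' simulation, and the per-variant association scan, yielding one
#' summary-statistics table per population plus study metadata and the
#' ground-truth table of planted effects.
#'
#' @param config A \code{\link{sim_config}}.
#' @param trait Trait label for the study metadata.
#' @return \code{list(records, metas, truth, variants)}: named lists of
#'   per-population summary statistics and \code{\link{study_meta}}
#'   objects, the truth \code{data.frame} (per causal variant: index,
#'   position, shared flag, per-population true beta and realized
#'   causal-variant ALT frequency), and the shared variant map.
#' @export
simulate_studies <- function(config, trait = "trait") {
  stopifnot(inherits(config, "sim_config"))
  vm <- .variant_map(config)
  ci <- config$causal$index
  records <- metas <- list()
  freq_real <- matrix(NA_real_, nrow = length(ci), ncol = config$n_pops)
  for (pop in seq_len(config$n_pops)) {
    fr <- .pop_freqs(config, pop)
    bid <- .block_ids(config, pop)
    n <- config$n_per_pop[pop]
    # pass A: regenerate only the blocks holding causal variants
    Xc <- matrix(0, nrow = n, ncol = length(ci))
    if (length(ci) > 0) {
      for (b in unique(bid[ci])) {
        cols <- which(bid == b)
        g <- .gen_block(config, pop, b, cols, fr$freq, fr$info_r2)
        hit <- ci %in% cols
        Xc[, hit] <- g$true[, match(ci[hit], cols), drop = FALSE]
      }
      freq_real[, pop] <- colMeans(Xc) / 2
    }
    ph <- simulate_phenotypes(Xc, config, pop)
    # pass B: regenerate every block (identical streams) and scan it
    ub <- sort(unique(bid))
    parts <- vector("list", length(ub))
    for (k in seq_along(ub)) {
      b <- ub[k]
      cols <- which(bid == b)
      g <- .gen_block(config, pop, b, cols, fr$freq, fr$info_r2)
      parts[[k]] <- run_single_variant_gwas(
        g$obs, ph$y, ph$weights,
        variants = vm[cols, , drop = FALSE],
        info_r2 = fr$info_r2[cols])
    }
    rec <- do.call(rbind, parts)
    attr(rec, "n_monomorphic") <- sum(vapply(parts, function(x)
      attr(x, "n_monomorphic"), numeric(1)))
    rownames(rec) <- NULL
    id <- sprintf("POP%d", pop)
    records[[id]] <- rec
    metas[[id]] <- study_meta(
      study_id = id, population = id, trait = trait,
      phenotype_kind = config$phenotype_kind[pop], n = n,
      genetic_sd = config$genetic_sd[pop])
  }
  truth <- data.frame(variant_index = ci,
                      chrom = vm$chrom[ci], pos = vm$pos[ci],
                      ref = vm$ref[ci], alt = vm$alt[ci],
                      shared = config$causal$shared,
                      stringsAsFactors = FALSE)
  for (pop in seq_len(config$n_pops)) {
    truth[[paste0("beta_", pop)]] <- .causal_beta(config, pop)
    truth[[paste0("freq_", pop)]] <- freq_real[, pop]
  }
  list(records = records, metas = metas, truth = truth, variants = vm)
}

#' Write a simulated study set to disk
#'
#' Runs \code{\link{simulate_studies}} and writes, per population, a
#' summary-statistics TSV and a study-metadata YAML, plus one
#' ground-truth TSV — byte-identical across runs with the same
#' configuration.
#'
#' @param config A \code{\link{sim_config}}.
#' @param out_dir Output directory (created if needed).
#' @param trait Trait label.
#' @return \code{list(sumstats, meta, truth)} of file paths (invisibly),
#'   with the in-memory study set attached as attribute
#'   \code{"studies"}.
#' @export
make_study_set <- function(config, out_dir, trait = "trait") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_studies(config, trait = trait)
  sumstat_paths <- meta_paths <- character(0)
  for (id in names(sim$records)) {
    sp <- file.path(out_dir, paste0(id, "_sumstats.tsv"))
    mp <- file.path(out_dir, paste0(id, "_meta.yml"))
    write_sumstats(sim$records[[id]], sp)
    write_study_meta(sim$metas[[id]], mp)
    sumstat_paths[id] <- sp
    meta_paths[id] <- mp
  }
  tp <- file.path(out_dir, "truth.tsv")
  tr <- sim$truth
  names(tr) <- toupper(names(tr))
  fwrite(tr, tp, sep = "\t", quote = FALSE)
  out <- list(sumstats = sumstat_paths, meta = meta_paths, truth = tp)
  attr(out, "studies") <- sim
  invisible(out)
}
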