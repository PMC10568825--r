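#' @name sumstats-format
#' @title Summary-statistics file format
#'
#' @description
#' Per-study GWAS summary statistics travel as tab-separated files with the
#' exact header \code{CHR POS REF ALT EA BETA SE P MAF INFO_R2 N}:
#' chromosome label, 1-based position, reference and alternative allele,
#' effect allele (the allele whose dosage the effect refers to; must be REF
#' or ALT), additive effect per allele dose, its standard error, two-sided
#' p-value, minor allele frequency, imputation accuracy (squared
#' correlation between imputed and true dosage), and sample size.  Missing
#' MAF or INFO_R2 is written as \code{"."}.  Coordinates are 1-based
#' inclusive; bi-allelic SNPs and InDels are supported (alleles are
#' non-empty strings over A/C/G/T).
#'
#' In memory a set of summary statistics is a plain \code{data.frame} with
#' lower-case columns \code{chrom, pos, ref, alt, effect_allele, beta, se,
#' p, maf, info_r2, n}.  Significance arithmetic downstream is done on the
#' \eqn{-\log_{10} p} scale so that extreme signals (the strongest peaks
#' in multi-population cattle meta-analyses reach \eqn{-\log_{10} p}
#' values above 150) never underflow.
NULL

.sumstat_cols <- c("CHR", "POS", "REF", "ALT", "EA", "BETA", "SE", "P",
                   "MAF", "INFO_R2", "N")
.internal_cols <- c("chrom", "pos", "ref", "alt", "effect_allele", "beta",
                    "se", "p", "maf", "info_r2", "n")

.valid_allele <- function(a) {
  nzchar(a) & grepl("^[ACGT]+$", a)
}

# internal: validate a parsed summary-statistics data.frame, reporting the
# first offending data row (1-based, excluding the header) per rule
validate_sumstats <- function(df, file = "<memory>") {
  fail <- function(rows, what) {
    if (any(rows)) {
      stop(sprintf("%s: %s (first at data row %d, file line %d)",
                   file, what, which(rows)[1], which(rows)[1] + 1L),
           call. = FALSE)
    }
  }
  fail(is.na(df$pos) | df$pos < 1, "POS must be >= 1")
  fail(!.valid_allele(df$ref), "REF must be a non-empty A/C/G/T string")
  fail(!.valid_allele(df$alt), "ALT must be a non-empty A/C/G/T string")
  fail(df$ref == df$alt, "REF and ALT must differ")
  fail(df$effect_allele != df$ref & df$effect_allele != df$alt,
       "EA must equal REF or ALT")
  fail(is.na(df$beta), "BETA must be numeric")
  fail(is.na(df$se) | df$se <= 0, "SE must be > 0")
  fail(is.na(df$p) | df$p <= 0 | df$p > 1, "P must be in (0, 1]")
  fail(!is.na(df$maf) & (df$maf < 0 | df$maf > 0.5),
       "MAF must be in [0, 0.5]")
  fail(!is.na(df$info_r2) & (df$info_r2 < 0 | df$info_r2 > 1),
       "INFO_R2 must be in [0, 1]")
  fail(is.na(df$n) | df$n < 1, "N must be >= 1")
  invisible(df)
}

.check_header <- function(got, want, file) {
  missing <- setdiff(want, got)
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s): %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read per-study GWAS summary statistics
#'
#' Parses a tab-separated summary-statistics file (see
#' \link{sumstats-format}), checks every row against the field invariants,
#' and returns one record per data row in file order.
#'
#' @param path Path to the TSV file.
#' @param meta Optional \code{\link{study_meta}} object; when supplied its
#'   \code{study_id} is attached as an attribute and its \code{n} is used
#'   to fill a missing N column.
#' @return A \code{data.frame} with columns \code{chrom, pos, ref, alt,
#'   effect_allele, beta, se, p, maf, info_r2, n}, in file order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c(paste(c("CHR","POS","REF","ALT","EA","BETA","SE","P",
#'                      "MAF","INFO_R2","N"), collapse = "\t"),
#'              "1\t12345\tA\tG\tG\t0.25\t0.10\t0.0124\t0.30\t0.95\t1000"),
#'            f)
#' read_sumstats(f)
#' @export
read_sumstats <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- fread(path, sep = "\t", header = TRUE, na.strings = ".",
              colClasses = list(character = c("CHR", "REF", "ALT", "EA")),
              data.table = FALSE, showProgress = FALSE)
  .check_header(names(dt), .sumstat_cols, path)
  df <- data.frame(
    chrom = as.character(dt$CHR),
    pos = as.numeric(dt$POS),
    ref = dt$REF,
    alt = dt$ALT,
    effect_allele = dt$EA,
    beta = as.numeric(dt$BETA),
    se = as.numeric(dt$SE),
    p = as.numeric(dt$P),
    maf = as.numeric(dt$MAF),
    info_r2 = as.numeric(dt$INFO_R2),
    n = as.numeric(dt$N),
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0) validate_sumstats(df, file = path)
  if (!is.null(meta)) attr(df, "study_id") <- meta$study_id
  df
}

#' Write per-study GWAS summary statistics
#'
#' Inverse of \code{\link{read_sumstats}}; numeric fields are written at
#' full precision so a write/read round trip is lossless well beyond six
#' significant digits.
#'
#' @param records Summary-statistics \code{data.frame}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sumstats <- function(records, path) {
  out <- data.frame(
    CHR = records$chrom, POS = records$pos, REF = records$ref,
    ALT = records$alt, EA = records$effect_allele, BETA = records$beta,
    SE = records$se, P = records$p, MAF = records$maf,
    INFO_R2 = records$info_r2, N = records$n,
    stringsAsFactors = FALSE
  )
  fwrite(out, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' Study metadata
#'
#' Describes one contributing study: the population, the trait, how the
#' phenotype was constructed (\code{YD} yield deviation, \code{DYD}
#' daughter yield deviation, \code{DRP} de-regressed proof), the sample
#' size, the trait's genetic standard deviation (the unit used to
#' standardize effects across populations), and the per-study minor
#' allele frequency threshold (0.005 by default; 0.02 is typical for
#' small cohorts).
#'
#' @param study_id,population,trait Character labels.
#' @param phenotype_kind One of \code{"YD"}, \code{"DYD"}, \code{"DRP"}.
#' @param n Sample count (>= 1).
#' @param genetic_sd Genetic standard deviation of the trait in trait
#'   units (> 0).
#' @param maf_threshold Per-study MAF filter threshold, in (0, 0.5).
#' @return An object of class \code{"study_meta"}.
#' @export
study_meta <- function(study_id, population = study_id, trait = "trait",
                       phenotype_kind = c("YD", "DYD", "DRP"), n,
                       genetic_sd = 1, maf_threshold = 0.005) {
  phenotype_kind <- match.arg(phenotype_kind)
  stopifnot(is.character(study_id), length(study_id) == 1L)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a single count >= 1", call. = FALSE)
  }
  if (!is.numeric(genetic_sd) || genetic_sd <= 0) {
    stop("genetic_sd must be > 0", call. = FALSE)
  }
  if (maf_threshold <= 0 || maf_threshold >= 0.5) {
    stop("maf_threshold must be in (0, 0.5)", call. = FALSE)
  }
  structure(list(study_id = study_id, population = population,
                 trait = trait, phenotype_kind = phenotype_kind,
                 n = as.numeric(n), genetic_sd = genetic_sd,
                 maf_threshold = maf_threshold),
            class = "study_meta")
}

#' @export
print.study_meta <- function(x, ...) {
  cat(sprintf("study %s: population %s, trait %s (%s), n = %d, genetic SD = %g, MAF >= %g\n",
              x$study_id, x$population, x$trait, x$phenotype_kind,
              as.integer(x$n), x$genetic_sd, x$maf_threshold))
  invisible(x)
}

#' Read / write study metadata
#'
#' Study metadata is stored as a plain-text key-value (YAML) file with
#' keys \code{study_id, population, trait, phenotype_kind, n, genetic_sd,
#' maf_threshold}.
#'
#' @param path File path.
#' @return \code{read_study_meta} returns a \code{\link{study_meta}};
#'   \code{write_study_meta} returns \code{path} invisibly.
#' @export
read_study_meta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  kv <- yaml::read_yaml(path)
  need <- c("study_id", "n")
  .check_header(names(kv), need, path)
  study_meta(study_id = as.character(kv$study_id),
             population = as.character(kv$population %||% kv$study_id),
             trait = as.character(kv$trait %||% "trait"),
             phenotype_kind = as.character(kv$phenotype_kind %||% "YD"),
             n = as.numeric(kv$n),
             genetic_sd = as.numeric(kv$genetic_sd %||% 1),
             maf_threshold = as.numeric(kv$maf_threshold %||% 0.005))
}

#' @rdname read_study_meta
#' @param meta A \code{\link{study_meta}} object.
#' @export
write_study_meta <- function(meta, path) {
  stopifnot(inherits(meta, "study_meta"))
  yaml::write_yaml(unclass(meta), path)
  invisible(path)
}

# ---- meta-analysis results I/O -------------------------------------------

.meta_cols <- c("CHR", "POS", "REF", "ALT", "EA", "METHOD", "K", "N",
                "DIRECTION", "BETA_META", "SE_META", "Z", "MLOG10P", "P")

# internal: scientific-notation p string from -log10 p, safe for
# mlog10p far beyond 308 (where a double p would underflow to 0)
format_p_mlog <- function(mlogp) {
  k <- floor(mlogp) + 1
  mant <- 10^(k - mlogp)
  adj <- mant >= 10
  mant[adj] <- mant[adj] / 10
  k[adj] <- k[adj] - 1
  sprintf("%.6fe-%02d", mant, k)
}

#' Write / read meta-analysis results
#'
#' Combined per-variant results are stored as a TSV with columns
#' \code{CHR POS REF ALT EA METHOD K N DIRECTION BETA_META SE_META Z
#' MLOG10P P}.  Significance is carried by \code{MLOG10P}; the \code{P}
#' column is a scientific-notation string rendered from it, so p-values
#' down to \eqn{10^{-300}} and beyond are stored as nonzero strings.  A
#' write-then-read round trip reproduces every numeric field to at least
#' six significant digits.  All records in one file must share one
#' combination method.
#'
#' @param records Meta-analysis results \code{data.frame} as produced by
#'   \code{\link{run_meta}}.
#' @param path File path.
#' @return \code{write_meta_results} returns \code{path} invisibly;
#'   \code{read_meta_results} returns the results \code{data.frame}.
#' @export
write_meta_results <- function(records, path) {
  if (nrow(records) > 0 && length(unique(records$method)) != 1L) {
    stop("records mix combination methods; write one method per file",
         call. = FALSE)
  }
  out <- data.frame(
    CHR = records$chrom, POS = records$pos, REF = records$ref,
    ALT = records$alt, EA = records$effect_allele,
    METHOD = records$method, K = records$k_studies, N = records$n_total,
    DIRECTION = records$direction, BETA_META = records$beta_meta,
    SE_META = records$se_meta, Z = records$z, MLOG10P = records$mlogp,
    P = if (nrow(records)) format_p_mlog(records$mlogp) else character(0),
    stringsAsFactors = FALSE
  )
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_meta_results
#' @export
read_meta_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("CHR", "REF", "ALT", "EA",
                                              "METHOD", "DIRECTION", "P")),
              data.table = FALSE, showProgress = FALSE)
  .check_header(names(dt), setdiff(.meta_cols, "P"), path)
  data.frame(
    chrom = as.character(dt$CHR), pos = as.numeric(dt$POS),
    ref = dt$REF, alt = dt$ALT, effect_allele = dt$EA,
    method = dt$METHOD, k_studies = as.integer(dt$K),
    n_total = as.numeric(dt$N), direction = dt$DIRECTION,
    beta_meta = as.numeric(dt$BETA_META), se_meta = as.numeric(dt$SE_META),
    z = as.numeric(dt$Z), mlogp = as.numeric(dt$MLOG10P),
    stringsAsFactors = FALSE
  )
}

# ---- annotation tables ----------------------------------------------------

#' Read an interval annotation database
#'
#' Tab-separated with columns \code{CHR START END CATEGORY NAME}
#' (1-based inclusive bounds), in the style of a cattle QTL database
#' export: each record is a published QTL interval labelled with a
#' trait-type category.
#'
#' @param path File path.
#' @return \code{data.frame} with columns \code{chrom, start, end,
#'   category, name}.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("CHR", "CATEGORY", "NAME")),
              data.table = FALSE, showProgress = FALSE)
  .check_header(names(dt), c("CHR", "START", "END", "CATEGORY", "NAME"), path)
  df <- data.frame(chrom = as.character(dt$CHR), start = as.numeric(dt$START),
                   end = as.numeric(dt$END), category = dt$CATEGORY,
                   name = dt$NAME, stringsAsFactors = FALSE)
  bad <- which(df$start > df$end)
  if (length(bad) > 0) {
    stop(sprintf("%s: START > END at data row %d", path, bad[1]),
         call. = FALSE)
  }
  df
}

# fixed vocabulary of variant consequence categories, in report order
.consequence_vocab <- c(
  "Intergenic_region", "Intron_variant", "Upstream_gene_variant",
  "Downstream_gene_variant", "Missense_variant", "3_prime_UTR_variant",
  "Synonymous_variant", "5_prime_UTR_variant",
  "Splice_region_variant and intron_variant", "Stop_gained",
  "Frameshift_variant", "Non_coding_transcript_exon_variant",
  "5_prime_UTR_premature_start_codon_gain_variant",
  "Splice_region_variant and synonymous_variant",
  "Stop_lost and splice_region_variant", "Gene_fusion", "other"
)

#' Variant consequence vocabulary
#'
#' The fixed set of consequence categories used by
#' \code{\link{read_consequences}} and
#' \code{\link{consequence_distribution}}, in report order (most common
#' first: intergenic, intronic, up/downstream, then coding and splice
#' categories, with \code{"other"} as the catch-all).
#'
#' @return Character vector of category labels.
#' @export
consequence_vocabulary <- function() .consequence_vocab

#' Read a variant-consequence table
#'
#' Tab-separated with columns \code{CHR POS REF ALT CONSEQUENCE}, in the
#' style of a condensed variant-effect-predictor output: one consequence
#' category per variant, drawn from \code{consequence_vocabulary} (any
#' other label is mapped to \code{"other"} with a warning).
#'
#' @param path File path.
#' @return \code{data.frame} with columns \code{chrom, pos, ref, alt,
#'   consequence}.
#' @export
read_consequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("CHR", "REF", "ALT",
                                              "CONSEQUENCE")),
              data.table = FALSE, showProgress = FALSE)
  .check_header(names(dt), c("CHR", "POS", "REF", "ALT", "CONSEQUENCE"), path)
  cons <- dt$CONSEQUENCE
  unknown <- !(cons %in% .consequence_vocab)
  if (any(unknown)) {
    warning(sprintf("%s: %d record(s) with unknown consequence mapped to 'other'",
                    path, sum(unknown)), call. = FALSE)
    cons[unknown] <- "other"
  }
  data.frame(chrom = as.character(dt$CHR), pos = as.numeric(dt$POS),
             ref = dt$REF, alt = dt$ALT, consequence = cons,
             stringsAsFactors = FALSE)
}

#' Read an e/sQTL table
#'
#' Tab-separated with columns \code{CHR POS REF ALT GENE TISSUE KIND P
#' P_ADJ}: per-variant cis-eQTL / cis-sQTL associations with a nominal
#' and a multiplicity-adjusted p-value, as exported from a
#' genotype-tissue-expression atlas.  \code{tissue_aliases} collapses
#' tissue labels at read time (e.g. gathering \code{Muscle_taurus},
#' \code{Muscle_indicus} and \code{Muscle_cross} into a single
#' \code{Muscle} group, as done for the bovine expression atlas).
#'
#' @param path File path.
#' @param tissue_aliases Named character vector mapping input tissue
#'   labels to group labels; unlisted tissues are kept as-is.
#' @return \code{data.frame} with columns \code{chrom, pos, ref, alt,
#'   gene, tissue, kind, p, p_adj}.
#' @export
read_eqtl <- function(path, tissue_aliases = muscle_tissue_aliases()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("CHR", "REF", "ALT", "GENE",
                                              "TISSUE", "KIND")),
              data.table = FALSE, showProgress = FALSE)
  .check_header(names(dt), c("CHR", "POS", "REF", "ALT", "GENE", "TISSUE",
                             "KIND", "P", "P_ADJ"), path)
  if (!all(dt$KIND %in% c("eQTL", "sQTL"))) {
    stop(path, ": KIND must be 'eQTL' or 'sQTL'", call. = FALSE)
  }
  bad <- which(dt$P <= 0 | dt$P > 1 | dt$P_ADJ <= 0 | dt$P_ADJ > 1)
  if (length(bad) > 0) {
    stop(sprintf("%s: p-values must be in (0, 1] (data row %d)", path,
                 bad[1]), call. = FALSE)
  }
  tissue <- dt$TISSUE
  hit <- tissue %in% names(tissue_aliases)
  tissue[hit] <- unname(tissue_aliases[tissue[hit]])
  data.frame(chrom = as.character(dt$CHR), pos = as.numeric(dt$POS),
             ref = dt$REF, alt = dt$ALT, gene = dt$GENE, tissue = tissue,
             kind = dt$KIND, p = as.numeric(dt$P),
             p_adj = as.numeric(dt$P_ADJ), stringsAsFactors = FALSE)
}

#' @rdname read_eqtl
#' @export
muscle_tissue_aliases <- function() {
  c(Muscle_taurus = "Muscle", Muscle_indicus = "Muscle",
    Muscle_cross = "Muscle")
}

#' Export QTL confidence intervals as BED
#'
#' Writes the confidence intervals of a QTL table (see
#' \code{\link{detect_qtl}}) as a 5-column BED file.  The internal
#' 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention only at this boundary.
#'
#' @param regions QTL table from \code{\link{detect_qtl}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_qtl_bed <- function(regions, path) {
  out <- data.frame(
    chrom = regions$chrom,
    start = as.integer(regions$ci_start) - 1L,
    end = as.integer(regions$ci_end),
    name = sprintf("QTL_%s_%d", regions$chrom, as.integer(regions$lead_pos)),
    score = round(pmin(regions$lead_mlogp, 1000), 3),
    stringsAsFactors = FALSE
  )
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
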