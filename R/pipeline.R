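#' Compare QTL sets across analyses
#'
#' Pairwise \code{\link{match_qtl}} over two or more named QTL tables
#' (e.g. each constituent within-population scan plus the fixed-effects
#' and z-score meta-analyses), tabulating per-set QTL counts and CI
#' summaries and, per pair, how many regions match and how many are
#' specific to each side.
#'
#' @param qtl_sets Named list (>= 2) of \code{\link{detect_qtl}} tables.
#' @return \code{list(per_set, pairwise)} of \code{data.frame}s.
#' @export
compare_analyses <- function(qtl_sets) {
  stopifnot(is.list(qtl_sets), length(qtl_sets) >= 2,
            !is.null(names(qtl_sets)))
  per_set <- do.call(rbind, lapply(names(qtl_sets), function(nm) {
    cbind(analysis = nm, summarize_qtl(qtl_sets[[nm]]))
  }))
  combs <- utils::combn(names(qtl_sets), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    m <- match_qtl(qtl_sets[[a]], qtl_sets[[b]])
    data.frame(set_a = a, set_b = b,
               n_a = nrow(qtl_sets[[a]]), n_b = nrow(qtl_sets[[b]]),
               n_matched = nrow(m$pairs),
               a_only = length(m$unmatched_a),
               b_only = length(m$unmatched_b),
               stringsAsFactors = FALSE)
  }))
  rownames(per_set) <- rownames(pairwise) <- NULL
  list(per_set = per_set, pairwise = pairwise)
}

#' Run the full pipeline on a simulated study set
#'
#' Orchestrates simulate, QC/harmonization, both meta-analyses, QTL
#' calling (per constituent study and per meta-analysis method), and a
#' comparison report, writing every stage's outputs under
#' \code{out_dir}.  Re-running with the same configuration reproduces
#' all outputs byte-identically.
#'
#' @param config A \code{\link{sim_config}} describing the study set.
#' @param out_dir Run directory (created if needed).
#' @param methods Meta-analysis methods to run.
#' @param threshold_mlogp,window_bp,peak_fraction QTL-calling parameters
#'   (see \code{\link{detect_qtl}}).
#' @param info_min,outlier_k QC parameters (see
#'   \code{\link{harmonize_studies}}).
#' @param stages Subset of
#'   \code{c("simulate","qc","meta","qtl","report")}; earlier stage
#'   outputs must exist for later stages.
#' @return An object of class \code{"bovmeta_run"}: stage outputs and
#'   file paths, including \code{report} (the cross-analysis
#'   comparison) when the report stage runs.
#' @export
run_pipeline <- function(config, out_dir,
                         methods = c("fixed", "zscore"),
                         threshold_mlogp = genomewide_threshold(),
                         window_bp = 2e6, peak_fraction = 1/3,
                         info_min = 0.20, outlier_k = 5,
                         stages = c("simulate", "qc", "meta", "qtl",
                                    "report")) {
  stopifnot(inherits(config, "sim_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  methods <- match.arg(methods, c("fixed", "zscore"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- list(out_dir = out_dir, config = config)

  if ("simulate" %in% stages) {
    run$files <- make_study_set(config, file.path(out_dir, "sim"))
  }

  if ("qc" %in% stages) {
    paths <- attr(run$files, "studies")
    if (is.null(paths)) {
      stop("qc stage needs the simulate stage outputs", call. = FALSE)
    }
    # read back from disk so the QC stage consumes only files
    recs <- lapply(run$files$sumstats, read_sumstats)
    metas <- lapply(run$files$meta, read_study_meta)
    names(recs) <- names(metas) <- names(run$files$sumstats)
    run$panel <- harmonize_studies(recs, metas, info_min = info_min,
                                   outlier_k = outlier_k)
    run$study_records <- lapply(names(recs), function(id) {
      standardize_effects(recs[[id]], metas[[id]]$genetic_sd)
    })
    names(run$study_records) <- names(recs)
    qc_dir <- file.path(out_dir, "qc")
    dir.create(qc_dir, showWarnings = FALSE)
    for (id in names(run$panel$studies)) {
      write_sumstats(run$panel$studies[[id]],
                     file.path(qc_dir, paste0(id, "_harmonized.tsv")))
    }
    rep <- run$panel$qc_report
    yaml::write_yaml(list(
      n_sites_seen = rep$n_sites_seen,
      n_single_study = rep$n_single_study,
      n_discordant = rep$n_discordant,
      n_retained = rep$n_retained,
      per_study_kept = as.list(rep$per_study_kept),
      per_study_filters = lapply(rep$per_study_filters, as.list)
    ), file.path(qc_dir, "qc_report.yml"))
  }

  if ("meta" %in% stages) {
    if (is.null(run$panel)) {
      stop("meta stage needs the qc stage outputs", call. = FALSE)
    }
    meta_dir <- file.path(out_dir, "meta")
    dir.create(meta_dir, showWarnings = FALSE)
    run$meta <- lapply(methods, function(mm) {
      res <- run_meta(run$panel, method = mm)
      write_meta_results(res, file.path(meta_dir, paste0(mm, ".tsv")))
      res
    })
    names(run$meta) <- methods
  }

  if ("qtl" %in% stages) {
    if (is.null(run$meta)) {
      stop("qtl stage needs the meta stage outputs", call. = FALSE)
    }
    qtl_dir <- file.path(out_dir, "qtl")
    dir.create(qtl_dir, showWarnings = FALSE)
    sets <- c(
      lapply(run$study_records, detect_qtl,
             threshold_mlogp = threshold_mlogp, window_bp = window_bp,
             peak_fraction = peak_fraction),
      lapply(run$meta, detect_qtl,
             threshold_mlogp = threshold_mlogp, window_bp = window_bp,
             peak_fraction = peak_fraction)
    )
    for (nm in names(sets)) {
      tab <- sets[[nm]]
      fwrite(data.frame(
        CHR = tab$chrom, LEAD_POS = tab$lead_pos,
        LEAD_REF = tab$lead_ref, LEAD_ALT = tab$lead_alt,
        LEAD_MLOG10P = tab$lead_mlogp, CI_START = tab$ci_start,
        CI_END = tab$ci_end, N_CI_VARIANTS = tab$n_ci_variants,
        CI_SIZE_KB = tab$ci_size_kb), sep = "\t", quote = FALSE,
        file = file.path(qtl_dir, paste0(nm, "_qtl.tsv")))
      if (nrow(tab) > 0) {
        write_qtl_bed(tab, file.path(qtl_dir, paste0(nm, "_ci.bed")))
      }
    }
    run$qtl <- sets
  }

  if ("report" %in% stages) {
    if (is.null(run$qtl)) {
      stop("report stage needs the qtl stage outputs", call. = FALSE)
    }
    run$report <- compare_analyses(run$qtl)
    fwrite(run$report$per_set, file.path(out_dir, "report_per_set.tsv"),
           sep = "\t", quote = FALSE)
    fwrite(run$report$pairwise, file.path(out_dir, "report_pairwise.tsv"),
           sep = "\t", quote = FALSE)
  }
  class(run) <- "bovmeta_run"
  run
}

#' @export
print.bovmeta_run <- function(x, ...) {
  cat("pipeline run in", x$out_dir, "\n")
  if (!is.null(x$report)) {
    cat("QTL per analysis:\n")
    print(x$report$per_set[, c("analysis", "n_qtl", "mean_ci_variants",
                               "mean_ci_kb")])
  }
  invisible(x)
}
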