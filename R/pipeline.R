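# End-to-end pipeline driver with a flat key-value configuration, plus
# the panel-validation reporting workflow for a full MADC dataset.

#' Pipeline configuration
#'
#' Flat, fully serializable configuration for [run_pipeline()]. Every
#' numeric threshold of the stage functions is exposed here so a run is
#' reproducible from its echoed config alone.
#'
#' @param madc,sheet,markers Input paths (MADC CSV, sample-sheet TSV,
#'   optional marker-table TSV).
#' @param out_dir Output directory for stage reports.
#' @param seed Seed echoed to every stochastic stage.
#' @param min_reads Per-cell read threshold.
#' @param sample_threshold,marker_threshold Missing-rate removal
#'   thresholds.
#' @param dedup_window_bp Target-SNP deduplication window (bp); set to 0
#'   to skip (requires marker positions).
#' @param ploidy_stage,dosage_stage Logical stage toggles.
#' @param dosage_m Ploidy for the "norm" dosage model.
#' @param ... Additional key-value overrides stored verbatim.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(madc = NULL, sheet = NULL, markers = NULL,
                            out_dir = ".", seed = 1L, min_reads = 10L,
                            sample_threshold = 0.95, marker_threshold = 0.95,
                            dedup_window_bp = 15L, ploidy_stage = FALSE,
                            dosage_stage = TRUE, dosage_m = 2L, ...) {
  cfg <- c(list(madc = madc, sheet = sheet, markers = markers,
                out_dir = out_dir, seed = as.integer(seed),
                min_reads = min_reads, sample_threshold = sample_threshold,
                marker_threshold = marker_threshold,
                dedup_window_bp = dedup_window_bp,
                ploidy_stage = ploidy_stage, dosage_stage = dosage_stage,
                dosage_m = dosage_m),
           list(...))
  stopifnot(cfg$min_reads >= 1, cfg$sample_threshold > 0,
            cfg$sample_threshold <= 1, cfg$marker_threshold > 0,
            cfg$marker_threshold <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a flat key-value pipeline config
#'
#' Format: one `key = value` pair per line, `#` comments allowed.
#' Logical values are `true`/`false`; everything numeric-looking is
#' parsed as a number.
#'
#' @param path File path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  if (any(lengths(kv) != 2L)) stop("malformed config line")
  vals <- lapply(kv, function(x) {
    v <- x[2]
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[[`, "", 1L)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param cfg A [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  keep <- !vapply(cfg, is.null, TRUE)
  writeLines(paste(names(cfg)[keep], "=",
                   vapply(cfg[keep], function(v)
                     if (is.logical(v)) tolower(as.character(v))
                     else as.character(v), "")),
             path)
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the processing pipeline
#'
#' Executes, in order: MADC parsing, optional target-SNP deduplication
#' (when marker positions are available), missingness computation and
#' sample/marker filtering, optional ploidy estimation, optional dosage
#' calling with post-dosage filters, and read-ratio QC statistics. Every
#' stage writes a TSV report into `out_dir` and a line into
#' `pipeline_log.tsv` recording input/output record counts. Identical
#' config and inputs produce identical outputs.
#'
#' @param config A [pipeline_config()] (or path to one).
#' @return Invisibly, a list with the loaded objects, stage logs and
#'   written file paths; stops with the stage name on error.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  files <- character(0)
  logln <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sheet <- stage("sheet", read_sample_sheet(cfg$sheet))
  mk <- if (!is.null(cfg$markers)) stage("markers", read_marker_table(cfg$markers))
  counts <- stage("read_madc", read_madc(cfg$madc, sheet, mk))
  logln$read <- c(n_loci = nrow(counts$ref), n_samples = ncol(counts$ref))

  if (!is.null(mk) && cfg$dedup_window_bp > 0) {
    dd <- stage("dedup", dedup_window(counts$markers, cfg$dedup_window_bp))
    counts <- counts[dd$kept$locus_id, ]
    files <- c(files, .write_tsv(dd$removed,
                                 file.path(cfg$out_dir, "dedup_removed.tsv")))
    logln$dedup <- c(kept = nrow(dd$kept), removed = nrow(dd$removed))
  }

  ms <- stage("missingness", missingness(counts, cfg$min_reads))
  files <- c(files, .write_tsv(
    data.frame(sample_id = counts$samples$sample_id,
               missing_rate = round(ms$report$sample_missing, 4)),
    file.path(cfg$out_dir, "sample_missingness.tsv")))
  flt <- stage("filter", filter_by_missing(counts, cfg$sample_threshold,
                                           cfg$marker_threshold, cfg$min_reads))
  counts_f <- flt$counts
  logln$filter <- c(samples_removed = flt$log$n_samples_removed,
                    markers_removed = flt$log$n_markers_removed,
                    n_loci = nrow(counts_f$ref), n_samples = ncol(counts_f$ref))

  ploidy_calls <- NULL
  if (isTRUE(cfg$ploidy_stage)) {
    ploidy_calls <- stage("ploidy", ploidy_pipeline(counts_f,
                                                    min_reads = cfg$min_reads))
    files <- c(files, .write_tsv(ploidy_calls,
                                 file.path(cfg$out_dir, "ploidy_calls.tsv")))
    logln$ploidy <- c(n_called = sum(!is.na(ploidy_calls$call)))
  }

  dosage_fit <- NULL
  if (isTRUE(cfg$dosage_stage)) {
    dosage_fit <- stage("dosage", fit_norm_model(counts_f, m = cfg$dosage_m,
                                                 min_reads = cfg$min_reads))
    pf <- filter_postdosage(dosage_fit$fits)
    geno_df <- data.frame(marker = rownames(dosage_fit$geno$dosage),
                          dosage_fit$geno$dosage, check.names = FALSE)
    files <- c(files,
               .write_tsv(dosage_fit$fits,
                          file.path(cfg$out_dir, "dosage_fits.tsv")),
               .write_tsv(geno_df, file.path(cfg$out_dir, "genotypes.tsv")),
               .write_tsv(pf$log, file.path(cfg$out_dir, "postdosage_filter.tsv")))
    logln$dosage <- c(n_fit = sum(!is.na(dosage_fit$fits$h)),
                      n_kept = sum(pf$keep))
  }

  maf <- stage("qc", maf_from_reads(counts_f))
  poly <- polymorphic_call(maf, counts_f$samples)
  qc <- data.frame(marker = counts_f$markers$locus_id,
                   maf = round(maf, 4),
                   polymorphic = poly$polymorphic,
                   missing_rate = round(missingness(counts_f, cfg$min_reads)$
                                          report$marker_missing, 4))
  files <- c(files, .write_tsv(qc, file.path(cfg$out_dir, "marker_qc.tsv")))
  logln$qc <- c(n_polymorphic = sum(poly$polymorphic, na.rm = TRUE),
                threshold = poly$threshold)

  log_df <- data.frame(stage = rep(names(logln), lengths(logln)),
                       key = unlist(lapply(logln, names)),
                       value = unlist(logln), row.names = NULL)
  files <- c(files, .write_tsv(log_df, file.path(cfg$out_dir, "pipeline_log.tsv")))
  write_pipeline_config(cfg, file.path(cfg$out_dir, "config_echo.txt"))
  invisible(list(config = cfg, counts = counts_f, filter_log = flt$log,
                 ploidy = ploidy_calls, dosage = dosage_fit,
                 qc = qc, files = files, log = logln))
}

#' Panel-validation summary on a full MADC dataset
#'
#' Runs the read-threshold validation workflow reported for a mid-density
#' panel: per-sample missingness at `min_reads` over all loci, removal of
#' samples then markers at or above 95% missing, group-wise mean missing
#' and amplification rates, and (when parental groups are given)
#' sub-genome classification of the hybrid-panel loci after removing the
#' hybrid panel's own high-missing markers.
#'
#' @param counts A [count_matrix()] of the full panel (all samples).
#' @param min_reads Per-cell read threshold (default 10).
#' @param threshold Missing-rate removal threshold (default 0.95).
#' @param hybrid_group `group` label of the hybrid samples in the sample
#'   sheet (optional).
#' @param blue_parents,cran_parents Parental sample ids for
#'   classification (optional).
#' @return List: `mean_sample_missing_pct` (over all samples, before
#'   removals), `group_mean_missing_pct`, `group_amplification_pct`
#'   (100 - mean missing), `n_samples_removed`, `n_markers_removed`,
#'   `n_markers_retained`, and if parents were given
#'   `n_hybrid_markers_removed`, `class_counts` and `n_shared`.
#' @export
reproduce_panel_validation <- function(counts, min_reads = 10L,
                                       threshold = 0.95,
                                       hybrid_group = NULL,
                                       blue_parents = NULL,
                                       cran_parents = NULL) {
  ms <- missingness(counts, min_reads)
  grp <- counts$samples$group
  out <- list(
    mean_sample_missing_pct = 100 * mean(ms$report$sample_missing),
    group_mean_missing_pct =
      100 * tapply(ms$report$sample_missing, grp, mean),
    group_amplification_pct =
      100 - 100 * tapply(ms$report$sample_missing, grp, mean))
  flt <- filter_by_missing(counts, threshold, threshold, min_reads)
  out$n_samples_removed <- flt$log$n_samples_removed
  out$n_markers_removed <- flt$log$n_markers_removed
  out$n_markers_retained <- nrow(flt$counts$ref)
  if (!is.null(hybrid_group) && !is.null(blue_parents) &&
      !is.null(cran_parents)) {
    hyb_ids <- counts$samples$sample_id[grp == hybrid_group]
    panel <- counts[, c(blue_parents, cran_parents, hyb_ids)]
    msh <- missingness(panel[, hyb_ids], min_reads)
    bad <- msh$report$marker_missing >= threshold
    out$n_hybrid_markers_removed <- sum(bad)
    panel <- panel[!bad, ]
    cls <- classify_loci(panel, blue_parents, cran_parents,
                         threshold = min_reads)
    out$class_counts <- table(cls$label)
    out$n_shared <- sum(cls$label == "shared")
  }
  out
}
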