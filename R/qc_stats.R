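# Detection/missingness QC, read-ratio MAF and polymorphism calls, PIC,
# IBS and allele-ratio PCA.

#' Read-threshold missingness
#'
#' A genotype data point is missing when its total (Ref + Alt) read count
#' is below `min_reads` (strictly `< min_reads`; exactly `min_reads` reads
#' is observed). Sample-level rate is missing loci over total tested loci;
#' marker-level rate is missing samples over total samples.
#'
#' @param counts A [count_matrix()].
#' @param min_reads Read threshold (default 10).
#' @return List with `mask` (logical loci x samples, TRUE = missing) and
#'   `report` (list: `sample_missing`, `marker_missing`, `min_reads`).
#' @export
missingness <- function(counts, min_reads = 10L) {
  stopifnot(min_reads >= 1)
  total <- counts$ref + counts$alt
  if (length(total) == 0L) stop("empty count matrix")
  mask <- total < min_reads
  list(mask = mask,
       report = list(sample_missing = colMeans(mask),
                     marker_missing = rowMeans(mask),
                     min_reads = min_reads))
}

#' Filter samples then markers by missing rate
#'
#' Samples at or above `sample_threshold` missing are removed first;
#' marker missing rates are then recomputed on the remaining samples and
#' markers at or above `marker_threshold` are removed. The order matters
#' and is recorded in the log.
#'
#' @param counts A [count_matrix()].
#' @param sample_threshold,marker_threshold Removal thresholds in (0, 1].
#' @param min_reads Read threshold defining a missing cell.
#' @return List with `counts` (filtered), and `log` (list with
#'   `samples_removed`, `markers_removed`, counts and thresholds).
#' @export
filter_by_missing <- function(counts, sample_threshold = 0.95,
                              marker_threshold = 0.95, min_reads = 10L) {
  stopifnot(sample_threshold > 0, sample_threshold <= 1,
            marker_threshold > 0, marker_threshold <= 1)
  ms <- missingness(counts, min_reads)
  bad_s <- ms$report$sample_missing >= sample_threshold
  kept <- counts[, !bad_s]
  ms2 <- missingness(kept, min_reads)
  bad_m <- ms2$report$marker_missing >= marker_threshold
  out <- kept[!bad_m, ]
  list(counts = out,
       log = list(order = c("samples", "markers"),
                  samples_removed = counts$samples$sample_id[bad_s],
                  markers_removed = kept$markers$locus_id[bad_m],
                  n_samples_removed = sum(bad_s),
                  n_markers_removed = sum(bad_m),
                  sample_threshold = sample_threshold,
                  marker_threshold = marker_threshold,
                  min_reads = min_reads))
}

#' Minor allele frequency from pooled read counts
#'
#' Per marker, MAF is the smaller of the pooled Ref and Alt read totals
#' over their sum, so it lies in [0, 0.5]. Markers with zero total reads
#' are undefined (NA).
#'
#' @param counts A [count_matrix()].
#' @return Named numeric vector of per-marker MAF.
#' @export
maf_from_reads <- function(counts) {
  sr <- rowSums(counts$ref)
  sa <- rowSums(counts$alt)
  tot <- sr + sa
  maf <- ifelse(tot > 0, pmin(sr, sa) / tot, NA_real_)
  names(maf) <- counts$markers$locus_id
  maf
}

#' Polymorphism call against the singleton threshold
#'
#' A marker is polymorphic when its read-ratio MAF is at least the
#' frequency of a singleton allele, 1/G, where G is the total number of
#' gametes contributed by the panel (the sum of nominal ploidies).
#'
#' @param maf Per-marker MAF, e.g. from [maf_from_reads()].
#' @param sheet Sample sheet with `nominal_ploidy`.
#' @return List with `polymorphic` (logical per marker, NA where MAF is
#'   undefined), `threshold` (1/G), and `n_gametes` (G).
#' @export
polymorphic_call <- function(maf, sheet) {
  if (nrow(sheet) == 0L) stop("empty sample sheet")
  G <- sum(sheet$nominal_ploidy)
  thr <- 1 / G
  list(polymorphic = maf >= thr, threshold = thr, n_gametes = G)
}

#' Polymorphism information content (Botstein)
#'
#' PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2 over the `n` allele
#' frequencies of a locus. For a biallelic locus it is maximized at
#' p = 0.5 (PIC = 0.375).
#'
#' @param p Numeric vector of allele frequencies summing to 1.
#' @return PIC value in [0, 1).
#' @export
pic <- function(p) {
  if (length(p) < 1L) stop("need at least one allele frequency")
  if (any(p < 0)) stop("allele frequencies must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  cross <- outer(p^2, p^2)
  1 - sum(p^2) - 2 * sum(cross[upper.tri(cross)])
}

#' Per-marker PIC from called dosages
#'
#' Biallelic allele frequencies are estimated from the dosage matrix as
#' p_alt = sum(dosage) / (ploidy x n called), pooling samples of the
#' stated ploidy, then fed to [pic()].
#'
#' @param geno A [genotype_matrix()] or dosage matrix.
#' @param ploidy Ploidy of the evaluated samples (scalar; defaults to the
#'   genotype matrix ploidy).
#' @return Named numeric vector of per-marker PIC (NA where no calls).
#' @export
pic_from_genotypes <- function(geno, ploidy = NULL) {
  d <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  if (is.null(ploidy)) {
    ploidy <- if (inherits(geno, "genotype_matrix")) geno$ploidy[1] else
      stop("ploidy required for a bare dosage matrix")
  }
  apply(d, 1L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    p <- sum(x) / (ploidy * length(x))
    pic(c(1 - p, p))
  })
}

#' Identity by state between two genotype vectors
#'
#' Proportion of loci with identical dosage among loci non-missing in
#' both samples.
#'
#' @param g1,g2 Equal-length dosage vectors (NA = missing).
#' @return List with `ibs` in [0, 1] and `n_compared`.
#' @export
ibs <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) stop("no loci non-missing in both samples")
  list(ibs = mean(g1[ok] == g2[ok]), n_compared = sum(ok))
}

#' Allele-ratio principal component analysis
#'
#' Uses the per-cell Ref/(Ref+Alt) read-depth ratio as an allele-frequency
#' proxy. Cells below `min_reads` total depth are treated as missing and
#' imputed with the marker mean ratio; markers with no observed cell are
#' dropped with a warning. Columns (markers) are centered and PCs come
#' from the singular value decomposition of the samples x markers ratio
#' matrix.
#'
#' @param counts A [count_matrix()].
#' @param n_pc Number of components to return.
#' @param min_reads Read threshold defining an observed cell.
#' @return List with `scores` (samples x n_pc), `loadings` (markers x
#'   n_pc), `var_explained` (percent per PC), and `markers_used`.
#' @export
allele_ratio_pca <- function(counts, n_pc = 10L, min_reads = 10L) {
  total <- counts$ref + counts$alt
  ratio <- ifelse(total >= min_reads, counts$ref / total, NA_real_)
  obs <- rowSums(!is.na(ratio)) > 0L
  if (any(!obs)) {
    warning(sum(!obs), " marker(s) with no observed cells dropped from PCA")
    ratio <- ratio[obs, , drop = FALSE]
  }
  mu <- rowMeans(ratio, na.rm = TRUE)
  idx <- which(is.na(ratio), arr.ind = TRUE)
  if (nrow(idx)) ratio[idx] <- mu[idx[, 1L]]
  X <- t(ratio)                      # samples x markers
  n_pc <- min(n_pc, nrow(X) - 1L, ncol(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_pc), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_pc), drop = FALSE],
       var_explained = ve[seq_len(n_pc)],
       markers_used = counts$markers$locus_id[obs])
}
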