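# Ploidy inference from allele-count ratios (B-allele frequencies).
#
# A sample's ploidy shows in the modal structure of its per-locus
# alternative-read fraction: diploids have a single heterozygous class
# near 0.5, natural tetraploids three (0.25, 0.5, 0.75). Raw ratios are
# shifted by per-marker allele bias, so they are first standardized
# against reference samples of known ploidy: per marker, the observed
# cluster means of the reference dosage classes are mapped onto their
# expected positions d/m by a piecewise-linear transform.
#
# Known limitation (reproduced deliberately by the simulator's
# colchicine_gen = 1 mode): first-generation chromosome-doubled
# tetraploids carry every allele in duplicate, so their ratios occupy
# only 0, 0.5, 1 and they score as diploids despite tetraploid genome
# content. Second-generation material recombines dosages and is called
# tetraploid again.

#' Allele-ratio (BAF) matrix
#'
#' @param counts A [count_matrix()].
#' @param min_reads Cells with total depth below this are NA.
#' @return Matrix loci x samples of alt/(ref+alt) with NA where
#'   unobserved, class `ratio_matrix`.
#' @export
ratio_matrix <- function(counts, min_reads = 10L) {
  total <- counts$ref + counts$alt
  baf <- ifelse(total >= min_reads, counts$alt / total, NA_real_)
  structure(baf, class = c("ratio_matrix", class(baf)))
}

#' Standardize allele ratios against reference samples
#'
#' For each marker, the reference samples' raw ratios are grouped by
#' their known dosage; a dosage cluster is usable when it has at least
#' `min_cluster` samples, and a marker is usable when it has at least two
#' usable clusters. Cluster means are mapped to the expected positions
#' d/m_ref by linear interpolation (constant extrapolation beyond the
#' outer clusters, then clamped to [0, 1]) and the transform is applied
#' to all samples. Markers failing the precondition are dropped and
#' listed in the `skipped` attribute.
#'
#' @param baf A [ratio_matrix()].
#' @param ref_samples Sample ids (column names) of the reference set.
#' @param ref_dosages Dosage matrix (loci x reference samples) for the
#'   reference set, NA where unknown.
#' @param ref_ploidy Ploidy of the reference samples (scalar m_ref).
#' @param min_cluster Minimum samples per usable dosage cluster.
#' @return Standardized `ratio_matrix` restricted to usable markers, with
#'   attribute `skipped` (locus ids excluded).
#' @export
standardize_baf <- function(baf, ref_samples, ref_dosages, ref_ploidy = 2L,
                            min_cluster = 3L) {
  jref <- match(ref_samples, colnames(baf))
  if (anyNA(jref)) stop("reference sample(s) not in ratio matrix")
  p <- nrow(baf)
  out <- matrix(NA_real_, p, ncol(baf), dimnames = dimnames(baf))
  usable <- logical(p)
  for (i in seq_len(p)) {
    x <- baf[i, jref]
    d <- ref_dosages[i, ]
    ok <- !is.na(x) & !is.na(d)
    if (!any(ok)) next
    means <- tapply(x[ok], d[ok], mean)
    sizes <- tapply(x[ok], d[ok], length)
    means <- means[sizes >= min_cluster]
    if (length(means) < 2L) next
    dd <- as.numeric(names(means))
    o <- order(means)
    knots_x <- means[o]
    knots_y <- (dd / ref_ploidy)[o]
    if (any(diff(knots_x) <= 0)) next   # degenerate, non-monotone clusters
    tr <- stats::approx(knots_x, knots_y, xout = baf[i, ], rule = 2L)$y
    out[i, ] <- pmin(pmax(tr, 0), 1)
    usable[i] <- TRUE
  }
  if (!any(usable)) stop("no marker passed the standardization precondition")
  res <- out[usable, , drop = FALSE]
  attr(res, "skipped") <- rownames(baf)[!usable]
  class(res) <- c("ratio_matrix", "matrix", "array")
  res
}

#' Call per-sample ploidy from standardized ratios
#'
#' For each candidate ploidy m, the score is the mean distance of the
#' sample's heterozygous-band ratios (inside `het_band`) to the nearest
#' expected interior peak k/m, plus `lambda` times the fraction of
#' interior peaks with occupancy below `occ_min` (a candidate whose
#' expected peaks are empty is penalized). Occupancy of a peak is the
#' share of het-band ratios within 0.04 of it: a tight window, so the
#' noise tails of a neighboring dosage class do not register as
#' occupancy. The call is the candidate with the lowest score; samples
#' with fewer than `min_markers` heterozygous-band markers are
#' `undetermined` (NA call).
#'
#' @param std Standardized [ratio_matrix()].
#' @param candidates Candidate ploidies (default diploid/tetraploid).
#' @param het_band Interval of ratios treated as heterozygous.
#' @param lambda Weight of the peak-occupancy penalty.
#' @param occ_min Minimum occupancy for a peak to count as present.
#' @param min_markers Minimum heterozygous-band markers per sample.
#' @return Data frame per sample: `sample_id`, one `score_<m>` column per
#'   candidate, `call` (NA = undetermined), `margin` (second best minus
#'   best), `n_het_markers`.
#' @export
call_ploidy <- function(std, candidates = c(2L, 4L),
                        het_band = c(0.1, 0.9), lambda = 0.5,
                        occ_min = 0.05, min_markers = 50L) {
  ns <- ncol(std)
  scores <- matrix(NA_real_, ns, length(candidates),
                   dimnames = list(colnames(std), paste0("score_", candidates)))
  n_het <- integer(ns)
  for (j in seq_len(ns)) {
    x <- std[, j]
    x <- x[!is.na(x) & x > het_band[1] & x < het_band[2]]
    n_het[j] <- length(x)
    if (length(x) < min_markers) next
    for (k in seq_along(candidates)) {
      m <- candidates[k]
      peaks <- (1:(m - 1)) / m
      dmat <- abs(outer(x, peaks, `-`))
      nearest <- max.col(-dmat)
      # occupancy of a peak: share of het-band ratios within +/- 0.04 of
      # it (a tight window so noise tails of a neighboring class do not
      # count as occupancy)
      occ <- colMeans(dmat <= 0.04)
      scores[j, k] <- mean(dmat[cbind(seq_along(x), nearest)]) +
        lambda * mean(occ < occ_min)
    }
  }
  call <- rep(NA_integer_, ns)
  margin <- rep(NA_real_, ns)
  done <- n_het >= min_markers
  if (any(done)) {
    best <- apply(scores[done, , drop = FALSE], 1L, which.min)
    call[done] <- candidates[best]
    margin[done] <- apply(scores[done, , drop = FALSE], 1L, function(s) {
      s <- sort(s); if (length(s) > 1L) s[2] - s[1] else 0
    })
  }
  out <- data.frame(sample_id = colnames(std), stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(scores))
  out$call <- call
  out$margin <- margin
  out$n_het_markers <- n_het
  rownames(out) <- NULL
  out
}

#' Two-pass ploidy estimation workflow
#'
#' Pass 1 calls tentative dosages for every sample under a provisional
#' diploid assumption ([fit_norm_model()] at m = 2), standardizes the
#' allele ratios against all samples, and calls ploidy. Pass 2
#' re-standardizes using only the samples confirmed diploid in pass 1 and
#' calls again; pass-2 calls are returned, with the pass-1 table attached.
#'
#' @param counts A [count_matrix()].
#' @param candidates,het_band,lambda,occ_min,min_markers Passed to
#'   [call_ploidy()].
#' @param min_reads Read threshold for observed cells.
#' @return The pass-2 call data frame, with attributes `pass1` (the
#'   pass-1 calls) and `n_reference` (diploid reference count used).
#' @export
ploidy_pipeline <- function(counts, candidates = c(2L, 4L),
                            het_band = c(0.1, 0.9), lambda = 0.5,
                            occ_min = 0.05, min_markers = 50L,
                            min_reads = 10L) {
  baf <- ratio_matrix(counts, min_reads)
  tent <- fit_norm_model(counts, m = 2L, min_reads = min_reads)
  all_ids <- counts$samples$sample_id
  std1 <- standardize_baf(baf, all_ids, tent$geno$dosage, ref_ploidy = 2L)
  pass1 <- call_ploidy(std1, candidates, het_band, lambda,
                       occ_min = occ_min, min_markers = min_markers)
  dip <- pass1$sample_id[!is.na(pass1$call) & pass1$call == 2L]
  if (length(dip) < 3L) {
    warning("fewer than 3 confirmed diploids; returning pass-1 calls")
    return(pass1)
  }
  std2 <- standardize_baf(baf, dip,
                          tent$geno$dosage[, match(dip, all_ids), drop = FALSE],
                          ref_ploidy = 2L)
  pass2 <- call_ploidy(std2, candidates, het_band, lambda,
                       occ_min = occ_min, min_markers = min_markers)
  attr(pass2, "pass1") <- pass1
  attr(pass2, "n_reference") <- length(dip)
  pass2
}
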