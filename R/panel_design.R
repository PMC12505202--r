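# Candidate-SNP filtering and even-genomic-distribution selection for
# mid-density panel design.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test for a biallelic variant: given the allele
#' totals, the p-value is the summed probability of all heterozygote
#' counts whose conditional probability does not exceed that of the
#' observed count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectorized).
#' @return p-value(s) in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (length(n_Aa) > 1L || length(n_AA) > 1L || length(n_aa) > 1L) {
    k <- max(length(n_AA), length(n_Aa), length(n_aa))
    n_AA <- rep_len(n_AA, k); n_Aa <- rep_len(n_Aa, k); n_aa <- rep_len(n_aa, k)
    return(vapply(seq_len(k), function(i)
      hwe_exact_test(n_AA[i], n_Aa[i], n_aa[i]), 0))
  }
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop("need at least one genotyped sample")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)
  rare <- min(nA, na)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(n_Aa = h | n, nA) up to a constant
  lp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) + hets * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_Aa)
  if (!length(obs)) stop("observed heterozygote count inconsistent with allele totals")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Filter candidate variants for panel design
#'
#' Pass requires a quality score strictly above `quality_min`, MAF
#' strictly above `maf_min`, missing rate strictly below `missing_max`,
#' and a nonsignificant exact HWE test (p strictly above `hwe_alpha`).
#' Per-rule verdicts are retained for audit.
#'
#' @param variants Data frame with columns `quality`, `maf`, `missing`
#'   and genotype counts `n_AA`, `n_Aa`, `n_aa` (or a precomputed
#'   `hwe_p`).
#' @param quality_min,maf_min,missing_max,hwe_alpha Rule thresholds
#'   (defaults 20, 0.05, 0.75, 0.01).
#' @return The input with added columns `hwe_p`, `ok_quality`, `ok_maf`,
#'   `ok_missing`, `ok_hwe`, `pass`.
#' @export
filter_candidates <- function(variants, quality_min = 20, maf_min = 0.05,
                              missing_max = 0.75, hwe_alpha = 0.01) {
  v <- as.data.frame(variants)
  if (is.null(v$hwe_p))
    v$hwe_p <- hwe_exact_test(v$n_AA, v$n_Aa, v$n_aa)
  v$ok_quality <- v$quality > quality_min
  v$ok_maf <- v$maf > maf_min
  v$ok_missing <- v$missing < missing_max
  v$ok_hwe <- v$hwe_p > hwe_alpha
  v$pass <- v$ok_quality & v$ok_maf & v$ok_missing & v$ok_hwe
  v
}

# per-chromosome quotas proportional to length (largest remainder)
.quotas <- function(target_n, chrom_lengths) {
  raw <- target_n * chrom_lengths / sum(chrom_lengths)
  q <- floor(raw)
  rem <- target_n - sum(q)
  if (rem > 0) {
    o <- order(raw - q, decreasing = TRUE)
    q[o[seq_len(rem)]] <- q[o[seq_len(rem)]] + 1L
  }
  q
}

#' Select an evenly spaced marker panel
#'
#' Chromosome quotas are proportional to physical length; each
#' chromosome is divided into quota-many equal bins and the top variant
#' per bin is picked by priority (QTL flag, then genic flag, then highest
#' MAF, then position/id for determinism). A user-supplied `mandatory`
#' list is always included and counted against its bins. Bins left empty
#' are backfilled by a second pass that repeatedly adds the passed
#' variant most reducing the current maximum inter-marker gap on its
#' chromosome.
#'
#' @param variants Data frame of passed candidates: `locus_id`, `chrom`,
#'   `pos`, `maf`, logical `qtl`, `genic`.
#' @param target_n Total panel size (at most the number of candidates).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param mandatory Locus ids that must be in the panel.
#' @return List with `selected` (data frame with a `bin` provenance
#'   column; backfilled rows have bin NA) and `quota` per chromosome.
#' @export
select_even <- function(variants, target_n, chrom_lengths,
                        mandatory = character(0)) {
  v <- as.data.frame(variants)
  if (target_n > nrow(v)) stop("target_n exceeds the number of candidates")
  if (is.null(v$qtl)) v$qtl <- FALSE
  if (is.null(v$genic)) v$genic <- FALSE
  if (!all(mandatory %in% v$locus_id))
    stop("mandatory locus absent from candidates: ",
         paste(setdiff(mandatory, v$locus_id), collapse = ", "))
  chroms <- names(chrom_lengths)
  if (is.null(chroms)) {
    chroms <- as.character(sort(unique(v$chrom)))
    names(chrom_lengths) <- chroms
  }
  quota <- .quotas(target_n, chrom_lengths)
  names(quota) <- chroms
  sel <- character(0)
  bin_of <- character(0)
  for (c in chroms) {
    qc <- quota[[c]]
    if (qc < 1L) next
    vc <- v[as.character(v$chrom) == c, , drop = FALSE]
    if (!nrow(vc)) next
    brk <- seq(0, chrom_lengths[[c]], length.out = qc + 1L)
    bin <- pmin(pmax(findInterval(vc$pos, brk, rightmost.closed = TRUE), 1L), qc)
    for (b in seq_len(qc)) {
      cand <- vc[bin == b, , drop = FALSE]
      if (!nrow(cand)) next
      mand_here <- cand$locus_id[cand$locus_id %in% mandatory]
      pick <- mand_here
      if (!length(pick)) {
        o <- order(-cand$qtl, -cand$genic, -cand$maf, cand$pos, cand$locus_id)
        pick <- cand$locus_id[o[1L]]
      }
      sel <- c(sel, pick)
      bin_of <- c(bin_of, rep(paste0(c, ":", b), length(pick)))
    }
  }
  # mandatory loci not yet captured (e.g. sharing a bin with another pick)
  extra_mand <- setdiff(mandatory, sel)
  sel <- c(sel, extra_mand)
  bin_of <- c(bin_of, rep(NA_character_, length(extra_mand)))
  # backfill toward target_n by max-gap reduction
  while (length(sel) < target_n) {
    pool <- v[!(v$locus_id %in% sel), , drop = FALSE]
    if (!nrow(pool)) break
    best <- NULL; best_gain <- -Inf
    for (c in unique(as.character(pool$chrom))) {
      cur <- sort(c(0, v$pos[v$locus_id %in% sel & as.character(v$chrom) == c],
                    chrom_lengths[[c]]))
      gaps <- diff(cur)
      gi <- which.max(gaps)
      lo <- cur[gi]; hi <- cur[gi + 1L]
      cand <- pool[as.character(pool$chrom) == c &
                     pool$pos > lo & pool$pos < hi, , drop = FALSE]
      if (!nrow(cand)) next
      mid <- (lo + hi) / 2
      ci <- which.min(abs(cand$pos - mid))
      gain <- gaps[gi] - max(cand$pos[ci] - lo, hi - cand$pos[ci])
      if (gain > best_gain) { best_gain <- gain; best <- cand$locus_id[ci] }
    }
    if (is.null(best)) break
    sel <- c(sel, best)
    bin_of <- c(bin_of, NA_character_)
  }
  out <- v[match(sel, v$locus_id), , drop = FALSE]
  out$bin <- bin_of
  list(selected = out, quota = quota)
}
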