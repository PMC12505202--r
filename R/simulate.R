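# Synthetic read-count generator.
#
# Emulates the statistical structure the analysis assumes: a 12-chromosome
# genome, per-locus founder allele frequencies, negative-binomial read
# depth, beta-binomial allele reads with per-locus allele bias and
# sequencing error, Haldane (no-interference) crossovers for F1 gametes,
# colchicine-doubled tetraploid dosage patterns, and two-sub-genome
# hybrids with locus-level amplification classes. Every generator returns
# the ground truth used to score downstream modules.
#
# All randomness flows from cfg$seed; each operation seeds its own stream
# as cfg$seed + a fixed small offset (cohort +1, f1 +2, hybrid +3) so runs
# are reproducible per operation and independent across operations.

#' Simulation configuration
#'
#' Defaults emulate the mid-density cranberry panel setting: 12
#' chromosomes of roughly 41 Mbp / 94 cM each, 3059 target loci, mean
#' target depth 60 reads (negative binomial, size 8), mild lognormal
#' allele bias, overdispersion 0.01 and sequencing error 0.005. Founder
#' alternative-allele frequencies are uniform on `founder_freq_range`.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len_bp Per-chromosome physical length (bp), recycled.
#' @param chrom_len_cM Per-chromosome map length (cM), recycled.
#' @param n_loci Total loci, spread across chromosomes proportionally to
#'   physical length.
#' @param founder_freq_range Range of founder alt-allele frequencies.
#' @param depth_mean,depth_size Negative-binomial depth mean and size
#'   (smaller size = more overdispersed depth).
#' @param bias_sdlog SD of log allele bias h (h ~ lognormal(0, bias_sdlog)).
#' @param rho Beta-binomial overdispersion in [0, 1).
#' @param eps Sequencing error rate in [0, 0.5).
#' @param seed Master seed; every generator derives its stream from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 12L, chrom_len_bp = 41e6,
                       chrom_len_cM = 94, n_loci = 3059L,
                       founder_freq_range = c(0.1, 0.9),
                       depth_mean = 60, depth_size = 8,
                       bias_sdlog = 0.25, rho = 0.01, eps = 0.005,
                       seed = 1L) {
  stopifnot(n_loci >= 1, rho >= 0, rho < 1, eps >= 0, eps < 0.5,
            depth_mean > 0, depth_size > 0)
  structure(list(n_chrom = n_chrom,
                 chrom_len_bp = rep(chrom_len_bp, length.out = n_chrom),
                 chrom_len_cM = rep(chrom_len_cM, length.out = n_chrom),
                 n_loci = as.integer(n_loci),
                 founder_freq_range = founder_freq_range,
                 depth_mean = depth_mean, depth_size = depth_size,
                 bias_sdlog = bias_sdlog, rho = rho, eps = eps,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# marker map: loci placed uniformly at random, sorted, per chromosome
.sim_markers <- function(cfg) {
  quota <- round(cfg$n_loci * cfg$chrom_len_bp / sum(cfg$chrom_len_bp))
  quota[1] <- quota[1] + cfg$n_loci - sum(quota)
  chrom <- rep(seq_len(cfg$n_chrom), quota)
  pos <- unlist(lapply(seq_len(cfg$n_chrom), function(c)
    sort(sample.int(cfg$chrom_len_bp[c], quota[c]))))
  cm <- pos / cfg$chrom_len_bp[chrom] * cfg$chrom_len_cM[chrom]
  data.frame(locus_id = sprintf("L%04d", seq_len(cfg$n_loci)),
             chrom = chrom, pos = pos, cM = cm,
             ref = "A", alt = "T", stringsAsFactors = FALSE)
}

# reads for a dosage matrix (loci x samples); ploidy per sample
.sim_reads <- function(cfg, dosage, ploidy, h = NULL) {
  p <- nrow(dosage); n <- ncol(dosage)
  if (is.null(h)) h <- stats::rlnorm(p, 0, cfg$bias_sdlog)
  ploidy <- rep(ploidy, length.out = n)
  depth <- matrix(stats::rnbinom(p * n, mu = cfg$depth_mean,
                                 size = cfg$depth_size), p, n)
  frac <- sweep(dosage, 2L, ploidy, `/`)
  xi0 <- frac * (1 - cfg$eps) + (1 - frac) * cfg$eps
  xi <- xi0 / (h * (1 - xi0) + xi0)       # h recycles by row
  if (cfg$rho > 1e-9) {
    s <- (1 - cfg$rho) / cfg$rho
    pmat <- matrix(stats::rbeta(p * n, xi * s, (1 - xi) * s), p, n)
  } else pmat <- xi
  alt <- matrix(stats::rbinom(p * n, depth, pmat), p, n)
  list(ref = depth - alt, alt = alt, h = h)
}

.sim_sheet <- function(ids, group, ploidy, parent1 = NA, parent2 = NA) {
  data.frame(sample_id = ids, group = group,
             nominal_ploidy = rep(ploidy, length.out = length(ids)),
             parent1 = parent1, parent2 = parent2,
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of unrelated samples
#'
#' Dosages are binomial in the founder allele frequency at the sample's
#' ploidy. `colchicine_gen = 1` models a first-generation
#' chromosome-doubled tetraploid: a diploid dosage is drawn and doubled,
#' so only dosages 0/2/4 occur and allele ratios cluster at 0, 0.5, 1
#' exactly as in a diploid. `colchicine_gen = 2` crosses two independent
#' first-generation tetraploids with tetrasomic (hypergeometric) gametes,
#' restoring intermediate dosages.
#'
#' @param cfg A [sim_config()].
#' @param n_samples Number of samples.
#' @param ploidy 2 or 4.
#' @param colchicine_gen 0 (natural), 1 or 2 (tetraploids only).
#' @return List with `markers`, `counts` (a [count_matrix()]) and `truth`
#'   (list: `dosage`, `ploidy`, `founder_freq`, `h`).
#' @export
simulate_cohort <- function(cfg, n_samples, ploidy,
                            colchicine_gen = 0L) {
  stopifnot(ploidy %in% c(2L, 4L))
  if (colchicine_gen > 0L && ploidy != 4L)
    stop("colchicine_gen > 0 requires ploidy 4")
  set.seed(cfg$seed + 1L)
  mk <- .sim_markers(cfg)
  p <- nrow(mk)
  f <- stats::runif(p, cfg$founder_freq_range[1], cfg$founder_freq_range[2])
  if (colchicine_gen == 0L) {
    dosage <- matrix(stats::rbinom(p * n_samples, ploidy, f), p, n_samples)
  } else if (colchicine_gen == 1L) {
    dosage <- 2L * matrix(stats::rbinom(p * n_samples, 2L, f), p, n_samples)
  } else {
    # gametes of gen-1 parents: parent dosage 2*Bin(2,f); a tetrasomic
    # gamete takes 2 of the 4 homologues -> hypergeometric in the dosage
    gen2 <- function() {
      d1 <- 2L * stats::rbinom(p, 2L, f)
      d2 <- 2L * stats::rbinom(p, 2L, f)
      stats::rhyper(p, d1, 4L - d1, 2L) + stats::rhyper(p, d2, 4L - d2, 2L)
    }
    dosage <- vapply(seq_len(n_samples), function(i) gen2(), integer(p))
  }
  rd <- .sim_reads(cfg, dosage, ploidy)
  ids <- sprintf("S%03d", seq_len(n_samples))
  cm <- count_matrix(rd$ref, rd$alt, mk,
                     .sim_sheet(ids, "cohort", ploidy))
  list(markers = mk, counts = cm,
       truth = list(dosage = dosage, ploidy = rep(ploidy, n_samples),
                    founder_freq = f, h = rd$h,
                    colchicine_gen = colchicine_gen))
}

# one gamete from a phased diploid parent (2 x p haplotype matrix) via
# Haldane model: recombination between adjacent markers with probability
# (1 - exp(-2 d_Morgan)) / 2, independent across intervals
.haldane_gamete <- function(hap, chrom, cM) {
  p <- ncol(hap)
  out <- integer(p)
  nrec <- 0L
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    d <- diff(cM[idx]) / 100
    r <- (1 - exp(-2 * d)) / 2
    sw <- c(stats::runif(1) < 0.5, stats::runif(length(r)) < r)
    strand <- 1L + (cumsum(sw) %% 2L)
    out[idx] <- hap[cbind(strand, idx)]
    nrec <- nrec + sum(sw[-1])
  }
  list(gamete = out, n_crossover = nrec)
}

#' Simulate a diploid F1 population
#'
#' Two phased diploid founders produce `n_offspring` offspring; each
#' gamete is generated by Haldane crossovers (no interference) along the
#' simulated map. Optional contaminant samples are unrelated founders,
#' mimicking pollen-contamination outliers. Parents are included as the
#' first two samples of the returned count matrix.
#'
#' @param cfg A [sim_config()].
#' @param n_offspring Number of true offspring (>= 1).
#' @param n_contaminants Number of unrelated contaminant samples.
#' @param parents Optional phased parents from a previous call (element
#'   `truth$parent_hap`), to reuse the same cross.
#' @return List with `markers`, `counts`, and `truth` (dosage matrix for
#'   all samples, parent haplotypes, per-offspring crossover counts,
#'   `is_contaminant`, founder frequencies, `h`).
#' @export
simulate_f1 <- function(cfg, n_offspring, n_contaminants = 0L,
                        parents = NULL) {
  stopifnot(n_offspring >= 1)
  set.seed(cfg$seed + 2L)
  mk <- .sim_markers(cfg)
  p <- nrow(mk)
  f <- stats::runif(p, cfg$founder_freq_range[1], cfg$founder_freq_range[2])
  if (is.null(parents)) {
    hap1 <- matrix(stats::rbinom(2L * p, 1L, f), 2L, p, byrow = TRUE)
    hap2 <- matrix(stats::rbinom(2L * p, 1L, f), 2L, p, byrow = TRUE)
  } else { hap1 <- parents[[1]]; hap2 <- parents[[2]] }
  off <- matrix(0L, p, n_offspring)
  ncx <- integer(n_offspring)
  for (k in seq_len(n_offspring)) {
    g1 <- .haldane_gamete(hap1, mk$chrom, mk$cM)
    g2 <- .haldane_gamete(hap2, mk$chrom, mk$cM)
    off[, k] <- g1$gamete + g2$gamete
    ncx[k] <- g1$n_crossover + g2$n_crossover
  }
  cont <- if (n_contaminants > 0L)
    matrix(stats::rbinom(p * n_contaminants, 2L, f), p, n_contaminants)
  else matrix(0L, p, 0L)
  dosage <- cbind(colSums(hap1), colSums(hap2), off, cont)
  n_tot <- ncol(dosage)
  rd <- .sim_reads(cfg, dosage, 2L)
  ids <- c("P1", "P2", sprintf("F1_%03d", seq_len(n_offspring)),
           if (n_contaminants > 0L) sprintf("CT_%03d", seq_len(n_contaminants)))
  sheet <- .sim_sheet(ids,
                      c("parent", "parent", rep("f1", n_offspring),
                        rep("f1", n_contaminants)), 2L,
                      parent1 = c(NA, NA, rep("P1", n_offspring + n_contaminants)),
                      parent2 = c(NA, NA, rep("P2", n_offspring + n_contaminants)))
  cm <- count_matrix(rd$ref, rd$alt, mk, sheet)
  list(markers = mk, counts = cm,
       truth = list(dosage = dosage, ploidy = rep(2L, n_tot),
                    parent_hap = list(hap1, hap2), n_crossover = ncx,
                    is_contaminant = c(FALSE, FALSE,
                                       rep(FALSE, n_offspring),
                                       rep(TRUE, n_contaminants)),
                    founder_freq = f, h = rd$h))
}

#' Simulate a two-sub-genome hybrid panel
#'
#' Models interspecific hybrids whose loci amplify from the cranberry
#' sub-genome, the blueberry sub-genome, both, or neither ("failed").
#' Parents are five tetraploid cranberry and two blueberry samples;
#' hybrids carry two copies of each sub-genome. Reads are generated only
#' from the amplifying sub-genome(s); non-amplifying samples at a locus
#' receive uniform 0..`noise_max` background depth.
#'
#' @param cfg A [sim_config()].
#' @param n_offspring Number of hybrid samples.
#' @param class_proportions Named numeric (cran, blue, shared), summing to
#'   <= 1; the remainder is the failed-locus proportion.
#' @param noise_max Maximum background total depth at non-amplifying
#'   cells (default 2).
#' @return List with `markers`, `counts` (7 parents then hybrids),
#'   `truth` (locus `class`, hybrid dosages on the amplifying sub-genome
#'   scale, parent dosages, `h`).
#' @export
simulate_hybrid <- function(cfg, n_offspring = 18L,
                            class_proportions = c(cran = 0.4, blue = 0.35,
                                                  shared = 0.2),
                            noise_max = 2L) {
  if (any(class_proportions < 0)) stop("negative class proportions")
  if (sum(class_proportions) > 1) stop("class proportions must sum to <= 1")
  set.seed(cfg$seed + 3L)
  mk <- .sim_markers(cfg)
  p <- nrow(mk)
  cls <- sample(c("cran_specific", "blue_specific", "shared", "failed"), p,
                replace = TRUE,
                prob = c(class_proportions, 1 - sum(class_proportions)))
  f_c <- stats::runif(p, cfg$founder_freq_range[1], cfg$founder_freq_range[2])
  f_b <- stats::runif(p, cfg$founder_freq_range[1], cfg$founder_freq_range[2])
  n_cran <- 5L; n_blue <- 2L
  cran_d <- matrix(stats::rbinom(p * n_cran, 4L, f_c), p, n_cran)
  blue_d <- matrix(stats::rbinom(p * n_blue, 4L, f_b), p, n_blue)
  # hybrid: 2 cranberry-derived + 2 blueberry-derived copies
  hyb_c <- matrix(stats::rbinom(p * n_offspring, 2L, f_c), p, n_offspring)
  hyb_b <- matrix(stats::rbinom(p * n_offspring, 2L, f_b), p, n_offspring)
  h <- stats::rlnorm(p, 0, cfg$bias_sdlog)

  amp_c <- cls %in% c("cran_specific", "shared")   # cranberry sub-genome amplifies
  amp_b <- cls %in% c("blue_specific", "shared")
  noise <- function(nr, nc) {
    tot <- matrix(sample.int(noise_max + 1L, nr * nc, replace = TRUE) - 1L, nr, nc)
    list(ref = tot, alt = matrix(0L, nr, nc))
  }
  fill <- function(dos, ploidy, amp) {
    out_r <- matrix(0L, p, ncol(dos)); out_a <- out_r
    if (any(amp)) {
      rd <- .sim_reads(cfg, dos[amp, , drop = FALSE], ploidy, h = h[amp])
      out_r[amp, ] <- rd$ref; out_a[amp, ] <- rd$alt
    }
    if (any(!amp)) {
      nz <- noise(sum(!amp), ncol(dos))
      out_r[!amp, ] <- nz$ref; out_a[!amp, ] <- nz$alt
    }
    list(ref = out_r, alt = out_a)
  }
  cran_rd <- fill(cran_d, 4L, amp_c)
  blue_rd <- fill(blue_d, 4L, amp_b)
  # hybrids: amplifying dosage is the sum over amplifying sub-genomes
  hyb_dos <- matrix(0L, p, n_offspring)
  hyb_dos[cls == "cran_specific", ] <- hyb_c[cls == "cran_specific", ]
  hyb_dos[cls == "blue_specific", ] <- hyb_b[cls == "blue_specific", ]
  hyb_dos[cls == "shared", ] <- hyb_c[cls == "shared", ] + hyb_b[cls == "shared", ]
  hyb_ploidy <- ifelse(cls == "shared", 4L, 2L)  # per locus, handled rowwise
  hyb_rd <- list(ref = matrix(0L, p, n_offspring),
                 alt = matrix(0L, p, n_offspring))
  for (group in c("cran_specific", "blue_specific", "shared")) {
    rows <- cls == group
    if (!any(rows)) next
    pl <- if (group == "shared") 4L else 2L
    rd <- .sim_reads(cfg, hyb_dos[rows, , drop = FALSE], pl, h = h[rows])
    hyb_rd$ref[rows, ] <- rd$ref; hyb_rd$alt[rows, ] <- rd$alt
  }
  fl <- cls == "failed"
  if (any(fl)) {
    nz <- noise(sum(fl), n_offspring)
    hyb_rd$ref[fl, ] <- nz$ref; hyb_rd$alt[fl, ] <- nz$alt
  }
  ids <- c(sprintf("CRAN4x_%d", 1:n_cran), sprintf("BLUE_%d", 1:n_blue),
           sprintf("HYB_%03d", seq_len(n_offspring)))
  sheet <- .sim_sheet(ids, c(rep("cran_parent", n_cran),
                             rep("blue_parent", n_blue),
                             rep("hybrid", n_offspring)), 4L)
  cm <- count_matrix(cbind(cran_rd$ref, blue_rd$ref, hyb_rd$ref),
                     cbind(cran_rd$alt, blue_rd$alt, hyb_rd$alt),
                     mk, sheet)
  list(markers = mk, counts = cm,
       truth = list(class = cls, hybrid_dosage = hyb_dos,
                    cran_parent_dosage = cran_d, blue_parent_dosage = blue_d,
                    h = h))
}
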