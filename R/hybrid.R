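# Sub-genome classification of panel loci in interspecific hybrids and
# per-class dosage calling.

#' Classify loci by parental sub-genome amplification
#'
#' Using the total (Ref + Alt) read counts of the two parental groups, a
#' locus is cranberry sub-genome specific when the blueberry parents show
#' at most `threshold` reads while the cranberry parents exceed it;
#' blueberry-specific in the converse case; shared when both groups
#' exceed the threshold; failed when neither does. By default "across the
#' group" is read as the sum of reads over the group's samples; set
#' `rule = "each"` to require every sample individually above/below the
#' threshold instead.
#'
#' @param counts A [count_matrix()].
#' @param blue_parents,cran_parents Sample ids of the two parent groups.
#' @param threshold Read threshold (default 10).
#' @param rule "sum" (default) or "each".
#' @return Data frame per locus: `locus_id`, `label` (one of
#'   `cran_specific`, `blue_specific`, `shared`, `failed`), and the group
#'   read totals `blue_reads`, `cran_reads`.
#' @export
classify_loci <- function(counts, blue_parents, cran_parents,
                          threshold = 10L, rule = c("sum", "each")) {
  rule <- match.arg(rule)
  ids <- counts$samples$sample_id
  if (!length(blue_parents) || !length(cran_parents))
    stop("both parent groups must be non-empty")
  unknown <- setdiff(c(blue_parents, cran_parents), ids)
  if (length(unknown))
    stop("unknown parent id(s): ", paste(unknown, collapse = ", "))
  total <- counts$ref + counts$alt
  jb <- match(blue_parents, ids)
  jc <- match(cran_parents, ids)
  B <- rowSums(total[, jb, drop = FALSE])
  C <- rowSums(total[, jc, drop = FALSE])
  if (rule == "sum") {
    blue_on <- B > threshold
    cran_on <- C > threshold
  } else {
    blue_on <- apply(total[, jb, drop = FALSE] > threshold, 1L, all)
    cran_on <- apply(total[, jc, drop = FALSE] > threshold, 1L, all)
  }
  label <- ifelse(cran_on & !blue_on, "cran_specific",
           ifelse(blue_on & !cran_on, "blue_specific",
           ifelse(blue_on & cran_on, "shared", "failed")))
  data.frame(locus_id = counts$markers$locus_id, label = label,
             blue_reads = B, cran_reads = C, stringsAsFactors = FALSE)
}

#' Call hybrid dosages per locus class
#'
#' Genome-specific loci (only one sub-genome amplifies) are called at
#' ploidy `specific_ploidy` (default 1, presence/absence of the
#' alternative allele); loci shared by both sub-genomes are called at
#' `shared_ploidy` (default 4). Failed loci are excluded. Calls use the
#' "norm" dosage model.
#'
#' @param counts A [count_matrix()].
#' @param classes Data frame from [classify_loci()].
#' @param hybrid_samples Sample ids of the hybrids to genotype.
#' @param specific_ploidy,shared_ploidy Ploidy settings per class.
#' @param min_reads Read threshold for observed cells.
#' @return List with `geno` (dosage matrix, rows = non-failed loci,
#'   columns = hybrids; specific loci in 0..specific_ploidy, shared loci
#'   in 0..shared_ploidy), `fits` (combined fit table with a `class`
#'   column), and `classes` used.
#' @export
call_hybrid_dosages <- function(counts, classes, hybrid_samples,
                                specific_ploidy = 1L, shared_ploidy = 4L,
                                min_reads = 10L) {
  stopifnot(identical(classes$locus_id, counts$markers$locus_id))
  hy <- counts[, hybrid_samples]
  spec <- classes$label %in% c("cran_specific", "blue_specific")
  shar <- classes$label == "shared"
  pieces <- list()
  fits <- list()
  if (any(spec)) {
    fs <- fit_norm_model(hy[spec, ], m = specific_ploidy, min_reads = min_reads)
    pieces$spec <- fs$geno$dosage
    fs$fits$class <- "specific"
    fits$spec <- fs$fits
  }
  if (any(shar)) {
    fh <- fit_norm_model(hy[shar, ], m = shared_ploidy, min_reads = min_reads)
    pieces$shar <- fh$geno$dosage
    fh$fits$class <- "shared"
    fits$shar <- fh$fits
  }
  geno <- do.call(rbind, pieces)
  list(geno = geno, fits = do.call(rbind, fits),
       classes = classes[!classes$label == "failed", , drop = FALSE])
}
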