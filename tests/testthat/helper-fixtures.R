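# Shared fixtures, built in code at test time.

toy_sheet <- function(ids = c("A", "B", "C"), ploidy = 2L) {
  data.frame(sample_id = ids, group = "toy",
             nominal_ploidy = rep(ploidy, length.out = length(ids)),
             parent1 = NA_character_, parent2 = NA_character_,
             stringsAsFactors = FALSE)
}

# write a toy MADC CSV; rows = list of c(AlleleID, counts...)
write_toy_madc <- function(rows, ids = c("A", "B", "C")) {
  path <- tempfile(fileext = ".csv")
  header <- paste(c("AlleleID", "CloneID", "AlleleSequence", ids),
                  collapse = ",")
  lines <- vapply(rows, function(r) {
    locus <- sub("\\|.*$", "", r[[1]])
    paste(c(r[[1]], locus, strrep("N", 81), r[-1]), collapse = ",")
  }, "")
  writeLines(c(header, lines), path)
  path
}

toy_counts <- function(ref, alt, ids = NULL, ploidy = 2L) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (is.null(ids)) ids <- paste0("S", seq_len(ncol(ref)))
  mk <- data.frame(locus_id = paste0("L", seq_len(nrow(ref))),
                   stringsAsFactors = FALSE)
  count_matrix(ref, alt, mk, toy_sheet(ids, ploidy))
}

# an F1 truth dosage matrix as a named genotype matrix input
f1_truth_geno <- function(sim) {
  d <- sim$truth$dosage
  rownames(d) <- sim$markers$locus_id
  colnames(d) <- sim$counts$samples$sample_id
  d
}
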