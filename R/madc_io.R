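# Parsing, validation and writing of the MADC (missing allele discovery
# count) read-count dialect, plus target-SNP window deduplication.
#
# Dialect: CSV, UTF-8, header
#   AlleleID,CloneID,AlleleSequence,<sample_1>,...,<sample_n>
# with AlleleID = "<locus_id>|<Ref|Alt|Other_k>" and non-negative integer
# count cells. Only Ref (exact reference match) and Alt (one variant at the
# target SNP site) microhaplotypes enter genotype computation; Other rows
# are tallied in the parse report and otherwise ignored.

#' Construct a count matrix container
#'
#' Holds per-locus, per-sample Ref and Alt read counts together with the
#' marker table and sample sheet they are indexed by. This is the central
#' data container consumed by the QC, ploidy, dosage, hybrid and linkage
#' functions.
#'
#' @param ref,alt Integer matrices, loci x samples, non-negative. Rownames
#'   are locus ids, colnames sample ids.
#' @param markers Data frame with at least `locus_id`; optionally `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `flags`.
#' @param samples Sample sheet data frame (see [read_sample_sheet()]).
#' @return An object of class `count_matrix`: a list with elements `ref`,
#'   `alt`, `markers`, `samples`.
#' @export
count_matrix <- function(ref, alt, markers, samples) {
  ref <- as.matrix(ref)
  alt <- as.matrix(alt)
  storage.mode(ref) <- "double"
  storage.mode(alt) <- "double"
  stopifnot(identical(dim(ref), dim(alt)))
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  if (nrow(ref) != nrow(markers))
    stop("marker table does not match count matrix rows")
  if (ncol(ref) != nrow(samples))
    stop("sample sheet does not match count matrix columns")
  rownames(ref) <- rownames(alt) <- markers$locus_id
  colnames(ref) <- colnames(alt) <- samples$sample_id
  structure(list(ref = ref, alt = alt,
                 markers = as.data.frame(markers),
                 samples = as.data.frame(samples)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d loci x %d samples\n",
              nrow(x$ref), ncol(x$ref)))
  cat(sprintf("  total reads: %.0f (Ref) + %.0f (Alt)\n",
              sum(x$ref, na.rm = TRUE), sum(x$alt, na.rm = TRUE)))
  invisible(x)
}

#' Subset a count matrix
#'
#' @param x A `count_matrix`.
#' @param i Marker (row) index: integer, logical, or locus ids.
#' @param j Sample (column) index: integer, logical, or sample ids.
#' @param ... Unused.
#' @return A `count_matrix` restricted to the requested loci and samples.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$ref))
  if (missing(j)) j <- seq_len(ncol(x$ref))
  if (is.character(i)) i <- match(i, x$markers$locus_id)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  count_matrix(x$ref[i, , drop = FALSE][, j, drop = FALSE],
               x$alt[i, , drop = FALSE][, j, drop = FALSE],
               x$markers[i, , drop = FALSE],
               x$samples[j, , drop = FALSE])
}

#' Read a sample sheet
#'
#' Tab-separated file with columns `sample_id`, `group`, `nominal_ploidy`
#' and optional `parent1`, `parent2`. `nominal_ploidy` is the chromosome
#' copy number asserted by the breeder/curator and is used for the
#' singleton polymorphism threshold (each sample contributes `ploidy`
#' gametes) and as candidate truth in ploidy validation.
#'
#' @param path Path to a TSV file.
#' @return Data frame with columns `sample_id`, `group`, `nominal_ploidy`,
#'   `parent1`, `parent2`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "nominal_ploidy")
  if (!all(req %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample_id in sample sheet")
  if (!all(sheet$nominal_ploidy %in% c(1L, 2L, 3L, 4L, 6L)))
    stop("nominal_ploidy must be one of 1, 2, 3, 4, 6")
  for (p in c("parent1", "parent2")) if (is.null(sheet[[p]])) sheet[[p]] <- NA_character_
  sheet
}

#' Read a marker definition table
#'
#' Tab-separated with columns `locus_id`, `chrom`, `pos` (1-based target
#' SNP position), `ref`, `alt` and optional comma-separated `flags`
#' (subset of `genic`, `qtl`).
#'
#' @param path Path to a TSV file.
#' @return Data frame of marker definitions.
#' @export
read_marker_table <- function(path) {
  mk <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("locus_id", "chrom", "pos")
  if (!all(req %in% names(mk)))
    stop("marker table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(mk$locus_id)) stop("duplicated locus_id in marker table")
  if (any(mk$pos < 1)) stop("pos must be >= 1 (1-based coordinates)")
  mk
}

#' Read an MADC read-count file
#'
#' Parses the MADC CSV dialect into a [count_matrix()]. Each locus
#' contributes one `Ref` and (usually) one `Alt` microhaplotype row; only
#' these enter the Ref/Alt count matrices. `Other_k` microhaplotype rows
#' (off-target variants within the amplicon) are counted in the parse
#' report but excluded from all genotype computation. A locus with no Alt
#' row gets an all-zero alt row (absence of the microhaplotype means zero
#' observations) and a warning.
#'
#' @param path Path to the MADC CSV file.
#' @param sheet Sample sheet data frame; every sample column in the file
#'   must appear in it. Columns are returned in file order.
#' @param markers Optional marker definition table used to attach
#'   `chrom`/`pos` to the parsed loci.
#' @return A `count_matrix` with attribute `parse_report`, a list with
#'   `n_other` (Other rows seen per locus), `loci_no_alt`, and
#'   `other_reads` (total read depth observed on Other rows).
#' @export
read_madc <- function(path, sheet, markers = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("AlleleID", "CloneID", "AlleleSequence")
  if (!all(fixed %in% names(raw)))
    stop("not an MADC file: missing columns ", paste(setdiff(fixed, names(raw)), collapse = ", "))
  sample_ids <- setdiff(names(raw), fixed)
  unknown <- setdiff(sample_ids, sheet$sample_id)
  if (length(unknown))
    stop("sample(s) in MADC file absent from sample sheet: ",
         paste(unknown, collapse = ", "))
  parts <- strsplit(raw$AlleleID, "|", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("malformed AlleleID (expected '<locus_id>|<class>'): ",
         raw$AlleleID[which(lengths(parts) != 2)[1]])
  locus <- vapply(parts, `[[`, "", 1L)
  cls <- vapply(parts, `[[`, "", 2L)
  cnt <- as.matrix(raw[, sample_ids, drop = FALSE])
  storage.mode(cnt) <- "double"
  if (anyNA(cnt) || any(cnt < 0)) stop("count cells must be non-negative integers")

  is_ref <- cls == "Ref"
  is_alt <- cls == "Alt"
  is_other <- grepl("^Other(_|$)", cls)
  if (any(!(is_ref | is_alt | is_other)))
    stop("unknown allele class: ", cls[which(!(is_ref | is_alt | is_other))[1]])
  if (anyDuplicated(locus[is_ref]))
    stop("duplicate Ref rows for locus: ",
         locus[is_ref][anyDuplicated(locus[is_ref])])
  if (anyDuplicated(locus[is_alt]))
    stop("duplicate Alt rows for locus: ",
         locus[is_alt][anyDuplicated(locus[is_alt])])

  loci <- unique(locus[is_ref | is_alt])
  ref <- matrix(0, length(loci), length(sample_ids),
                dimnames = list(loci, sample_ids))
  alt <- ref
  ref[locus[is_ref], ] <- cnt[is_ref, , drop = FALSE]
  alt[locus[is_alt], ] <- cnt[is_alt, , drop = FALSE]
  no_alt <- setdiff(loci, locus[is_alt])
  if (length(no_alt))
    warning(length(no_alt), " locus/loci without an Alt row; alt counts set to 0: ",
            paste(utils::head(no_alt, 5), collapse = ", "))

  mk <- data.frame(locus_id = loci, stringsAsFactors = FALSE)
  if (!is.null(markers)) {
    idx <- match(loci, markers$locus_id)
    for (col in setdiff(names(markers), "locus_id")) mk[[col]] <- markers[[col]][idx]
  }
  sm <- sheet[match(sample_ids, sheet$sample_id), , drop = FALSE]
  out <- count_matrix(ref, alt, mk, sm)
  attr(out, "parse_report") <- list(
    n_other = table(locus[is_other]),
    other_reads = sum(cnt[is_other, , drop = FALSE]),
    loci_no_alt = no_alt)
  out
}

#' Write a count matrix in the MADC dialect
#'
#' Inverse of [read_madc()] for the Ref/Alt rows (Other rows are not
#' reconstructed). Reading the written file back reproduces the Ref/Alt
#' counts exactly.
#'
#' @param counts A `count_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_madc <- function(counts, path) {
  loci <- counts$markers$locus_id
  seqs <- if (!is.null(counts$markers$sequence)) counts$markers$sequence
          else strrep("N", 81L)
  rows <- data.frame(
    AlleleID = c(rbind(paste0(loci, "|Ref"), paste0(loci, "|Alt"))),
    CloneID = rep(loci, each = 2L),
    AlleleSequence = rep(seqs, each = 2L),
    stringsAsFactors = FALSE, check.names = FALSE)
  cnt <- matrix(0, nrow(rows), ncol(counts$ref))
  cnt[seq(1, nrow(rows), by = 2L), ] <- counts$ref
  cnt[seq(2, nrow(rows), by = 2L), ] <- counts$alt
  colnames(cnt) <- counts$samples$sample_id
  utils::write.csv(cbind(rows, as.data.frame(cnt, check.names = FALSE)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deduplicate target SNPs within a physical window
#'
#' Amplicons of nearby target SNPs overlap; to keep one target SNP per
#' region, markers are scanned per chromosome in ascending position and a
#' marker is removed when its position lies within `window_bp` (inclusive)
#' of the last *kept* marker. Ties at identical position are broken by
#' lexicographic locus id, so the result is deterministic.
#'
#' @param markers Marker table with `locus_id`, `chrom`, `pos`.
#' @param window_bp Window size in base pairs (default 15).
#' @return List with data frames `kept` and `removed`, partitioning the
#'   input rows.
#' @export
dedup_window <- function(markers, window_bp = 15L) {
  stopifnot(window_bp >= 1)
  if (is.null(markers$pos) || anyNA(markers$pos))
    stop("dedup_window requires a complete pos column")
  ord <- order(markers$chrom, markers$pos, markers$locus_id)
  m <- markers[ord, , drop = FALSE]
  keep <- logical(nrow(m))
  last_chrom <- NA_character_
  last_pos <- -Inf
  for (k in seq_len(nrow(m))) {
    if (!identical(as.character(m$chrom[k]), last_chrom) ||
        m$pos[k] - last_pos > window_bp) {
      keep[k] <- TRUE
      last_chrom <- as.character(m$chrom[k])
      last_pos <- m$pos[k]
    }
  }
  list(kept = m[keep, , drop = FALSE], removed = m[!keep, , drop = FALSE])
}
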