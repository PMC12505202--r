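# Two-point linkage utilities for diploid F1 (outcross) populations:
# marker screening, segregation tests, recombination-fraction / LOD
# estimation with phase enumeration, RF-based filtering, +/-5-neighbor
# physical-order repositioning, linkage-group clustering and a two-point
# map summary.
#
# Informative diploid markers carry one of five parent-dosage patterns:
# (1,0), (1,2)  het x hom (testcross through parent 1)
# (0,1), (2,1)  hom x het (testcross through parent 2)
# (1,1)         het x het (1:2:1)
# A pair of markers is linkage-informative only through a parent that is
# heterozygous at both; likelihoods are maximized over the admissible
# phase configurations on a grid of r in [0, 0.5].

#' Haldane map distance
#'
#' cM = -50 ln(1 - 2r); r at or above 0.5 is capped at 50 cM.
#'
#' @param r Recombination fraction(s) in [0, 0.5].
#' @return Map distance(s) in centimorgans.
#' @export
haldane_cm <- function(r) {
  r <- pmin(pmax(r, 0), 0.5)
  ifelse(r >= 0.5 - 1e-12, 50, -50 * log(1 - 2 * r))
}

#' Inverse Haldane map function
#'
#' @param d Map distance(s) in centimorgans.
#' @return Recombination fraction(s).
#' @export
haldane_r <- function(d) (1 - exp(-2 * d / 100)) / 2

# cross type from diploid parent dosages
.cross_type <- function(p1, p2) {
  if (is.na(p1) || is.na(p2)) return("parent_missing")
  if (p1 == 1L && p2 %in% c(0L, 2L)) return("ab_x_aa")
  if (p2 == 1L && p1 %in% c(0L, 2L)) return("aa_x_ab")
  if (p1 == 1L && p2 == 1L) return("ab_x_ab")
  if (p1 != p2) return("unexpected")      # aa x bb type
  "uninformative"                          # both hom, identical
}

# offspring dosage set possible under parent dosages
.possible_offspring <- function(p1, p2) {
  g <- function(d) if (d == 1L) 0:1 else d / 2L
  sort(unique(outer(g(p1), g(p2), `+`)))
}

#' Screen F1 markers before linkage analysis
#'
#' Removes, in this order (each step logged with counts): markers where a
#' parent call is missing; markers monomorphic in the offspring; markers
#' with parent patterns that cannot segregate or with offspring calls
#' impossible given the parents (fraction above `max_impossible`);
#' redundant markers (identical offspring genotype vectors; the first is
#' kept and recorded as representative); markers with more than
#' `max_missing` offspring missing; and markers failing the segregation
#' chi-square test at a Bonferroni-adjusted p of `alpha` (the divisor is
#' the number of markers entering this final step).
#'
#' @param geno A [genotype_matrix()] (or dosage matrix) containing the
#'   two parents and the offspring.
#' @param parents Character vector of the two parent sample ids.
#' @param max_missing Maximum offspring missing fraction (default 0.1).
#' @param alpha Familywise segregation-test level (default 0.05).
#' @param max_impossible Tolerated fraction of impossible offspring calls
#'   before a marker is declared unexpected (default 0.05).
#' @return List with `info` (data frame for kept markers: marker, p1, p2,
#'   cross_type, seg_p), `kept` (marker ids), `offspring` (dosage matrix
#'   of kept markers x offspring), and `log` (per-step removals).
#' @export
screen_f1_markers <- function(geno, parents, max_missing = 0.1,
                              alpha = 0.05, max_impossible = 0.05) {
  d <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  if (!all(parents %in% colnames(d)))
    stop("parent(s) absent from genotype matrix: ",
         paste(setdiff(parents, colnames(d)), collapse = ", "))
  off_ids <- setdiff(colnames(d), parents)
  P <- d[, parents, drop = FALSE]
  O <- d[, off_ids, drop = FALSE]
  ids <- rownames(d)
  log <- list()
  active <- rep(TRUE, nrow(d))

  step <- function(bad, name) {
    bad <- bad & active
    log[[name]] <<- list(n = sum(bad), markers = ids[bad])
    active[bad] <<- FALSE
  }

  step(is.na(P[, 1L]) | is.na(P[, 2L]), "parent_missing")

  n_classes <- apply(O, 1L, function(x) length(unique(x[!is.na(x)])))
  step(n_classes < 2L, "monomorphic")

  ct <- vapply(seq_len(nrow(d)),
               function(i) .cross_type(P[i, 1L], P[i, 2L]), "")
  imp_frac <- vapply(seq_len(nrow(d)), function(i) {
    if (!active[i]) return(0)
    ok <- .possible_offspring(P[i, 1L], P[i, 2L])
    x <- O[i, ]; x <- x[!is.na(x)]
    if (!length(x)) return(1)
    mean(!(x %in% ok))
  }, 0)
  step(ct %in% c("unexpected", "uninformative") | imp_frac > max_impossible,
       "unexpected")

  key <- apply(O, 1L, paste, collapse = ",")
  key[!active] <- NA
  dup <- duplicated(key) & !is.na(key)
  rep_map <- data.frame(marker = ids[dup],
                        representative = ids[match(key[dup], key)],
                        stringsAsFactors = FALSE)
  step(dup, "redundant")
  log$redundant$representative <- rep_map

  miss <- rowMeans(is.na(O))
  step(miss > max_missing, "high_missing")

  n_tested <- sum(active)
  seg_p <- rep(NA_real_, nrow(d))
  for (i in which(active)) {
    x <- O[i, ]; x <- x[!is.na(x)]
    if (ct[i] %in% c("ab_x_aa", "aa_x_ab")) {
      lv <- .possible_offspring(P[i, 1L], P[i, 2L])
      obs <- c(sum(x == lv[1]), sum(x == lv[2]))
      expd <- c(0.5, 0.5)
    } else {
      obs <- c(sum(x == 0L), sum(x == 1L), sum(x == 2L))
      expd <- c(0.25, 0.5, 0.25)
    }
    chi <- sum((obs - sum(obs) * expd)^2 / (sum(obs) * expd))
    seg_p[i] <- stats::pchisq(chi, df = length(obs) - 1L, lower.tail = FALSE)
  }
  step(!is.na(seg_p) & seg_p <= alpha / n_tested, "segregation")
  log$segregation$n_tested <- n_tested
  log$segregation$bonferroni_threshold <- alpha / n_tested
  pv <- seg_p[!is.na(seg_p)]
  names(pv) <- ids[!is.na(seg_p)]
  log$segregation$p_values <- pv

  kept <- ids[active]
  info <- data.frame(marker = kept,
                     p1 = P[active, 1L], p2 = P[active, 2L],
                     cross_type = ct[active], seg_p = seg_p[active],
                     stringsAsFactors = FALSE)
  list(info = info, kept = kept,
       offspring = O[active, , drop = FALSE], log = log)
}

# gamete distribution of one parent at a marker pair: 2 x 2 matrix over
# (allele at locus A, allele at locus B) in {0,1}; phase in {1 coupling,
# 2 repulsion}, used only when het at both loci
.gamete_table <- function(dA, dB, r, phase = 1L) {
  if (dA == 1L && dB == 1L) {
    if (phase == 1L)
      matrix(c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2), 2L, 2L)
    else
      matrix(c(r / 2, (1 - r) / 2, (1 - r) / 2, r / 2), 2L, 2L)
  } else {
    pa <- if (dA == 1L) c(0.5, 0.5) else if (dA == 0L) c(1, 0) else c(0, 1)
    pb <- if (dB == 1L) c(0.5, 0.5) else if (dB == 0L) c(1, 0) else c(0, 1)
    outer(pa, pb)
  }
}

# 3 x 3 offspring joint-dosage table for a marker pair
.pair_table <- function(p1A, p1B, p2A, p2B, r, ph1 = 1L, ph2 = 1L) {
  g1 <- .gamete_table(p1A, p1B, r, ph1)
  g2 <- .gamete_table(p2A, p2B, r, ph2)
  P <- matrix(0, 3L, 3L)
  for (a1 in 0:1) for (b1 in 0:1) for (a2 in 0:1) for (b2 in 0:1)
    P[a1 + a2 + 1L, b1 + b2 + 1L] <-
      P[a1 + a2 + 1L, b1 + b2 + 1L] + g1[a1 + 1L, b1 + 1L] * g2[a2 + 1L, b2 + 1L]
  P
}

#' Estimate pairwise recombination fractions and LOD scores
#'
#' Maximum-likelihood two-point estimation for screened diploid F1
#' markers. For each pair the likelihood of the 3 x 3 joint offspring
#' dosage table is maximized over a grid of r in [0, 0.5] and over the
#' admissible phase configurations (two per doubly heterozygous parent);
#' phase ties break toward the smaller estimate. Pairs informative
#' through neither parent (testcrosses through different parents) and
#' pairs with fewer than `min_joint` jointly observed offspring are
#' returned as NA. LOD is log10 of the likelihood ratio against r = 0.5.
#'
#' @param offspring Dosage matrix (kept markers x offspring), e.g. from
#'   [screen_f1_markers()].
#' @param info Marker info data frame from [screen_f1_markers()].
#' @param min_joint Minimum jointly observed offspring per pair.
#' @param grid_step Resolution of the r grid (default 0.005).
#' @return Object of class `rf_matrix`: list with symmetric matrices `r`,
#'   `lod`, `phase` (1..4, configuration index), `n` (joint counts) and
#'   `markers`.
#' @export
estimate_rf <- function(offspring, info, min_joint = 10L,
                        grid_step = 0.005) {
  stopifnot(identical(rownames(offspring), info$marker))
  p <- nrow(offspring)
  ids <- info$marker
  rg <- c(1e-4, seq(grid_step, 0.5, by = grid_step))
  if (rg[length(rg)] < 0.5) rg <- c(rg, 0.5)
  ng <- length(rg)

  # indicator matrices and the 9 pairwise count tables
  X <- lapply(0:2, function(v) {
    M <- t(offspring) == v
    M[is.na(M)] <- FALSE
    storage.mode(M) <- "double"
    M
  })
  N <- vector("list", 9L)
  for (j in 0:2) for (k in 0:2)
    N[[j * 3L + k + 1L]] <- crossprod(X[[j + 1L]], X[[k + 1L]])
  n_joint <- Reduce(`+`, N)

  classes <- paste(info$p1, info$p2)
  class_defs <- list("1 0" = c(1L, 0L), "1 2" = c(1L, 2L),
                     "0 1" = c(0L, 1L), "2 1" = c(2L, 1L),
                     "1 1" = c(1L, 1L))
  r_mat <- matrix(NA_real_, p, p, dimnames = list(ids, ids))
  lod_mat <- matrix(NA_real_, p, p, dimnames = list(ids, ids))
  ph_mat <- matrix(NA_integer_, p, p, dimnames = list(ids, ids))

  for (ca in names(class_defs)) for (cb in names(class_defs)) {
    Ia <- which(classes == ca)
    Ib <- which(classes == cb)
    if (!length(Ia) || !length(Ib)) next
    da <- class_defs[[ca]]; db <- class_defs[[cb]]
    p1_informative <- da[1] == 1L && db[1] == 1L
    p2_informative <- da[2] == 1L && db[2] == 1L
    if (!p1_informative && !p2_informative) next
    phases <- expand.grid(ph1 = if (p1_informative) 1:2 else 1L,
                          ph2 = if (p2_informative) 1:2 else 1L)
    best_ll <- matrix(-Inf, length(Ia), length(Ib))
    best_r <- matrix(NA_real_, length(Ia), length(Ib))
    best_ph <- matrix(NA_integer_, length(Ia), length(Ib))
    ll05 <- NULL
    Nb <- lapply(N, function(M) M[Ia, Ib, drop = FALSE])
    for (phi in seq_len(nrow(phases))) {
      for (g in seq_len(ng)) {
        P <- .pair_table(da[1], db[1], da[2], db[2], rg[g],
                         phases$ph1[phi], phases$ph2[phi])
        lp <- pmax(log(P), -30)
        ll <- matrix(0, length(Ia), length(Ib))
        for (j in 0:2) for (k in 0:2)
          ll <- ll + Nb[[j * 3L + k + 1L]] * lp[j + 1L, k + 1L]
        if (g == ng && is.null(ll05)) ll05 <- ll  # r = 0.5, phase-free
        upd <- ll > best_ll + 1e-12
        if (any(upd)) {
          best_ll[upd] <- ll[upd]
          best_r[upd] <- rg[g]
          best_ph[upd] <- phi
        }
      }
    }
    lod <- (best_ll - ll05) / log(10)
    r_mat[Ia, Ib] <- best_r
    lod_mat[Ia, Ib] <- pmax(lod, 0)
    ph_mat[Ia, Ib] <- best_ph
  }
  low <- n_joint < min_joint
  r_mat[low] <- NA_real_
  lod_mat[low] <- NA_real_
  diag(r_mat) <- 0
  diag(lod_mat) <- NA_real_
  structure(list(r = r_mat, lod = lod_mat, phase = ph_mat,
                 n = n_joint, markers = ids),
            class = "rf_matrix")
}

#' @export
print.rf_matrix <- function(x, ...) {
  cat(sprintf("rf_matrix: %d markers, %d estimable pairs\n",
              length(x$markers),
              sum(!is.na(x$r[upper.tri(x$r)]))))
  invisible(x)
}

#' Filter markers by linkage support
#'
#' A marker is removed when it has fewer than `min_linked` partners
#' showing linkage (r at most `link_rf` and LOD at least `link_lod`), or
#' when its linked partners span more than `max_regions` distinct
#' chromosomes (a chimeric signature).
#'
#' @param rf An `rf_matrix`.
#' @param chrom Physical chromosome assignment per marker (aligned with
#'   `rf$markers`).
#' @param min_linked Minimum linked partners (default 2).
#' @param max_regions Maximum chromosomes spanned (default 3).
#' @param link_rf,link_lod Linkage thresholds (defaults 0.3, 3).
#' @return List with `removed` (marker ids) and `detail` data frame
#'   (marker, n_linked, n_regions).
#' @export
rf_filter <- function(rf, chrom, min_linked = 2L, max_regions = 3L,
                      link_rf = 0.3, link_lod = 3) {
  linked <- !is.na(rf$r) & !is.na(rf$lod) & rf$r <= link_rf & rf$lod >= link_lod
  diag(linked) <- FALSE
  n_linked <- rowSums(linked)
  n_regions <- vapply(seq_along(rf$markers), function(i)
    length(unique(chrom[linked[i, ]])), 0L)
  bad <- n_linked < min_linked | n_regions > max_regions
  list(removed = rf$markers[bad],
       detail = data.frame(marker = rf$markers, n_linked = n_linked,
                           n_regions = n_regions, removed = bad,
                           stringsAsFactors = FALSE))
}

#' Reposition markers that disagree with their physical placement
#'
#' Each marker is compared with its physical neighbors (the `window`
#' markers on either side, in physical order on its assigned chromosome).
#' A marker is detached from its chromosome when it shows weak linkage
#' (RF above `weak_rf`) with at least one neighbor (`neighbor_rule =
#' "any"`, the default) or with all of them (`"all"`). A detached marker
#' showing strong linkage (RF below `strong_rf`) with markers on exactly
#' one other chromosome is reassigned there, with no physical position
#' (placement by linkage only); strong links to several chromosomes leave
#' it detached.
#'
#' @param rf An `rf_matrix`.
#' @param markers Data frame with `locus_id`, `chrom`, `pos` aligned with
#'   `rf$markers`.
#' @param weak_rf,strong_rf RF thresholds (defaults 0.4, 0.1).
#' @param window Number of physical neighbors per side (default 5).
#' @param neighbor_rule "any" (default) or "all".
#' @return List with `detached` (ids), `reassigned` (data frame:
#'   locus_id, old_chrom, new_chrom), and `unplaced` (detached but not
#'   reassigned).
#' @export
reposition_markers <- function(rf, markers, weak_rf = 0.4, strong_rf = 0.1,
                               window = 5L, neighbor_rule = c("any", "all")) {
  neighbor_rule <- match.arg(neighbor_rule)
  stopifnot(identical(markers$locus_id, rf$markers))
  p <- length(rf$markers)
  detach <- logical(p)
  for (c in unique(markers$chrom)) {
    idx <- which(markers$chrom == c)
    idx <- idx[order(markers$pos[idx])]
    for (k in seq_along(idx)) {
      nb <- idx[setdiff(max(1L, k - window):min(length(idx), k + window), k)]
      rr <- rf$r[idx[k], nb]
      rr <- rr[!is.na(rr)]
      if (!length(rr)) next
      detach[idx[k]] <- if (neighbor_rule == "any") any(rr > weak_rf)
                        else all(rr > weak_rf)
    }
  }
  reassigned <- data.frame(locus_id = character(0), old_chrom = character(0),
                           new_chrom = character(0), stringsAsFactors = FALSE)
  unplaced <- character(0)
  for (i in which(detach)) {
    strong <- which(!is.na(rf$r[i, ]) & rf$r[i, ] < strong_rf)
    strong <- strong[strong != i]
    chroms <- setdiff(unique(markers$chrom[strong]), markers$chrom[i])
    if (length(chroms) == 1L) {
      reassigned <- rbind(reassigned, data.frame(
        locus_id = markers$locus_id[i],
        old_chrom = as.character(markers$chrom[i]),
        new_chrom = as.character(chroms), stringsAsFactors = FALSE))
    } else {
      unplaced <- c(unplaced, markers$locus_id[i])
    }
  }
  list(detached = markers$locus_id[detach], reassigned = reassigned,
       unplaced = unplaced)
}

#' Cluster markers into linkage groups
#'
#' Builds a graph with an edge between markers at RF at most `link_rf`
#' and LOD at least `link_lod`, and reports its connected components.
#'
#' @param rf An `rf_matrix`.
#' @param link_rf,link_lod Edge thresholds (defaults 0.25, 5).
#' @return List with `groups` (list of marker-id vectors, multi-marker
#'   components, largest first), `singletons` (ids), and `membership`
#'   (named integer vector; NA for singletons).
#' @export
cluster_linkage_groups <- function(rf, link_rf = 0.25, link_lod = 5) {
  adj <- !is.na(rf$r) & !is.na(rf$lod) & rf$r <= link_rf & rf$lod >= link_lod
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)
  sizes <- comp$csize
  multi <- which(sizes >= 2L)
  multi <- multi[order(sizes[multi], decreasing = TRUE)]
  groups <- lapply(multi, function(c) rf$markers[comp$membership == c])
  membership <- rep(NA_integer_, length(rf$markers))
  names(membership) <- rf$markers
  for (k in seq_along(groups)) membership[groups[[k]]] <- k
  list(groups = groups,
       singletons = rf$markers[comp$membership %in% which(sizes == 1L)],
       membership = membership)
}

#' Two-point map for one linkage group
#'
#' Markers with a physical position are ordered by position; reassigned
#' markers (no position on this chromosome) are inserted immediately
#' after their strongest-linked neighbor. Cumulative positions follow the
#' Haldane map function on adjacent-pair RF estimates. When the adjacent
#' pair is not estimable (markers informative through different parents),
#' the gap is bridged through the nearest preceding marker with an
#' estimable RF to the current one (the bridged distance minus the map
#' already accumulated since that marker, floored at 0). An adjacent r at
#' or above 0.5, or a pair with no estimable bridge within `lookback`
#' markers, contributes a capped, flagged 50 cM gap.
#'
#' @param group Marker ids of the group.
#' @param rf An `rf_matrix`.
#' @param markers Data frame `locus_id`, `chrom`, `pos`; reassigned
#'   markers should carry NA pos.
#' @param lookback How many preceding markers to consider when bridging
#'   a non-estimable adjacent pair (default 15).
#' @return List with `map` (data frame: marker, order, adjacent r, gap
#'   cM, cumulative cM, capped flag) and `summary` (length_cM,
#'   markers_per_cM, n_markers, max_gap_cM).
#' @export
two_point_map <- function(group, rf, markers, lookback = 15L) {
  mk <- markers[match(group, markers$locus_id), , drop = FALSE]
  placed <- mk$locus_id[!is.na(mk$pos)]
  placed <- placed[order(mk$pos[match(placed, mk$locus_id)])]
  floating <- setdiff(mk$locus_id, placed)
  ord <- placed
  for (f in floating) {
    rr <- rf$r[f, ord]
    if (all(is.na(rr))) { ord <- c(ord, f); next }
    anchor <- which.min(rr)
    ord <- append(ord, f, after = anchor)
  }
  n <- length(ord)
  radj <- rep(NA_real_, n)
  if (n > 1L)
    radj[-1L] <- rf$r[cbind(ord[-n], ord[-1L])]
  gap <- numeric(n)
  capped <- logical(n)
  cum <- numeric(n)
  for (i in seq_len(n)[-1L]) {
    r_i <- radj[i]
    if (!is.na(r_i) && r_i < 0.5 - 1e-12) {
      gap[i] <- haldane_cm(r_i)
    } else if (!is.na(r_i)) {
      # estimable but at independence: evidence of a real break
      gap[i] <- 50
      capped[i] <- TRUE
    } else {
      # not estimable (different informative parents): bridge through the
      # nearest preceding marker with an estimable RF to this one; with
      # no bridge at all there is no distance evidence, so contribute 0
      bridged <- FALSE
      for (j in (i - 1L):1L) {
        r_ji <- rf$r[ord[j], ord[i]]
        if (!is.na(r_ji) && r_ji < 0.5 - 1e-12) {
          gap[i] <- max(0, haldane_cm(r_ji) - (cum[i - 1L] - cum[j]))
          bridged <- TRUE
          break
        }
        if (i - j >= lookback && bridged) break
      }
      if (!bridged) { gap[i] <- 0; capped[i] <- TRUE }
    }
    cum[i] <- cum[i - 1L] + gap[i]
  }
  map <- data.frame(marker = ord, order = seq_len(n), r_adjacent = radj,
                    gap_cM = gap, cum_cM = cum, capped = capped,
                    stringsAsFactors = FALSE)
  len <- cum[n]
  list(map = map,
       summary = data.frame(length_cM = len,
                            markers_per_cM = if (len > 0) n / len else NA_real_,
                            n_markers = n,
                            max_gap_cM = if (n > 1L) max(gap[-1L]) else 0))
}

#' Map summary table across linkage groups
#'
#' @param groups List of marker-id vectors (e.g. from
#'   [cluster_linkage_groups()]).
#' @param rf An `rf_matrix`.
#' @param markers Marker data frame with `locus_id`, `chrom`, `pos`.
#' @return Data frame, one row per group plus a `Total` row, with map
#'   length, marker density, marker count and maximum gap.
#' @export
map_summary <- function(groups, rf, markers) {
  rows <- lapply(seq_along(groups), function(k) {
    s <- two_point_map(groups[[k]], rf, markers)$summary
    cbind(data.frame(group = k), s)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(group = NA_integer_,
                      length_cM = sum(out$length_cM),
                      markers_per_cM = sum(out$n_markers) / sum(out$length_cM),
                      n_markers = sum(out$n_markers),
                      max_gap_cM = max(out$max_gap_cM))
  rbind(out, total)
}
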