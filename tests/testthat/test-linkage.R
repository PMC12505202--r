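# helper: build a testcross genotype matrix with parents P1 (het) and P2
# (hom-ref); offspring columns carry P1's gamete allele
tc_geno <- function(gametes_list, n_off) {
  g <- do.call(rbind, gametes_list)
  d <- cbind(1L, 0L, g)
  rownames(d) <- sprintf("M%02d", seq_len(nrow(d)))
  colnames(d) <- c("P1", "P2", sprintf("O%03d", seq_len(n_off)))
  d
}

test_that("screening removes marker classes in the documented order", {
  n <- 60
  seg <- rep(c(0, 1), c(28, 32))
  aaxbb_off <- rep(1, n); aaxbb_off[1:4] <- 0  # impossible calls for 0 x 2
  d <- rbind(
    mono = c(2, 2, rep(2, n)),                       # monomorphic
    aaxbb = c(0, 2, aaxbb_off),                      # unexpected cross
    good1 = c(1, 0, seg),
    dup1 = c(1, 0, seg),                             # redundant with good1
    dist = c(1, 0, c(rep(0, round(0.9 * n)), rep(1, n - round(0.9 * n)))),
    miss = c(1, 0, ifelse(seq_len(n) <= 20, NA, seg)),  # >10% missing
    good2 = c(1, 1, rep(c(0, 1, 2), c(15, 30, 15))))
  colnames(d) <- c("P1", "P2", sprintf("O%03d", 1:n))
  sc <- screen_f1_markers(d, c("P1", "P2"))
  expect_equal(sc$log$monomorphic$markers, "mono")
  expect_equal(sc$log$unexpected$markers, "aaxbb")
  expect_equal(sc$log$redundant$markers, "dup1")
  expect_equal(sc$log$high_missing$markers, "miss")
  expect_equal(sc$log$segregation$markers, "dist")  # 54:6 fails 1:1
  expect_setequal(sc$kept, c("good1", "good2"))
  expect_error(screen_f1_markers(d, c("P1", "NOPE")), "NOPE")
})

test_that("Bonferroni uses the count of tested markers as divisor", {
  set.seed(12)
  n <- 100
  rows <- lapply(1:10, function(i) rbinom(n, 1, 0.5))
  d <- tc_geno(rows, n)
  sc <- screen_f1_markers(d, c("P1", "P2"))
  n_tested <- sc$log$segregation$n_tested
  expect_equal(sc$log$segregation$bonferroni_threshold, 0.05 / n_tested)
  # hand recomputation on one marker
  x <- d["M01", -(1:2)]
  obs <- c(sum(x == 0), sum(x == 1))
  chi <- sum((obs - n / 2)^2 / (n / 2))
  expect_equal(unname(sc$log$segregation$p_values["M01"]),
               pchisq(chi, 1, lower.tail = FALSE))
})

test_that("segregation test type-I error is near nominal", {
  set.seed(13)
  n <- 100
  rows <- lapply(1:2000, function(i) rbinom(n, 1, 0.5))
  d <- tc_geno(rows, n)
  sc <- screen_f1_markers(d, c("P1", "P2"))
  pv <- sc$log$segregation$p_values
  expect_gte(length(pv), 1500)   # most null markers reach the test
  expect_lte(mean(pv <= 0.05), 0.07)
})

test_that("identical informative markers give r = 0 with high LOD", {
  set.seed(14)
  g <- rbinom(30, 1, 0.5)
  d <- tc_geno(list(g, g), 30)
  sc <- screen_f1_markers(d, c("P1", "P2"))
  # the duplicate is screened as redundant; rebuild with one flipped cell
  g2 <- g; g2[1] <- 1 - g2[1]
  d2 <- tc_geno(list(g, g2), 30)
  sc2 <- screen_f1_markers(d2, c("P1", "P2"))
  rf <- estimate_rf(sc2$offspring, sc2$info)
  expect_lte(rf$r["M01", "M02"], 1 / 30 + 0.01)
  expect_gt(rf$lod["M01", "M02"], 3)
})

test_that("RF is recovered within sampling error for a planted r = 0.2", {
  set.seed(15)
  n <- 200
  g1 <- rbinom(n, 1, 0.5)
  rec <- rbinom(n, 1, 0.2)            # exact recombination process
  g2 <- ifelse(rec == 1, 1 - g1, g1)
  d <- tc_geno(list(g1, g2), n)
  sc <- screen_f1_markers(d, c("P1", "P2"))
  rf <- estimate_rf(sc$offspring, sc$info)
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(rf$r["M01", "M02"] - 0.2), 2 * se + 0.005)
})

test_that("ab x ab pairs are estimated by phase enumeration", {
  # construct a double-het pair in coupling at known r
  set.seed(16)
  n <- 300
  gam <- function(r) {
    a <- rbinom(n, 1, 0.5)
    b <- ifelse(rbinom(n, 1, r) == 1, 1 - a, a)
    cbind(a, b)
  }
  m1 <- gam(0.15); m2 <- gam(0.15)     # gametes from each parent
  d <- rbind(M1 = c(1, 1, m1[, 1] + m2[, 1]),
             M2 = c(1, 1, m1[, 2] + m2[, 2]))
  colnames(d) <- c("P1", "P2", sprintf("O%03d", 1:n))
  sc <- screen_f1_markers(d, c("P1", "P2"))
  rf <- estimate_rf(sc$offspring, sc$info)
  expect_lt(abs(rf$r["M1", "M2"] - 0.15), 0.05)
  expect_gt(rf$lod["M1", "M2"], 3)
})

test_that("markers on different chromosomes appear unlinked", {
  set.seed(17)
  hits <- 0; attempts <- 0
  for (rep in 1:200) {
    n <- 100
    g1 <- rbinom(n, 1, 0.5)
    g2 <- rbinom(n, 1, 0.5)   # independent
    d <- tc_geno(list(g1, g2), n)
    sc <- screen_f1_markers(d, c("P1", "P2"))
    if (!all(c("M01", "M02") %in% sc$kept)) next
    attempts <- attempts + 1
    rf <- estimate_rf(sc$offspring, sc$info)
    if (rf$r["M01", "M02"] >= 0.4) hits <- hits + 1
  }
  expect_gte(attempts, 150)
  expect_gte(hits / attempts, 0.9)
})

test_that("rf_filter removes unlinked and chimeric markers", {
  set.seed(18)
  cfg <- sim_config(n_chrom = 4, n_loci = 80, chrom_len_cM = 80, seed = 81)
  sim <- simulate_f1(cfg, 120)
  d <- f1_truth_geno(sim)
  # plant: randomize a kept, segregating marker so it is unlinked to all
  sc0 <- screen_f1_markers(d, c("P1", "P2"))
  victim <- sc0$kept[1]
  d[victim, -(1:2)] <- sample(d[victim, -(1:2)])
  sc <- screen_f1_markers(d, c("P1", "P2"))
  expect_true(victim %in% sc$kept)   # permutation preserves segregation
  rf <- estimate_rf(sc$offspring, sc$info)
  mk <- sim$markers[match(sc$kept, sim$markers$locus_id), ]
  out <- rf_filter(rf, mk$chrom)
  expect_true(victim %in% out$removed)
  normal <- setdiff(sc$kept, victim)
  expect_lt(mean(normal %in% out$removed), 0.2)
})

test_that("repositioning recovers a planted chromosome misassignment", {
  cfg <- sim_config(n_chrom = 2, n_loci = 140, chrom_len_cM = 90, seed = 83)
  sim <- simulate_f1(cfg, 150)
  d <- f1_truth_geno(sim)
  sc <- screen_f1_markers(d, c("P1", "P2"))
  rf <- estimate_rf(sc$offspring, sc$info)
  mk <- sim$markers[match(sc$kept, sim$markers$locus_id), ]
  # swap the chromosome label of one well-connected marker
  victim <- sc$kept[which(mk$chrom == 1)[5]]
  true_chrom <- mk$chrom[mk$locus_id == victim]
  mk$chrom[mk$locus_id == victim] <- 2
  rp <- reposition_markers(rf, mk)
  expect_true(victim %in% rp$detached)
  expect_true(victim %in% rp$reassigned$locus_id)
  expect_equal(rp$reassigned$new_chrom[rp$reassigned$locus_id == victim],
               as.character(true_chrom))
  # never reassigns without detaching
  expect_true(all(rp$reassigned$locus_id %in% rp$detached))

  # a fully consistent panel is left unchanged
  mk2 <- sim$markers[match(sc$kept, sim$markers$locus_id), ]
  rp2 <- reposition_markers(rf, mk2)
  expect_length(rp2$detached, 0)
  expect_equal(nrow(rp2$reassigned), 0L)
})

test_that("a randomized marker is detached but not reassigned", {
  cfg <- sim_config(n_chrom = 2, n_loci = 140, chrom_len_cM = 90, seed = 85)
  sim <- simulate_f1(cfg, 120)
  d <- f1_truth_geno(sim)
  set.seed(86)
  sc0 <- screen_f1_markers(d, c("P1", "P2"))
  victim <- sc0$kept[3]
  d[victim, -(1:2)] <- sample(d[victim, -(1:2)])
  sc <- screen_f1_markers(d, c("P1", "P2"))
  rf <- estimate_rf(sc$offspring, sc$info)
  mk <- sim$markers[match(sc$kept, sim$markers$locus_id), ]
  rp <- reposition_markers(rf, mk)
  expect_true(victim %in% rp$detached)
  expect_false(victim %in% rp$reassigned$locus_id)
})

test_that("linkage-group clustering is invariant to marker order", {
  cfg <- sim_config(n_chrom = 3, n_loci = 60, chrom_len_cM = 90, seed = 87)
  sim <- simulate_f1(cfg, 120)
  d <- f1_truth_geno(sim)
  sc <- screen_f1_markers(d, c("P1", "P2"))
  rf <- estimate_rf(sc$offspring, sc$info)
  cl <- cluster_linkage_groups(rf)
  set.seed(88)
  perm <- sample(length(rf$markers))
  rf2 <- rf
  rf2$r <- rf$r[perm, perm]; rf2$lod <- rf$lod[perm, perm]
  rf2$n <- rf$n[perm, perm]; rf2$markers <- rf$markers[perm]
  cl2 <- cluster_linkage_groups(rf2)
  norm <- function(cl) sort(vapply(cl$groups,
                                   function(g) paste(sort(g), collapse = ","),
                                   ""))
  expect_equal(norm(cl), norm(cl2))
})

test_that("two unlinked markers form two singletons", {
  set.seed(19)
  d <- tc_geno(list(rbinom(40, 1, 0.5), rbinom(40, 1, 0.5)), 40)
  sc <- screen_f1_markers(d, c("P1", "P2"))
  rf <- estimate_rf(sc$offspring, sc$info)
  cl <- cluster_linkage_groups(rf)
  expect_length(cl$groups, 0)
  expect_setequal(cl$singletons, c("M01", "M02"))
})

test_that("two-point map distances follow the Haldane function", {
  # three testcross markers with exact planted recombinants
  set.seed(20)
  n <- 5000
  g1 <- rbinom(n, 1, 0.5)
  g2 <- g1                               # r = 0
  flip <- sample(n, round(0.0906 * n))
  g3 <- g2; g3[flip] <- 1 - g3[flip]     # r = 0.0906 -> 10 cM
  d <- tc_geno(list(g1, g2, g3), n)
  d["M02", 3] <- 1 - d["M02", 3]         # break exact redundancy
  sc <- screen_f1_markers(d, c("P1", "P2"))
  rf <- estimate_rf(sc$offspring, sc$info)
  mk <- data.frame(locus_id = c("M01", "M02", "M03"), chrom = 1,
                   pos = c(100, 200, 300), stringsAsFactors = FALSE)
  tp <- two_point_map(c("M01", "M02", "M03"), rf, mk)
  expect_lt(tp$map$gap_cM[2], 0.05)      # r ~ 0
  expect_equal(tp$map$gap_cM[3], 10.0, tolerance = 0.05)
  expect_equal(tp$summary$length_cM, tp$map$cum_cM[3])
})

test_that("simulated chromosome length is recovered within 20%", {
  cfg <- sim_config(n_chrom = 1, n_loci = 40, chrom_len_cM = 100, seed = 1)
  sim <- simulate_f1(cfg, 200)
  d <- f1_truth_geno(sim)
  sc <- screen_f1_markers(d, c("P1", "P2"))
  rf <- estimate_rf(sc$offspring, sc$info)
  mk <- sim$markers[match(sc$kept, sim$markers$locus_id), ]
  tp <- two_point_map(sc$kept, rf, mk)
  true_len <- diff(range(mk$cM))
  expect_lt(abs(tp$summary$length_cM - true_len) / true_len, 0.2)
})

test_that("RF estimation is consistent as the population grows", {
  set.seed(21)
  err <- vapply(c(50, 100, 200, 400), function(n) {
    reps <- vapply(1:20, function(k) {
      g1 <- rbinom(n, 1, 0.5)
      rec <- rbinom(n, 1, 0.2)
      g2 <- ifelse(rec == 1, 1 - g1, g1)
      d <- tc_geno(list(g1, g2), n)
      sc <- screen_f1_markers(d, c("P1", "P2"))
      if (!all(c("M01", "M02") %in% sc$kept)) return(NA_real_)
      rf <- estimate_rf(sc$offspring, sc$info)
      abs(rf$r["M01", "M02"] - 0.2)
    }, 0)
    mean(reps, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(err) < 0.02))   # non-increasing up to noise
  expect_lt(err[4], err[1])
})
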