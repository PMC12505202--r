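test_that("missingness applies the strict <10-read rule per cell", {
  cm <- toy_counts(ref = rbind(c(4, 10, 100)), alt = rbind(c(5, 0, 3)))
  ms <- missingness(cm, 10L)
  expect_equal(unname(ms$mask[1, ]), c(TRUE, FALSE, FALSE))
  cm3 <- toy_counts(ref = rbind(c(2, 50, 50), c(50, 50, 50), c(50, 50, 50)),
                    alt = rbind(c(2, 0, 0), c(0, 0, 0), c(0, 0, 0)))
  ms3 <- missingness(cm3)
  expect_equal(unname(ms3$report$sample_missing), c(1 / 3, 0, 0))
  expect_equal(unname(ms3$report$marker_missing), c(1 / 3, 0, 0))
})

test_that("filter_by_missing removes samples before recomputing marker rates", {
  ref <- rbind(c(0, 50, 50, 50), c(0, 40, 40, 40), c(0, 30, 30, 30))
  cm <- toy_counts(ref, ref * 0, ids = c("BAD", "S1", "S2", "S3"))
  out <- filter_by_missing(cm, 0.95, 0.95)
  expect_equal(out$log$samples_removed, "BAD")
  expect_equal(out$log$n_markers_removed, 0L)   # rates clean after removal
  expect_equal(ncol(out$counts$ref), 3L)

  # planted 95%-missing marker among clean markers
  set.seed(1)
  ref2 <- matrix(50, 10, 20)
  ref2[4, 1:19] <- 0
  cm2 <- toy_counts(ref2, ref2 * 0)
  out2 <- filter_by_missing(cm2)
  expect_equal(out2$log$markers_removed, "L4")

  # all observed: nothing removed
  out3 <- filter_by_missing(toy_counts(matrix(50, 3, 3), matrix(0, 3, 3)))
  expect_equal(out3$log$n_samples_removed + out3$log$n_markers_removed, 0L)
})

test_that("missingness agrees with a brute-force recount on random fixtures", {
  set.seed(5)
  for (rep in 1:100) {
    p <- sample(2:8, 1); n <- sample(2:8, 1)
    ref <- matrix(rpois(p * n, 8), p, n)
    alt <- matrix(rpois(p * n, 4), p, n)
    cm <- toy_counts(ref, alt)
    ms <- missingness(cm)
    for (j in seq_len(n))
      expect_equal(ms$report$sample_missing[[j]],
                   sum(ref[, j] + alt[, j] < 10) / p)
    flt <- filter_by_missing(cm, 0.6, 0.6)
    bad_s <- colMeans(ref + alt < 10) >= 0.6
    expect_equal(flt$log$n_samples_removed, sum(bad_s))
  }
})

test_that("read-ratio MAF and the singleton polymorphism threshold", {
  cm <- toy_counts(rbind(c(50, 40), c(30, 30), c(10, 10)),
                   rbind(c(5, 5), c(30, 30), c(0, 0)), ids = c("A", "B"))
  maf <- maf_from_reads(cm)
  expect_equal(unname(maf), c(10 / 100, 0.5, 0))

  # 330 diploids + 13 tetraploids: threshold 1/712, printed as 0.14%
  sheet <- toy_sheet(sprintf("X%03d", 1:343),
                     ploidy = c(rep(2L, 330), rep(4L, 13)))
  pc <- polymorphic_call(maf, sheet)
  expect_equal(pc$n_gametes, 712)
  expect_equal(pc$threshold, 1 / 712)
  expect_equal(round(100 * pc$threshold, 2), 0.14)

  # exact-threshold MAF is polymorphic; just below is not
  sheet10 <- toy_sheet(sprintf("Y%02d", 1:10), 2L)
  pc10 <- polymorphic_call(c(0.05, 0.04), sheet10)
  expect_identical(unname(pc10$polymorphic), c(TRUE, FALSE))
})

test_that("pic evaluates the Botstein formula exactly", {
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(c(1)), 0)
  expect_equal(pic(c(1, 0)), 0)
  expect_equal(pic(c(0.9, 0.1)), 1 - 0.82 - 2 * 0.81 * 0.01)
  # maximized at p = 0.5 for biallelic loci
  grid <- seq(0.01, 0.99, by = 0.01)
  vals <- vapply(grid, function(p) pic(c(p, 1 - p)), 0)
  expect_equal(grid[which.max(vals)], 0.5)
  expect_true(all(vals <= 0.375 + 1e-12))
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
})

test_that("pic_from_genotypes derives frequencies from dosages", {
  g <- rbind(c(1, 1, 1, 1), c(0, 1, 1, 2), c(2, 2, 2, 2))
  expect_equal(unname(pic_from_genotypes(g, 2)),
               c(pic(c(0.5, 0.5)), pic(c(0.5, 0.5)), 0))
})

test_that("ibs counts shared calls over mutually observed loci", {
  expect_equal(ibs(c(0, 1, 2), c(0, 1, 2)),
               list(ibs = 1, n_compared = 3L))
  r <- ibs(c(0, 1, 2, NA), c(0, 1, 1, 2))
  expect_equal(r$ibs, 2 / 3)
  expect_equal(r$n_compared, 3L)
  expect_error(ibs(c(NA, 1), c(2, NA)), "non-missing")
  expect_error(ibs(c(1, 2), c(1, 2, 3)), "length")
  # symmetry and self-identity under a property sweep
  set.seed(8)
  for (rep in 1:50) {
    g1 <- sample(c(0:2, NA), 30, replace = TRUE)
    g2 <- sample(c(0:2, NA), 30, replace = TRUE)
    if (!any(!is.na(g1) & !is.na(g2))) next
    expect_equal(ibs(g1, g2), ibs(g2, g1))
    if (any(!is.na(g1))) expect_equal(ibs(g1, g1)$ibs, 1)
  }
})

test_that("allele-ratio PCA separates simulated populations", {
  cfg <- sim_config(n_loci = 300, seed = 61, founder_freq_range = c(0.1, 0.4))
  a <- simulate_cohort(cfg, 20, 2)
  cfgb <- sim_config(n_loci = 300, seed = 61, founder_freq_range = c(0.6, 0.9))
  b <- simulate_cohort(cfgb, 20, 2)
  cm <- count_matrix(cbind(a$counts$ref, b$counts$ref),
                     cbind(a$counts$alt, b$counts$alt),
                     a$markers, toy_sheet(sprintf("S%02d", 1:40)))
  pca <- allele_ratio_pca(cm, n_pc = 4)
  lab <- rep(1:2, each = 20)
  # silhouette of the two known populations on PC1
  s1 <- pca$scores[, 1]
  sil <- vapply(1:40, function(i) {
    a_d <- mean(abs(s1[i] - s1[lab == lab[i]][-which(which(lab == lab[i]) == i)]))
    b_d <- mean(abs(s1[i] - s1[lab != lab[i]]))
    (b_d - a_d) / max(a_d, b_d)
  }, 0)
  expect_gt(mean(sil), 0.5)
  expect_true(all(diff(pca$var_explained) <= 1e-9))
  expect_lte(sum(pca$var_explained), 100 + 1e-9)
})

test_that("identical samples get identical PC scores", {
  set.seed(3)
  ref <- matrix(rpois(200, 40), 20, 10)
  alt <- matrix(rpois(200, 20), 20, 10)
  cm <- toy_counts(cbind(ref, ref[, 1]), cbind(alt, alt[, 1]))
  pca <- allele_ratio_pca(cm, n_pc = 3)
  expect_equal(pca$scores[1, ], pca$scores[11, ])
})
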