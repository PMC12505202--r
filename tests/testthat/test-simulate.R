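test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_loci = 50, seed = 9)
  a <- simulate_f1(cfg, 20)
  b <- simulate_f1(cfg, 20)
  expect_identical(a$counts$ref, b$counts$ref)
  expect_identical(a$counts$alt, b$counts$alt)
  expect_identical(a$truth$dosage, b$truth$dosage)
  c2 <- simulate_f1(sim_config(n_loci = 50, seed = 10), 20)
  expect_false(identical(a$counts$alt, c2$counts$alt))
})

test_that("realized depth matches the configured negative binomial mean", {
  cfg <- sim_config(n_loci = 2000, depth_mean = 60, seed = 2)
  sim <- simulate_cohort(cfg, 60, 2)   # 120k cells
  expect_lt(abs(mean(sim$counts$ref + sim$counts$alt) - 60) / 60, 0.02)
})

test_that("alt-ratio means track d/ploidy without error or bias", {
  cfg <- sim_config(n_loci = 800, seed = 5, eps = 0, bias_sdlog = 0,
                    rho = 1e-12, depth_mean = 200)
  sim <- simulate_cohort(cfg, 40, 2)
  ratio <- sim$counts$alt / (sim$counts$ref + sim$counts$alt)
  for (d in 0:2) {
    cells <- sim$truth$dosage == d
    se <- stats::sd(ratio[cells]) / sqrt(sum(cells))
    expect_lt(abs(mean(ratio[cells]) - d / 2), 3 * se + 1e-9)
  }
})

test_that("colchicine generations reproduce the expected ratio modes", {
  base <- function(s) sim_config(n_loci = 600, seed = s, eps = 0,
                                 bias_sdlog = 0, rho = 1e-12,
                                 depth_mean = 200)
  ratio_of <- function(sim) {
    tot <- sim$counts$ref + sim$counts$alt
    (sim$counts$alt / tot)[tot >= 10]
  }
  r2 <- ratio_of(simulate_cohort(base(1), 20, 2))
  expect_gt(mean(abs(r2 - 0.5) < 0.1 | r2 < 0.1 | r2 > 0.9), 0.99)

  r4 <- ratio_of(simulate_cohort(base(2), 20, 4))
  expect_gt(mean(abs(r4 - 0.25) < 0.08), 0.1)   # dosage-1 class present
  expect_gt(mean(abs(r4 - 0.75) < 0.08), 0.1)   # dosage-3 class present

  r41 <- ratio_of(simulate_cohort(base(3), 20, 4, colchicine_gen = 1))
  expect_lt(mean(abs(r41 - 0.25) < 0.08), 0.001)  # no mass at quarter peaks
  expect_lt(mean(abs(r41 - 0.75) < 0.08), 0.001)

  r42 <- ratio_of(simulate_cohort(base(4), 20, 4, colchicine_gen = 2))
  expect_gt(mean(abs(r42 - 0.25) < 0.08), 0.05)   # intermediate dosages back
  expect_error(simulate_cohort(base(5), 5, 2, colchicine_gen = 1), "ploidy 4")
})

test_that("F1 gametes recombine at the Haldane rate", {
  # single chromosome; recombinant fraction between testcross markers
  # (P1 het at both, P2 hom at both) estimates r = (1 - exp(-2d))/2
  cfg <- sim_config(n_chrom = 1, n_loci = 12, chrom_len_cM = 50, seed = 33)
  sim <- simulate_f1(cfg, 2000)
  d <- f1_truth_geno(sim)
  p1 <- d[, "P1"]; p2 <- d[, "P2"]
  tc <- which(p1 == 1L & p2 != 1L)
  expect_gte(length(tc), 2L)
  i <- tc[1]; j <- tc[length(tc)]
  # P1 gamete allele = offspring dosage minus P2 fixed contribution
  gi <- d[i, -(1:2)] - p2[i] / 2
  gj <- d[j, -(1:2)] - p2[j] / 2
  # recombinant under one of the two phases
  rec <- mean(gi != gj)
  rhat <- min(rec, 1 - rec)
  dist <- abs(sim$markers$cM[j] - sim$markers$cM[i])
  r_true <- haldane_r(dist)
  se <- sqrt(r_true * (1 - r_true) / 2000)
  expect_lt(abs(rhat - r_true), 3 * se)
})

test_that("F1 segregation matches the cross-type expectation", {
  cfg <- sim_config(n_loci = 300, seed = 41, depth_mean = 200)
  sim <- simulate_f1(cfg, 1000)
  d <- f1_truth_geno(sim)
  p1 <- d[, "P1"]; p2 <- d[, "P2"]
  off <- d[, -(1:2)]
  pvals <- c()
  for (i in seq_len(nrow(d))) {
    if (p1[i] == 1L && p2[i] == 1L) {
      obs <- c(sum(off[i, ] == 0), sum(off[i, ] == 1), sum(off[i, ] == 2))
      expd <- c(0.25, 0.5, 0.25)
    } else if (xor(p1[i] == 1L, p2[i] == 1L)) {
      lv <- sort(unique(off[i, ]))
      if (length(lv) != 2L) next
      obs <- c(sum(off[i, ] == lv[1]), sum(off[i, ] == lv[2]))
      expd <- c(0.5, 0.5)
    } else next
    chi <- sum((obs - sum(obs) * expd)^2 / (sum(obs) * expd))
    pvals <- c(pvals, stats::pchisq(chi, length(obs) - 1, lower.tail = FALSE))
  }
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("hybrid locus classes are realized at the configured proportions", {
  cfg <- sim_config(n_loci = 2500, seed = 77)
  sim <- simulate_hybrid(cfg, 10,
                         class_proportions = c(cran = 0.4, blue = 0.35,
                                               shared = 0.2))
  tb <- table(sim$truth$class)
  probs <- c(blue_specific = 0.35, cran_specific = 0.4,
             failed = 0.05, shared = 0.2)
  for (k in names(probs)) {
    # multinomial 99% bounds per class
    bound <- 2.58 * sqrt(2500 * probs[k] * (1 - probs[k]))
    expect_lt(abs(tb[k] - 2500 * probs[k]), bound + 1)
  }
  expect_error(simulate_hybrid(cfg, 5, class_proportions = c(-0.1, 0.5, 0.2)),
               "negative")
})

test_that("hybrid parents show the classification read pattern", {
  sim <- simulate_hybrid(sim_config(n_loci = 400, seed = 13), 8)
  total <- sim$counts$ref + sim$counts$alt
  blue <- rowSums(total[, 6:7])
  cran <- rowSums(total[, 1:5])
  cs <- sim$truth$class == "cran_specific"
  expect_true(all(blue[cs] <= 10 * 2))      # background noise only
  expect_true(all(cran[cs] > 10))
  fl <- sim$truth$class == "failed"
  expect_true(all(blue[fl] <= 2 * 2 & cran[fl] <= 2 * 5))
})
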