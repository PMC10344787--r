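test_that("preprocess log2-transforms, centres and only imputes gaps", {
  # constant matrix collapses to zero after log2 + median centring
  m <- matrix(1024, 4, 4,
              dimnames = list(paste0("P", 1:4, "_S1"), paste0("s", 1:4)))
  tb <- phospho_table(m, protein_id = paste0("P", 1:4),
                      design = factor(rep(c("a", "b"), each = 2)))
  out <- preprocess(tb)
  expect_true(all(out$intensity == 0))

  # complete matrix: imputation is a no-op
  set.seed(1)
  m2 <- matrix(2^rnorm(40, 20, 2), 10, 4,
               dimnames = list(paste0("P", 1:10, "_S1"), paste0("s", 1:4)))
  tb2 <- phospho_table(m2, protein_id = paste0("P", 1:10),
                       design = factor(rep(c("a", "b"), each = 2)))
  ref <- sweep(log2(m2), 2, apply(log2(m2), 2, median))
  expect_equal(unname(preprocess(tb2)$intensity), unname(ref))

  # a fully missing sample is named in the error
  m3 <- m2; m3[, 2] <- NA
  tb3 <- phospho_table(m3, protein_id = paste0("P", 1:10),
                       design = factor(rep(c("a", "b"), each = 2)))
  expect_error(preprocess(tb3), "s2")
})

test_that("imputed values land below the observed per-sample median", {
  frac_below <- replicate(20, {
    seed <- sample.int(1e6, 1)
    cfg <- phospho_sim_config(n_proteins = 150, peptides_per_protein = c(2, 3),
                              missing_rate = 0.2, mnar_weight = 0,
                              seed = seed)
    sim <- simulate_phospho_table(cfg)
    miss <- is.na(sim$table$intensity)
    pre <- preprocess(sim$table, seed = seed)
    below <- 0; total <- 0
    for (j in seq_len(ncol(miss))) {
      obs_med <- median(pre$intensity[!miss[, j], j])
      below <- below + sum(pre$intensity[miss[, j], j] < obs_med)
      total <- total + sum(miss[, j])
    }
    below / total
  })
  expect_gte(mean(frac_below), 0.95)
})

test_that("welch_test matches hand computation and its conventions", {
  r <- welch_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  # identical groups
  expect_equal(welch_test(c(5, 5, 5), c(5, 5, 5))[c("t", "p")],
               list(t = 0, p = 1))
  # swapping groups negates t, keeps p
  r2 <- welch_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  expect_error(welch_test(c(1), c(2, 3)), "at least 2")
})

test_that("bh_adjust equals the brute-force step-up on exhaustive small cases", {
  expect_equal(bh_adjust(c(0.01, 0.03, 0.04, 0.05)),
               c(0.04, 0.05, 0.05, 0.05))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  grid <- c(0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 0.9)
  set.seed(42)
  for (m in 1:6) {
    combos <- as.matrix(expand.grid(rep(list(grid), m)))
    # exhaustive up to 3, random subsample beyond to keep the loop tight
    if (m > 3) combos <- combos[sample.int(nrow(combos), 300), , drop = FALSE]
    for (i in seq_len(nrow(combos)))
      expect_equal(bh_adjust(combos[i, ]), bh_brute(combos[i, ]),
                   ignore_attr = TRUE)
  }
})

test_that("anti-conservativeness detection follows the excess-mass rule", {
  expect_true(detect_anticonservative(c(rep(0.01, 30), runif(70, 0.1, 1))))
  expect_false(detect_anticonservative(seq(0.51, 0.99, length.out = 60)))
  expect_error(detect_anticonservative(runif(10)), "too few")
  # uniform p-values rarely trip the detector
  set.seed(7)
  trips <- replicate(40, detect_anticonservative(runif(1000)))
  expect_lte(mean(trips), 0.05)
})

test_that("significance calling applies BH first and gates the fallback", {
  # BH has hits: fallback never fires
  res <- data.frame(p = c(0.0001, runif(99, 0.2, 1)),
                    log2fc = rnorm(100))
  out <- call_significance(res)
  expect_identical(unique(out$procedure), "BH")
  expect_true(out$significant[1])

  # no BH hits + anti-conservative p's: fold-change rule decides
  set.seed(1)
  p <- c(0.04, 0.04, 0.2, runif(57, 0.02, 0.049), runif(40, 0.5, 1))
  fc <- c(log2(1.6), log2(1.2), log2(3), rep(0, 97))
  out2 <- call_significance(data.frame(p = p, log2fc = fc))
  expect_identical(unique(out2$procedure), "fallback")
  expect_true(out2$significant[1])   # p < 0.05 and FC 1.6 > 1.5
  expect_false(out2$significant[2])  # FC too small
  expect_false(out2$significant[3])  # p too large

  # no BH hits + uniform p's: nothing called, procedure stays BH
  out3 <- call_significance(data.frame(p = seq(0.3, 0.99, length.out = 60),
                                       log2fc = rnorm(60)))
  expect_identical(unique(out3$procedure), "BH")
  expect_false(any(out3$significant))
})

test_that("delta-Ps sums significant fold changes and classifies by 2 sigma", {
  res <- data.frame(
    protein_id = c("A", "A", "B", "B", "B", "C", "D", "E"),
    log2fc = c(0.7, -0.3, 1.0, -0.5, 2.0, 5.0, 0.2, 0.1),
    p = c(0.2, 0.6, 0.01, 0.2, 0.04, 0.01, 0.9, 0.7))
  dps <- delta_ps(res)
  got <- setNames(dps$delta_ps, dps$protein_id)
  expect_equal(unname(got["A"]), 0)  # no site below 0.05
  expect_equal(unname(got["B"]), 3)  # 1.0 + 2.0
  expect_equal(unname(got["C"]), 5)
  expect_equal(dps$n_sig[dps$protein_id == "A"], 0L)
  expect_identical(as.character(dps$klass[dps$protein_id == "A"]), "none")

  # population-sd cohort example: [0,0,0,0,10] -> sigma 4, the 10 is hyper
  res2 <- data.frame(protein_id = letters[1:5],
                     log2fc = c(1, 1, 1, 1, 10),
                     p = c(0.5, 0.5, 0.5, 0.5, 0.01))
  dps2 <- delta_ps(res2)
  expect_equal(attr(dps2, "sigma"), 4)
  expect_identical(as.character(dps2$klass), c(rep("none", 4), "hyper"))

  # empty input
  expect_equal(nrow(delta_ps(res2[0, ])), 0)

  # nonzero sigma mode drops zero scores from the sigma pool
  dps3 <- delta_ps(res2, sigma_mode = "nonzero")
  expect_equal(attr(dps3, "sigma"), 0)
})

test_that("z-scoring yields zero-mean unit-population-sd rows", {
  expect_equal(unname(zscore_sites(matrix(c(1, 2, 3), 1))[1, ]),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_warning(z <- zscore_sites(matrix(5, 2, 4)), "zero-variance")
  expect_true(all(z == 0))
  set.seed(3)
  z2 <- zscore_sites(matrix(rnorm(60), 6, 10))
  expect_true(all(abs(rowMeans(z2)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(z2^2)) - 1) < 1e-9))
})

test_that("clustering separates planted profiles and obeys the contract", {
  skip_if_not_installed("mclust")
  set.seed(10)
  up <- matrix(rep(c(2, 2, -2, -2), each = 15), 15) +
    matrix(rnorm(60, 0, 0.2), 15)
  dn <- -matrix(rep(c(2, 2, -2, -2), each = 15), 15) +
    matrix(rnorm(60, 0, 0.2), 15)
  z <- zscore_sites(rbind(up, dn))
  cl <- cluster_sites(z, k = 2,
                      design = factor(c("a", "a", "b", "b")))
  planted <- rep(1:2, each = 15)
  expect_equal(mclust::adjustedRandIndex(cl$assignments, planted), 1)
  expect_equal(dim(cl$cluster_group_mean), c(2L, 2L))

  expect_identical(unname(cluster_sites(z, k = 1)$assignments),
                   rep(1L, 30))
  expect_error(cluster_sites(z, k = 31), "exceeds")
  # duplicated rows co-cluster
  dup <- z[c(1, 1, 16, 16), ]
  a <- cluster_sites(dup, k = 2)$assignments
  expect_equal(a[1], a[2])
  expect_equal(a[3], a[4])

  kt <- cluster_group_test(z, cl$assignments, cluster = 1,
                           design = factor(c("a", "a", "b", "b")))
  expect_s3_class(kt, "htest")
})

test_that("reported percentages match the printed-fraction convention", {
  expect_equal(report_fractions(863, 2160), 39.95)
  expect_equal(report_fractions(309, 4553), 6.79)
  expect_equal(report_fractions(212, 1712), 12.38)
  expect_equal(report_fractions(0, 100), 0)
  expect_error(report_fractions(1, 0), "n_total")
  expect_error(report_fractions(5, 3), "n_sig")
})

test_that("statistics are invariant under sample-order permutation", {
  cfg <- phospho_sim_config(n_proteins = 40, missing_rate = 0, seed = 21)
  sim <- simulate_phospho_table(cfg)
  pre <- preprocess(sim$table)
  res <- differential_sites(pre)
  perm <- sample(ncol(pre$intensity))
  shuffled <- phospho_table(pre$intensity[, perm], pre$protein_id,
                            design = pre$design[perm], log2 = TRUE)
  res_p <- differential_sites(shuffled)
  expect_equal(res_p$p, res$p)
  expect_equal(res_p$log2fc, res$log2fc)
  expect_equal(res_p$t, res$t)
})
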