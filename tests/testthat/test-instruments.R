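test_that("the p-value screen keeps exactly the sub-threshold records", {
  ss <- SummaryStats("t", rec_df(c("rs1", "rs2", "rs3"), beta = 0.1,
                                 se = 0.02, pval = c(1e-6, 1e-4, 1e-8)))
  expect_equal(snpIds(selectCandidates(ss, 1e-5)), c("rs1", "rs3"))
  expect_equal(nsnp(selectCandidates(ss, 1 - 1e-12)), 3L)
  expect_error(selectCandidates(ss, 1e-12), "no candidate instruments")

  # brute-force recount on a large uniform-p table
  set.seed(7)
  p <- c(runif(990), runif(10, 1e-8, 1e-5))
  big <- SummaryStats("t", rec_df(sprintf("rs%04d", 1:1000), 0.1, 0.02,
                                  pval = p))
  expect_equal(nsnp(selectCandidates(big, 1e-5)),
               sum(records(big)$pval < 1e-5))
})

test_that("greedy clumping follows the hand-run procedure", {
  # three same-chromosome variants within the window; the third is
  # correlated with the best one and must be pruned
  ss <- SummaryStats("t", rec_df(c("s1", "s2", "s3"), 0.1, 0.02,
                                 pval = c(1e-8, 1e-6, 1e-7),
                                 pos = c(1e6, 2e6, 3e6)))
  r2 <- diag(1, 3)
  r2[1, 3] <- r2[3, 1] <- 0.5
  ld <- LDMatrix(r2, c("s1", "s2", "s3"))
  kept <- clumpVariants(ss, ld, r2_max = 0.001, window_kb = 10000)
  expect_setequal(snpIds(kept), c("s1", "s2"))

  # independence: all pairwise r2 = 0 keeps everything
  kept2 <- clumpVariants(ss, LDMatrix(diag(1, 3), c("s1", "s2", "s3")))
  expect_equal(nsnp(kept2), 3L)

  # the window never spans chromosomes, whatever the r2
  ss2 <- SummaryStats("t", rec_df(c("a", "b"), 0.1, 0.02,
                                  pval = c(1e-8, 1e-7),
                                  chrom = c("1", "2"), pos = c(1e6, 1e6)))
  r2b <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_equal(nsnp(clumpVariants(ss2, LDMatrix(r2b, c("a", "b")))), 2L)

  expect_error(clumpVariants(ss, LDMatrix(diag(1, 2), c("s1", "s2"))),
               "absent from the LD matrix")
})

test_that("clumping is order-invariant and leaves no correlated pair", {
  set.seed(13)
  k <- 60
  ids <- sprintf("v%03d", 1:k)
  rec <- rec_df(ids, 0.1, 0.02, pval = runif(k, 1e-12, 1e-4),
                chrom = as.character(rep(1:3, each = 20)),
                pos = rep(seq(1e6, by = 2e6, length.out = 20), 3))
  m <- matrix(runif(k * k, 0, 0.4), k)
  r2 <- (m + t(m)) / 2
  diag(r2) <- 1
  dimnames(r2) <- list(ids, ids)
  ld <- LDMatrix(r2, ids)
  ss <- SummaryStats("t", rec)
  kept <- clumpVariants(ss, ld, r2_max = 0.1, window_kb = 10000)

  perm <- sample(k)
  kept_perm <- clumpVariants(SummaryStats("t", rec[perm, ]), ld,
                             r2_max = 0.1, window_kb = 10000)
  expect_identical(snpIds(kept), snpIds(kept_perm))

  # exhaustive pairwise check within every window
  krec <- records(kept)
  for (i in seq_len(nrow(krec))) for (j in seq_len(nrow(krec))) {
    if (i >= j) next
    if (krec$chrom[i] == krec$chrom[j] &&
        abs(krec$pos[i] - krec$pos[j]) <= 1e7)
      expect_lte(r2[krec$snp_id[i], krec$snp_id[j]], 0.1)
  }
})

test_that("the MAF filter is symmetric, strict and missing-tolerant", {
  ss <- SummaryStats("t", rec_df(paste0("r", 1:3), 0.1, 0.02,
                                 eaf = c(0.005, 0.20, 0.995)))
  expect_equal(snpIds(mafFilter(ss, 0.01)), "r2")
  ss2 <- SummaryStats("t", rec_df("r1", 0.1, 0.02, eaf = 0.01))
  expect_warning(out <- mafFilter(ss2, 0.01), "removed every record")
  expect_equal(nsnp(out), 0L)
  ss3 <- SummaryStats("t", rec_df(paste0("r", 1:3), 0.1, 0.02,
                                  eaf = c(NA, 0.2, 0.004)))
  out3 <- mafFilter(ss3, 0.01)
  expect_setequal(snpIds(out3), c("r1", "r2"))
  expect_true(any(grepl("missing eaf", loadReport(out3)$reason)))
})

test_that("the F statistic matches direct substitution", {
  expect_equal(fStatistic(0.05, 10000, 10), 0.05 * 9989 / (10 * 0.95))
  expect_equal(fStatistic(0.05, 10000, 10), 52.5737, tolerance = 1e-5)
  expect_equal(fStatistic(0, 5000, 5), 0)
  # a single weak instrument in a small cohort falls under the F > 10 bar
  f <- fStatistic(0.01, 771, 1)
  expect_equal(f, 0.01 * 769 / 0.99)
  expect_equal(f, 7.7677, tolerance = 1e-4)
  expect_lt(f, 10)
  expect_error(fStatistic(0.1, 11, 10), "degenerate design")
})

test_that("the F statistic is monotone in r2, n and k", {
  expect_gt(fStatistic(0.06, 1000, 5), fStatistic(0.05, 1000, 5))
  expect_gt(fStatistic(0.05, 2000, 5), fStatistic(0.05, 1000, 5))
  expect_lt(fStatistic(0.05, 1000, 6), fStatistic(0.05, 1000, 5))
})

test_that("per-variant R2 uses 2p(1-p)b^2 with an se-based fallback", {
  expect_equal(perSnpR2(0.5, 0.1), 0.005)
  expect_equal(perSnpR2(0.3, 0), 0)
  r2 <- perSnpR2(NA, 0.1, se = 0.01, n = 1000)
  expect_equal(as.numeric(r2), 0.1^2 / (0.1^2 + 1000 * 0.01^2))
  expect_equal(as.numeric(r2), 0.0909, tolerance = 1e-3)
  expect_equal(attr(r2, "eaf_fallback"), 1L)
  expect_error(perSnpR2(NA, 0.1), "needs se and n")
})

test_that("weak instruments are removed before the set-level F", {
  # ten uniformly strong variants all survive
  h <- HarmonizedSet(bx = rep(0.15, 10), se_x = rep(0.02, 10),
                     by = rep(0.05, 10), se_y = rep(0.05, 10),
                     eaf = rep(0.3, 10))
  iv <- buildInstrumentSet(h, exposure_n = 5000, f_min = 10)
  expect_equal(nsnp(iv), 10L)

  # one planted weak variant goes, and totals are recomputed from scratch
  bx <- c(rep(0.15, 9), 0.02)
  h2 <- HarmonizedSet(bx = bx, se_x = rep(0.02, 10),
                      by = rep(0.05, 10), se_y = rep(0.05, 10),
                      eaf = rep(0.3, 10),
                      snp_id = sprintf("v%02d", 1:10))
  iv2 <- buildInstrumentSet(h2, exposure_n = 5000, f_min = 10)
  expect_equal(nsnp(iv2), 9L)
  expect_equal(iv2@removed$snp_id, "v10")
  r2_each <- 2 * 0.3 * 0.7 * bx[1:9]^2
  expect_equal(iv2@r2_total, sum(r2_each))
  expect_equal(iv2@f_stat,
               sum(r2_each) * (5000 - 9 - 1) / (9 * (1 - sum(r2_each))))

  # all-weak input is an error
  h3 <- HarmonizedSet(bx = rep(0.01, 3), se_x = rep(0.02, 3),
                      by = rep(0, 3), se_y = rep(0.05, 3),
                      eaf = rep(0.3, 3))
  expect_error(buildInstrumentSet(h3, exposure_n = 5000), "no instruments")
})

test_that("LD matrices round-trip through their file format", {
  set.seed(5)
  m <- matrix(runif(16, 0, 0.5), 4)
  r2 <- (m + t(m)) / 2
  diag(r2) <- 1
  ld <- LDMatrix(r2, paste0("rs", 1:4))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLDMatrix(ld, path)
  back <- readLDMatrix(path)
  expect_equal(snpIds(back), snpIds(ld))
  expect_equal(ldR2(back), ldR2(ld), tolerance = 1e-8)
})
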