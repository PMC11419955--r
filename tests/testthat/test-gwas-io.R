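test_that("a well-formed table round-trips through write and read", {
  ss <- SummaryStats("trait", rec_df(c("rs1", "rs2", "rs3"),
                                     beta = c(0.1, -0.2, 0.05),
                                     se = c(0.02, 0.03, 0.01)))
  expect_equal(nsnp(ss), 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSummaryStats(ss, path)
  back <- readSummaryStats(path, dialect = "generic", trait_id = "trait")
  expect_equal(records(back), records(ss), tolerance = 1e-12)
})

test_that("rows violating record invariants are dropped and tallied", {
  df <- rec_df(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, 0.3),
               se = c(0.02, 0, 0.01))
  ss <- SummaryStats("trait", df)
  expect_equal(nsnp(ss), 2L)
  rep <- loadReport(ss)
  expect_equal(sum(rep$n), 1L)
  expect_match(rep$reason, "se not > 0")

  # indel-style and duplicate rows are rejected too
  df2 <- rec_df(c("rs1", "rs1", "rs2"), beta = 0.1, se = 0.02)
  df2$effect_allele[3] <- "AT"
  ss2 <- SummaryStats("trait", df2)
  expect_equal(nsnp(ss2), 1L)
  expect_setequal(loadReport(ss2)$reason,
                  c("duplicate variant id",
                    "invalid alleles (indel, multi-allelic or identical)"))
})

test_that("the gwascat dialect maps harmonized-file headers correctly", {
  src <- data.frame(hm_rsid = c("rs10", "rs11"), hm_chrom = c("2", "2"),
                    hm_pos = c(5e5, 9e5), hm_effect_allele = c("C", "T"),
                    hm_other_allele = c("G", "C"),
                    hm_effect_allele_frequency = c(0.25, 0.4),
                    hm_beta = c(0.12, -0.07),
                    standard_error = c(0.03, 0.02),
                    p_value = c(1e-6, 0.02), n = c(5000, 5000))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(src, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- readSummaryStats(path, dialect = "gwascat")
  expect_equal(records(ss)$snp_id, c("rs10", "rs11"))
  expect_equal(records(ss)$beta, c(0.12, -0.07))
  # round-trip oracle: writing back in the generic dialect and re-reading
  # reproduces the mapped content exactly
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeSummaryStats(ss, path2)
  back <- readSummaryStats(path2, trait_id = traitId(ss))
  expect_equal(records(back), records(ss), tolerance = 1e-12)
})

test_that("read errors are informative", {
  expect_error(readSummaryStats(file.path(tempdir(), "nope.tsv")),
               "no such file")
  df <- rec_df("rs1", beta = 0.1, se = 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSummaryStats(path), "no valid records")
})

test_that("an allele swap flips the outcome effect sign", {
  ex <- SummaryStats("x", rec_df("rs1", 0.10, 0.02, ea = "A", oa = "G"))
  ou <- SummaryStats("y", rec_df("rs1", -0.05, 0.03, ea = "G", oa = "A",
                                 eaf = 0.7))
  h <- harmonize(ex, ou)
  expect_equal(h@by, 0.05)
  expect_equal(nsnp(h), 1L)
})

test_that("strand-complement alleles are flipped before matching", {
  # exposure A/G; outcome reported on the other strand as T/C (same
  # orientation) and as C/T (swapped): signs must come out as identity
  # and negation respectively
  ex <- SummaryStats("x", rec_df(c("rs1", "rs2"), c(0.10, 0.10), 0.02,
                                 ea = "A", oa = "G"))
  ou <- SummaryStats("y", rec_df(c("rs1", "rs2"), c(0.04, 0.04), 0.03,
                                 ea = c("T", "C"), oa = c("C", "T"),
                                 eaf = 0.3))
  h <- harmonize(ex, ou)
  expect_equal(h@by[h@snp_id == "rs1"], 0.04)
  expect_equal(h@by[h@snp_id == "rs2"], -0.04)
})

test_that("palindromic variants near 50% frequency are unorientable", {
  ex <- SummaryStats("x", rec_df("rs1", 0.1, 0.02, ea = "A", oa = "T",
                                 eaf = 0.5))
  ou1 <- SummaryStats("y", rec_df("rs1", 0.05, 0.03, ea = "A", oa = "T",
                                  eaf = 0.5))
  ou2 <- SummaryStats("y", rec_df(c("rs1", "rs2"), 0.05, 0.03,
                                  ea = c("A", "C"), oa = c("T", "G"),
                                  eaf = 0.10))
  expect_error(harmonize(ex, ou1), "no shared variant survived")
  # orientable at modest frequency, kept under infer_by_eaf
  ex2 <- SummaryStats("x", rec_df(c("rs1", "rs2"), 0.1, 0.02,
                                  ea = c("A", "C"), oa = c("T", "G"),
                                  eaf = 0.10))
  h <- harmonize(ex2, ou2)
  expect_equal(nsnp(h), 2L)
  expect_equal(h@by, c(0.05, 0.05))
  # same pair under drop_all loses both
  expect_error(harmonize(ex2, ou2, palindrome_policy = "drop_all"),
               "no shared variant survived")
})

test_that("incompatible allele sets are dropped with a recorded reason", {
  ids <- paste0("rs", 1:5)
  ex <- SummaryStats("x", rec_df(ids, 0.1, 0.02, ea = "A", oa = "G"))
  oa <- c("G", "G", "G", "G", "C")   # rs5 has allele set {A, C}
  ou <- SummaryStats("y", rec_df(ids, 0.05, 0.03, ea = "A", oa = oa,
                                 eaf = 0.3))
  h <- harmonize(ex, ou)
  expect_equal(nsnp(h), 4L)
  expect_equal(droppedRecords(h)$snp_id, "rs5")
  expect_match(droppedRecords(h)$reason, "incompatible alleles")
})

test_that("harmonization is idempotent and sign-consistent", {
  set.seed(41)
  k <- 40
  ea <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
  oa <- vapply(ea, function(a)
    sample(setdiff(c("A", "C", "G", "T"), a), 1), "")
  ids <- sprintf("rs%03d", 1:k)
  eaf <- runif(k, 0.05, 0.45)
  ex <- SummaryStats("x", rec_df(ids, rnorm(k, 0, 0.2), 0.02, ea = ea,
                                 oa = oa, eaf = eaf))
  ou <- SummaryStats("y", rec_df(ids, rnorm(k, 0, 0.1), 0.03, ea = ea,
                                 oa = oa, eaf = eaf))
  h1 <- harmonize(ex, ou)

  # idempotence: the aligned pair re-harmonizes to itself
  ou_aligned <- SummaryStats("y", rec_df(
    snpIds(h1), h1@by, h1@se_y,
    ea = records(ex)$effect_allele[match(snpIds(h1), ids)],
    oa = records(ex)$other_allele[match(snpIds(h1), ids)],
    eaf = records(ou)$eaf[match(snpIds(h1), ids)]))
  ex_aligned <- .ssSubset_test(ex, snpIds(h1))
  h2 <- harmonize(ex_aligned, ou_aligned)
  expect_equal(h2@by, h1@by)
  expect_equal(h2@bx, h1@bx)

  # sign consistency: negate all outcome betas, swap outcome alleles
  # (and complement eaf, the equivalent representation)
  rec <- records(ou)
  ou_swapped <- SummaryStats("y", rec_df(
    rec$snp_id, -rec$beta, rec$se, ea = rec$other_allele,
    oa = rec$effect_allele, eaf = 1 - rec$eaf))
  h3 <- harmonize(ex, ou_swapped)
  expect_equal(snpIds(h3), snpIds(h1))
  expect_equal(h3@by, h1@by)

  # conservation: retained + dropped = shared
  shared <- intersect(snpIds(ex), snpIds(ou))
  expect_equal(nsnp(h1) + nrow(droppedRecords(h1)), length(shared))
})
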