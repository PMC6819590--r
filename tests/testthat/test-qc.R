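# engineered panels exercising each filter boundary

test_that("a SNP below the MAF threshold is removed with reason 'maf'", {
  # 5 samples x 4 SNPs; SNP s4 has pooled alt frequency 0.1 -> MAF 0.1;
  # s3 has one alt allele in 10 -> MAF 0.1? no: engineer 0.01-style with
  # frequency below 0.02 impossible at n = 5, so use MAF 0 (monomorphic)
  # and a 50-sample panel for the sub-threshold case.
  d <- cbind(s1 = c(0, 1, 2, 1, 0), s2 = c(2, 2, 1, 2, 2),
             s3 = c(0, 0, 0, 0, 0), s4 = c(1, 1, 0, 1, 1))
  rownames(d) <- paste0("i", 1:5)
  p <- genotype_panel(d, line_labels = rep("A", 5))
  res <- apply_qc(p)
  expect_equal(res$report$removed_snps$id, "s3")
  expect_equal(res$report$removed_snps$reason, "maf")

  # 50 diploid samples, one alt allele at s_low: pooled MAF 0.01 < 0.02
  d2 <- matrix(1, 50, 2, dimnames = list(paste0("i", 1:50), c("s_ok", "s_low")))
  d2[, "s_low"] <- 0; d2[1, "s_low"] <- 1
  p2 <- genotype_panel(d2, line_labels = rep("A", 50))
  res2 <- apply_qc(p2)
  expect_equal(res2$report$removed_snps$id, "s_low")
  expect_equal(res2$report$removed_snps$reason, "maf")
  expect_equal(n_snps(res2$panel), 1)
})

test_that("low call-rate samples go first and can rescue a SNP", {
  # i5 has call rate 0.25 (<= 0.90): removed; SNP s2 is missing only in i5
  # and is complete afterwards, so it is retained
  d <- cbind(s1 = c(0, 1, 2, 1, NA), s2 = c(1, 1, 2, 0, NA),
             s3 = c(2, 1, 0, 1, 1), s4 = c(1, 0, 1, 2, NA))
  rownames(d) <- paste0("i", 1:5)
  p <- genotype_panel(d, line_labels = rep("A", 5))
  res <- apply_qc(p)
  expect_equal(res$report$removed_samples$individual_id, "i5")
  expect_equal(res$report$removed_samples$reason, "sample_call_rate")
  expect_true(all(c("s1", "s2", "s4") %in% colnames(res$panel$dosages)))
  expect_equal(sum(is.na(res$panel$dosages)), 0)
})

test_that("a sample at exactly the 0.90 boundary is removed (strict keep rule)", {
  set.seed(1)
  d <- matrix(rbinom(10 * 40, 2, 0.4), 10, 40,
              dimnames = list(paste0("i", 1:10), paste0("s", 1:40)))
  d[1, 1:4] <- NA   # call rate exactly 36/40 = 0.90
  p <- genotype_panel(d, line_labels = rep("A", 10))
  res <- apply_qc(p)
  expect_true("i1" %in% res$report$removed_samples$individual_id)
})

test_that("a complete high-MAF panel passes unchanged and QC is idempotent", {
  p <- sim_two_lines(0.05, 0.05, 20, 20, 500, seed = 4, snp_missing_rate = 0.01)
  once <- apply_qc(p)
  expect_equal(sum(is.na(once$panel$dosages)), 0)
  twice <- apply_qc(once$panel)
  expect_identical(twice$panel$dosages, once$panel$dosages)
  expect_equal(nrow(twice$report$removed_snps), 0)
  expect_equal(nrow(twice$report$removed_samples), 0)
  expect_equal(twice$report$n_snps_in, twice$report$n_snps_out)
})

test_that("in/out bookkeeping is consistent and reasons are unique", {
  p <- sim_two_lines(0.05, 0.05, 25, 25, 2000, seed = 6,
                     snp_missing_rate = 0.005)
  res <- apply_qc(p)
  rep <- res$report
  expect_equal(rep$n_individuals_in - nrow(rep$removed_samples),
               rep$n_individuals_out)
  expect_equal(rep$n_snps_in - nrow(rep$removed_snps), rep$n_snps_out)
  expect_equal(anyDuplicated(rep$removed_snps$id), 0)
  expect_true(all(rep$removed_snps$reason %in% c("maf", "snp_call_rate")))
})

test_that("MAF is computed after sample removal, not before", {
  # 20 complete samples all heterozygous at s_flip except carriers in a bad
  # sample block: before sample removal pooled MAF of s_flip >= 0.02, after
  # removal it is 0 -> the SNP must be dropped, proving the order
  n_good <- 49
  d <- matrix(1, n_good + 1, 3,
              dimnames = list(paste0("i", 1:(n_good + 1)),
                              c("s_a", "s_b", "s_flip")))
  d[1:n_good, "s_flip"] <- 0          # monomorphic among good samples
  d[n_good + 1, "s_flip"] <- 2        # only the bad sample carries alt
  d[n_good + 1, c("s_a", "s_b")] <- NA  # call rate 1/3 -> removed
  p <- genotype_panel(d, line_labels = rep("A", n_good + 1))
  res <- apply_qc(p)
  expect_true("s_flip" %in% res$report$removed_snps$id)
  expect_equal(
    res$report$removed_snps$reason[res$report$removed_snps$id == "s_flip"],
    "maf")
})

test_that("removing everything raises an error that still carries the report", {
  d <- matrix(NA_real_, 3, 3, dimnames = list(paste0("i", 1:3), paste0("s", 1:3)))
  d[1, 1] <- 0
  p <- genotype_panel(d, line_labels = rep("A", 3))
  err <- tryCatch(apply_qc(p), error = identity)
  expect_s3_class(err, "snpdiv_qc_error")
})
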