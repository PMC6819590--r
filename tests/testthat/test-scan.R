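test_that("BH q-values match hand cases and the step-up oracle", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  expect_equal(bh_qvalues(numeric(0)), numeric(0))
  expect_error(bh_qvalues(c(0.5, 0)), "\\(0, 1\\]")

  set.seed(107)
  p <- runif(100)
  expect_equal(bh_qvalues(p), oracle_bh(p), tolerance = 1e-12)
  # monotone in sorted-p order
  o <- order(p)
  expect_true(all(diff(bh_qvalues(p)[o]) >= -1e-12))
})

test_that("permutation p-values hit the add-one floor for extreme loci", {
  # one locus fixed between the lines: no permutation can reach the observed
  # theta except the (rare) label-preserving ones; with distinct group sizes
  # the observed split is unique up to complement, so p = (1 + k)/(n_perm + 1)
  # with k the count of recreations; assert the floor is respected
  set.seed(109)
  d <- cbind(matrix(rbinom(12 * 50, 2, 0.5), 12, 50),
             rep(c(0, 2), c(5, 7)))
  colnames(d) <- c(paste0("s", 1:50), "fixed")
  rownames(d) <- paste0("i", 1:12)
  p <- genotype_panel(d, line_labels = rep(c("A", "B"), c(5, 7)))
  sc <- locus_scan(p, "A", "B", n_perm = 199, seed = 3)
  pf <- sc$table$p[sc$table$id == "fixed"]
  expect_gte(pf, 1 / 200)
  expect_lt(pf, 0.05)
  expect_error(locus_scan(p, "A", "B", n_perm = 10), "at least 19")
})

test_that("the same seed reproduces the scan exactly", {
  p <- sim_two_lines(0.05, 0.05, 10, 10, 300, seed = 113)
  s1 <- locus_scan(p, "A", "B", n_perm = 99, seed = 7)
  s2 <- locus_scan(p, "A", "B", n_perm = 99, seed = 7)
  expect_identical(s1$table, s2$table)
  s3 <- locus_scan(p, "A", "B", n_perm = 99, seed = 8)
  expect_false(identical(s1$table$p, s3$table$p))
})

test_that("outlier sets are nested in the q threshold", {
  p <- sim_two_lines(0.2, 0.2, 15, 15, 1000, seed = 127)
  s05 <- locus_scan(p, "A", "B", n_perm = 199, q_threshold = 0.05, seed = 5)
  s01 <- locus_scan(p, "A", "B", n_perm = 199, q_threshold = 0.01, seed = 5)
  out05 <- s05$table$id[s05$table$outlier]
  out01 <- s01$table$id[s01$table$outlier]
  expect_true(all(out01 %in% out05))
})

test_that("null permutation p-values are valid (super-uniform) and not degenerate", {
  # theta on dosage data is discrete, and ties count against the observed
  # value, so p-values are conservative rather than exactly uniform; the
  # property that matters for error control is P(p <= a) <= a at every a
  p <- sim_two_lines(0.001, 0.001, 25, 25, 5000, seed = 131)
  sc <- locus_scan(p, "A", "B", n_perm = 199, seed = 11)
  pv <- sc$table$p[!is.na(sc$table$p)]
  m <- length(pv)
  for (a in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(pv <= a), a + 3 * sqrt(a * (1 - a) / m))
  }
  # but small p-values are still reachable at a useful rate
  expect_gt(mean(pv <= 0.05), 0.01)
  expect_gt(mean(pv <= 0.25), 0.10)
})

test_that("planted frequency shifts are recovered with few false positives", {
  set.seed(137)
  m_null <- 950; m_shift <- 50
  n <- 25
  p0 <- runif(m_null + m_shift, 0.15, 0.85)
  p_a <- p0
  p_b <- p0
  shift_idx <- seq_len(m_shift) + m_null
  p_b[shift_idx] <- pmin(pmax(p0[shift_idx] + 0.4 * sign(0.5 - p0[shift_idx]),
                              0.02), 0.98)
  xa <- matrix(rbinom(n * length(p0), 2, rep(p_a, each = n)), n)
  xb <- matrix(rbinom(n * length(p0), 2, rep(p_b, each = n)), n)
  d <- rbind(xa, xb)
  rownames(d) <- paste0("i", seq_len(2 * n))
  panel <- genotype_panel(d, line_labels = rep(c("A", "B"), each = n))
  sc <- locus_scan(panel, "A", "B", n_perm = 999, seed = 13)
  flagged <- which(sc$table$outlier)
  expect_gte(length(intersect(flagged, shift_idx)), 0.8 * m_shift)
  expect_lte(length(setdiff(flagged, shift_idx)), 0.01 * m_null)
})

test_that("gene windows are inclusive at both boundaries", {
  set.seed(139)
  d <- cbind(sig = rep(c(0, 2), each = 10),
             matrix(rbinom(20 * 30, 2, 0.5), 20, 30))
  rownames(d) <- paste0("i", 1:20)
  meta <- data.frame(id = c("sig", paste0("s", 1:30)), chrom = "7",
                     pos = c(100000L, 200000L + 1000L * (1:30)))
  panel <- genotype_panel(d, line_labels = rep(c("A", "B"), each = 10),
                          snp_meta = meta)
  sc <- locus_scan(panel, "A", "B", n_perm = 999, seed = 17)
  expect_true(sc$table$outlier[sc$table$id == "sig"])

  genes <- data.frame(
    chrom = "7",
    start = c(105000L, 80000L, 99990L),      # at +5000; ends at -5001; overlap
    end =   c(106000L, 94999L, 100010L),
    id = c("at_boundary", "too_far", "inside")
  )
  hits <- annotate_outliers(sc, genes, window_bp = 5000)
  expect_true("at_boundary" %in% hits$gene_id)
  expect_false("too_far" %in% hits$gene_id)
  inside <- hits[hits$gene_id == "inside", ]
  expect_equal(inside$distance_bp, 0L)
  expect_equal(inside$side, "overlap")
  expect_equal(hits$distance_bp[hits$gene_id == "at_boundary"], 5000L)
  expect_equal(hits$side[hits$gene_id == "at_boundary"], "downstream")
})

test_that("annotation matches the brute-force overlap oracle on random input", {
  set.seed(149)
  n <- 16
  d <- rbind(matrix(0, 8, n), matrix(2, 8, n))  # every locus an outlier
  rownames(d) <- paste0("i", 1:16)
  meta <- data.frame(id = paste0("s", 1:n),
                     chrom = rep(c("1", "2"), each = n / 2),
                     pos = rep(sort(sample(1e5, n / 2)), 2) + rep(c(0, 7), each = n / 2))
  meta <- meta[order(meta$chrom, meta$pos), ]
  meta$id <- paste0("s", 1:n)
  panel <- genotype_panel(d, line_labels = rep(c("A", "B"), each = 8),
                          snp_meta = meta)
  sc <- locus_scan(panel, "A", "B", n_perm = 199, seed = 19)
  genes <- data.frame(
    chrom = sample(c("1", "2", "3"), 40, replace = TRUE),
    start = sample(1e5, 40)
  )
  genes$end <- genes$start + sample(500:5000, 40, replace = TRUE)
  genes$id <- paste0("g", 1:40)

  has_mismatch <- "3" %in% genes$chrom
  hits <- if (has_mismatch) {
    expect_warning(annotate_outliers(sc, genes, window_bp = 2000), "skipped")
    suppressWarnings(annotate_outliers(sc, genes, window_bp = 2000))
  } else {
    annotate_outliers(sc, genes, window_bp = 2000)
  }
  outl <- sc$table[sc$table$outlier, ]
  oracle <- oracle_gene_hits(
    data.frame(id = outl$id, chrom = outl$chrom, pos = outl$pos),
    genes[genes$chrom %in% c("1", "2"), ], window = 2000)
  got <- paste(hits$snp_id, hits$gene_id)
  want <- paste(oracle$snp_id, oracle$gene_id)
  expect_setequal(got, want)
})
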