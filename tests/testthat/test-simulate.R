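test_that("config validation rejects out-of-range parameters", {
  pl <- data.frame(name = "A", size = 10, drift_F = 0.1)
  expect_s3_class(sim_config(100, pl), "sim_config")
  expect_error(sim_config(0, pl), "positive")
  expect_error(sim_config(100, data.frame(name = "A", size = 0, drift_F = 0.1)),
               "sizes")
  expect_error(sim_config(100, data.frame(name = "A", size = 5, drift_F = 1)),
               "drift_F")
  expect_error(sim_config(100, pl, admixed_line = list(name = "X", size = 5,
                                                       dirichlet_alpha = c(1, 1))),
               "one entry per parent line")
  expect_error(sim_config(100, pl, sample_missing_rate = 1), "rates")
  expect_error(sim_config(100, pl, ancestral_maf_range = c(0, 0.5)), "range")
})

test_that("identical config and seed give a bit-identical panel", {
  cfg <- sim_config(500, data.frame(name = c("A", "B"), size = c(8, 12),
                                    drift_F = c(0.05, 0.1)),
                    admixed_line = list(name = "X", size = 6,
                                        dirichlet_alpha = c(2, 1)),
                    snp_missing_rate = 0.01, seed = 11)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$dosages, p2$dosages)
  expect_identical(p1$ancestry, p2$ancestry)
  expect_identical(attr(p1, "true_freqs"), attr(p2, "true_freqs"))
})

test_that("near-zero drift produces essentially undifferentiated lines", {
  p <- sim_two_lines(0.001, 0.001, 50, 50, 20000, seed = 5)
  fst <- pairwise_fst(p, "A", "B", per_locus = FALSE)
  expect_lt(abs(fst$theta), 0.005)
})

test_that("a degenerate Dirichlet collapses the admixed line onto one parent", {
  cfg <- sim_config(
    20000,
    data.frame(name = c("P1", "P2"), size = c(40, 40), drift_F = c(0.1, 0.1)),
    admixed_line = list(name = "X", size = 30,
                        dirichlet_alpha = c(1e6, 1e-6)),
    snp_missing_rate = 0, seed = 9
  )
  p <- simulate_panel(cfg)
  expect_true(all(abs(p$ancestry[p$line_labels == "X", "P1"] - 1) < 1e-4))
  fst <- pairwise_fst(p, "X", "P1", per_locus = FALSE)
  expect_lt(abs(fst$theta), 0.01)
  fst2 <- pairwise_fst(p, "X", "P2", per_locus = FALSE)
  expect_gt(fst2$theta, 0.05)
})

test_that("simulated theta at drift 0.10 matches the Monte-Carlo oracle", {
  p <- sim_two_lines(0.10, 0.10, 50, 50, 20000, seed = 21)
  est <- pairwise_fst(p, "A", "B", per_locus = FALSE)$theta
  expected <- oracle_bn_theta(0.10, 0.10, 50, 50, 200000, seed = 22)
  expect_lt(abs(est - expected), 0.02)
})

test_that("estimated theta is monotone increasing in drift_F", {
  thetas <- vapply(c(0.01, 0.05, 0.1, 0.2), function(f) {
    p <- sim_two_lines(f, f, 30, 30, 20000, seed = 31)
    pairwise_fst(p, "A", "B", per_locus = FALSE)$theta
  }, numeric(1))
  expect_true(all(diff(thetas) > 0))
})

test_that("truth report rows are normalised ancestry, indicators for parents", {
  cfg <- sim_config(
    2000,
    data.frame(name = c("A", "B", "C"), size = c(10, 10, 10),
               drift_F = c(0.05, 0.05, 0.05)),
    admixed_line = list(name = "X", size = 200, dirichlet_alpha = c(2, 2, 2)),
    seed = 13
  )
  p <- simulate_panel(cfg)
  tr <- truth_report(p)
  anc <- as.matrix(tr$ancestry[, c("A", "B", "C")])
  expect_equal(unname(rowSums(anc)), rep(1, nrow(anc)), tolerance = 1e-12)
  parent_rows <- anc[tr$ancestry$line != "X", ]
  expect_true(all(parent_rows %in% c(0, 1)))
  expect_equal(unname(rowSums(parent_rows)), rep(1, nrow(parent_rows)))
  # symmetric alpha: mean ancestry per parent ~ 1/K (Dirichlet mean oracle);
  # MC error at n = 200, concentration 6 is ~ sd 0.19/sqrt(200)
  mix_rows <- anc[tr$ancestry$line == "X", ]
  expect_equal(unname(colMeans(mix_rows)), rep(1 / 3, 3), tolerance = 0.05)
})

test_that("truth_report refuses panels without simulation truth", {
  d <- matrix(c(0, 1, 2, 1), 2, 2)
  p <- genotype_panel(d, line_labels = c("A", "B"))
  expect_error(truth_report(p), "simulated panel")
})

test_that("admixed kinship with a parent line tracks true ancestry", {
  cfg <- sim_config(
    20000,
    data.frame(name = c("A", "B"), size = c(30, 30), drift_F = c(0.1, 0.1)),
    admixed_line = list(name = "X", size = 30, dirichlet_alpha = c(1.5, 1.5)),
    snp_missing_rate = 0, seed = 17
  )
  p <- apply_qc(simulate_panel(cfg))$panel
  g <- compute_grm(p)
  f <- g$values / 2
  ix <- which(p$line_labels == "X")
  ia <- which(p$line_labels == "A")
  kin_with_a <- rowMeans(f[ix, ia])
  anc_a <- p$ancestry[ix, "A"]
  expect_gt(cor(kin_with_a, anc_a, method = "spearman"), 0.8)
})
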