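# Independent oracles used across the suite. Each re-derives a quantity by
# the most transparent route available (double loops, direct formula
# evaluation, brute-force enumeration) and never calls the package's own
# computational path for the quantity it checks.

# Yang et al. GRM by per-SNP double loop
oracle_grm <- function(x) {
  n <- nrow(x); m <- ncol(x)
  p <- colMeans(x) / 2
  g <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        acc <- 0
        for (k in seq_len(m)) {
          acc <- acc + (x[i, k]^2 - (1 + 2 * p[k]) * x[i, k] + 2 * p[k]^2) /
            (2 * p[k] * (1 - p[k]))
        }
        g[i, j] <- 1 + acc / m
      } else {
        acc <- 0
        for (k in seq_len(m)) {
          acc <- acc + (x[i, k] - 2 * p[k]) * (x[j, k] - 2 * p[k]) /
            (2 * p[k] * (1 - p[k]))
        }
        g[i, j] <- acc / m
      }
    }
  }
  dimnames(g) <- list(rownames(x), rownames(x))
  g
}

# line-average kinship by explicit pair enumeration (f = G/2, self pairs in)
oracle_line_kinship <- function(g, labels) {
  lev <- unique(labels)
  f <- g / 2
  out <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (a in lev) {
    for (b in lev) {
      ia <- which(labels == a); ib <- which(labels == b)
      acc <- 0
      for (i in ia) for (j in ib) acc <- acc + f[i, j]
      out[a, b] <- acc / (length(ia) * length(ib))
    }
  }
  out
}

# Weir-Cockerham (1984) two-population variance components for one locus,
# written out scalar-by-scalar from the published formulas
oracle_wc_locus <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
  h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# multi-locus theta over a two-line dosage matrix, locus-by-locus loop
oracle_wc_multilocus <- function(xa, xb) {
  num <- 0; den <- 0
  for (k in seq_len(ncol(xa))) {
    comp <- oracle_wc_locus(xa[, k], xb[, k])
    tot <- sum(comp)
    if (tot != 0) {
      num <- num + comp["a"]
      den <- den + tot
    }
  }
  unname(num / den)
}

# Monte-Carlo expectation of multi-locus theta under Balding-Nichols drift:
# direct simulation of per-locus components at an inflated locus count
oracle_bn_theta <- function(F1, F2, n1, n2, m, seed) {
  set.seed(seed)
  maf <- runif(m, 0.01, 0.5)
  p <- ifelse(runif(m) < 0.5, maf, 1 - maf)
  p1 <- rbeta(m, p * (1 - F1) / F1, (1 - p) * (1 - F1) / F1)
  p2 <- rbeta(m, p * (1 - F2) / F2, (1 - p) * (1 - F2) / F2)
  num <- 0; den <- 0
  x1 <- matrix(rbinom(n1 * m, 2, rep(p1, each = n1)), n1, m)
  x2 <- matrix(rbinom(n2 * m, 2, rep(p2, each = n2)), n2, m)
  for (k in seq_len(m)) {
    comp <- oracle_wc_locus(x1[, k], x2[, k])
    tot <- sum(comp)
    if (tot != 0) {
      num <- num + comp["a"]
      den <- den + tot
    }
  }
  unname(num / den)
}

# Benjamini-Hochberg step-up by direct definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# brute-force interval overlap of SNP windows and gene intervals
oracle_gene_hits <- function(snps, genes, window) {
  hits <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(genes))) {
      if (snps$chrom[i] != genes$chrom[j]) next
      lo <- snps$pos[i] - window; hi <- snps$pos[i] + window
      if (genes$end[j] >= lo && genes$start[j] <= hi) {
        hits[[length(hits) + 1]] <- data.frame(
          snp_id = snps$id[i], gene_id = genes$id[j])
      }
    }
  }
  if (length(hits) == 0) return(data.frame(snp_id = character(0),
                                           gene_id = character(0)))
  do.call(rbind, hits)
}

# random positive-definite kinship-like matrix with diagonal in (0, 1)
random_pd_kinship <- function(n, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n * n, sd = 0.08), n)
  m <- crossprod(a) + diag(runif(n, 0.08, 0.3))
  dimnames(m) <- list(paste0("L", seq_len(n)), paste0("L", seq_len(n)))
  m
}

# small deterministic panel used by several suites
make_toy_panel <- function() {
  d <- rbind(
    A1 = c(0, 1, 2, 1, 0, 1),
    A2 = c(1, 1, 2, 0, 0, 2),
    A3 = c(0, 2, 1, 1, 1, 1),
    B1 = c(2, 0, 0, 2, 1, 0),
    B2 = c(2, 1, 0, 2, 2, 0),
    B3 = c(1, 0, 1, 2, 2, 1)
  )
  genotype_panel(d, line_labels = rep(c("A", "B"), each = 3))
}

# two-line simulated panel shared by fst/grm tests
sim_two_lines <- function(F1, F2, n1, n2, m, seed,
                          snp_missing_rate = 0) {
  cfg <- sim_config(
    n_snps = m,
    parent_lines = data.frame(name = c("A", "B"), size = c(n1, n2),
                              drift_F = c(F1, F2)),
    snp_missing_rate = snp_missing_rate,
    seed = seed
  )
  simulate_panel(cfg)
}
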