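#' Genomic relationship matrix (Yang et al. form)
#'
#' Off-diagonal entries average, over SNPs, the cross-product of centred and
#' standardised dosages,
#' `G_ij = mean_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k (1 - p_k))`,
#' while the diagonal uses the dedicated estimator of the genomic inbreeding
#' coefficient,
#' `G_ii = 1 + mean_k (x_ik^2 - (1 + 2 p_k) x_ik + 2 p_k^2) / (2 p_k (1 - p_k))`.
#' Allele frequencies `p` are estimated from the full panel with all lines
#' pooled: a single reference frequency is what makes between-line entries
#' negative for lines on opposite sides of the pooled mean, which is the
#' structure the core-set analysis consumes.
#'
#' @param panel A [genotype_panel()] with no missing genotypes (run
#'   [apply_qc()] first) and no monomorphic SNPs.
#' @return An object of class `grm`: list with `values` (n x n symmetric
#'   matrix), `individual_ids`, and `allele_freqs`.
#' @references Yang et al. (2010) Common SNPs explain a large proportion of
#'   the heritability for human height. Nature Genetics 42:565-569.
#' @export
compute_grm <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  x <- panel$dosages
  if (anyNA(x)) {
    stop("panel contains missing genotypes; run apply_qc() (SNP call rate 100%) first")
  }
  p <- colMeans(x) / 2
  if (any(p <= 0 | p >= 1)) {
    stop(sprintf("%d monomorphic SNP(s) present; the MAF filter in apply_qc() removes these",
                 sum(p <= 0 | p >= 1)))
  }
  m <- ncol(x)
  w <- sweep(x, 2, 2 * p)
  ws <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  g <- tcrossprod(ws) / m
  # Yang diagonal replaces the plain cross-product diagonal
  num <- sweep(x^2 - sweep(x, 2, 1 + 2 * p, "*"), 2, 2 * p^2, "+")
  diag(g) <- 1 + rowMeans(sweep(num, 2, 2 * p * (1 - p), "/"))
  structure(
    list(values = g, individual_ids = rownames(x), allele_freqs = p),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d individuals, %d SNPs; mean diagonal %.4f\n",
              nrow(x$values), length(x$allele_freqs), mean(diag(x$values))))
  invisible(x)
}

#' Line-kinship matrix
#'
#' Bundles an n x n matrix of average within-line (diagonal) and
#' between-line (off-diagonal) kinship coefficients with its line names.
#' Usually produced by [aggregate_line_kinship()] or [read_line_kinship()].
#'
#' @param values Square symmetric numeric matrix with line names as
#'   dimnames.
#' @param n_per_line Optional named integer vector of line sizes.
#' @return An object of class `line_kinship`.
#' @export
line_kinship <- function(values, n_per_line = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("kinship matrix must be square")
  if (is.null(rownames(values))) stop("kinship matrix needs line names")
  if (!isSymmetric(unname(values), tol = 1e-8)) {
    stop("kinship matrix must be symmetric")
  }
  if (any(!is.finite(values))) stop("kinship matrix must be finite")
  structure(
    list(values = values, line_names = rownames(values),
         n_lines = nrow(values), n_per_line = n_per_line),
    class = "line_kinship"
  )
}

#' @export
print.line_kinship <- function(x, ...) {
  cat(sprintf("<line_kinship> %d lines: %s\n", x$n_lines,
              paste(x$line_names, collapse = ", ")))
  print(round(x$values, 4))
  invisible(x)
}

#' Average within- and between-line kinship from a GRM
#'
#' Kinship is taken as half the genomic relationship, `f = G / 2`. The
#' within-line entry for a line averages `f` over all ordered pairs of its
#' members including self pairs (`f_ii = G_ii / 2`); the between-line entry
#' averages `f` over all cross-line pairs.
#'
#' @param grm A `grm` from [compute_grm()].
#' @param labels Character vector of line labels, one per individual in the
#'   GRM (or a [genotype_panel()] whose labels are used).
#' @return A [line_kinship()].
#' @export
aggregate_line_kinship <- function(grm, labels) {
  stopifnot(inherits(grm, "grm"))
  if (inherits(labels, "genotype_panel")) labels <- labels$line_labels
  labels <- as.character(labels)
  if (length(labels) != nrow(grm$values)) {
    stop("labels length does not match GRM dimension")
  }
  if (anyNA(labels) || any(labels == "")) stop("unknown (empty) line label")
  f <- grm$values / 2
  lev <- unique(labels)
  fac <- factor(labels, levels = lev)
  sums <- rowsum(f, fac)
  sums <- t(rowsum(t(sums), fac))
  cnt <- as.integer(table(fac))
  denom <- outer(cnt, cnt)
  m <- sums / denom
  dimnames(m) <- list(lev, lev)
  m <- (m + t(m)) / 2   # symmetrise numerical noise
  line_kinship(m, n_per_line = stats::setNames(cnt, lev))
}
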