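# Weir & Cockerham (1984) variance components for two populations at
# biallelic loci, vectorised over loci. Inputs are per-population allele
# frequencies p, observed heterozygote frequencies h and sample sizes n.
# Returns the per-locus components a (among populations), b (among
# individuals within populations) and c (within individuals).
.wc_components <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

.pop_stats <- function(x) {
  list(p = colMeans(x) / 2, h = colMeans(x == 1), n = nrow(x))
}

#' Pairwise Weir-Cockerham Fst between two lines
#'
#' Estimates the fixation index theta of Weir & Cockerham (1984) between two
#' lines of a panel. Per-locus variance components `a` (among populations),
#' `b` (among individuals within populations) and `c` (within individuals)
#' are computed from observed allele and heterozygote frequencies; the
#' multi-locus estimate is the ratio of sums `sum(a) / sum(a + b + c)` (not
#' the mean of per-locus ratios). Loci with `a + b + c = 0` carry no
#' information and are skipped, with a count reported.
#'
#' @param panel A [genotype_panel()] with no missing genotypes.
#' @param pop_a,pop_b Line labels; each line needs at least 2 individuals.
#' @param per_locus Return the per-locus component table (default `TRUE`).
#' @return A list with `theta` (multi-locus estimate), `n_loci_used`,
#'   `n_loci_skipped`, and (optionally) `per_locus`, a data frame with
#'   columns `id`, `a`, `b`, `c`, `theta`.
#' @references Weir BS, Cockerham CC (1984) Estimating F-statistics for the
#'   analysis of population structure. Evolution 38:1358-1370.
#' @export
pairwise_fst <- function(panel, pop_a, pop_b, per_locus = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (anyNA(panel$dosages)) {
    stop("panel contains missing genotypes; run apply_qc() first")
  }
  xa <- .line_matrix(panel, pop_a)
  xb <- .line_matrix(panel, pop_b)
  if (nrow(xa) < 2L || nrow(xb) < 2L) {
    stop(sprintf("lines must have >= 2 individuals (%s: %d, %s: %d)",
                 pop_a, nrow(xa), pop_b, nrow(xb)))
  }
  sa <- .pop_stats(xa)
  sb <- .pop_stats(xb)
  comp <- .wc_components(sa$p, sb$p, sa$h, sb$h, sa$n, sb$n)
  tot <- comp$a + comp$b + comp$c
  usable <- tot != 0
  if (!any(usable)) stop("no usable loci: a + b + c is zero everywhere")
  theta <- sum(comp$a[usable]) / sum(tot[usable])
  out <- list(theta = theta,
              n_loci_used = sum(usable),
              n_loci_skipped = sum(!usable),
              pops = c(pop_a, pop_b))
  if (per_locus) {
    out$per_locus <- data.frame(
      id = panel$snp_meta$id,
      a = comp$a, b = comp$b, c = comp$c,
      theta = ifelse(usable, comp$a / tot, NA_real_)
    )
  }
  out
}

#' All pairwise Fst estimates among the lines of a panel
#'
#' @param panel A [genotype_panel()] with no missing genotypes; every line
#'   needs at least 2 individuals.
#' @param per_locus Keep the per-pair per-locus tables (default `FALSE`).
#' @return An object of class `fst_result`: `pairwise` (symmetric matrix of
#'   multi-locus theta, diagonal 0), `line_names`, and optionally
#'   `per_locus` (named list of per-pair tables).
#' @export
all_pairwise_fst <- function(panel, per_locus = FALSE) {
  lines <- panel_lines(panel)
  n <- length(lines)
  m <- matrix(0, n, n, dimnames = list(lines, lines))
  pl <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        res <- pairwise_fst(panel, lines[i], lines[j], per_locus = per_locus)
        m[i, j] <- m[j, i] <- res$theta
        if (per_locus) pl[[paste(lines[i], lines[j], sep = "-")]] <- res$per_locus
      }
    }
  }
  structure(
    list(pairwise = m, line_names = lines,
         per_locus = if (per_locus) pl else NULL),
    class = "fst_result"
  )
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result> multi-locus Weir-Cockerham theta\n")
  print(round(x$pairwise, 4))
  invisible(x)
}
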