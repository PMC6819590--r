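#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a thin, validated wrapper around
#' `p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Permutation Fst-outlier scan between two lines
#'
#' Flags loci whose Weir-Cockerham theta between two lines is larger than
#' expected under the no-differentiation null. The null distribution is
#' built by permuting individual line labels `n_perm` times and recomputing
#' the per-locus theta; the permutation p-value uses the add-one correction
#' `p = (1 + #\{theta_perm >= theta_obs\}) / (n_perm + 1)` with ties counted
#' against the observed value (conservative). Benjamini-Hochberg q-values
#' control the false-discovery rate and loci with `q <= q_threshold` are
#' flagged as outliers.
#'
#' This scan is an explicitly simplified analog of Bayesian Fst-outlier
#' methods: a label-permutation null in place of a model-based posterior.
#' The result records this in its `method` field.
#'
#' @param panel A [genotype_panel()] with no missing genotypes.
#' @param pop_a,pop_b Line labels, each with at least 2 individuals.
#' @param n_perm Number of permutations (at least 19, default 999).
#' @param q_threshold Outlier threshold on the q-value (default 0.05).
#' @param seed Integer seed making the permutations reproducible.
#' @param block_size Number of loci processed per block (memory knob).
#' @return An object of class `scan_result`: `table` (data frame with `id`,
#'   `chrom`, `pos`, `theta`, `p`, `q`, `outlier`), `n_perm`, `seed`,
#'   `pops`, `q_threshold`, `method`.
#' @export
locus_scan <- function(panel, pop_a, pop_b, n_perm = 999, q_threshold = 0.05,
                       seed = 1L, block_size = 4000L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (anyNA(panel$dosages)) {
    stop("panel contains missing genotypes; run apply_qc() first")
  }
  if (n_perm < 19L) {
    stop("n_perm must be at least 19 to resolve p-values below 0.05")
  }
  xa <- .line_matrix(panel, pop_a)
  xb <- .line_matrix(panel, pop_b)
  n1 <- nrow(xa); n2 <- nrow(xb)
  if (n1 < 2L || n2 < 2L) {
    stop(sprintf("lines must have >= 2 individuals (%s: %d, %s: %d)",
                 pop_a, n1, pop_b, n2))
  }
  x <- rbind(xa, xb)
  n <- n1 + n2
  m <- ncol(x)

  sa <- .pop_stats(xa); sb <- .pop_stats(xb)
  comp <- .wc_components(sa$p, sb$p, sa$h, sb$h, n1, n2)
  tot <- comp$a + comp$b + comp$c
  obs <- ifelse(tot != 0, comp$a / tot, NA_real_)

  set.seed(seed)
  perm_ind <- matrix(0, n_perm, n)
  for (i in seq_len(n_perm)) perm_ind[i, sample.int(n, n1)] <- 1

  het <- (x == 1) * 1
  count_ge <- integer(m)
  for (start in seq(1L, m, by = block_size)) {
    idx <- start:min(start + block_size - 1L, m)
    xb_blk <- x[, idx, drop = FALSE]
    hb_blk <- het[, idx, drop = FALSE]
    s_tot <- colSums(xb_blk)
    h_tot <- colSums(hb_blk)
    sA <- perm_ind %*% xb_blk
    hA <- perm_ind %*% hb_blk
    p1 <- sA / (2 * n1)
    h1 <- hA / n1
    p2 <- sweep(-sA, 2, s_tot, "+") / (2 * n2)
    h2 <- sweep(-hA, 2, h_tot, "+") / n2
    pc <- .wc_components(p1, p2, h1, h2, n1, n2)
    ptot <- pc$a + pc$b + pc$c
    theta_perm <- pc$a / ptot        # NaN where ptot == 0
    ge <- theta_perm >= matrix(obs[idx], n_perm, length(idx), byrow = TRUE)
    count_ge[idx] <- colSums(ge, na.rm = TRUE)
  }

  p <- rep(NA_real_, m)
  usable <- !is.na(obs)
  p[usable] <- (1 + count_ge[usable]) / (n_perm + 1)
  q <- rep(NA_real_, m)
  q[usable] <- bh_qvalues(p[usable])

  structure(
    list(table = data.frame(
           id = panel$snp_meta$id,
           chrom = panel$snp_meta$chrom,
           pos = panel$snp_meta$pos,
           theta = obs, p = p, q = q,
           outlier = !is.na(q) & q <= q_threshold),
         n_perm = n_perm, seed = seed, pops = c(pop_a, pop_b),
         q_threshold = q_threshold,
         method = "permutation Fst-outlier scan (label-permutation null, BH FDR); simplified analog of model-based Bayesian outlier scans"),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s vs %s: %d loci, %d outliers at q <= %s (%d permutations)\n",
              x$pops[1], x$pops[2], nrow(x$table), sum(x$table$outlier),
              format(x$q_threshold), x$n_perm))
  cat(" ", x$method, "\n")
  invisible(x)
}

#' Read a gene annotation table
#'
#' GFF3 (`.gff`, `.gff3`) and BED (`.bed`) files are parsed with
#' \pkg{rtracklayer}; BED's 0-based half-open coordinates are converted to
#' the 1-based inclusive convention used throughout. Any other extension is
#' read as a headered 4-column TSV (`chrom`, `start`, `end`, `id`)
#' interpreted as 0-based half-open, BED-style.
#'
#' @param path Annotation file path.
#' @return Data frame with columns `chrom`, `start`, `end`, `id`
#'   (1-based inclusive).
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.gff3?$", lower) || grepl("\\.bed$", lower)) {
    gr <- rtracklayer::import(path)
    md <- as.data.frame(gr)
    id <- md$ID %||% md$Name %||% md$gene_id %||% md$name
    if (is.null(id)) id <- paste0("feature_", seq_along(gr))
    id <- as.character(id)
    id[is.na(id)] <- paste0("feature_", which(is.na(id)))
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               id = id, stringsAsFactors = FALSE)
  } else {
    d <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
    names(d)[1:4] <- c("chrom", "start", "end", "id")
    data.frame(chrom = as.character(d$chrom),
               start = as.integer(d$start) + 1L,   # 0-based half-open -> 1-based
               end = as.integer(d$end),
               id = as.character(d$id), stringsAsFactors = FALSE)
  }
}

#' Annotate outlier SNPs with nearby genes
#'
#' For each outlier SNP, reports every gene whose (1-based inclusive)
#' interval intersects the window `[pos - window_bp, pos + window_bp]`,
#' i.e. genes within `window_bp` up- or downstream (a 2 x `window_bp` total
#' window). The distance is 0 when the SNP falls inside the gene; otherwise
#' it is the gap in bp, with `side` recording whether the gene lies before
#' (`upstream`) or after (`downstream`) the SNP on the chromosome.
#'
#' @param scan A `scan_result` from [locus_scan()].
#' @param genes A gene table from [read_gene_table()] (or a data frame with
#'   columns `chrom`, `start`, `end`, `id`, 1-based inclusive).
#' @param window_bp Window half-width in bp on each side (default 5000).
#' @return Data frame of hits: `snp_id`, `chrom`, `pos`, `gene_id`,
#'   `gene_start`, `gene_end`, `distance_bp`, `side`.
#' @export
annotate_outliers <- function(scan, genes, window_bp = 5000) {
  stopifnot(inherits(scan, "scan_result"))
  out <- scan$table[scan$table$outlier, , drop = FALSE]
  empty <- data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), gene_id = character(0),
                      gene_start = integer(0), gene_end = integer(0),
                      distance_bp = integer(0), side = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(out) == 0L || nrow(genes) == 0L) return(empty)

  unknown <- setdiff(unique(genes$chrom), unique(out$chrom))
  skipped <- genes$chrom %in% unknown
  if (any(skipped)) {
    warning(sprintf("skipped %d gene(s) on chromosome(s) absent from the scan: %s",
                    sum(skipped), paste(unknown, collapse = ", ")))
  }
  genes <- genes[!skipped, , drop = FALSE]
  if (nrow(genes) == 0L) return(empty)

  snp_gr <- GenomicRanges::GRanges(
    out$chrom,
    IRanges::IRanges(pmax(out$pos - window_bp, 1L), out$pos + window_bp))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  if (length(hits) == 0L) return(empty)

  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  pos <- out$pos[i]
  gs <- genes$start[j]
  ge <- genes$end[j]
  inside <- pos >= gs & pos <= ge
  dist <- ifelse(inside, 0L,
                 ifelse(pos < gs, gs - pos, pos - ge))
  side <- ifelse(inside, "overlap", ifelse(pos < gs, "downstream", "upstream"))
  data.frame(snp_id = out$id[i], chrom = out$chrom[i], pos = pos,
             gene_id = genes$id[j], gene_start = gs, gene_end = ge,
             distance_bp = as.integer(dist), side = side,
             stringsAsFactors = FALSE)
}

#' Write a scan result as TSV
#'
#' @param scan A `scan_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scan_tsv <- function(scan, path) {
  data.table::fwrite(scan$table, path, sep = "\t", na = "NA")
  invisible(path)
}
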