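#' Construct a genotype panel
#'
#' A genotype panel is the substrate of every analysis in this package: a
#' matrix of biallelic SNP dosages (count of the alternate allele, 0/1/2,
#' `NA` for a missing call) for a set of individuals, each carrying exactly
#' one line (population) label, together with per-SNP map information.
#'
#' @param dosages Numeric matrix, individuals in rows and SNPs in columns.
#'   Entries must be 0, 1, 2 or `NA`. Row and column names are used as
#'   individual and SNP ids when present.
#' @param line_labels Character vector of line names, one per individual.
#' @param snp_meta Data frame with columns `id`, `chrom`, `pos` (1-based),
#'   one row per SNP. If `NULL`, SNPs are placed on a single pseudo-chromosome
#'   `"1"` at 1 kb spacing.
#' @param individual_ids Optional character vector of individual ids;
#'   defaults to the dosage row names or `ind_1 ... ind_n`.
#' @param ancestry Optional numeric matrix (individuals x source lines) of
#'   true ancestry proportions; only simulated panels carry this.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages`, `line_labels`, `snp_meta` and (optionally) `ancestry`.
#' @seealso [simulate_panel()], [read_panel()], [apply_qc()]
#' @export
genotype_panel <- function(dosages, line_labels, snp_meta = NULL,
                           individual_ids = NULL, ancestry = NULL) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (n == 0L || m == 0L) stop("panel must have at least one individual and one SNP")

  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) {
    stop(sprintf("dosages must be 0, 1, 2 or NA; %d offending entries (first: %s)",
                 sum(bad), format(dosages[which(bad)[1]])))
  }

  if (is.null(individual_ids)) {
    individual_ids <- rownames(dosages)
    if (is.null(individual_ids)) individual_ids <- paste0("ind_", seq_len(n))
  }
  if (length(individual_ids) != n) stop("individual_ids length does not match dosage rows")
  if (anyDuplicated(individual_ids)) stop("duplicated individual ids")
  rownames(dosages) <- individual_ids

  line_labels <- as.character(line_labels)
  if (length(line_labels) != n) {
    stop(sprintf("line_labels has length %d but the panel has %d individuals",
                 length(line_labels), n))
  }
  if (anyNA(line_labels) || any(line_labels == "")) {
    stop("every individual must carry exactly one non-empty line label")
  }
  names(line_labels) <- individual_ids

  if (is.null(snp_meta)) {
    ids <- colnames(dosages)
    if (is.null(ids)) ids <- paste0("snp_", seq_len(m))
    snp_meta <- data.frame(id = ids, chrom = "1", pos = 1000L * seq_len(m),
                           stringsAsFactors = FALSE)
  }
  if (!all(c("id", "chrom", "pos") %in% names(snp_meta))) {
    stop("snp_meta needs columns id, chrom, pos")
  }
  if (nrow(snp_meta) != m) stop("snp_meta rows do not match dosage columns")
  if (anyDuplicated(snp_meta$id)) stop("duplicated SNP ids")
  for (ch in unique(snp_meta$chrom)) {
    p <- snp_meta$pos[snp_meta$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop(sprintf("SNP positions must be strictly increasing within chromosome %s", ch))
    }
  }
  colnames(dosages) <- snp_meta$id

  if (!is.null(ancestry)) {
    ancestry <- as.matrix(ancestry)
    if (nrow(ancestry) != n) stop("ancestry rows do not match individuals")
    rownames(ancestry) <- individual_ids
  }

  structure(
    list(dosages = dosages, line_labels = line_labels,
         snp_meta = snp_meta, ancestry = ancestry),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  tab <- table(x$line_labels)
  cat(sprintf("<genotype_panel> %d individuals x %d SNPs, %d lines%s\n",
              nrow(x$dosages), ncol(x$dosages), length(tab),
              if (is.null(x$ancestry)) "" else " (simulated)"))
  cat("  lines:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / SNPs in a panel
#' @param panel A [genotype_panel()].
#' @return Integer count.
#' @export
n_individuals <- function(panel) nrow(panel$dosages)

#' @rdname n_individuals
#' @export
n_snps <- function(panel) ncol(panel$dosages)

#' Line names present in a panel
#' @param panel A [genotype_panel()].
#' @return Character vector of unique line names, in order of first appearance.
#' @export
panel_lines <- function(panel) unique(panel$line_labels)

#' Pooled alternate-allele frequencies
#'
#' Frequencies are estimated from the full panel with all lines pooled,
#' ignoring missing calls.
#'
#' @param panel A [genotype_panel()].
#' @return Numeric vector of per-SNP alternate-allele frequencies.
#' @export
allele_freqs <- function(panel) {
  colMeans(panel$dosages, na.rm = TRUE) / 2
}

#' Subset a panel by individuals and/or SNPs
#'
#' @param panel A [genotype_panel()].
#' @param individuals Logical/integer/character index over individuals.
#' @param snps Logical/integer/character index over SNPs.
#' @return A new [genotype_panel()] with metadata kept in register.
#' @export
subset_panel <- function(panel, individuals = NULL, snps = NULL) {
  if (is.null(individuals)) individuals <- seq_len(n_individuals(panel))
  if (is.null(snps)) snps <- seq_len(n_snps(panel))
  d <- panel$dosages[individuals, snps, drop = FALSE]
  genotype_panel(
    dosages = d,
    line_labels = unname(panel$line_labels[individuals]),
    snp_meta = panel$snp_meta[match(colnames(d), panel$snp_meta$id), , drop = FALSE],
    individual_ids = rownames(d),
    ancestry = if (is.null(panel$ancestry)) NULL else
      panel$ancestry[individuals, , drop = FALSE]
  )
}

# internal: dosage submatrix for one line, with checks
.line_matrix <- function(panel, line) {
  if (!line %in% panel$line_labels) {
    stop(sprintf("unknown line label '%s'", line))
  }
  panel$dosages[panel$line_labels == line, , drop = FALSE]
}
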