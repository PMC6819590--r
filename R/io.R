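#' Read a genotype panel from VCF or a dosage TSV
#'
#' VCF input (`.vcf` / `.vcf.gz`) is parsed with \pkg{vcfR}; only the GT
#' field is used and dosages count the alternate allele. Multi-allelic
#' records are rejected and their count reported in a message. The TSV
#' alternative has a header row of SNP ids, individual ids in the first
#' column, and cells 0/1/2/NA.
#'
#' @param genotype_path Path to a `.vcf`, `.vcf.gz` or `.tsv` file.
#' @param labels_path Path to a two-column TSV (individual_id, line); every
#'   sample in the genotype file must be labelled.
#' @return A [genotype_panel()].
#' @export
read_panel <- function(genotype_path, labels_path) {
  if (!file.exists(genotype_path)) stop("genotype file not found: ", genotype_path)
  if (!file.exists(labels_path)) stop("label file not found: ", labels_path)
  labs <- data.table::fread(labels_path, header = TRUE, sep = "\t",
                            colClasses = "character", data.table = FALSE)
  if (ncol(labs) < 2L) stop("label file needs two columns: individual_id, line")
  lab_map <- stats::setNames(labs[[2]], labs[[1]])

  if (grepl("\\.vcf(\\.gz)?$", genotype_path, ignore.case = TRUE)) {
    panel <- .read_panel_vcf(genotype_path, lab_map)
  } else {
    panel <- .read_panel_tsv(genotype_path, lab_map)
  }
  panel
}

.check_labels <- function(ids, lab_map) {
  missing_ids <- setdiff(ids, names(lab_map))
  if (length(missing_ids) > 0L) {
    stop("samples without a line label: ", paste(missing_ids, collapse = ", "))
  }
  unname(lab_map[ids])
}

.read_panel_vcf <- function(path, lab_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message(sprintf("rejected %d multi-allelic record(s)", sum(multi)))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic records left in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code <- gsub("|", "/", gt, fixed = TRUE)
  dos[code %in% c("0/0")] <- 0
  dos[code %in% c("0/1", "1/0")] <- 1
  dos[code %in% c("1/1")] <- 2
  unknown <- !is.na(code) & !(code %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(unknown)) {
    bad <- which(unknown, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed GT '%s' at record %d, sample %s",
                 gt[unknown][1], bad[1], colnames(gt)[bad[2]]))
  }
  dos <- t(dos)   # individuals x SNPs
  ids <- rownames(dos)
  snp_ids <- fix$ID
  if (anyNA(snp_ids) || any(snp_ids == ".")) {
    snp_ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                      paste0(fix$CHROM, "_", fix$POS), fix$ID)
  }
  genotype_panel(
    dosages = dos,
    line_labels = .check_labels(ids, lab_map),
    snp_meta = data.frame(id = snp_ids, chrom = fix$CHROM,
                          pos = as.integer(fix$POS), stringsAsFactors = FALSE),
    individual_ids = ids
  )
}

.read_panel_tsv <- function(path, lab_map) {
  d <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  ids <- as.character(d[[1]])
  mat <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  bad <- !(mat %in% c(0, 1, 2) | is.na(mat))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed dosage at row %d (individual %s), SNP %s",
                 ij[1] + 1L, ids[ij[1]], colnames(mat)[ij[2]]))
  }
  rownames(mat) <- ids
  genotype_panel(
    dosages = mat,
    line_labels = .check_labels(ids, lab_map),
    individual_ids = ids
  )
}

#' Write a panel as VCF plus label (and ancestry) TSVs
#'
#' Writes a minimal VCF 4.2 with GT-only genotypes; REF/ALT are placeholder
#' alleles `A`/`B` because dosage panels carry no nucleotide information.
#'
#' @param panel A [genotype_panel()].
#' @param vcf_path Output VCF path.
#' @param labels_path Output path for the two-column line-label TSV
#'   (`NULL` to skip).
#' @param ancestry_path Output path for the ancestry-truth TSV (`NULL` to
#'   skip; only written for simulated panels).
#' @return Invisibly, `vcf_path`.
#' @export
write_panel_vcf <- function(panel, vcf_path, labels_path = NULL,
                            ancestry_path = NULL) {
  d <- panel$dosages
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  idx <- !is.na(t(d))
  gt[idx] <- codes[t(d)[idx] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=snpdiv",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t")
  )
  left <- paste(panel$snp_meta$chrom, panel$snp_meta$pos, panel$snp_meta$id,
                "A", "B", ".", ".", ".", "GT", sep = "\t")
  body <- do.call(paste, c(list(left), as.data.frame(gt), list(sep = "\t")))
  writeLines(c(header, body), vcf_path)

  if (!is.null(labels_path)) write_labels_tsv(panel, labels_path)
  if (!is.null(ancestry_path) && !is.null(panel$ancestry)) {
    tr <- truth_report(panel)
    data.table::fwrite(tr$ancestry, ancestry_path, sep = "\t")
  }
  invisible(vcf_path)
}

#' @rdname write_panel_vcf
#' @param path Output TSV path.
#' @export
write_dosage_tsv <- function(panel, path) {
  d <- data.frame(individual_id = rownames(panel$dosages),
                  panel$dosages, check.names = FALSE)
  data.table::fwrite(d, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_vcf
#' @export
write_labels_tsv <- function(panel, path) {
  data.table::fwrite(
    data.frame(individual_id = names(panel$line_labels),
               line = unname(panel$line_labels)),
    path, sep = "\t"
  )
  invisible(path)
}

#' Write and read square labelled matrices (GRM, line kinship)
#'
#' Values are written with 12 significant digits so a write/read round trip
#' is lossless at that precision. The long ("sparse-style") GRM format has
#' columns `id_i`, `id_j`, `value` over the upper triangle including the
#' diagonal.
#'
#' @param m A square numeric matrix with row/column names.
#' @param path Output path.
#' @return Invisibly, `path` (writers) or the matrix (readers).
#' @export
write_square_tsv <- function(m, path) {
  d <- data.frame(id = rownames(m),
                  apply(m, 2, function(x) sprintf("%.12g", x)),
                  check.names = FALSE)
  data.table::fwrite(d, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_square_tsv
#' @export
read_square_tsv <- function(path) {
  d <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d[[1]]
  m
}

#' @rdname write_square_tsv
#' @export
write_grm_long_tsv <- function(m, path) {
  ut <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  d <- data.frame(id_i = rownames(m)[ut[, 1]], id_j = colnames(m)[ut[, 2]],
                  value = sprintf("%.12g", m[ut]))
  data.table::fwrite(d, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a line-kinship matrix from TSV
#'
#' Accepts the square TSV written by [write_square_tsv()]; validates symmetry
#' and returns a [line_kinship()] object usable by the core-set functions.
#'
#' @param path Path to a square kinship TSV with line names.
#' @return A [line_kinship()] object.
#' @export
read_line_kinship <- function(path) {
  m <- read_square_tsv(path)
  colnames(m) <- rownames(m)
  line_kinship(m)
}

#' The published seven-line Dutch Landrace kinship matrix
#'
#' Average genomic kinship coefficients within and between seven Dutch
#' Landrace pig breeding lines (six former lines and the current merged
#' line, TN), as printed in the study this package accompanies: within-line
#' values on the diagonal, between-line values off it, all rounded to three
#' decimals. This matrix is the worked example for the core-set functions.
#'
#' @return A [line_kinship()] over lines CNF, DL, DN, FL, FZ, SB, TN.
#' @seealso [solve_core_set()], [unique_diversity()]
#' @export
landrace_kinship <- function() {
  read_line_kinship(system.file("extdata", "landrace_line_kinship.tsv",
                                package = "snpdiv", mustWork = TRUE))
}
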