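#' Quality control for a genotype panel
#'
#' Applies the three marker QC filters in a fixed order:
#' \enumerate{
#'   \item drop samples whose genotype call rate is not strictly above
#'     `sample_call_rate_min` (default 0.90; a sample at exactly the
#'     threshold is removed);
#'   \item on the surviving samples, drop SNPs whose minor allele frequency,
#'     pooled over all lines, is below `maf_min` (default 0.02);
#'   \item drop SNPs whose call rate on the surviving samples is below
#'     `snp_call_rate_min` (default 1.0, i.e. any SNP with a missing call
#'     goes).
#' }
#' With the defaults the output panel is free of missing genotypes, which
#' the kinship and PCA steps require. MAF is always computed after sample
#' removal. Sample MAF per line is deliberately not used: the filter pools
#' all lines, mirroring QC of one combined dataset (set `maf_pooled = FALSE`
#' to require the MAF threshold in at least one line instead).
#'
#' An intensity-score (GenCall) filter common on array data is accepted as a
#' no-op flag `gencall` and logged as skipped, since dosage panels carry no
#' intensity information.
#'
#' @param panel A [genotype_panel()].
#' @param sample_call_rate_min Keep samples with call rate strictly above
#'   this value.
#' @param maf_min Drop SNPs with pooled MAF strictly below this value.
#' @param snp_call_rate_min Keep SNPs with call rate at least this value.
#' @param maf_pooled Pool lines when computing MAF (default `TRUE`).
#' @param gencall Ignored; recorded in the report as a skipped filter.
#' @return A list with `panel` (the filtered [genotype_panel()]) and
#'   `report` (a `qc_report`).
#' @export
apply_qc <- function(panel, sample_call_rate_min = 0.90, maf_min = 0.02,
                     snp_call_rate_min = 1.0, maf_pooled = TRUE,
                     gencall = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  n_in <- n_individuals(panel)
  m_in <- n_snps(panel)

  # 1. sample call rate (strict: keep iff rate > threshold)
  scr <- rowMeans(!is.na(panel$dosages))
  keep_s <- scr > sample_call_rate_min
  removed_samples <- data.frame(
    individual_id = rownames(panel$dosages)[!keep_s],
    call_rate = unname(scr[!keep_s]),
    reason = if (any(!keep_s)) "sample_call_rate" else character(0),
    stringsAsFactors = FALSE
  )
  if (!any(keep_s)) {
    stop(.qc_all_removed("all samples removed by the call-rate filter",
                         n_in, m_in, removed_samples, NULL))
  }
  d <- panel$dosages[keep_s, , drop = FALSE]

  # 2. MAF on surviving samples
  if (maf_pooled) {
    p <- colMeans(d, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
  } else {
    labs <- panel$line_labels[keep_s]
    per_line <- vapply(unique(labs), function(l) {
      p <- colMeans(d[labs == l, , drop = FALSE], na.rm = TRUE) / 2
      pmin(p, 1 - p)
    }, numeric(ncol(d)))
    maf <- apply(per_line, 1, max, na.rm = TRUE)
  }
  maf[is.nan(maf)] <- 0   # SNPs with no calls left
  fail_maf <- maf < maf_min

  # 3. SNP call rate on surviving samples (only judged for SNPs passing MAF)
  ccr <- colMeans(!is.na(d))
  fail_cr <- !fail_maf & (ccr < snp_call_rate_min)

  removed_snps <- rbind(
    data.frame(id = colnames(d)[fail_maf], reason = rep("maf", sum(fail_maf)),
               stringsAsFactors = FALSE),
    data.frame(id = colnames(d)[fail_cr],
               reason = rep("snp_call_rate", sum(fail_cr)),
               stringsAsFactors = FALSE)
  )
  keep_m <- !(fail_maf | fail_cr)

  report <- structure(
    list(
      n_individuals_in = n_in, n_individuals_out = sum(keep_s),
      n_snps_in = m_in, n_snps_out = sum(keep_m),
      removed_samples = removed_samples,
      removed_snps = removed_snps,
      thresholds = list(sample_call_rate_min = sample_call_rate_min,
                        maf_min = maf_min,
                        snp_call_rate_min = snp_call_rate_min,
                        maf_pooled = maf_pooled),
      skipped_filters = if (is.null(gencall)) character(0) else
        "gencall (no intensity data in a dosage panel)"
    ),
    class = "qc_report"
  )

  if (!any(keep_m)) {
    stop(.qc_all_removed("all SNPs removed by QC", n_in, m_in,
                         removed_samples, report))
  }
  out <- subset_panel(panel, individuals = keep_s, snps = keep_m)
  list(panel = out, report = report)
}

# error condition that still carries the report
.qc_all_removed <- function(msg, n_in, m_in, removed_samples, report) {
  structure(
    class = c("snpdiv_qc_error", "error", "condition"),
    list(message = paste0(msg, " (", n_in, " samples, ", m_in,
                          " SNPs in); inspect the attached qc_report"),
         call = sys.call(-1), report = report)
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  samples: %d in, %d out (%d removed)\n",
              x$n_individuals_in, x$n_individuals_out,
              nrow(x$removed_samples)))
  cat(sprintf("  SNPs:    %d in, %d out (%d maf, %d call rate)\n",
              x$n_snps_in, x$n_snps_out,
              sum(x$removed_snps$reason == "maf"),
              sum(x$removed_snps$reason == "snp_call_rate")))
  th <- x$thresholds
  cat(sprintf("  thresholds: sample call rate > %s, MAF >= %s, SNP call rate >= %s (MAF %s)\n",
              th$sample_call_rate_min, th$maf_min, th$snp_call_rate_min,
              if (th$maf_pooled) "pooled" else "per line"))
  for (s in x$skipped_filters) cat("  skipped:", s, "\n")
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report` from [apply_qc()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
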