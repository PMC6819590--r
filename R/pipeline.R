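#' Run the full diversity analysis pipeline
#'
#' One call takes a panel from raw input (or simulation) to all result
#' files: quality control, genomic relationship matrix, line-kinship matrix,
#' core-set contributions with unique diversity, pairwise Fst, PCA,
#' neighbor-joining tree, and (optionally) a permutation outlier scan with
#' gene annotation.
#'
#' The YAML configuration has the blocks:
#' \describe{
#'   \item{`input`}{either `simulate: {...}` (arguments of [sim_config()],
#'     see [read_sim_config()] for the layout) or `genotypes:` /
#'     `labels:` paths for [read_panel()].}
#'   \item{`qc`}{optional overrides of [apply_qc()] thresholds.}
#'   \item{`tree`}{optional; `distance: fst|kinship` (default fst).}
#'   \item{`scan`}{optional; `pair: [A, B]`, `n_perm`, `q_threshold`,
#'     `seed`, `genes:` annotation path.}
#' }
#'
#' @param config Path to a YAML configuration file, or an equivalent list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results: `panel`, `qc`,
#'   `grm`, `line_kinship`, `core_set`, `unique_diversity`, `fst`, `pca`,
#'   `tree`, and (when configured) `scan`, `gene_hits`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, ...)

  inp <- cfg$input
  if (!is.null(inp$simulate)) {
    sim_cfg <- if (is.character(inp$simulate)) read_sim_config(inp$simulate)
      else .sim_config_from_list(inp$simulate)
    panel <- simulate_panel(sim_cfg)
    write_panel_vcf(panel, path("panel.vcf"), path("line_labels.tsv"),
                    path("ancestry_truth.tsv"))
  } else if (!is.null(inp$genotypes)) {
    panel <- read_panel(inp$genotypes, inp$labels)
  } else {
    stop("config$input must provide either 'simulate' or 'genotypes' + 'labels'")
  }

  qc_args <- cfg$qc %||% list()
  qc <- do.call(apply_qc, c(list(panel = panel), qc_args))
  write_qc_report(qc$report, path("qc_report.json"))
  panel_qc <- qc$panel

  grm <- compute_grm(panel_qc)
  write_square_tsv(grm$values, path("grm.tsv"))
  write_grm_long_tsv(grm$values, path("grm_long.tsv"))

  lk <- aggregate_line_kinship(grm, panel_qc)
  write_square_tsv(lk$values, path("line_kinship.tsv"))

  cs <- suppressWarnings(solve_core_set(lk))
  ud <- if (lk$n_lines >= 2L)
    suppressWarnings(unique_diversity(lk)) else NULL
  write_core_set(cs, ud, tsv_path = path("core_set.tsv"),
                 json_path = path("core_set.json"))

  fst <- all_pairwise_fst(panel_qc)
  write_square_tsv(fst$pairwise, path("fst_pairwise.tsv"))

  pca <- run_pca(panel_qc)
  data.table::fwrite(
    data.frame(individual_id = rownames(pca$scores),
               line = unname(pca$line_labels), pca$scores,
               check.names = FALSE),
    path("pca_scores.tsv"), sep = "\t")

  tree_cfg <- cfg$tree %||% list(distance = "fst")
  dist_source <- if (identical(tree_cfg$distance, "kinship")) lk else fst
  tree <- nj_tree(line_distance(dist_source,
                                method = tree_cfg$distance %||% "fst"))
  write_newick(tree, path("nj_tree.nwk"))

  res <- list(panel = panel_qc, qc = qc$report, grm = grm,
              line_kinship = lk, core_set = cs, unique_diversity = ud,
              fst = fst, pca = pca, tree = tree)

  if (!is.null(cfg$scan)) {
    sc <- cfg$scan
    pair <- unlist(sc$pair)
    if (length(pair) != 2L) stop("config$scan$pair must name two lines")
    scan <- locus_scan(panel_qc, pair[1], pair[2],
                       n_perm = sc$n_perm %||% 999,
                       q_threshold = sc$q_threshold %||% 0.05,
                       seed = sc$seed %||% 1L)
    write_scan_tsv(scan, path("scan.tsv"))
    res$scan <- scan
    if (!is.null(sc$genes)) {
      hits <- annotate_outliers(scan, read_gene_table(sc$genes),
                                window_bp = sc$window_bp %||% 5000)
      data.table::fwrite(hits, path("gene_hits.tsv"), sep = "\t")
      res$gene_hits <- hits
    }
  }
  invisible(res)
}

# sim_config from a nested list as found in the pipeline YAML
.sim_config_from_list <- function(x) {
  pl <- do.call(rbind, lapply(x$parent_lines, function(p) {
    data.frame(name = p$name, size = as.integer(p$size),
               drift_F = as.numeric(p$drift_F), stringsAsFactors = FALSE)
  }))
  ad <- x$admixed_line
  if (!is.null(ad)) {
    ad <- list(name = ad$name, size = as.integer(ad$size),
               dirichlet_alpha = as.numeric(unlist(ad$dirichlet_alpha)))
  }
  sim_config(
    n_snps = x$n_snps, parent_lines = pl, admixed_line = ad,
    ancestral_maf_range = if (is.null(x$ancestral_maf_range)) c(0.01, 0.5)
      else as.numeric(unlist(x$ancestral_maf_range)),
    sample_missing_rate = x$sample_missing_rate %||% 0,
    snp_missing_rate = x$snp_missing_rate %||% 5e-4,
    seed = x$seed %||% 1L
  )
}
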