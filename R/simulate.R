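#' Simulation configuration for drifted lines plus an admixed merged line
#'
#' Describes a Balding-Nichols style simulation: every parent line drifts
#' independently from a common ancestral allele-frequency spectrum, with the
#' amount of drift parameterised by an Fst-like coefficient `drift_F`; an
#' optional merged line is an admixture of the parent lines with
#' individual-specific ancestry proportions drawn from a Dirichlet
#' distribution.
#'
#' @param n_snps Number of SNPs to simulate.
#' @param parent_lines Data frame with columns `name`, `size`, `drift_F`;
#'   one row per parent line. `size >= 1`, `drift_F` strictly in (0, 1).
#' @param admixed_line Optional list with elements `name`, `size` and
#'   `dirichlet_alpha` (positive vector, one entry per parent line, in the
#'   order of `parent_lines$name`). `NULL` for no admixed line.
#' @param ancestral_maf_range Length-2 numeric, the ancestral minor-allele
#'   frequency is drawn uniformly in this range (within (0, 0.5]) and then
#'   reflected about 0.5 with probability one half.
#' @param sample_missing_rate Probability that a call is dropped through the
#'   per-sample missingness process.
#' @param snp_missing_rate Probability that a call is dropped through the
#'   per-SNP missingness process.
#' @param seed Integer seed; the panel is fully reproducible from it.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_panel()], [default_sim_config()]
#' @export
sim_config <- function(n_snps,
                       parent_lines,
                       admixed_line = NULL,
                       ancestral_maf_range = c(0.01, 0.5),
                       sample_missing_rate = 0,
                       snp_missing_rate = 5e-4,
                       seed = 1L) {
  n_snps <- as.integer(n_snps)
  if (is.na(n_snps) || n_snps < 1L) stop("n_snps must be a positive integer")

  parent_lines <- as.data.frame(parent_lines, stringsAsFactors = FALSE)
  if (!all(c("name", "size", "drift_F") %in% names(parent_lines))) {
    stop("parent_lines needs columns name, size, drift_F")
  }
  if (nrow(parent_lines) < 1L) stop("at least one parent line is required")
  if (anyDuplicated(parent_lines$name)) stop("parent line names must be unique")
  if (any(parent_lines$size < 1)) stop("line sizes must be >= 1")
  if (any(parent_lines$drift_F <= 0 | parent_lines$drift_F >= 1)) {
    stop("drift_F must be strictly in (0, 1)")
  }

  if (!is.null(admixed_line)) {
    need <- c("name", "size", "dirichlet_alpha")
    if (!all(need %in% names(admixed_line))) {
      stop("admixed_line needs elements name, size, dirichlet_alpha")
    }
    if (admixed_line$size < 1) stop("admixed line size must be >= 1")
    if (length(admixed_line$dirichlet_alpha) != nrow(parent_lines)) {
      stop("dirichlet_alpha must have one entry per parent line")
    }
    if (any(admixed_line$dirichlet_alpha <= 0)) stop("dirichlet_alpha must be positive")
    if (admixed_line$name %in% parent_lines$name) {
      stop("admixed line name clashes with a parent line")
    }
  }

  if (length(ancestral_maf_range) != 2L ||
      ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      ancestral_maf_range[1] > ancestral_maf_range[2]) {
    stop("ancestral_maf_range must be an increasing pair within (0, 0.5]")
  }
  for (r in c(sample_missing_rate, snp_missing_rate)) {
    if (r < 0 || r >= 1) stop("missingness rates must lie in [0, 1)")
  }

  structure(
    list(n_snps = n_snps, parent_lines = parent_lines,
         admixed_line = admixed_line,
         ancestral_maf_range = as.numeric(ancestral_maf_range),
         sample_missing_rate = sample_missing_rate,
         snp_missing_rate = snp_missing_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default simulation: seven Landrace-style breeding lines
#'
#' Emulates the design of the study this package supports: six parent lines
#' of unequal size (46, 49, 24, 11, 11, 12) with low-to-moderate drift, and a
#' 34-animal merged line admixed from the six parents with individual-varying
#' ancestry. Drift coefficients are chosen so pairwise Fst between parent
#' lines falls in the 0.02-0.10 band; the Dirichlet mean echoes the reported
#' admixture proportions of the merged line (concentration 10, so ancestry
#' varies visibly between individuals).
#'
#' @param n_snps Number of SNPs (default 48000; quality control on the
#'   default missingness and MAF structure trims this towards the low 40k).
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
default_sim_config <- function(n_snps = 48000, seed = 1L) {
  sim_config(
    n_snps = n_snps,
    parent_lines = data.frame(
      name = c("CNF", "DL", "DN", "FL", "FZ", "SB"),
      size = c(46L, 49L, 24L, 11L, 11L, 12L),
      drift_F = c(0.045, 0.04, 0.12, 0.07, 0.08, 0.06)
    ),
    admixed_line = list(
      name = "TN", size = 34L,
      dirichlet_alpha = c(2.05, 1.12, 0.43, 3.50, 1.45, 1.45)
    ),
    seed = seed
  )
}

#' Read a simulation configuration from a YAML file
#'
#' The file is a flat mapping mirroring the arguments of [sim_config()];
#' `parent_lines` is a list of `{name, size, drift_F}` mappings and
#' `admixed_line` a `{name, size, dirichlet_alpha}` mapping.
#'
#' @param path Path to a YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pl <- do.call(rbind, lapply(raw$parent_lines, function(x) {
    data.frame(name = x$name, size = as.integer(x$size),
               drift_F = as.numeric(x$drift_F), stringsAsFactors = FALSE)
  }))
  ad <- raw$admixed_line
  if (!is.null(ad)) {
    ad <- list(name = ad$name, size = as.integer(ad$size),
               dirichlet_alpha = as.numeric(unlist(ad$dirichlet_alpha)))
  }
  sim_config(
    n_snps = raw$n_snps,
    parent_lines = pl,
    admixed_line = ad,
    ancestral_maf_range = if (is.null(raw$ancestral_maf_range)) c(0.01, 0.5)
      else as.numeric(unlist(raw$ancestral_maf_range)),
    sample_missing_rate = raw$sample_missing_rate %||% 0,
    snp_missing_rate = raw$snp_missing_rate %||% 5e-4,
    seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a genotype panel under drift and admixture
#'
#' Ancestral frequencies are drawn uniformly in the configured MAF range and
#' reflected about 0.5 at random. Each parent line's frequency at a SNP is a
#' Balding-Nichols draw, `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so the expected
#' differentiation of the line from the ancestor equals `drift_F`. Admixed
#' individuals receive ancestry proportions `q ~ Dirichlet(alpha)` and a
#' per-individual mixture frequency `sum(q_k * p_k)` at every SNP. Genotypes
#' are Hardy-Weinberg draws (two independent Bernoulli trials); missing calls
#' are injected completely at random at the configured per-sample and per-SNP
#' rates. The true ancestry and line frequencies are recorded for
#' parameter-recovery checks (see [truth_report()]).
#'
#' @param config A [sim_config()].
#' @return A [genotype_panel()] carrying an `ancestry` matrix; true line
#'   frequencies are attached as attribute `"true_freqs"`.
#' @export
simulate_panel <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config object")
  set.seed(config$seed)
  m <- config$n_snps
  pl <- config$parent_lines
  K <- nrow(pl)

  lo <- config$ancestral_maf_range[1]
  hi <- config$ancestral_maf_range[2]
  maf <- stats::runif(m, lo, hi)
  p_anc <- ifelse(stats::runif(m) < 0.5, maf, 1 - maf)
  # guard against degenerate Beta parameters; cannot occur for lo > 0 but the
  # resample keeps the generator total
  while (any(bad <- (p_anc <= 0 | p_anc >= 1))) {
    p_anc[bad] <- stats::runif(sum(bad), lo, hi)
  }

  p_line <- matrix(NA_real_, m, K, dimnames = list(NULL, pl$name))
  for (k in seq_len(K)) {
    f <- pl$drift_F[k]
    p_line[, k] <- stats::rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }

  sizes <- pl$size
  ids <- unlist(lapply(seq_len(K), function(k)
    sprintf("%s_%03d", pl$name[k], seq_len(sizes[k]))))
  labels <- rep(pl$name, sizes)
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    blocks[[k]] <- matrix(
      stats::rbinom(sizes[k] * m, 2L, rep(p_line[, k], each = sizes[k])),
      nrow = sizes[k], ncol = m
    )
  }
  dos <- do.call(rbind, blocks)

  anc <- matrix(0, nrow(dos), K, dimnames = list(NULL, pl$name))
  anc[cbind(seq_len(nrow(dos)), match(labels, pl$name))] <- 1

  ad <- config$admixed_line
  if (!is.null(ad)) {
    g <- matrix(stats::rgamma(ad$size * K, shape = rep(ad$dirichlet_alpha, each = ad$size)),
                nrow = ad$size, ncol = K)
    q <- g / rowSums(g)
    # per-individual mixture frequency at every SNP
    p_mix <- q %*% t(p_line)                       # size x m
    dmix <- matrix(stats::rbinom(length(p_mix), 2L, p_mix),
                   nrow = ad$size, ncol = m)
    dos <- rbind(dos, dmix)
    labels <- c(labels, rep(ad$name, ad$size))
    ids <- c(ids, sprintf("%s_%03d", ad$name, seq_len(ad$size)))
    colnames(q) <- pl$name
    anc <- rbind(anc, q)
  }

  # two independent MCAR missingness processes, union of the masks
  n_tot <- nrow(dos)
  if (config$sample_missing_rate > 0) {
    dos[matrix(stats::runif(n_tot * m) < config$sample_missing_rate, n_tot, m)] <- NA
  }
  if (config$snp_missing_rate > 0) {
    dos[matrix(stats::runif(n_tot * m) < config$snp_missing_rate, n_tot, m)] <- NA
  }

  rownames(dos) <- ids
  snp_meta <- data.frame(id = sprintf("snp_%06d", seq_len(m)),
                         chrom = "1", pos = 1000L * seq_len(m),
                         stringsAsFactors = FALSE)
  panel <- genotype_panel(dos, line_labels = labels, snp_meta = snp_meta,
                          individual_ids = ids, ancestry = anc)
  attr(panel, "true_freqs") <- cbind(ancestral = p_anc, p_line)
  attr(panel, "sim_config") <- config
  panel
}

#' Truth tables of a simulated panel
#'
#' @param panel A panel produced by [simulate_panel()].
#' @return A list with `ancestry` (data frame of per-individual true ancestry
#'   proportions over parent lines) and `line_freqs` (data frame of ancestral
#'   and per-line true allele frequencies, one row per SNP).
#' @export
truth_report <- function(panel) {
  if (is.null(panel$ancestry) || is.null(attr(panel, "true_freqs"))) {
    stop("truth_report() requires a simulated panel; this panel carries no simulation truth")
  }
  freqs <- as.data.frame(attr(panel, "true_freqs"))
  freqs <- cbind(snp = panel$snp_meta$id, freqs)
  anc <- data.frame(individual = rownames(panel$ancestry),
                    line = unname(panel$line_labels),
                    as.data.frame(panel$ancestry),
                    check.names = FALSE, row.names = NULL)
  list(ancestry = anc, line_freqs = freqs)
}
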