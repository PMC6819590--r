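#' Principal component analysis of a genotype panel
#'
#' Dosages are column-centred and left unscaled, then decomposed by singular
#' value decomposition (the behaviour of `prcomp()` with `center = TRUE`,
#' `scale. = FALSE`). Explained variances are the squared singular values
#' over `n - 1`.
#'
#' @param panel A [genotype_panel()] with no missing genotypes and at least
#'   two individuals.
#' @param n_components Number of components to keep (default
#'   `min(n - 1, 10)`).
#' @return An object of class `pca_result`: `scores` (individuals x
#'   components), `explained_variance`, `prop_variance`, `loadings`, and
#'   `line_labels` for plotting.
#' @export
run_pca <- function(panel, n_components = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  x <- panel$dosages
  if (anyNA(x)) stop("panel contains missing genotypes; run apply_qc() first")
  if (nrow(x) < 2L) stop("PCA needs at least two individuals")
  if (all(apply(x, 2, function(col) length(unique(col)) == 1L))) {
    stop("constant dosage matrix: no variance to decompose")
  }
  if (is.null(n_components)) n_components <- min(nrow(x) - 1L, 10L)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  structure(
    list(scores = pc$x[, seq_len(k), drop = FALSE],
         explained_variance = pc$sdev[seq_len(k)]^2,
         prop_variance = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2),
         loadings = pc$rotation[, seq_len(k), drop = FALSE],
         line_labels = panel$line_labels),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$explained_variance))
  cat(sprintf("<pca_result> %d individuals, %d components kept\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$prop_variance[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}
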