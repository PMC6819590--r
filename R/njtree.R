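#' Distance matrix between lines
#'
#' Builds the between-line distance matrix fed to the neighbor-joining tree.
#' The default distance is the pairwise multi-locus Fst matrix (negative
#' estimates clipped to zero); the alternative is one minus the between-line
#' kinship, with the diagonal set to zero.
#'
#' @param x An `fst_result` from [all_pairwise_fst()] or a [line_kinship()].
#' @param method `"fst"` or `"kinship"`.
#' @return Square symmetric non-negative distance matrix, zero diagonal.
#' @export
line_distance <- function(x, method = c("fst", "kinship")) {
  method <- match.arg(method)
  if (method == "fst") {
    if (!inherits(x, "fst_result")) stop("method 'fst' needs an fst_result")
    d <- pmax(x$pairwise, 0)
  } else {
    m <- .as_kinship_matrix(x)
    d <- 1 - m
    diag(d) <- 0
    if (any(d < 0)) {
      warning("negative distances from kinship > 1 clipped to 0")
      d <- pmax(d, 0)
    }
  }
  d
}

#' Neighbor-joining tree of lines
#'
#' Saitou-Nei agglomeration (via \pkg{ape}) on a distance matrix over lines.
#' Negative branch lengths, which the NJ length formulas can produce on
#' non-additive input, are clipped to zero with a warning. Two taxa are
#' handled as a single edge.
#'
#' @param d Square symmetric non-negative distance matrix with zero
#'   diagonal, line names as dimnames.
#' @return An unrooted `phylo` tree (class from \pkg{ape}).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix needs line names")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  n <- nrow(d)
  if (n < 2L) stop("need at least two taxa")
  if (n == 2L) {
    txt <- sprintf("(%s:%.10g,%s:%.10g);", rownames(d)[1], d[1, 2] / 2,
                   rownames(d)[2], d[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    warning(sprintf("%d negative branch length(s) clipped to 0",
                    sum(tr$edge.length < 0)))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
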