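#' Diversity of a weighted set of lines
#'
#' The genetic diversity conserved by a mixture of lines with contribution
#' vector `c` (non-negative, summing to one) is one minus its mean kinship:
#' `g_div = 1 - c' M c`, where `M` is the line-kinship matrix.
#'
#' @param M A [line_kinship()] (or square symmetric matrix with line names).
#' @param contributions Numeric contribution vector summing to 1; if named,
#'   names are matched against the line names.
#' @return The diversity value `1 - c' M c`.
#' @export
set_diversity <- function(M, contributions) {
  M <- .as_kinship_matrix(M)
  cvec <- contributions
  if (!is.null(names(cvec))) {
    if (!setequal(names(cvec), rownames(M))) {
      stop("contribution names do not match the kinship matrix lines")
    }
    cvec <- cvec[rownames(M)]
  }
  if (length(cvec) != nrow(M)) {
    stop(sprintf("contribution vector has length %d but M has %d lines",
                 length(cvec), nrow(M)))
  }
  if (abs(sum(cvec) - 1) > 1e-6) stop("contributions must sum to 1")
  1 - drop(crossprod(cvec, M %*% cvec))
}

.as_kinship_matrix <- function(M) {
  if (inherits(M, "line_kinship")) return(M$values)
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("kinship matrix must be square")
  if (is.null(rownames(M))) rownames(M) <- colnames(M) <- paste0("L", seq_len(nrow(M)))
  if (!isSymmetric(unname(M), tol = 1e-8)) stop("kinship matrix must be symmetric")
  M
}

#' Core-set optimal contributions (Eding's method)
#'
#' Solves for the line contributions that maximise the conserved diversity
#' `1 - c' M c` subject to `sum(c) = 1`. The stationary solution is the
#' closed form `c_max = M^-1 1 / (1' M^-1 1)`, at which the diversity equals
#' `1 / (1' M^-1 1)` subtracted from one. Because the closed form can turn
#' negative, the default adds an iterative non-negativity projection: the
#' line with the most negative contribution is removed (its contribution set
#' to zero) and the reduced system re-solved until all remaining
#' contributions are non-negative. The unconstrained solution is always
#' reported alongside.
#'
#' The closed form is a maximum only when `M` is positive definite; if it is
#' not, a warning is issued and the stationary solution is reported as
#' computed.
#'
#' @param M A [line_kinship()] or square symmetric kinship matrix.
#' @param enforce_nonneg Apply the non-negativity projection (default `TRUE`).
#' @return An object of class `core_set_result` with elements
#'   `contributions` (the returned vector, projected when
#'   `enforce_nonneg = TRUE`), `contributions_unconstrained`,
#'   `mean_kinship` (`c' M c` of the returned vector), `diversity`
#'   (`1 - mean_kinship`), `lines_zeroed`, and `line_names`.
#' @export
solve_core_set <- function(M, enforce_nonneg = TRUE) {
  M <- .as_kinship_matrix(M)
  n <- nrow(M)
  if (n == 0L) stop("empty kinship matrix")
  .check_solvable(M)
  if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    warning("kinship matrix is not positive definite: the stationary contribution vector is not a diversity maximum")
  }

  c_unc <- .core_solve(M)
  cvec <- c_unc
  zeroed <- character(0)
  if (enforce_nonneg && any(c_unc < 0)) {
    active <- rownames(M)
    repeat {
      sub <- .core_solve(M[active, active, drop = FALSE])
      if (all(sub >= -1e-12) || length(active) == 1L) break
      drop_line <- names(which.min(sub))
      zeroed <- c(zeroed, drop_line)
      active <- setdiff(active, drop_line)
    }
    cvec <- stats::setNames(numeric(n), rownames(M))
    cvec[active] <- pmax(sub, 0)
    cvec <- cvec / sum(cvec)
  }
  mk <- drop(crossprod(cvec, M %*% cvec))
  structure(
    list(contributions = cvec,
         contributions_unconstrained = c_unc,
         mean_kinship = mk,
         diversity = 1 - mk,
         lines_zeroed = zeroed,
         line_names = rownames(M)),
    class = "core_set_result"
  )
}

# stationary point of c'Mc on the sum-to-one plane, via a linear system
.core_solve <- function(M) {
  x <- solve(M, rep(1, nrow(M)))
  stats::setNames(x / sum(x), rownames(M))
}

.check_solvable <- function(M) {
  k <- kappa(M, exact = TRUE)
  if (!is.finite(k) || k > 1e12) {
    stop(sprintf(
      "kinship matrix is singular or near-singular (condition number %.3g); consider merging indistinguishable lines or adding a small ridge",
      k))
  }
  invisible(k)
}

#' @export
print.core_set_result <- function(x, ...) {
  cat("<core_set_result>\n")
  cat(sprintf("  diversity 1 - c'Mc = %.4f (mean kinship %.4f)\n",
              x$diversity, x$mean_kinship))
  cat("  contributions (%):\n")
  print(round(100 * x$contributions, 2))
  if (length(x$lines_zeroed) > 0) {
    cat("  zeroed by non-negativity projection:",
        paste(x$lines_zeroed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Unique diversity of each line
#'
#' For every line k the core set is re-solved without that line; the unique
#' diversity of k is the rise in the optimal mean kinship,
#' `unique_k = f(core set without k) - f(core set with all lines)`,
#' i.e. the share of conserved diversity that is lost when the line may not
#' contribute.
#'
#' @param M A [line_kinship()] or square symmetric kinship matrix with at
#'   least two lines.
#' @param enforce_nonneg Use the non-negativity projection in each solve
#'   (default `TRUE`, matching [solve_core_set()]).
#' @return Named numeric vector of unique diversities.
#' @export
unique_diversity <- function(M, enforce_nonneg = TRUE) {
  M <- .as_kinship_matrix(M)
  if (nrow(M) < 2L) stop("unique diversity needs at least two lines")
  full <- suppressWarnings(solve_core_set(M, enforce_nonneg = enforce_nonneg))
  vapply(rownames(M), function(k) {
    sub <- M[rownames(M) != k, colnames(M) != k, drop = FALSE]
    loo <- suppressWarnings(solve_core_set(sub, enforce_nonneg = enforce_nonneg))
    loo$mean_kinship - full$mean_kinship
  }, numeric(1))
}

#' Write core-set results as TSV and JSON
#'
#' @param result A `core_set_result` from [solve_core_set()].
#' @param unique_div Optional named vector from [unique_diversity()].
#' @param tsv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_core_set <- function(result, unique_div = NULL, tsv_path = NULL,
                           json_path = NULL) {
  tab <- data.frame(
    line = result$line_names,
    contribution_pct = 100 * result$contributions[result$line_names],
    contribution_unconstrained_pct =
      100 * result$contributions_unconstrained[result$line_names]
  )
  if (!is.null(unique_div)) tab$unique_diversity <- unique_div[result$line_names]
  if (!is.null(tsv_path)) {
    data.table::fwrite(tab, tsv_path, sep = "\t")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(diversity = result$diversity,
           mean_kinship = result$mean_kinship,
           lines_zeroed = result$lines_zeroed,
           contributions = as.list(result$contributions),
           contributions_unconstrained =
             as.list(result$contributions_unconstrained),
           unique_diversity = if (is.null(unique_div)) NULL else
             as.list(unique_div)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(tsv_path, json_path))
}
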