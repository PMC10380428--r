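#' Gower-center a dissimilarity matrix
#'
#' Converts squared dissimilarities into the centered inner-product matrix
#' `G = J (-1/2 D*D) J`, where `J = I - 11'/n` is the centering projector.
#' Eigendecomposition of `G` yields principal coordinates.
#'
#' @param D a `dist_matrix` or square symmetric matrix.
#' @return A square symmetric matrix whose rows and columns each sum to 0.
#' @export
gower_center <- function(D) {
  d <- as_dist_values(D)
  a <- -0.5 * d * d
  rm <- rowMeans(a)
  g <- a - outer(rm, rep(1, ncol(a))) - outer(rep(1, nrow(a)), rm) + mean(a)
  (g + t(g)) / 2
}

#' Principal coordinates analysis
#'
#' Metric multidimensional scaling: eigendecomposition of the Gower-centered
#' matrix. Axes with eigenvalue above `eig_tolerance * |lambda_1|` are
#' retained; negative eigenvalues (possible for semimetric dissimilarities
#' such as Bray-Curtis) are reported but their axes dropped. No Lingoes or
#' Cailliez correction is applied.
#'
#' @param D a `dist_matrix` or square symmetric matrix (N >= 2 samples).
#' @param eig_tolerance relative eigenvalue tolerance (default `1e-10`).
#' @return An object of class `pcoa_result` with elements `sample_ids`,
#'   `eigenvalues` (all N, descending), `vectors` (orthonormal eigenvectors of
#'   the retained axes), `axis_scores` (`vectors` scaled by `sqrt(lambda)`),
#'   `retained_axes`, `proportion_explained` (per retained axis, relative to
#'   the positive-eigenvalue total).
#' @export
pcoa <- function(D, eig_tolerance = 1e-10) {
  d <- as_dist_values(D)
  ids <- rownames(d)
  g <- gower_center(d)
  ee <- eigen(g, symmetric = TRUE)
  lambda <- ee$values
  keep <- lambda > eig_tolerance * max(abs(lambda), .Machine$double.eps)
  if (!any(keep)) {
    vx_abort("all eigenvalues at or below tolerance: degenerate configuration",
             "volatax_degenerate_error")
  }
  vectors <- ee$vectors[, keep, drop = FALSE]
  lam_keep <- lambda[keep]
  scores <- sweep(vectors, 2L, sqrt(lam_keep), "*")
  rownames(vectors) <- rownames(scores) <- ids
  structure(
    list(sample_ids = ids,
         eigenvalues = lambda,
         vectors = vectors,
         axis_scores = scores,
         retained_axes = sum(keep),
         proportion_explained = lam_keep / sum(lambda[lambda > 0])),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d retained axes (of %d eigenvalues, %d negative)\n",
              length(x$sample_ids), x$retained_axes, length(x$eigenvalues),
              sum(x$eigenvalues < 0)))
  cat("  first eigenvalues:",
      paste(signif(head(x$eigenvalues, 5L), 4L), collapse = ", "), "\n")
  invisible(x)
}

# Gower's add-a-point formula: coordinates of a supplementary sample given its
# squared distances to the N training samples. With training scores
# Y = V diag(sqrt(lambda)), the new point is y* = 1/2 diag(1/sqrt(lambda)) V'
# (b - d2), b = diag(G). Returned on the *orthonormal* (unit-eigenvector)
# scale used for the canonical analysis, i.e. q*_k = y*_k / sqrt(lambda_k).
project_supplementary <- function(pc, g, d2_new) {
  b <- diag(g)
  lam <- pc$eigenvalues[seq_len(pc$retained_axes)]
  drop(crossprod(pc$vectors, b - d2_new)) / (2 * lam)
}
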