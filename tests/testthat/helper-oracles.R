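# Independent oracles: deliberately computed along a different path from the
# package (coordinates + SVD instead of distances + Gower eigendecomposition).

# Canonical variate analysis directly on coordinates: orthonormal basis of the
# centered coordinate column space (SVD), then eigenanalysis of O' H O with H
# the group hat matrix. Squared canonical correlations and nearest-centroid
# allocations are basis-invariant, so they must match CAP on the Euclidean
# distance matrix exactly.
oracle_cva <- function(X, groups, tol = 1e-10) {
  groups <- factor(groups, levels = unique(groups))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  keep <- sv$d > tol * max(sv$d)
  O <- sv$u[, keep, drop = FALSE]
  counts <- as.vector(table(groups))
  B <- rowsum(O, groups) / sqrt(counts)
  ee <- eigen(crossprod(B), symmetric = TRUE)
  a <- min(ncol(O), nlevels(groups) - 1L)
  delta_sq <- ee$values[seq_len(a)]
  scores <- O %*% ee$vectors[, seq_len(a), drop = FALSE]
  centroids <- rowsum(scores, groups) / counts
  d2 <- vapply(seq_len(nrow(centroids)), function(g) {
    rowSums(sweep(scores, 2L, centroids[g, ])^2)
  }, numeric(nrow(scores)))
  list(delta_sq = delta_sq,
       allocation = rownames(centroids)[max.col(-d2, ties.method = "first")])
}

# Doubly centered cross-product of centered coordinates: what gower_center of
# the Euclidean distances must reproduce.
oracle_gower_from_coords <- function(X) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  tcrossprod(Xc)
}
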