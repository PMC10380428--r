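# Canonical analysis of principal coordinates (CAP): constrained ordination =
# PCoA of a chosen dissimilarity, truncated to m axes, followed by canonical
# discriminant analysis against a-priori groups. Quality is measured by
# leave-one-out nearest-centroid allocation and permutation tests.

group_factor <- function(groups, ids = NULL) {
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  else groups <- droplevels(groups)
  if (anyNA(groups)) {
    vx_abort("every sample must carry a group label", "volatax_grouping_error")
  }
  if (nlevels(groups) < 2L) {
    vx_abort("canonical analysis needs at least 2 groups", "volatax_grouping_error")
  }
  if (any(table(groups) == 0L)) {
    vx_abort("empty group in design", "volatax_grouping_error")
  }
  names(groups) <- ids
  groups
}

#' Canonical discriminant step of CAP
#'
#' With `Q` the first `m` orthonormal principal-coordinate axes and `H` the
#' group-membership projection ("hat") matrix, the eigenvalues of `Q'HQ` are
#' the squared canonical correlations `delta^2_k` between the ordination space
#' and the group structure; canonical sample scores are the projections onto
#' the corresponding eigenvectors. The number of canonical axes is
#' `min(m, g - 1)` for `g` groups. Each axis is oriented so the first group's
#' centroid has nonnegative coordinate, making results deterministic.
#'
#' @param pc a [pcoa()] result.
#' @param groups a-priori group label per sample (factor or character, in
#'   sample order).
#' @param m number of principal-coordinate axes to use
#'   (`<= pc$retained_axes`).
#' @return An object of class `cap_result`: `m`, `groups`, `delta_sq`
#'   (descending, each in `[0, 1]`), `trace_statistic` (`sum(delta_sq)`),
#'   `canonical_scores` (samples x axes), `group_centroids`, `allocation`
#'   (resubstitution nearest-centroid assignment), `confusion_resub`, and the
#'   rotation internals used for projecting new samples.
#' @export
canonical_analysis <- function(pc, groups, m) {
  stopifnot(inherits(pc, "pcoa_result"))
  groups <- group_factor(groups, pc$sample_ids)
  n <- length(pc$sample_ids)
  if (length(groups) != n) {
    vx_abort("`groups` length must match the number of samples",
             "volatax_grouping_error")
  }
  if (!is_count(m) || m > pc$retained_axes) {
    vx_abort(sprintf("m must be an integer in [1, %d]", pc$retained_axes),
             "volatax_config_error")
  }
  g <- nlevels(groups)
  a <- min(m, g - 1L)
  Q <- pc$vectors[, seq_len(m), drop = FALSE]
  # Q'HQ without forming H: H = X (X'X)^{-1} X' with X the indicator matrix,
  # so Q'HQ = B' B where B has rows = per-group column sums of Q / sqrt(n_g).
  counts <- as.vector(table(groups))
  B <- rowsum(Q, groups) / sqrt(counts)
  M <- crossprod(B)
  ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
  delta_sq <- pmin(pmax(ee$values[seq_len(a)], 0), 1)
  U <- ee$vectors[, seq_len(a), drop = FALSE]
  scores <- Q %*% U
  centroids <- rowsum(scores, groups) / counts
  # deterministic sign: first group's centroid >= 0 on every axis (falling
  # back to later groups when its coordinate is numerically zero)
  for (k in seq_len(a)) {
    ref <- centroids[, k][abs(centroids[, k]) > 1e-12][1L]
    if (!is.na(ref) && ref < 0) {
      U[, k] <- -U[, k]
      scores[, k] <- -scores[, k]
      centroids[, k] <- -centroids[, k]
    }
  }
  allocation <- allocate_nearest(scores, centroids)
  confusion <- table(truth = groups,
                     allocated = factor(allocation, levels = levels(groups)))
  structure(
    list(sample_ids = pc$sample_ids, m = m, groups = groups,
         delta_sq = delta_sq, trace_statistic = sum(delta_sq),
         canonical_scores = scores, group_centroids = centroids,
         allocation = allocation, confusion_resub = confusion,
         rotation = U, loo_error_pct = NULL, confusion = NULL,
         p_trace = NULL, p_first = NULL),
    class = "cap_result"
  )
}

allocate_nearest <- function(scores, centroids) {
  d2 <- outer(rowSums(scores^2), rep(1, nrow(centroids))) -
    2 * scores %*% t(centroids) +
    outer(rep(1, nrow(scores)), rowSums(centroids^2))
  rownames(centroids)[max.col(-d2, ties.method = "first")]
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf("<cap_result> m = %d, %d groups, %d canonical axes\n",
              x$m, nlevels(x$groups), length(x$delta_sq)))
  cat("  delta^2:", paste(signif(x$delta_sq, 4L), collapse = ", "), "\n")
  if (!is.null(x$loo_error_pct)) {
    cat(sprintf("  LOO misclassification: %.4g%%\n", x$loo_error_pct))
  }
  if (!is.null(x$p_trace)) {
    cat(sprintf("  p(trace) = %.4g, p(delta^2_1) = %.4g\n", x$p_trace, x$p_first))
  }
  invisible(x)
}

#' Leave-one-out misclassification of a CAP model
#'
#' For each sample in turn: drop it, recompute the centering, PCoA and
#' canonical axes on the remaining N - 1 samples, place the left-out sample
#' into the reduced canonical space through Gower's supplementary-point
#' projection of its squared dissimilarities, and allocate it to the nearest
#' group centroid (Euclidean distance in canonical space). No information
#' about the left-out sample leaks into the axes it is judged against.
#'
#' @param D a `dist_matrix` or square symmetric matrix.
#' @param groups a-priori group label per sample.
#' @param m number of principal-coordinate axes; folds whose reduced
#'   ordination supports fewer axes use the reduced number (with a message).
#' @param eig_tolerance passed to [pcoa()].
#' @return A list with `loo_error_pct` (100 * misallocated / N), `confusion`
#'   (truth x allocation table), `allocation` (character vector).
#' @export
loo_misclassification <- function(D, groups, m, eig_tolerance = 1e-10) {
  d <- as_dist_values(D)
  n <- nrow(d)
  groups <- group_factor(groups, rownames(d))
  if (length(groups) != n) {
    vx_abort("`groups` length must match the distance matrix",
             "volatax_grouping_error")
  }
  allocation <- character(n)
  reduced_folds <- 0L
  for (i in seq_len(n)) {
    d_sub <- d[-i, -i, drop = FALSE]
    grp_sub <- droplevels(groups[-i])
    if (nlevels(grp_sub) < 2L) {
      # left-out sample's group structure collapsed; allocate to the single
      # remaining group (necessarily a misallocation unless labels match)
      allocation[i] <- levels(grp_sub)[1L]
      next
    }
    pc_sub <- pcoa(d_sub, eig_tolerance)
    m_i <- min(m, pc_sub$retained_axes)
    if (m_i < m) reduced_folds <- reduced_folds + 1L
    cap_sub <- canonical_analysis(pc_sub, grp_sub, m_i)
    g_sub <- gower_center(d_sub)
    q_new <- project_supplementary(pc_sub, g_sub, d[i, -i]^2)
    c_new <- crossprod(cap_sub$rotation, q_new[seq_len(m_i)])
    d2 <- colSums((t(cap_sub$group_centroids) - drop(c_new))^2)
    allocation[i] <- rownames(cap_sub$group_centroids)[which.min(d2)]
  }
  if (reduced_folds > 0L) {
    message(sprintf("LOO: m reduced in %d fold(s) with insufficient axes",
                    reduced_folds))
  }
  confusion <- table(truth = groups,
                     allocated = factor(allocation, levels = levels(groups)))
  list(loo_error_pct = 100 * sum(allocation != as.character(groups)) / n,
       confusion = confusion, allocation = allocation)
}

#' Choose the number of principal-coordinate axes m
#'
#' Scans `m` from `g - 1` to `m_max` (capped by the retained axes and by
#' `N - g`) and returns the value minimising the leave-one-out
#' misclassification error; ties are broken toward the smallest `m`.
#'
#' @param D a `dist_matrix` or square symmetric matrix.
#' @param groups a-priori group label per sample.
#' @param m_max upper bound on the scan (default 20).
#' @param pc optional precomputed [pcoa()] of `D`.
#' @return A list with `m`, `loo_error_pct` at that `m`, and the scanned
#'   `candidates`/`errors`.
#' @export
select_m <- function(D, groups, m_max = 20L, pc = NULL) {
  d <- as_dist_values(D)
  groups <- group_factor(groups, rownames(d))
  g <- nlevels(groups)
  n <- nrow(d)
  pc <- pc %||% pcoa(d)
  upper <- min(m_max, pc$retained_axes, n - g)
  lower <- g - 1L
  if (upper < lower) {
    # fall back to the largest feasible m when the design is too small for
    # the canonical minimum g - 1
    if (upper < 1L) {
      vx_abort("no feasible m: too few samples/axes for the group design",
               "volatax_degenerate_error")
    }
    lower <- upper
  }
  candidates <- seq(lower, upper)
  errors <- vapply(candidates, function(m) {
    loo_misclassification(d, groups, m)$loo_error_pct
  }, numeric(1L))
  best <- candidates[which.min(errors)]  # which.min takes the first = smallest m
  list(m = best, loo_error_pct = min(errors),
       candidates = candidates, errors = errors)
}

#' Permutation test for group separation
#'
#' Group labels are permuted `n_perm` times; for each permutation the trace
#' statistic `sum(delta^2)` and the first squared canonical correlation are
#' recomputed on the fixed ordination. P-values use the standard
#' `(1 + #{perm >= observed}) / (1 + n_perm)` estimator.
#'
#' @param D a `dist_matrix` or square symmetric matrix.
#' @param groups a-priori group label per sample.
#' @param m number of principal-coordinate axes.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed; results are reproducible given the seed.
#' @return A list with `p_trace`, `p_first`, `observed_trace`,
#'   `observed_first`.
#' @export
permutation_test <- function(D, groups, m, n_perm = 999L, seed = 1L) {
  if (!is_count(n_perm) || n_perm < 99L) {
    vx_abort("n_perm must be an integer >= 99", "volatax_config_error")
  }
  d <- as_dist_values(D)
  groups <- group_factor(groups, rownames(d))
  pc <- pcoa(d)
  m <- min(m, pc$retained_axes)
  stat <- function(grp) {
    cap <- canonical_analysis(pc, grp, m)
    c(cap$trace_statistic, cap$delta_sq[1L])
  }
  obs <- stat(groups)
  perm <- with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(b) stat(sample(groups)), numeric(2L))
  })
  list(p_trace = (1 + sum(perm[1L, ] >= obs[1L])) / (1 + n_perm),
       p_first = (1 + sum(perm[2L, ] >= obs[2L])) / (1 + n_perm),
       observed_trace = obs[1L], observed_first = obs[2L])
}

#' Compound-vector overlay
#'
#' Each compound is represented by a vector `(X, Y)` of Pearson correlations
#' between its (transformed) abundances and the first two canonical axes; the
#' squared vector length `X^2 + Y^2` measures how strongly the compound drives
#' the displayed separation. Longer vectors are the more diagnostic compounds.
#'
#' @param pt the transformed [peak_table()] the distance matrix was computed
#'   from (columns must match the CAP sample order).
#' @param cap a [canonical_analysis()] result.
#' @param sig_cutoff per-round significance threshold.
#' @param sig_mode `"len2"` flags `X^2 + Y^2 > sig_cutoff`; `"abs_r"` flags
#'   `|X| > sig_cutoff` or `|Y| > sig_cutoff`.
#' @return A `data.frame` (class `compound_vectors`) with columns
#'   `compound_id`, `x`, `y`, `len2`, `significant`.
#' @export
compound_vectors <- function(pt, cap, sig_cutoff = 0.29,
                             sig_mode = c("len2", "abs_r")) {
  stopifnot(inherits(pt, "peak_table"), inherits(cap, "cap_result"))
  sig_mode <- match.arg(sig_mode)
  if (!identical(pt$sample_ids, cap$sample_ids)) {
    vx_abort("peak table columns do not match CAP sample order",
             "volatax_mapping_error")
  }
  scores <- cap$canonical_scores
  ax1 <- scores[, 1L]
  if (ncol(scores) >= 2L) {
    ax2 <- scores[, 2L]
  } else {
    vx_warn("only one canonical axis: Y coordinates set to 0")
    ax2 <- NULL
  }
  m <- pt$abundances
  sds <- apply(m, 1L, stats::sd)
  zero_var <- sds == 0
  x <- y <- numeric(nrow(m))
  if (any(!zero_var)) {
    x[!zero_var] <- apply(m[!zero_var, , drop = FALSE], 1L, cor, y = ax1)
    if (!is.null(ax2)) {
      y[!zero_var] <- apply(m[!zero_var, , drop = FALSE], 1L, cor, y = ax2)
    }
  }
  if (any(zero_var)) {
    vx_warn(sprintf("%d zero-variance compound(s) assigned vector (0, 0)",
                    sum(zero_var)))
  }
  len2 <- x^2 + y^2
  significant <- switch(sig_mode,
    len2 = len2 > sig_cutoff,
    abs_r = abs(x) > sig_cutoff | abs(y) > sig_cutoff
  )
  out <- data.frame(compound_id = pt$compound_ids, x = x, y = y, len2 = len2,
                    significant = significant, stringsAsFactors = FALSE)
  class(out) <- c("compound_vectors", "data.frame")
  out
}

#' Scatter/vector plot of a CAP round
#'
#' Minimal base-graphics helper: canonical sample scores coloured by group,
#' with significant compound vectors overlaid as arrows (scaled to the plot).
#' Cosmetic only; untested.
#'
#' @param x a `cap_result`.
#' @param vectors optional [compound_vectors()] output.
#' @param ... passed to [plot()].
#' @export
plot.cap_result <- function(x, vectors = NULL, ...) {
  s <- x$canonical_scores
  if (ncol(s) < 2L) s <- cbind(s, 0)
  grp <- as.integer(x$groups)
  graphics::plot(s[, 1L], s[, 2L], col = grp, pch = grp,
                 xlab = "Canonical axis 1", ylab = "Canonical axis 2", ...)
  graphics::legend("topright", legend = levels(x$groups),
                   col = seq_len(nlevels(x$groups)),
                   pch = seq_len(nlevels(x$groups)), cex = 0.8)
  if (!is.null(vectors)) {
    sig <- vectors[vectors$significant, , drop = FALSE]
    if (nrow(sig) > 0L) {
      sc <- max(abs(s)) / max(sqrt(sig$len2))
      graphics::arrows(0, 0, sig$x * sc, sig$y * sc, length = 0.05, col = "grey40")
      graphics::text(sig$x * sc, sig$y * sc, sig$compound_id, cex = 0.6, pos = 3)
    }
  }
  invisible(x)
}
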