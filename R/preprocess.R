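#' Average technical replicates
#'
#' Collapses the sample columns of a peak table to one column per
#' `replicate_group` by the arithmetic mean, mirroring standard GC-MS practice
#' of analysing the mean of n >= 3 technical replicates. A warning is emitted
#' for any group with fewer than 3 replicates.
#'
#' @param pt a [peak_table()].
#' @param st a [sample_table()] covering every sample column of `pt`.
#' @return A `peak_table` whose columns are replicate groups, in order of
#'   first appearance in `pt`.
#' @export
average_technical_replicates <- function(pt, st) {
  stopifnot(inherits(pt, "peak_table"))
  st <- sample_table(as.data.frame(st))
  missing <- setdiff(pt$sample_ids, st$sample_id)
  if (length(missing) > 0L) {
    vx_abort(sprintf("sample(s) absent from metadata: %s",
                     paste(missing, collapse = ", ")), "volatax_mapping_error")
  }
  rep_of <- setNames(st$replicate_group, st$sample_id)[pt$sample_ids]
  groups <- unique(rep_of)
  sizes <- table(rep_of)[groups]
  if (any(sizes < 3L)) {
    vx_warn(sprintf("replicate group(s) with fewer than 3 replicates: %s",
                    paste(groups[sizes < 3L], collapse = ", ")),
            "volatax_replicate_warning")
  }
  out <- vapply(groups, function(g) {
    rowMeans(pt$abundances[, rep_of == g, drop = FALSE])
  }, numeric(nrow(pt$abundances)))
  out <- matrix(out, nrow = nrow(pt$abundances),
                dimnames = list(pt$compound_ids, groups))
  peak_table(out, annotations = pt$annotations)
}

#' Transform abundances
#'
#' @param pt a [peak_table()].
#' @param mode one of:
#'   * `"relative"`: divide each sample column by its sum (compositional
#'     profile); an all-zero column stays zero with a warning.
#'   * `"log1p"`: natural log of (1 + abundance).
#'   * `"presence"`: 1 if abundance exceeds `detection_threshold`, else 0.
#'   * `"none"`: identity.
#' @param detection_threshold intensity above which a compound counts as
#'   detected under `"presence"` (default 0: any nonzero peak).
#' @return A transformed `peak_table`.
#' @export
transform_abundances <- function(pt, mode = c("relative", "log1p", "presence", "none"),
                                 detection_threshold = 0) {
  stopifnot(inherits(pt, "peak_table"))
  mode <- match.arg(mode)
  m <- pt$abundances
  m <- switch(mode,
    relative = {
      cs <- colSums(m)
      if (any(cs == 0)) {
        vx_warn(sprintf("all-zero sample column(s) left unscaled: %s",
                        paste(colnames(m)[cs == 0], collapse = ", ")))
      }
      sweep(m, 2L, ifelse(cs == 0, 1, cs), "/")
    },
    log1p = log1p(m),
    presence = (m > detection_threshold) + 0,
    none = m
  )
  peak_table(m, annotations = pt$annotations)
}

#' Drop compounds absent from every retained sample
#'
#' After groups are peeled off between cascade rounds, compounds private to the
#' removed groups become all-zero rows and are removed; the pruned ids are
#' reported in a message.
#'
#' @param pt a [peak_table()].
#' @return A `peak_table` without all-zero compound rows.
#' @export
prune_compounds <- function(pt) {
  stopifnot(inherits(pt, "peak_table"))
  keep <- rowSums(pt$abundances) > 0
  if (all(keep)) return(pt)
  if (!any(keep)) {
    vx_abort("pruning removed every compound (all rows zero)",
             "volatax_degenerate_error")
  }
  message(sprintf("pruned %d all-zero compound(s): %s", sum(!keep),
                  paste(pt$compound_ids[!keep], collapse = ", ")))
  subset_peak_table(pt, compounds = which(keep))
}

#' Compute a sample-by-sample dissimilarity matrix
#'
#' @param pt a [peak_table()] (columns are the entities to compare, typically
#'   replicate-group means after [transform_abundances()]).
#' @param metric one of:
#'   * `"bray-curtis"`: `sum(|u - v|) / sum(u + v)` (0 when both profiles are
#'     all-zero); bounded in `[0, 1]` for nonnegative data.
#'   * `"euclidean"`: standard L2 distance.
#'   * `"jaccard-binary"`: `1 - |intersection| / |union|` of the presence
#'     (value > 0) sets; 0 for two empty profiles.
#' @return A `dist_matrix`: list with `sample_ids`, `values` (square symmetric
#'   matrix, zero diagonal) and `metric`.
#' @export
compute_distance_matrix <- function(pt, metric = c("bray-curtis", "euclidean",
                                                   "jaccard-binary")) {
  stopifnot(inherits(pt, "peak_table"))
  if (is.character(metric) && length(metric) == 1L &&
      !metric %in% c("bray-curtis", "euclidean", "jaccard-binary")) {
    vx_abort(sprintf(
      "unknown metric '%s'; valid metrics: bray-curtis, euclidean, jaccard-binary",
      metric), "volatax_config_error")
  }
  metric <- match.arg(metric)
  m <- pt$abundances
  n <- ncol(m)
  if (n < 2L) vx_abort("need at least 2 samples for a distance matrix",
                       "volatax_degenerate_error")
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      u <- m[, i]; v <- m[, j]
      d[i, j] <- d[j, i] <- switch(metric,
        "bray-curtis" = {
          tot <- sum(u + v)
          if (tot == 0) 0 else sum(abs(u - v)) / tot
        },
        "euclidean" = sqrt(sum((u - v)^2)),
        "jaccard-binary" = {
          pu <- u > 0; pv <- v > 0
          un <- sum(pu | pv)
          if (un == 0) 0 else 1 - sum(pu & pv) / un
        })
    }
  }
  dist_matrix(d, metric)
}

#' Construct a dist_matrix from a square symmetric matrix
#'
#' @param values square numeric matrix with sample ids as dimnames.
#' @param metric metric label.
#' @return A `dist_matrix` object.
#' @export
dist_matrix <- function(values, metric = "unknown") {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    vx_abort("distance values must form a square matrix", "volatax_format_error")
  }
  if (max(abs(values - t(values))) > 1e-12 * max(1, max(abs(values)))) {
    vx_abort("distance matrix is not symmetric", "volatax_invariant_error")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (any(values < 0)) {
    vx_abort("distances must be nonnegative", "volatax_invariant_error")
  }
  ids <- rownames(values) %||% as.character(seq_len(nrow(values)))
  dimnames(values) <- list(ids, ids)
  structure(list(sample_ids = ids, values = values, metric = metric),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d samples, metric = %s\n",
              length(x$sample_ids), x$metric))
  invisible(x)
}

as_dist_values <- function(D) {
  if (inherits(D, "dist_matrix")) return(D$values)
  if (inherits(D, "dist")) return(as.matrix(D))
  if (is.matrix(D)) return(dist_matrix(D)$values)
  vx_abort("expected a dist_matrix or square matrix", "volatax_format_error")
}
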