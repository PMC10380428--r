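#' Construct a peak table
#'
#' A peak table holds a nonnegative compound-by-sample abundance matrix from an
#' aligned, annotated GC-MS headspace experiment, together with optional
#' per-compound annotations (retention time in minutes, compound name,
#' compound class such as alkane/terpene/ester).
#'
#' @param abundances numeric matrix, one row per compound, one column per
#'   sample; dimnames give compound and sample ids (or pass `compound_ids` /
#'   `sample_ids`).
#' @param annotations optional `data.frame` with column `compound_id` and any
#'   of `rt_min`, `name`, `class`; rows are matched to compounds by id.
#' @param compound_ids,sample_ids character vectors overriding the dimnames.
#' @return An object of class `peak_table` with elements `abundances`
#'   (named matrix), `compound_ids`, `sample_ids`, `annotations`.
#' @examples
#' m <- matrix(c(1, 0, 2, 3, 0, 5), nrow = 2,
#'             dimnames = list(c("cmp1", "cmp2"), c("s1", "s2", "s3")))
#' pt <- peak_table(m)
#' dim(pt)
#' @export
peak_table <- function(abundances, annotations = NULL,
                       compound_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(abundances) || !is.numeric(abundances)) {
    vx_abort("`abundances` must be a numeric matrix", "volatax_format_error")
  }
  compound_ids <- compound_ids %||% rownames(abundances)
  sample_ids <- sample_ids %||% colnames(abundances)
  if (is.null(compound_ids) || is.null(sample_ids)) {
    vx_abort("compound and sample ids are required (dimnames or arguments)",
             "volatax_format_error")
  }
  dimnames(abundances) <- list(compound_ids, sample_ids)
  if (anyDuplicated(compound_ids)) {
    dup <- unique(compound_ids[duplicated(compound_ids)])
    vx_abort(sprintf("duplicate compound ids: %s", paste(dup, collapse = ", ")),
             "volatax_format_error", duplicates = dup)
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    vx_abort(sprintf("duplicate sample ids: %s", paste(dup, collapse = ", ")),
             "volatax_format_error", duplicates = dup)
  }
  if (anyNA(abundances)) {
    vx_abort("abundances contain missing values; impute to 0 before construction",
             "volatax_format_error")
  }
  if (any(abundances < 0)) {
    idx <- which(abundances < 0, arr.ind = TRUE)[1L, ]
    vx_abort(sprintf("negative abundance at compound '%s', sample '%s'",
                     compound_ids[idx[1L]], sample_ids[idx[2L]]),
             "volatax_format_error")
  }
  if (!is.null(annotations)) {
    if (!is.data.frame(annotations) || is.null(annotations$compound_id)) {
      vx_abort("`annotations` must be a data.frame with a compound_id column",
               "volatax_format_error")
    }
    annotations <- annotations[match(compound_ids, annotations$compound_id), ,
                               drop = FALSE]
    annotations$compound_id <- compound_ids
    rownames(annotations) <- NULL
    if (!is.null(annotations$rt_min) &&
        any(annotations$rt_min < 0, na.rm = TRUE)) {
      vx_abort("retention times must be >= 0", "volatax_format_error")
    }
  }
  structure(
    list(abundances = abundances, compound_ids = compound_ids,
         sample_ids = sample_ids, annotations = annotations),
    class = "peak_table"
  )
}

#' @export
dim.peak_table <- function(x) dim(x$abundances)

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d compounds x %d samples\n",
              nrow(x$abundances), ncol(x$abundances)))
  if (!is.null(x$annotations) && !is.null(x$annotations$class)) {
    cl <- table(x$annotations$class, useNA = "no")
    cat("  classes:", paste(sprintf("%s (%d)", names(cl), cl), collapse = ", "),
        "\n")
  }
  cat("  samples:", paste(head(x$sample_ids, 6L), collapse = ", "),
      if (length(x$sample_ids) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Subset a peak table by compounds and/or samples
#'
#' @param pt a [peak_table()].
#' @param compounds,samples character vectors of ids (or logical/integer
#'   indices) to retain; `NULL` keeps everything. Order follows the selection.
#' @return A `peak_table`.
#' @export
subset_peak_table <- function(pt, compounds = NULL, samples = NULL) {
  stopifnot(inherits(pt, "peak_table"))
  m <- pt$abundances
  if (!is.null(compounds)) m <- m[compounds, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  ann <- pt$annotations
  if (!is.null(ann)) ann <- ann[match(rownames(m), ann$compound_id), , drop = FALSE]
  peak_table(m, annotations = ann)
}

# File layout: first column compound_id, then any of rt_min/name/class,
# then one numeric column per sample.
ANNOTATION_COLS <- c("rt_min", "name", "class")

#' Read a wide-format peak table from CSV/TSV
#'
#' The canonical interchange format is a wide table: one row per compound,
#' first column `compound_id`, optional annotation columns (`rt_min`, `name`,
#' `class`), then one numeric column per sample. Blank or missing abundance
#' cells are treated as not-detected and set to 0 (with a warning counting the
#' imputations) -- the downstream analysis is driven by compound
#' presence/absence, so an unrecorded peak means absence, never an unknown.
#'
#' @param path path to a CSV (or TSV if the extension is `.tsv`/`.txt`) file
#'   with a header row, UTF-8 encoded.
#' @param layout currently only `"wide"`.
#' @param sep field separator; guessed from the extension by default.
#' @return A [peak_table()]; compound and sample order equals file order.
#' @export
read_peak_table <- function(path, layout = "wide", sep = NULL) {
  layout <- match.arg(layout, "wide")
  if (!file.exists(path)) {
    vx_abort(sprintf("peak table file not found: %s", path), "volatax_io_error")
  }
  sep <- sep %||% (if (grepl("\\.(tsv|txt)$", path)) "\t" else ",")
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) {
    vx_abort("peak table has no sample columns", "volatax_format_error")
  }
  names(df)[1L] <- "compound_id"
  ann_cols <- intersect(ANNOTATION_COLS, names(df))
  sample_cols <- setdiff(names(df), c("compound_id", ann_cols))
  if (length(sample_cols) == 0L) {
    vx_abort("peak table has no sample columns", "volatax_format_error")
  }
  m <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
    if (any(is.na(m) & df[, sample_cols] != "" & !is.na(df[, sample_cols]))) {
      vx_abort("non-numeric abundance values in sample columns",
               "volatax_format_error")
    }
  }
  n_missing <- sum(is.na(m))
  if (n_missing > 0L) {
    m[is.na(m)] <- 0
    vx_warn(sprintf("%d missing abundance cell(s) imputed as 0 (not detected)",
                    n_missing), "volatax_imputation_warning")
  }
  rownames(m) <- df$compound_id
  ann <- NULL
  if (length(ann_cols) > 0L) {
    ann <- df[, c("compound_id", ann_cols), drop = FALSE]
  }
  peak_table(m, annotations = ann)
}

#' Write a peak table to CSV
#'
#' Inverse of [read_peak_table()]; round-trips are lossless.
#'
#' @param pt a [peak_table()].
#' @param path output file path.
#' @export
write_peak_table <- function(pt, path) {
  stopifnot(inherits(pt, "peak_table"))
  df <- data.frame(compound_id = pt$compound_ids, stringsAsFactors = FALSE)
  if (!is.null(pt$annotations)) {
    for (col in intersect(ANNOTATION_COLS, names(pt$annotations))) {
      df[[col]] <- pt$annotations[[col]]
    }
  }
  df <- cbind(df, as.data.frame(pt$abundances, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a CSV with header columns `sample_id`, `replicate_group`,
#' `group_label` and optionally `is_outgroup`, `host_plant`, `location`.
#' `replicate_group` labels technical replicates of one biological sample;
#' `group_label` is the a-priori group (species, host plant, or outgroup
#' device) supplied to the discriminant analysis.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `sample_table`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) {
    vx_abort(sprintf("metadata file not found: %s", path), "volatax_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  sample_table(df)
}

#' Construct/validate a sample table
#'
#' @param df data.frame with columns `sample_id`, `replicate_group`,
#'   `group_label` and optionally `is_outgroup` (logical, default `FALSE`),
#'   `host_plant`, `location`.
#' @return `df` with class `sample_table` prepended.
#' @export
sample_table <- function(df) {
  required <- c("sample_id", "replicate_group", "group_label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    vx_abort(sprintf("metadata missing required column(s): %s",
                     paste(missing, collapse = ", ")), "volatax_format_error")
  }
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    vx_abort(sprintf("duplicate sample ids in metadata: %s",
                     paste(dup, collapse = ", ")), "volatax_format_error")
  }
  if (is.null(df$is_outgroup)) df$is_outgroup <- FALSE
  df$is_outgroup <- as.logical(df$is_outgroup)
  # One replicate group = one biological sample = one a-priori group.
  split_groups <- tapply(df$group_label, df$replicate_group,
                         function(x) length(unique(x)))
  bad <- names(split_groups)[split_groups > 1L]
  if (length(bad) > 0L) {
    vx_abort(sprintf(
      "replicate group(s) span multiple group labels: %s",
      paste(bad, collapse = ", ")), "volatax_consistency_error", groups = bad)
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Write sample metadata to CSV
#' @param st a [sample_table()].
#' @param path output file path.
#' @export
write_sample_metadata <- function(st, path) {
  write.csv(as.data.frame(st), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
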