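# JSON serialisation of dichotomous keys and cascade plans. Both carry an
# explicit schema_version for forward compatibility.

KEY_SCHEMA_VERSION <- 1L
PLAN_SCHEMA_VERSION <- 1L

#' Write a dichotomous key to JSON
#'
#' Schema: `{schema_version, taxa: [{taxon, eb: [...], seb: [...],
#' provenance: [...]}]}`. Round-trips through [read_key()] are lossless.
#'
#' @param key a `dichotomous_key`.
#' @param path output file path.
#' @export
write_key <- function(key, path) {
  validate_key(key)
  payload <- list(
    schema_version = KEY_SCHEMA_VERSION,
    taxa = lapply(unname(key$taxa), function(e) {
      list(taxon = e$taxon, eb = as.list(e$eb), seb = as.list(e$seb),
           provenance = as.list(e$provenance))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a dichotomous key from JSON
#'
#' @param path JSON file written by [write_key()].
#' @return A `dichotomous_key`.
#' @export
read_key <- function(path) {
  if (!file.exists(path)) {
    vx_abort(sprintf("key file not found: %s", path), "volatax_io_error")
  }
  payload <- jsonlite::read_json(path)
  ver <- payload$schema_version
  if (is.null(ver) || ver != KEY_SCHEMA_VERSION) {
    vx_abort(sprintf("unsupported key schema_version '%s' (expected %d)",
                     ver %||% "<missing>", KEY_SCHEMA_VERSION),
             "volatax_schema_error")
  }
  taxa <- lapply(payload$taxa, function(e) {
    list(taxon = e$taxon,
         eb = as.character(unlist(e$eb)),
         seb = as.character(unlist(e$seb)),
         provenance = as.character(unlist(e$provenance)))
  })
  names(taxa) <- vapply(taxa, `[[`, character(1L), "taxon")
  key <- structure(list(schema_version = as.integer(ver), taxa = taxa),
                   class = "dichotomous_key")
  validate_key(key)
  key
}

#' Read a cascade plan from JSON
#'
#' Schema: `{schema_version, defaults: {transform, metric, presence_threshold,
#' n_perm, seed, m_max}, rounds: [{round_id, grouping_variable, groups,
#' outgroup, thresholds: {sig_cutoff, sig_mode, eb_low, eb_high, seb_low},
#' groups_to_remove_after, m}]}`. Omitted per-round fields inherit from
#' `defaults`.
#'
#' @param path JSON file path.
#' @return A `cascade_plan` (see [cascade_plan()]).
#' @export
read_cascade_plan <- function(path) {
  if (!file.exists(path)) {
    vx_abort(sprintf("cascade plan file not found: %s", path),
             "volatax_io_error")
  }
  payload <- jsonlite::read_json(path)
  ver <- payload$schema_version %||% PLAN_SCHEMA_VERSION
  if (ver != PLAN_SCHEMA_VERSION) {
    vx_abort(sprintf("unsupported plan schema_version '%s'", ver),
             "volatax_schema_error")
  }
  defaults <- payload$defaults %||% list()
  rounds <- lapply(payload$rounds, function(r) {
    thr <- r$thresholds %||% list()
    round_plan(
      round_id = r$round_id,
      grouping_variable = r$grouping_variable %||% "group_label",
      groups = as.character(unlist(r$groups)),
      outgroup = if (is.null(r$outgroup)) NULL else as.character(r$outgroup),
      groups_to_remove_after = as.character(unlist(r$groups_to_remove_after)),
      thresholds = do.call(biomarker_thresholds, thr),
      m = r$m,
      seed = r$seed
    )
  })
  cascade_plan(rounds, defaults = defaults)
}

#' Write a cascade plan to JSON
#'
#' @param plan a [cascade_plan()].
#' @param path output file path.
#' @export
write_cascade_plan <- function(plan, path) {
  stopifnot(inherits(plan, "cascade_plan"))
  payload <- list(
    schema_version = PLAN_SCHEMA_VERSION,
    defaults = plan$defaults,
    rounds = lapply(plan$rounds, function(r) {
      list(round_id = r$round_id,
           grouping_variable = r$grouping_variable,
           groups = as.list(r$groups),
           outgroup = r$outgroup,
           thresholds = unclass(r$thresholds),
           groups_to_remove_after = as.list(r$groups_to_remove_after),
           m = r$m, seed = r$seed)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
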