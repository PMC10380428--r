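# Hierarchical rounds of CAP: run a round against the current a-priori
# groups, collect biomarkers of the groups the plan peels off, prune compounds
# that became all-zero, and repeat. Which groups leave after each round is a
# plan decision (the scatter is read by the analyst), not an automatic one;
# suggest_group_removals() offers candidates but never decides.

#' Define one cascade round
#'
#' @param round_id unique round label (e.g. `"A1"`).
#' @param groups a-priori group labels analysed in this round (>= 3, the
#'   minimum CAP design; an outgroup added purely to reach 3 counts).
#' @param grouping_variable where group labels come from: `"group_label"`
#'   (species rounds), `"host_plant"` (host rounds on one species' samples),
#'   or `"custom"` (labels supplied via `group_map`).
#' @param outgroup optional label of a group used only to satisfy the
#'   three-group minimum; its biomarkers never enter the key.
#' @param groups_to_remove_after groups peeled off after this round; their
#'   biomarker sets become key entries (must be a subset of `groups`).
#' @param transform,metric,presence_threshold preprocessing settings (see
#'   [transform_abundances()], [compute_distance_matrix()]); `NULL` inherits
#'   the plan defaults.
#' @param thresholds a [biomarker_thresholds()] object (per-round significance
#'   cutoff and EB/SEB bounds).
#' @param m fixed number of ordination axes, or `NULL` to choose by
#'   [select_m()].
#' @param m_max cap for the [select_m()] scan.
#' @param n_perm permutations for the significance test (0 disables).
#' @param seed per-round seed; `NULL` derives one from the plan seed.
#' @param group_map named character vector (sample_id -> group) used when
#'   `grouping_variable = "custom"`.
#' @return A `round_plan` list.
#' @export
round_plan <- function(round_id, groups,
                       grouping_variable = c("group_label", "host_plant", "custom"),
                       outgroup = NULL, groups_to_remove_after = character(0),
                       transform = NULL, metric = NULL,
                       presence_threshold = NULL,
                       thresholds = biomarker_thresholds(),
                       m = NULL, m_max = NULL, n_perm = NULL, seed = NULL,
                       group_map = NULL) {
  grouping_variable <- match.arg(grouping_variable)
  groups <- as.character(groups)
  if (!is_string(round_id)) {
    vx_abort("round_id must be a single string", "volatax_config_error")
  }
  if (length(unique(groups)) < 3L) {
    vx_abort(sprintf(
      "round '%s' has %d a-priori group(s); CAP requires at least three (add an outgroup if needed)",
      round_id, length(unique(groups))), "volatax_plan_error")
  }
  bad <- setdiff(groups_to_remove_after, groups)
  if (length(bad) > 0L) {
    vx_abort(sprintf("round '%s': groups_to_remove_after not in groups: %s",
                     round_id, paste(bad, collapse = ", ")),
             "volatax_plan_error")
  }
  if (!is.null(outgroup) && !outgroup %in% groups) {
    vx_abort(sprintf("round '%s': outgroup '%s' not among groups",
                     round_id, outgroup), "volatax_plan_error")
  }
  structure(list(round_id = round_id, grouping_variable = grouping_variable,
                 groups = groups, outgroup = outgroup,
                 groups_to_remove_after = as.character(groups_to_remove_after),
                 transform = transform, metric = metric,
                 presence_threshold = presence_threshold,
                 thresholds = thresholds, m = m, m_max = m_max,
                 n_perm = n_perm, seed = seed, group_map = group_map),
            class = "round_plan")
}

#' Assemble a cascade plan
#'
#' @param rounds list of [round_plan()] objects with unique ids.
#' @param defaults global defaults: `transform` ("relative"), `metric`
#'   ("bray-curtis"), `presence_threshold` (0), `n_perm` (199), `m_max` (20),
#'   `seed` (1).
#' @return A `cascade_plan`.
#' @export
cascade_plan <- function(rounds, defaults = list()) {
  if (length(rounds) < 1L) {
    vx_abort("a cascade plan needs at least one round", "volatax_plan_error")
  }
  ids <- vapply(rounds, `[[`, character(1L), "round_id")
  if (anyDuplicated(ids)) {
    vx_abort("round ids must be unique", "volatax_plan_error")
  }
  base <- list(transform = "relative", metric = "bray-curtis",
               presence_threshold = 0, n_perm = 199L, m_max = 20L, seed = 1L)
  defaults <- modifyList(base, defaults[!vapply(defaults, is.null, logical(1L))])
  structure(list(defaults = defaults, rounds = rounds), class = "cascade_plan")
}

#' @export
print.cascade_plan <- function(x, ...) {
  cat(sprintf("<cascade_plan> %d round(s); defaults: %s + %s\n",
              length(x$rounds), x$defaults$transform, x$defaults$metric))
  for (r in x$rounds) {
    cat(sprintf("  %s [%s]: %s -> remove {%s}\n", r$round_id,
                r$grouping_variable, paste(r$groups, collapse = ", "),
                paste(r$groups_to_remove_after, collapse = ", ")))
  }
  invisible(x)
}

sample_groups <- function(st, plan) {
  grp <- switch(plan$grouping_variable,
    group_label = st$group_label,
    host_plant = {
      if (is.null(st$host_plant)) {
        vx_abort(sprintf("round '%s' groups by host_plant but metadata has no host_plant column",
                         plan$round_id), "volatax_plan_error")
      }
      st$host_plant
    },
    custom = {
      if (is.null(plan$group_map)) {
        vx_abort(sprintf("round '%s' uses custom grouping but no group_map",
                         plan$round_id), "volatax_plan_error")
      }
      unname(plan$group_map[st$sample_id])
    })
  as.character(grp)
}

#' Run one CAP round
#'
#' Executes the full per-round pipeline: subset samples to the plan's groups,
#' prune all-zero compounds, average technical replicates, transform, compute
#' the dissimilarity matrix, choose m (unless fixed), run the canonical
#' analysis with leave-one-out allocation and a permutation test, overlay
#' compound vectors, and classify significant vectors into per-group EB/SEB
#' sets. Deterministic given the round seed.
#'
#' @param pt a [peak_table()] (technical-replicate columns).
#' @param st a [sample_table()].
#' @param plan a [round_plan()].
#' @param defaults plan defaults (see [cascade_plan()]); used for settings the
#'   round leaves `NULL`.
#' @return An object of class `round_result`: `round_id`, `plan`, `cap` (a
#'   `cap_result` augmented with `loo_error_pct`, `confusion`, `p_trace`,
#'   `p_first`), `vectors`, `biomarkers` (per-group `biomarker_set`s,
#'   outgroup excluded), `groups` (per analysed replicate-group), and the
#'   transformed table the vectors were computed on.
#' @export
run_round <- function(pt, st, plan, defaults = cascade_plan(list(plan))$defaults) {
  stopifnot(inherits(plan, "round_plan"))
  plan <- local({
    p <- plan
    p$transform <- p$transform %||% defaults$transform
    p$metric <- p$metric %||% defaults$metric
    p$presence_threshold <- p$presence_threshold %||% defaults$presence_threshold
    p$n_perm <- p$n_perm %||% defaults$n_perm
    p$m_max <- p$m_max %||% defaults$m_max
    p$seed <- p$seed %||% as.integer(defaults$seed)
    p
  })
  st <- sample_table(as.data.frame(st))
  grp_all <- sample_groups(st, plan)
  keep <- grp_all %in% plan$groups & st$sample_id %in% pt$sample_ids
  present <- unique(grp_all[keep])
  missing <- setdiff(plan$groups, present)
  if (length(missing) > 0L) {
    vx_abort(sprintf("round '%s': plan group(s) absent from data: %s",
                     plan$round_id, paste(missing, collapse = ", ")),
             "volatax_plan_error", round_id = plan$round_id)
  }
  st_sub <- st[keep, , drop = FALSE]
  pt_sub <- subset_peak_table(pt, samples = match(st_sub$sample_id, pt$sample_ids))
  pt_sub <- prune_compounds(pt_sub)
  pt_avg <- average_technical_replicates(pt_sub, st_sub)
  grp_by_rep <- vapply(pt_avg$sample_ids, function(rg) {
    unique(sample_groups(st_sub, plan)[st_sub$replicate_group == rg])[1L]
  }, character(1L))
  pt_tr <- transform_abundances(pt_avg, plan$transform,
                                detection_threshold = plan$presence_threshold)
  D <- compute_distance_matrix(pt_tr, plan$metric)
  pc <- pcoa(D)
  m <- plan$m %||% select_m(D, grp_by_rep, m_max = plan$m_max, pc = pc)$m
  cap <- canonical_analysis(pc, grp_by_rep, m)
  loo <- loo_misclassification(D, grp_by_rep, m)
  cap$loo_error_pct <- loo$loo_error_pct
  cap$confusion <- loo$confusion
  cap$loo_allocation <- loo$allocation
  if (!is.null(plan$n_perm) && plan$n_perm > 0L) {
    perm <- permutation_test(D, grp_by_rep, m, n_perm = plan$n_perm,
                             seed = plan$seed)
    cap$p_trace <- perm$p_trace
    cap$p_first <- perm$p_first
  }
  vectors <- compound_vectors(pt_tr, cap, sig_cutoff = plan$thresholds$sig_cutoff,
                              sig_mode = plan$thresholds$sig_mode)
  biomarkers <- classify_biomarkers(vectors, plan$thresholds, cap,
                                    round_id = plan$round_id)
  outgroups <- union(plan$outgroup,
                     unique(st_sub$group_label[st_sub$is_outgroup]))
  biomarkers <- biomarkers[setdiff(names(biomarkers), outgroups)]
  structure(
    list(round_id = plan$round_id, plan = plan, cap = cap, vectors = vectors,
         biomarkers = biomarkers, groups = grp_by_rep,
         distance = D, transformed = pt_tr,
         n_compounds = nrow(pt_tr$abundances),
         n_samples = ncol(pt_sub$abundances)),
    class = "round_result")
}

#' @export
print.round_result <- function(x, ...) {
  cat(sprintf("<round_result> %s: %d compounds, %d samples (%d replicate groups), m = %d\n",
              x$round_id, x$n_compounds, x$n_samples, length(x$groups), x$cap$m))
  cat(sprintf("  LOO error %.4g%%; %d significant vector(s)\n",
              x$cap$loo_error_pct, sum(x$vectors$significant)))
  invisible(x)
}

#' Run a full CAP cascade and build the dichotomous key
#'
#' Rounds run in order; after each, samples of `groups_to_remove_after` are
#' dropped and compounds that became all-zero are pruned. The biomarker sets
#' of the groups removed after each round -- plus, for the final round, all
#' remaining non-outgroup groups -- become the taxa of the dichotomous key.
#'
#' @param pt a [peak_table()].
#' @param st a [sample_table()].
#' @param plan a [cascade_plan()].
#' @return An object of class `cascade_result`: `rounds` (list of
#'   `round_result`), `key` (a `dichotomous_key`), `plan`.
#' @export
run_cascade <- function(pt, st, plan) {
  stopifnot(inherits(plan, "cascade_plan"))
  st <- sample_table(as.data.frame(st))
  cur_pt <- pt
  cur_st <- st
  results <- list()
  key_sets <- list()
  n_rounds <- length(plan$rounds)
  for (i in seq_len(n_rounds)) {
    rp <- plan$rounds[[i]]
    if (is.null(rp$seed)) {
      rp$seed <- as.integer((as.numeric(plan$defaults$seed) * 1009 + i) %% 2147483647)
    }
    res <- tryCatch(
      run_round(cur_pt, cur_st, rp, defaults = plan$defaults),
      volatax_error = function(e) {
        vx_abort(sprintf("cascade halted at round '%s': %s",
                         rp$round_id, conditionMessage(e)),
                 "volatax_cascade_error", round_id = rp$round_id)
      })
    results[[rp$round_id]] <- res
    separated <- rp$groups_to_remove_after
    if (i == n_rounds) {
      outgroups <- union(rp$outgroup,
                         unique(cur_st$group_label[cur_st$is_outgroup]))
      separated <- union(separated,
                         setdiff(unique(res$groups), outgroups))
    }
    key_sets[[rp$round_id]] <-
      res$biomarkers[intersect(names(res$biomarkers), separated)]
    if (length(rp$groups_to_remove_after) > 0L && i < n_rounds) {
      grp_all <- sample_groups(cur_st, rp)
      drop_samples <- cur_st$sample_id[grp_all %in% rp$groups_to_remove_after]
      cur_st <- sample_table(as.data.frame(cur_st)[
        !cur_st$sample_id %in% drop_samples, , drop = FALSE])
      keep_cols <- setdiff(cur_pt$sample_ids, drop_samples)
      cur_pt <- prune_compounds(subset_peak_table(cur_pt, samples = keep_cols))
    }
  }
  key <- build_key(key_sets)
  structure(list(rounds = results, key = key, plan = plan,
                 final_pt = cur_pt, final_st = cur_st),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result> %d round(s), key with %d taxa\n",
              length(x$rounds), length(x$key$taxa)))
  for (r in x$rounds) {
    cat(sprintf("  %s: %d compounds, LOO %.4g%%\n", r$round_id,
                r$n_compounds, r$cap$loo_error_pct))
  }
  invisible(x)
}

#' Suggest groups that a round cleanly separated
#'
#' Advisory helper: groups with zero leave-one-out misallocations whose
#' centroid silhouette in canonical space exceeds `min_silhouette` are
#' candidates for removal in the next round. The plan still decides.
#'
#' @param res a [run_round()] result.
#' @param min_silhouette minimum mean silhouette width (default 0.5).
#' @return Character vector of group labels.
#' @export
suggest_group_removals <- function(res, min_silhouette = 0.5) {
  stopifnot(inherits(res, "round_result"))
  cap <- res$cap
  conf <- cap$confusion
  perfect <- rownames(conf)[diag(conf) == rowSums(conf)]
  scores <- cap$canonical_scores
  grp <- as.character(cap$groups)
  sil_of <- function(gl) {
    idx <- which(grp == gl)
    mean(vapply(idx, function(i) {
      d <- sqrt(colSums((t(scores) - scores[i, ])^2))
      a <- mean(d[setdiff(idx, i)])
      b <- min(vapply(setdiff(unique(grp), gl), function(o) {
        mean(d[grp == o])
      }, numeric(1L)))
      if (length(idx) == 1L) 1 else (b - a) / max(a, b)
    }, numeric(1L)))
  }
  perfect[vapply(perfect, sil_of, numeric(1L)) > min_silhouette]
}

#' Round report as a JSON-ready list / file
#'
#' @param res a [run_round()] result.
#' @param path optional output path; when given, the report is written as JSON.
#' @return The report list, invisibly when written.
#' @export
round_report <- function(res, path = NULL) {
  stopifnot(inherits(res, "round_result"))
  cap <- res$cap
  rep <- list(
    round_id = res$round_id,
    m = cap$m,
    delta_sq = as.numeric(cap$delta_sq),
    trace = cap$trace_statistic,
    loo_error_pct = cap$loo_error_pct,
    confusion = as.data.frame.matrix(unclass(cap$confusion)),
    p_trace = cap$p_trace,
    p_first = cap$p_first,
    n_compounds = res$n_compounds,
    n_samples = res$n_samples,
    seed = res$plan$seed,
    settings = list(transform = res$plan$transform, metric = res$plan$metric,
                    presence_threshold = res$plan$presence_threshold,
                    sig_cutoff = res$plan$thresholds$sig_cutoff,
                    sig_mode = res$plan$thresholds$sig_mode),
    vectors = res$vectors[, c("compound_id", "x", "y", "len2", "significant")]
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows", digits = NA)
    return(invisible(rep))
  }
  rep
}

#' Identify an unknown volatile profile
#'
#' Two reference modes:
#' * a `dichotomous_key`: the unknown's technical replicates are averaged, the
#'   presence set extracted, and [match_profile()] applied;
#' * a reference dataset `list(pt = , st = , plan = )` (plan optional): the
#'   unknown is appended as its own a-priori group over the union compound
#'   vocabulary and one CAP round is run; the unknown is reported as a
#'   distinct (new) group when every one of its samples is allocated back to
#'   it under leave-one-out, and its EB/SEB pattern is extracted.
#'
#' @param unknown_pt a [peak_table()] of the unknown's replicates.
#' @param reference a `dichotomous_key` or `list(pt, st, plan)`.
#' @param presence_threshold detection threshold for the presence profile.
#' @param eb_accept,margin passed to [match_profile()] (key mode).
#' @param ... further arguments passed to [round_plan()] (CAP mode), e.g.
#'   `thresholds`.
#' @return Key mode: an `identification`. CAP mode: a list of class
#'   `unknown_cap_report` with `status` (`"unidentified"` when the unknown
#'   separates as its own group, otherwise `"ambiguous"`), `separates`,
#'   `allocation`, `biomarkers` (the unknown group's `biomarker_set`), and the
#'   underlying `round_result`.
#' @export
identify_unknown <- function(unknown_pt, reference, presence_threshold = 0,
                             eb_accept = 1.0, margin = 0.25, ...) {
  stopifnot(inherits(unknown_pt, "peak_table"))
  if (inherits(reference, "dichotomous_key")) {
    avg <- rowMeans(unknown_pt$abundances)
    profile <- unknown_pt$compound_ids[avg > presence_threshold]
    return(match_profile(profile, reference, eb_accept = eb_accept,
                         margin = margin))
  }
  if (!is.list(reference) || is.null(reference$pt) || is.null(reference$st)) {
    vx_abort("reference must be a dichotomous_key or list(pt, st, plan)",
             "volatax_config_error")
  }
  ref_pt <- reference$pt
  ref_st <- sample_table(as.data.frame(reference$st))
  shared <- intersect(ref_pt$compound_ids, unknown_pt$compound_ids)
  if (length(shared) == 0L) {
    vx_abort("unknown shares no compounds with the reference vocabulary",
             "volatax_vocabulary_error")
  }
  all_cmp <- union(ref_pt$compound_ids, unknown_pt$compound_ids)
  expand <- function(p) {
    m <- matrix(0, length(all_cmp), ncol(p$abundances),
                dimnames = list(all_cmp, p$sample_ids))
    m[p$compound_ids, ] <- p$abundances
    m
  }
  comb <- peak_table(cbind(expand(ref_pt), expand(unknown_pt)))
  # unknown replicates enter as individual samples so leave-one-out can
  # still place each against the remaining ones
  unk_st <- data.frame(sample_id = unknown_pt$sample_ids,
                       replicate_group = unknown_pt$sample_ids,
                       group_label = "unknown",
                       is_outgroup = FALSE, stringsAsFactors = FALSE)
  comb_st <- sample_table(rbind(
    as.data.frame(ref_st)[, c("sample_id", "replicate_group", "group_label",
                              "is_outgroup")],
    unk_st))
  defaults <- if (!is.null(reference$plan)) reference$plan$defaults
              else cascade_plan(list(round_plan("unknown-check",
                                                c("a", "b", "c"))))$defaults
  rp <- round_plan("unknown-check",
                   groups = c(unique(comb_st$group_label)),
                   groups_to_remove_after = character(0), ...)
  res <- run_round(comb, comb_st, rp, defaults = defaults)
  unk_idx <- res$groups == "unknown"
  separates <- all(res$cap$loo_allocation[unk_idx] == "unknown") &&
    sum(unk_idx) > 0L
  bm <- classify_biomarkers(res$vectors, rp$thresholds, res$cap,
                            round_id = "unknown-check")[["unknown"]]
  structure(list(status = if (separates) "unidentified" else "ambiguous",
                 separates = separates,
                 allocation = res$cap$loo_allocation[unk_idx],
                 biomarkers = bm, round = res),
            class = "unknown_cap_report")
}

#' @export
print.unknown_cap_report <- function(x, ...) {
  cat(sprintf("<unknown_cap_report> status: %s (separates as own group: %s)\n",
              x$status, x$separates))
  if (!is.null(x$biomarkers)) print(x$biomarkers)
  invisible(x)
}
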