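# Synthetic multi-species volatilome generator. The stated world: a panel of
# species each carrying a small set of always-present, high-abundance marker
# compounds (planted EBs), probabilistic semi-specific markers (planted SEBs),
# one abundant compound shared by most-but-not-all species (the alarm-pheromone
# analogue whose absence drives the first cascade split), optional host-plant
# compounds, a bed of widely shared background volatiles, log-normal
# biological and technical noise, and class-wise detection dropout.

#' Describe a synthetic volatile dataset
#'
#' Defaults emulate the shape of the motivating study: 10 species, 81 aligned
#' compounds, 2 planted essential + 2 planted semi-essential markers per
#' species, a shared marker carried by 8 of the 10 species, and 3 technical
#' replicates per biological sample. Marker abundances are drawn log-normally
#' with median 100x the background median; dropout models the detection limit
#' that makes presence/absence informative.
#'
#' @param n_species number of species.
#' @param n_compounds total aligned compounds (must accommodate all planted
#'   markers).
#' @param n_eb,n_seb planted essential / semi-essential markers per species
#'   (EB compounds are disjoint across species by construction).
#' @param p_seb per-biological-sample presence probability of a planted SEB in
#'   its own species (0.5: present in about half the samples, which is what
#'   makes it semi- rather than fully diagnostic).
#' @param n_shared_species how many species carry the shared marker (the two
#'   (or `n_species - n_shared_species`) lacking species mirror the
#'   alarm-pheromone-free split).
#' @param n_biological biological samples per species (default 6: the
#'   emulated study's opening round analysed 63 replicate-averaged samples
#'   across 10 species).
#' @param n_replicates technical replicates per biological sample (>= 3 in
#'   the emulated protocol).
#' @param marker_median,background_median log-normal medians (arbitrary
#'   intensity units) for marker and background compounds.
#' @param sigma_bio,sigma_tech log-scale standard deviations of the
#'   per-biological-sample draw and the per-replicate multiplier.
#' @param dropout probability that a detected compound is lost in a given
#'   replicate (applied after the abundance draw); scalar, or a named vector
#'   by role (`eb`, `seb`, `shared`, `host`, `background`).
#' @param p_background per-(compound, biological sample) presence probability
#'   of a background compound.
#' @param host_plants optional named character vector species -> host plant;
#'   each host gets one diagnostic host-linked compound shared by all species
#'   on that host.
#' @param seed integer seed.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_species = 10L, n_compounds = 81L,
                           n_eb = 2L, n_seb = 2L, p_seb = 0.5,
                           n_shared_species = 8L,
                           n_biological = 6L, n_replicates = 3L,
                           marker_median = 100, background_median = 1,
                           sigma_bio = 0.6, sigma_tech = 0.25,
                           dropout = 0.05, p_background = 0.9,
                           host_plants = NULL, seed = 20230701L) {
  for (v in list(n_species, n_compounds, n_biological, n_replicates)) {
    if (!is_count(v)) vx_abort("counts must be positive integers",
                               "volatax_spec_error")
  }
  if (n_eb < 1L || n_seb < 0L) {
    vx_abort("need n_eb >= 1 and n_seb >= 0", "volatax_spec_error")
  }
  if (any(c(p_seb, p_background, unlist(dropout)) < 0) ||
      any(c(p_seb, p_background, unlist(dropout)) > 1)) {
    vx_abort("probabilities must lie in [0, 1]", "volatax_spec_error")
  }
  if (n_shared_species > n_species) {
    vx_abort("n_shared_species cannot exceed n_species", "volatax_spec_error")
  }
  n_host <- if (is.null(host_plants)) 0L else length(unique(host_plants))
  n_planted <- n_species * (n_eb + n_seb) + (n_shared_species > 0L) + n_host
  if (n_planted > n_compounds) {
    vx_abort(sprintf(
      "spec plants %d marker compounds but n_compounds = %d",
      n_planted, n_compounds), "volatax_spec_error")
  }
  structure(
    list(n_species = as.integer(n_species), n_compounds = as.integer(n_compounds),
         n_eb = as.integer(n_eb), n_seb = as.integer(n_seb), p_seb = p_seb,
         n_shared_species = as.integer(n_shared_species),
         n_biological = as.integer(n_biological),
         n_replicates = as.integer(n_replicates),
         marker_median = marker_median, background_median = background_median,
         sigma_bio = sigma_bio, sigma_tech = sigma_tech,
         dropout = dropout, p_background = p_background,
         host_plants = host_plants, seed = as.integer(seed)),
    class = "synthetic_spec")
}

dropout_for <- function(dropout, role) {
  if (length(dropout) == 1L && is.null(names(dropout))) return(as.numeric(dropout))
  as.numeric(dropout[[role]] %||% 0.05)
}

COMPOUND_CLASSES <- c("alkane", "terpene", "ester", "aldehyde", "benzenoid",
                      "ketone", "alcohol")

#' Generate a synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `pt` (a [peak_table()], one column per technical
#'   replicate), `st` (a [sample_table()]), and `truth` (class
#'   `ground_truth`): planted `eb`/`seb` compound ids per species,
#'   `shared_compound`, `shared_species`, `host_map`. Reproducible given
#'   `spec$seed`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_dataset_impl(spec))
}

generate_dataset_impl <- function(spec) {
  species <- sprintf("sp%02d", seq_len(spec$n_species))
  cmp_ids <- sprintf("cmp%03d", seq_len(spec$n_compounds))
  # planted marker layout at the head of the compound list; roles recorded in
  # the annotation table's class column are cosmetic (EBs skew alkane/aldehyde,
  # SEBs skew terpene/ester, as in real volatilome keys)
  idx <- 0L
  take <- function(k) {
    out <- cmp_ids[idx + seq_len(k)]
    idx <<- idx + k
    out
  }
  eb <- setNames(lapply(species, function(s) take(spec$n_eb)), species)
  seb <- setNames(lapply(species, function(s) take(spec$n_seb)), species)
  shared_compound <- if (spec$n_shared_species > 0L) take(1L) else character(0)
  shared_species <- species[seq_len(spec$n_shared_species)]
  host_map <- spec$host_plants
  host_compound <- character(0)
  if (!is.null(host_map)) {
    hosts <- unique(host_map)
    host_compound <- setNames(take(length(hosts)), hosts)
  }
  background <- cmp_ids[seq(idx + 1L, length.out = spec$n_compounds - idx)]

  role <- setNames(rep("background", spec$n_compounds), cmp_ids)
  role[unlist(eb)] <- "eb"
  role[unlist(seb)] <- "seb"
  role[shared_compound] <- "shared"
  role[host_compound] <- "host"

  st <- do.call(rbind, lapply(species, function(s) {
    do.call(rbind, lapply(seq_len(spec$n_biological), function(b) {
      data.frame(
        sample_id = sprintf("%s_b%d_r%d", s, b, seq_len(spec$n_replicates)),
        replicate_group = sprintf("%s_b%d", s, b),
        group_label = s,
        is_outgroup = FALSE,
        host_plant = if (is.null(host_map)) NA_character_ else unname(host_map[s]),
        stringsAsFactors = FALSE)
    }))
  }))

  n_samples <- nrow(st)
  m <- matrix(0, spec$n_compounds, n_samples,
              dimnames = list(cmp_ids, st$sample_id))
  bio_ids <- unique(st$replicate_group)
  bio_species <- setNames(
    st$group_label[match(bio_ids, st$replicate_group)], bio_ids)

  present_in_bio <- function(cmp, s) {
    switch(role[[cmp]],
      eb = cmp %in% eb[[s]],
      seb = if (cmp %in% seb[[s]]) runif(1L) < spec$p_seb else FALSE,
      shared = s %in% shared_species,
      host = !is.null(host_map) && !is.na(host_map[s]) &&
        identical(unname(host_compound[host_map[s]]), cmp),
      background = runif(1L) < spec$p_background)
  }
  median_of <- function(cmp) {
    if (role[[cmp]] == "background") spec$background_median else spec$marker_median
  }

  for (bg in bio_ids) {
    s <- bio_species[[bg]]
    cols <- which(st$replicate_group == bg)
    for (cmp in cmp_ids) {
      if (!present_in_bio(cmp, s)) next
      base <- median_of(cmp) * exp(rnorm(1L, 0, spec$sigma_bio))
      vals <- base * exp(rnorm(length(cols), 0, spec$sigma_tech))
      drop <- runif(length(cols)) < dropout_for(spec$dropout, role[[cmp]])
      vals[drop] <- 0
      m[cmp, cols] <- vals
    }
  }
  # honour the ground-truth invariant: every planted EB is observed in at
  # least one replicate of its species even under unlucky dropout
  for (s in species) {
    for (cmp in eb[[s]]) {
      cols <- which(st$group_label == s)
      if (all(m[cmp, cols] == 0)) {
        m[cmp, cols[1L]] <- median_of(cmp)
      }
    }
  }

  class_pool <- c(eb = "alkane", seb = "terpene", shared = "sesquiterpene",
                  host = "benzenoid")
  ann <- data.frame(
    compound_id = cmp_ids,
    name = ifelse(role == "shared", "beta-farnesene-like (synthetic)",
                  paste0("synthetic-", cmp_ids)),
    class = ifelse(role == "background",
                   rep_len(COMPOUND_CLASSES, spec$n_compounds),
                   class_pool[role]),
    stringsAsFactors = FALSE)

  truth <- structure(
    list(eb = eb, seb = seb,
         shared_compound = shared_compound, shared_species = shared_species,
         lacking_species = setdiff(species, shared_species),
         host_map = host_map,
         host_compound = if (length(host_compound)) host_compound else NULL,
         role = role),
    class = "ground_truth")
  list(pt = peak_table(m, annotations = ann), st = sample_table(st),
       truth = truth)
}

#' Default cascade plan for a synthetic dataset
#'
#' Builds a species cascade in the hierarchical style of the emulated study:
#' the species lacking the shared marker are ordered first so the opening
#' round peels them off (the alarm-pheromone split), then rounds of three
#' species peel two (or one, when four remain) at a time until a final
#' three-group round keys the remainder.
#'
#' @param truth a `ground_truth` from [generate_dataset()] (used to order the
#'   shared-marker-lacking species first), or a character vector of species.
#' @param thresholds a [biomarker_thresholds()] object used for every round.
#' @param transform per-round transform; `"presence"` by default because the
#'   emulated study describes every round's separation as driven by the
#'   presence and absence of headspace compounds.
#' @param ... extra arguments stored in the plan defaults (e.g. `seed`,
#'   `n_perm`).
#' @return A [cascade_plan()].
#' @export
default_recovery_plan <- function(truth, thresholds = biomarker_thresholds(),
                                  transform = "presence", ...) {
  if (inherits(truth, "ground_truth")) {
    species <- c(truth$lacking_species,
                 setdiff(names(truth$eb), truth$lacking_species))
  } else {
    species <- as.character(truth)
  }
  if (length(species) < 3L) {
    vx_abort("need at least 3 species for a cascade plan", "volatax_plan_error")
  }
  rounds <- list()
  remaining <- species
  i <- 0L
  repeat {
    i <- i + 1L
    if (length(remaining) <= 3L) {
      rounds[[i]] <- round_plan(sprintf("A%d", i), groups = remaining,
                                thresholds = thresholds, transform = transform)
      break
    }
    n_rm <- if (length(remaining) == 4L) 1L else 2L
    grp <- remaining[seq_len(3L)]
    rounds[[i]] <- round_plan(sprintf("A%d", i), groups = grp,
                              groups_to_remove_after = remaining[seq_len(n_rm)],
                              thresholds = thresholds, transform = transform)
    remaining <- remaining[-seq_len(n_rm)]
  }
  cascade_plan(rounds, defaults = list(...))
}

#' Planted-marker recovery experiment
#'
#' Generates a dataset, runs the cascade, and scores the key's essential
#' biomarkers against the planted ones, per species and in aggregate:
#' * `recall` -- planted EBs recovered as EBs of their species / planted EBs;
#' * `precision` -- reported EBs that are planted markers (EB *or* SEB) of
#'   their species / reported EBs. A planted semi-essential marker whose
#'   realised vector length falls in the essential band is a property of that
#'   data draw, not a pipeline error, so it does not count against precision;
#'   background or shared compounds reported as EBs do;
#' * `strict_precision` -- reported EBs that are planted EBs / reported EBs,
#'   for transparency about band crossings.
#'
#' @param spec a [synthetic_spec()].
#' @param plan optional [cascade_plan()]; by default
#'   [default_recovery_plan()] with the experiment seed.
#' @param shuffle_labels negative control: permute the species labels of the
#'   biological samples before analysis (recall should collapse).
#' @return A list with `recall`, `precision`, `strict_precision`,
#'   `per_species` (data.frame), `key`, `cascade`, `truth`.
#' @export
eb_recovery_experiment <- function(spec = synthetic_spec(), plan = NULL,
                                   shuffle_labels = FALSE) {
  data <- generate_dataset(spec)
  plan <- plan %||% default_recovery_plan(data$truth, seed = spec$seed)
  st <- data$st
  if (shuffle_labels) {
    st <- with_seed(spec$seed + 1L, {
      df <- as.data.frame(st)
      perm <- setNames(sample(unique(df$group_label)), unique(df$group_label))
      # permute at the replicate-group level to keep replicates coherent
      df$group_label <- unname(perm[df$group_label])
      sample_table(df)
    })
  }
  cas <- run_cascade(data$pt, st, plan)
  species <- names(data$truth$eb)
  per <- do.call(rbind, lapply(species, function(s) {
    planted_eb <- data$truth$eb[[s]]
    planted_any <- c(planted_eb, data$truth$seb[[s]])
    found <- if (s %in% names(cas$key$taxa)) cas$key$taxa[[s]]$eb else character(0)
    data.frame(species = s,
               n_planted = length(planted_eb), n_reported = length(found),
               n_recovered = length(intersect(planted_eb, found)),
               n_marker = length(intersect(planted_any, found)),
               stringsAsFactors = FALSE)
  }))
  n_rep <- sum(per$n_reported)
  list(recall = sum(per$n_recovered) / sum(per$n_planted),
       precision = if (n_rep == 0L) NA_real_ else sum(per$n_marker) / n_rep,
       strict_precision = if (n_rep == 0L) NA_real_ else
         sum(per$n_recovered) / n_rep,
       per_species = per, key = cas$key, cascade = cas, truth = data$truth)
}

#' Read a synthetic spec from JSON
#' @param path JSON file whose fields mirror the [synthetic_spec()] arguments.
#' @return A `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  if (!file.exists(path)) {
    vx_abort(sprintf("spec file not found: %s", path), "volatax_io_error")
  }
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(args$host_plants)) {
    args$host_plants <- unlist(args$host_plants)
  }
  do.call(synthetic_spec, args)
}
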