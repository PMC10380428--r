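make_vectors <- function(df) {
  df$len2 <- df$x^2 + df$y^2
  df$significant <- df$significant %||% TRUE
  class(df) <- c("compound_vectors", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

two_centroids <- matrix(c(1, 0, -1, 0), 2, 2, byrow = TRUE,
                        dimnames = list(c("east", "west"), NULL))

test_that("threshold validation enforces the band ordering", {
  expect_s3_class(biomarker_thresholds(), "biomarker_thresholds")
  expect_error(biomarker_thresholds(eb_low = 0.2, seb_low = 0.3),
               class = "volatax_config_error")
  expect_error(biomarker_thresholds(eb_high = 3), class = "volatax_config_error")
})

test_that("squared-length bands classify vectors as EB / SEB / dropped", {
  v <- make_vectors(data.frame(
    compound_id = c("eb_one", "seb_one", "short"),
    x = sqrt(c(0.60, 0.35, 0.10)), y = 0, significant = TRUE,
    stringsAsFactors = FALSE))
  sets <- classify_biomarkers(v, biomarker_thresholds(), two_centroids, "R1")
  expect_identical(sets$east$eb$compound_id, "eb_one")     # 0.60 in [0.49, 0.97]
  expect_identical(sets$east$seb$compound_id, "seb_one")   # 0.35 in [0.29, 0.49)
  expect_false("short" %in% c(sets$east$eb$compound_id,
                              sets$east$seb$compound_id))  # 0.10 dropped
  expect_identical(sets$east$round_id, "R1")

  # band boundaries are closed on the left (exact len2 values, no sqrt
  # round-trip)
  vb <- data.frame(compound_id = c("at_eb", "at_seb"), x = c(0.7, 0.5), y = 0,
                   len2 = c(0.49, 0.29), significant = TRUE,
                   stringsAsFactors = FALSE)
  sb <- classify_biomarkers(vb, biomarker_thresholds(), two_centroids)
  expect_identical(sb$east$eb$compound_id, "at_eb")
  expect_identical(sb$east$seb$compound_id, "at_seb")

  # above eb_high stays an EB, with a note
  vh <- make_vectors(data.frame(compound_id = "huge", x = 0.999, y = 0.2,
                                significant = TRUE, stringsAsFactors = FALSE))
  expect_message(sh <- classify_biomarkers(vh, biomarker_thresholds(),
                                           two_centroids), "eb_high")
  expect_identical(sh$east$eb$compound_id, "huge")
})

test_that("classification partitions significant vectors exclusively", {
  set.seed(71)
  v <- make_vectors(data.frame(
    compound_id = sprintf("c%02d", 1:40),
    x = runif(40, -1, 1), y = runif(40, -1, 1),
    significant = runif(40) > 0.3, stringsAsFactors = FALSE))
  v$len2 <- pmin(v$len2, 2)
  sets <- classify_biomarkers(v, biomarker_thresholds(), two_centroids)
  seen <- unlist(lapply(sets, function(s) c(s$eb$compound_id, s$seb$compound_id)))
  expect_identical(anyDuplicated(seen), 0L)              # never EB and SEB both
  expect_true(all(seen %in% v$compound_id[v$significant]))
  thr <- biomarker_thresholds()
  for (s in sets) {
    expect_true(all(s$eb$len2 >= thr$eb_low))
    expect_true(all(s$seb$len2 >= thr$seb_low & s$seb$len2 < thr$eb_low))
  }
})

test_that("vectors are assigned to the group they point toward", {
  v <- make_vectors(data.frame(compound_id = c("to_east", "to_west"),
                               x = c(0.8, -0.8), y = c(0.05, -0.05),
                               significant = TRUE, stringsAsFactors = FALSE))
  sets <- classify_biomarkers(v, biomarker_thresholds(), two_centroids)
  expect_identical(sets$east$eb$compound_id, "to_east")
  expect_identical(sets$west$eb$compound_id, "to_west")
})

test_that("build_key unions rounds and rejects EB-less taxa", {
  key <- tiny_key()
  expect_identical(sort(names(key$taxa)), c("taxA", "taxB"))
  expect_identical(key$taxa$taxA$eb, c("e1", "e2"))

  # same taxon separated in two rounds: union without duplicates, EB wins
  r1 <- list(structure(list(group_label = "tax",
                            eb = data.frame(compound_id = c("a", "b"), len2 = c(0.6, 0.7)),
                            seb = data.frame(compound_id = "c", len2 = 0.3),
                            round_id = "R1"), class = "biomarker_set"))
  r2 <- list(structure(list(group_label = "tax",
                            eb = data.frame(compound_id = c("b", "c"), len2 = c(0.8, 0.5)),
                            seb = data.frame(compound_id = "d", len2 = 0.4),
                            round_id = "R2"), class = "biomarker_set"))
  k2 <- build_key(list(r1, r2))
  expect_identical(k2$taxa$tax$eb, c("a", "b", "c"))
  expect_identical(k2$taxa$tax$seb, "d")  # c promoted to EB, deduplicated
  expect_identical(sort(k2$taxa$tax$provenance), c("R1", "R2"))
})

test_that("match_profile implements the scoring and status rules", {
  key <- tiny_key()  # taxA: EB {e1,e2}, SEB {s1}; taxB: EB {e3}, SEB {s2,s3}

  id <- match_profile(c("e1", "e2", "s1"), key)
  expect_identical(id$status, "identified")
  expect_identical(id$candidates$taxon[1], "taxA")
  expect_equal(id$candidates$score[1], 1.5)

  # half of taxA's EBs is not enough under eb_accept = 1
  half <- match_profile(c("e1", "s1"), key)
  expect_false(half$status == "identified")

  empty <- match_profile(character(0), key)
  expect_identical(empty$status, "unidentified")
  expect_true(all(empty$candidates$score == 0))

  expect_warning(match_profile(c("e1", "e2", "s1", "never_seen"), key),
                 "outside the key vocabulary")

  # margin: a second taxon scoring close forces ambiguity
  key2 <- build_key(list(list(
    structure(list(group_label = "t1",
                   eb = data.frame(compound_id = "x", len2 = 0.6),
                   seb = data.frame(compound_id = character(0), len2 = numeric(0)),
                   round_id = "R"), class = "biomarker_set"),
    structure(list(group_label = "t2",
                   eb = data.frame(compound_id = "x", len2 = 0.6),
                   seb = data.frame(compound_id = character(0), len2 = numeric(0)),
                   round_id = "R"), class = "biomarker_set"))))
  amb <- match_profile("x", key2)
  expect_identical(amb$status, "ambiguous")
})

test_that("adding a missing EB never lowers a taxon's score", {
  set.seed(73)
  key <- tiny_key()
  for (rep in 1:20) {
    vocab <- c("e1", "e2", "e3", "s1", "s2", "s3")
    profile <- sample(vocab, sample(0:5, 1))
    missing <- setdiff(key$taxa$taxA$eb, profile)
    if (length(missing) == 0L) next
    s0 <- suppressWarnings(match_profile(profile, key))
    s1 <- suppressWarnings(match_profile(c(profile, missing[1]), key))
    score0 <- s0$candidates$score[s0$candidates$taxon == "taxA"]
    score1 <- s1$candidates$score[s1$candidates$taxon == "taxA"]
    expect_gte(score1, score0)
  }
})

test_that("keys self-match after an IO round trip", {
  key <- tiny_key()
  path <- tempfile(fileext = ".json")
  write_key(key, path)
  back <- read_key(path)
  for (tx in names(back$taxa)) {
    own <- c(back$taxa[[tx]]$eb, back$taxa[[tx]]$seb)
    id <- match_profile(own, back)
    expect_identical(id$status, "identified")
    expect_identical(id$candidates$taxon[1], tx)
  }
})
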