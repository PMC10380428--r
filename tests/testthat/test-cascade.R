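test_that("a round separates the group lacking the shared compound", {
  fx <- fig2_like_fixture()
  rp <- round_plan("A1", groups = c("lackA", "lackB", "haveC"),
                   transform = "presence", n_perm = 99L, seed = 5L)
  res <- suppressWarnings(suppressMessages(run_round(fx$pt, fx$st, rp)))
  expect_equal(res$cap$loo_error_pct, 0)
  expect_lte(res$cap$p_trace, 0.05)
  # the shared compound's vector is significant and points away from the
  # species lacking it
  shared <- res$vectors[res$vectors$compound_id == "sharedEbf", ]
  expect_true(shared$significant)
  proj <- res$cap$group_centroids[, 1:2, drop = FALSE] %*%
    c(shared$x, shared$y)
  expect_identical(rownames(res$cap$group_centroids)[which.max(proj)], "haveC")
  # private markers become that species' essential biomarkers
  expect_true(all(c("mkA1", "mkA2") %in% res$biomarkers$lackA$eb$compound_id))
})

test_that("the three-group minimum is enforced", {
  expect_error(round_plan("bad", groups = c("only", "two")),
               "at least three", class = "volatax_plan_error")
})

test_that("rounds are deterministic given the seed", {
  fx <- fig2_like_fixture()
  rp <- round_plan("A1", groups = c("lackA", "lackB", "haveC"),
                   n_perm = 99L, seed = 9L)
  r1 <- suppressWarnings(suppressMessages(run_round(fx$pt, fx$st, rp)))
  r2 <- suppressWarnings(suppressMessages(run_round(fx$pt, fx$st, rp)))
  expect_identical(round_report(r1), round_report(r2))
})

test_that("a single-round cascade equals run_round plus the key", {
  fx <- fig2_like_fixture()
  rp <- round_plan("A1", groups = c("lackA", "lackB", "haveC"),
                   transform = "presence", n_perm = 0L, seed = 2L)
  plan <- cascade_plan(list(rp), defaults = list(seed = 2L))
  cas <- suppressWarnings(suppressMessages(run_cascade(fx$pt, fx$st, plan)))
  single <- suppressWarnings(suppressMessages(
    run_round(fx$pt, fx$st, rp, defaults = plan$defaults)))
  expect_identical(round_report(cas$rounds$A1), round_report(single))
  expect_setequal(names(cas$key$taxa), c("lackA", "lackB", "haveC"))
})

test_that("group removal drops private compounds and counts never grow", {
  spec <- synthetic_spec(n_species = 5L, n_compounds = 30L, n_biological = 4L,
                         n_shared_species = 4L, seed = 301L)
  data <- generate_dataset(spec)
  plan <- default_recovery_plan(data$truth, seed = 301L)
  cas <- suppressWarnings(suppressMessages(run_cascade(data$pt, data$st, plan)))
  n_cmp <- vapply(cas$rounds, function(r) r$n_compounds, integer(1L))
  n_rep <- vapply(cas$rounds, function(r) length(r$groups), integer(1L))
  expect_true(all(diff(n_cmp) <= 0))
  expect_true(all(diff(n_rep) <= 0))
  # species removed after round 1 take their private EB compounds with them
  removed <- plan$rounds[[1]]$groups_to_remove_after
  private <- unlist(data$truth$eb[removed])
  expect_false(any(private %in% cas$rounds[[2]]$transformed$compound_ids))
})

test_that("the cascade halts with a structured error when groups run out", {
  fx <- fig2_like_fixture()
  plan <- cascade_plan(list(
    round_plan("A1", groups = c("lackA", "lackB", "haveC"),
               groups_to_remove_after = c("lackA")),
    round_plan("A2", groups = c("lackA", "lackB", "haveC"))
  ))
  expect_error(suppressMessages(run_cascade(fx$pt, fx$st, plan)),
               "A2", class = "volatax_cascade_error")
})

test_that("host-plant rounds group by the host_plant column", {
  fx <- fig2_like_fixture()
  st <- as.data.frame(fx$st)
  st$host_plant <- c(lackA = "mint", lackB = "lemon",
                     haveC = "vinca")[st$group_label]
  rp <- round_plan("B1", groups = c("mint", "lemon", "vinca"),
                   grouping_variable = "host_plant", transform = "presence",
                   n_perm = 0L, seed = 4L)
  res <- suppressWarnings(suppressMessages(run_round(fx$pt, sample_table(st), rp)))
  expect_setequal(unique(res$groups), c("mint", "lemon", "vinca"))
  expect_equal(res$cap$loo_error_pct, 0)
})

test_that("outgroup biomarkers never enter the key", {
  fx <- fig2_like_fixture()
  st <- as.data.frame(fx$st)
  st$is_outgroup <- st$group_label == "haveC"
  plan <- cascade_plan(list(
    round_plan("A1", groups = c("lackA", "lackB", "haveC"), outgroup = "haveC")
  ))
  cas <- suppressWarnings(suppressMessages(run_cascade(fx$pt, sample_table(st), plan)))
  expect_setequal(names(cas$key$taxa), c("lackA", "lackB"))
})

test_that("suggest_group_removals flags cleanly separated groups", {
  fx <- fig2_like_fixture()
  rp <- round_plan("A1", groups = c("lackA", "lackB", "haveC"),
                   transform = "presence", n_perm = 0L)
  res <- suppressWarnings(suppressMessages(run_round(fx$pt, fx$st, rp)))
  expect_setequal(suggest_group_removals(res),
                  c("lackA", "lackB", "haveC"))  # all three separate cleanly
})

test_that("identify_unknown matches a key or separates a novel profile", {
  spec <- synthetic_spec(n_species = 5L, n_compounds = 30L, n_biological = 4L,
                         n_shared_species = 4L, seed = 77L)
  data <- generate_dataset(spec)
  plan <- default_recovery_plan(data$truth, seed = 77L)
  cas <- suppressWarnings(suppressMessages(run_cascade(data$pt, data$st, plan)))

  # unknown = replicate of a reference species' template -> identified
  sp <- names(data$truth$eb)[3]
  template <- c(data$truth$eb[[sp]], data$truth$seb[[sp]],
                if (sp %in% data$truth$shared_species) data$truth$shared_compound)
  m <- matrix(100, length(template), 3,
              dimnames = list(template, paste0("u", 1:3)))
  id <- suppressWarnings(identify_unknown(peak_table(m), cas$key))
  expect_identical(id$status, "identified")
  expect_identical(id$candidates$taxon[1], sp)

  # unknown sharing only half of a taxon's EBs is not identified
  half <- data$truth$eb[[sp]][1]
  m_half <- matrix(100, 1, 3, dimnames = list(half, paste0("u", 1:3)))
  id_half <- suppressWarnings(identify_unknown(peak_table(m_half), cas$key))
  expect_false(id_half$status == "identified")

  # disjoint terpene-dominated profile: separates as its own group in CAP mode
  novel <- paste0("terp", 1:6)
  m_nov <- matrix(rep(c(80, 120, 100), each = 6), 6, 3,
                  dimnames = list(novel, paste0("u", 1:3)))
  m_nov <- rbind(m_nov,
                 matrix(5, 2, 3, dimnames = list(data$truth$seb[[1]],
                                                 paste0("u", 1:3))))
  rep_cap <- suppressWarnings(suppressMessages(
    identify_unknown(peak_table(m_nov), list(pt = data$pt, st = data$st),
                     transform = "presence")))
  expect_identical(rep_cap$status, "unidentified")
  expect_true(rep_cap$separates)
  # and against the key it is unidentified too
  id_nov <- suppressWarnings(identify_unknown(peak_table(m_nov), cas$key))
  expect_identical(id_nov$status, "unidentified")

  # no shared vocabulary at all is a structured error
  alien <- peak_table(matrix(1, 2, 3, dimnames = list(c("zz1", "zz2"),
                                                      paste0("u", 1:3))))
  expect_error(identify_unknown(alien, list(pt = data$pt, st = data$st)),
               class = "volatax_vocabulary_error")
})
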