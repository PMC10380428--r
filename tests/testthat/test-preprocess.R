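test_that("technical replicates are averaged per replicate group", {
  m <- matrix(c(2, 10, 4, 20, 6, 30), nrow = 2,
              dimnames = list(c("c1", "c2"), c("s1", "s2", "s3")))
  st <- sample_table(data.frame(
    sample_id = c("s1", "s2", "s3"), replicate_group = c("rg1", "rg1", "rg2"),
    group_label = "A", stringsAsFactors = FALSE))
  expect_warning(avg <- average_technical_replicates(peak_table(m), st),
                 class = "volatax_replicate_warning")  # both groups < 3 reps
  expect_equal(avg$abundances["c1", "rg1"], 3)         # mean of 2, 4
  expect_equal(avg$abundances["c2", "rg2"], 30)        # size-1 pass-through

  # sample missing from metadata is a mapping error
  expect_error(
    average_technical_replicates(peak_table(m), st[st$sample_id != "s2", ]),
    "s2", class = "volatax_mapping_error")
})

test_that("averaging a 3x6 table matches the brute-force per-cell oracle", {
  set.seed(21)
  m <- matrix(rexp(18), 3, 6,
              dimnames = list(paste0("c", 1:3), paste0("s", 1:6)))
  st <- sample_table(data.frame(
    sample_id = paste0("s", 1:6), replicate_group = rep(c("g1", "g2"), each = 3),
    group_label = rep(c("A", "B"), each = 3), stringsAsFactors = FALSE))
  avg <- average_technical_replicates(peak_table(m), st)
  expect_identical(dim(avg), c(3L, 2L))
  for (i in 1:3) for (g in c("g1", "g2")) {
    cols <- st$sample_id[st$replicate_group == g]
    expect_equal(avg$abundances[i, g], mean(m[i, cols]))
  }
})

test_that("abundance transforms follow their definitions", {
  pt <- make_pt(matrix(c(2, 3, 5, 0, 0, 0, 0, 7, 1), nrow = 3,
                       dimnames = list(NULL, c("a", "b", "c"))))
  expect_warning(rel <- transform_abundances(pt, "relative"), "all-zero")
  expect_equal(unname(rel$abundances[, "a"]), c(0.2, 0.3, 0.5))
  expect_equal(unname(rel$abundances[, "b"]), c(0, 0, 0))  # stays zero

  pres <- transform_abundances(pt, "presence")
  expect_equal(unname(pres$abundances[, "c"]), c(0, 1, 1))
  pres2 <- transform_abundances(pt, "presence", detection_threshold = 2)
  expect_equal(unname(pres2$abundances[, "a"]), c(0, 1, 1))

  lg <- transform_abundances(pt, "log1p")
  expect_equal(lg$abundances[1, "b"], 0)                 # log1p(0) = 0
  expect_equal(lg$abundances[1, "a"], log(3))

  expect_equal(transform_abundances(pt, "none")$abundances, pt$abundances)
})

test_that("relative transform makes nonzero columns sum to one", {
  set.seed(5)
  for (i in 1:10) {
    pt <- make_pt(matrix(rexp(40), 8, 5))
    rel <- transform_abundances(pt, "relative")
    expect_true(all(abs(colSums(rel$abundances) - 1) < 1e-12))
  }
})

test_that("distance metrics follow their formulas", {
  pt <- make_pt(matrix(c(1, 0, 0, 1), 2, dimnames = list(NULL, c("u", "v"))))
  D <- compute_distance_matrix(pt, "bray-curtis")
  expect_equal(D$values["u", "v"], 1)  # disjoint support

  pt2 <- make_pt(matrix(c(2, 1, 1, 1), 2, dimnames = list(NULL, c("u", "v"))))
  expect_equal(compute_distance_matrix(pt2, "bray-curtis")$values["u", "v"],
               0.2)  # (1 + 0) / (3 + 2)

  same <- make_pt(matrix(c(3, 4, 3, 4), 2))
  for (metric in c("bray-curtis", "euclidean", "jaccard-binary")) {
    expect_equal(max(compute_distance_matrix(same, metric)$values), 0)
  }
  expect_error(compute_distance_matrix(pt, "bogus"),
               "valid metrics", class = "volatax_config_error")
})

test_that("distances agree with the vegan oracle on random profiles", {
  skip_if_not_installed("vegan")
  set.seed(31)
  m <- matrix(rexp(60) * rbinom(60, 1, 0.7), 10, 6)
  pt <- make_pt(m)
  expect_equal(compute_distance_matrix(pt, "bray-curtis")$values,
               as.matrix(vegan::vegdist(t(m), "bray")),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(compute_distance_matrix(pt, "euclidean")$values,
               as.matrix(dist(t(m))), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(compute_distance_matrix(pt, "jaccard-binary")$values,
               as.matrix(vegan::vegdist(t(m), "jaccard", binary = TRUE)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("metric axioms and permutation equivariance hold on random data", {
  set.seed(41)
  for (rep in 1:5) {
    m <- matrix(rexp(36) * rbinom(36, 1, 0.8), 6, 6)
    m[, 1] <- pmax(m[, 1], 0.1)  # avoid the all-zero degenerate column
    pt <- make_pt(m)
    for (metric in c("bray-curtis", "euclidean", "jaccard-binary")) {
      D <- compute_distance_matrix(pt, metric)$values
      expect_true(all(diag(D) == 0))
      expect_true(all(D >= 0))
      expect_equal(D, t(D))
      if (metric == "bray-curtis") expect_true(all(D <= 1 + 1e-12))
    }
    # euclidean triangle inequality on random triples
    D <- compute_distance_matrix(pt, "euclidean")$values
    for (k in 1:5) {
      ijk <- sample(ncol(m), 3L)
      expect_lte(D[ijk[1], ijk[3]],
                 D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
    }
    # permutation equivariance
    perm <- sample(ncol(m))
    Dp <- compute_distance_matrix(subset_peak_table(pt, samples = perm),
                                  "bray-curtis")$values
    D0 <- compute_distance_matrix(pt, "bray-curtis")$values
    expect_equal(Dp, D0[perm, perm])
  }
})

test_that("pruning removes exactly the all-zero compound rows", {
  m <- matrix(c(1, 0, 3, 2, 0, 4), nrow = 3,
              dimnames = list(c("keep1", "zero", "keep2"), c("s1", "s2")))
  expect_message(pr <- prune_compounds(peak_table(m)), "zero")
  expect_identical(pr$compound_ids, c("keep1", "keep2"))

  nopr <- make_pt(matrix(1:4, 2))
  expect_identical(prune_compounds(nopr)$abundances, nopr$abundances)

  allzero <- make_pt(matrix(0, 2, 2))
  expect_error(suppressMessages(prune_compounds(allzero)),
               class = "volatax_degenerate_error")

  # a compound private to dropped samples is pruned after subsetting
  m2 <- matrix(c(5, 1, 1, 0, 1, 1), nrow = 3,
               dimnames = list(c("private", "bg1", "bg2"), c("s1", "s2")))
  sub <- subset_peak_table(peak_table(m2), samples = "s2")
  expect_false("private" %in% suppressMessages(prune_compounds(sub))$compound_ids)
})
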