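# Fixtures are built in code at test time; nothing is read from disk except
# files the tests themselves write to tempdir().

make_pt <- function(m, ...) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  peak_table(m, ...)
}

# Euclidean dist_matrix + labels from a coordinate matrix
coords_dist <- function(X, ids = sprintf("s%02d", seq_len(nrow(X)))) {
  rownames(X) <- ids
  d <- as.matrix(dist(X))
  dist_matrix(d, "euclidean")
}

# Two well-separated clusters in `dims` dimensions
two_cluster_fixture <- function(n_per = 5L, sep = 10, spread = 0.1,
                                dims = 2L, seed = 42L) {
  withr::with_seed(seed, {
    X <- rbind(
      matrix(rnorm(n_per * dims, 0, spread), n_per, dims),
      matrix(rnorm(n_per * dims, 0, spread), n_per, dims))
    X[(n_per + 1):(2 * n_per), 1] <- X[(n_per + 1):(2 * n_per), 1] + sep
    list(X = X, D = coords_dist(X),
         groups = rep(c("A", "B"), each = n_per))
  })
}

# Small 3-species peak table mimicking the opening-round structure: two
# species lack the widely shared compound, each species has private markers.
fig2_like_fixture <- function(n_bio = 4L, n_rep = 3L, seed = 7L) {
  withr::with_seed(seed, {
    species <- c("lackA", "lackB", "haveC")
    st <- do.call(rbind, lapply(species, function(s) {
      do.call(rbind, lapply(seq_len(n_bio), function(b) {
        data.frame(sample_id = sprintf("%s_b%d_r%d", s, b, seq_len(n_rep)),
                   replicate_group = sprintf("%s_b%d", s, b),
                   group_label = s, is_outgroup = FALSE,
                   stringsAsFactors = FALSE)
      }))
    }))
    cmp <- c("sharedEbf", "mkA1", "mkA2", "mkB1", "mkB2", "mkC1", "mkC2",
             sprintf("bg%02d", 1:8))
    m <- matrix(0, length(cmp), nrow(st), dimnames = list(cmp, st$sample_id))
    noise <- function(n, med = 1) med * exp(rnorm(n, 0, 0.3))
    for (i in seq_len(nrow(st))) {
      s <- st$group_label[i]
      m["sharedEbf", i] <- if (s == "haveC") noise(1, 100) else 0
      if (s == "lackA") m[c("mkA1", "mkA2"), i] <- noise(2, 100)
      if (s == "lackB") m[c("mkB1", "mkB2"), i] <- noise(2, 100)
      if (s == "haveC") m[c("mkC1", "mkC2"), i] <- noise(2, 100)
      m[sprintf("bg%02d", 1:8), i] <- noise(8, 1)
    }
    list(pt = peak_table(m), st = sample_table(st))
  })
}

write_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_key <- function() {
  build_key(list(list(
    structure(list(group_label = "taxA",
                   eb = data.frame(compound_id = c("e1", "e2"), len2 = c(0.8, 0.6)),
                   seb = data.frame(compound_id = "s1", len2 = 0.35),
                   round_id = "R1"), class = "biomarker_set"),
    structure(list(group_label = "taxB",
                   eb = data.frame(compound_id = c("e3"), len2 = 0.7),
                   seb = data.frame(compound_id = c("s2", "s3"), len2 = c(0.3, 0.4)),
                   round_id = "R1"), class = "biomarker_set")
  )))
}
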