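test_that("distance formulas match independent closed-form evaluation", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_equal(k2p_distance("AAAA", "AAAA"), 0)

  # P = 0.1 transitions, Q = 0.05 transversions over 20 sites:
  # 2 A->G changes and 1 A->C change among 20 A's
  a <- strrep("A", 20)
  b <- paste0("GG", "C", strrep("A", 17))
  P <- 2 / 20; Q <- 1 / 20
  expect_equal(k2p_distance(a, b),
               -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
               tolerance = 1e-12)
  p <- 3 / 20
  expect_equal(jc_distance(a, b), -0.75 * log(1 - 4 * p / 3),
               tolerance = 1e-12)

  # pairwise deletion: gaps/N columns drop out of the denominator
  expect_equal(p_distance("AC-TN", "ACGTA"), 0)
  expect_equal(p_distance("ACN", "AGN"), 0.5)

  expect_error(p_distance("ACG", "AC"), class = "aspcr_shape_error")
  expect_error(k2p_distance("AG", "GA"), class = "aspcr_saturation_error")
  expect_error(p_distance("NNN", "AAA"), class = "aspcr_saturation_error")
})

test_that("brute-force column comparison agrees on random pairs, and the
           model ordering p <= jc <= k2p-ish bounds hold", {
  withr::with_seed(31, {
    for (i in 1:20) {
      a <- sample(c("A", "C", "G", "T", "N", "-"), 150, replace = TRUE,
                  prob = c(rep(0.23, 4), 0.04, 0.04))
      b <- a
      flip <- runif(150) < 0.12
      b[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
      sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
      both <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      want_p <- sum(a[both] != b[both]) / sum(both)
      expect_equal(p_distance(sa, sb), want_p, tolerance = 1e-12)
      expect_gte(jc_distance(sa, sb), p_distance(sa, sb))
      expect_gte(k2p_distance(sa, sb), p_distance(sa, sb))
    }
  })
})

test_that("distance matrices are symmetric and consistent with per-pair calls", {
  aln <- related_alignment(n_records = 6L, len = 200L, seed = 2L)
  for (model in c("p", "jc", "k2p")) {
    dm <- build_distance_matrix(aln, model)
    expect_true(isSymmetric(dm$d))
    expect_equal(unname(diag(dm$d)), rep(0, 6))
    f <- switch(model, p = p_distance, jc = jc_distance, k2p = k2p_distance)
    expect_equal(dm$d[2, 5], f(aln$seq[2], aln$seq[5]))
  }
  same <- species_alignment(c("a", "b", "c"), c("S1", "S2", "S3"),
                            rep("ACGTACGT", 3))
  expect_true(all(build_distance_matrix(same, "k2p")$d == 0))
  expect_error(build_distance_matrix(
    species_alignment(c("a", "b"), c("S1", "S2"), c("AC", "AC"))),
    class = "aspcr_size_error")
})

test_that("NJ reproduces the 3-taxon closed form to 1e-12", {
  D <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(D)
  pd <- tree_path_distances(tree)
  expect_equal(pd["A", "B"], 0.3, tolerance = 1e-12)
  expect_equal(pd["A", "C"], 0.5, tolerance = 1e-12)
  expect_equal(pd["B", "C"], 0.6, tolerance = 1e-12)
  # pendant branch lengths: x_A = (d_AB + d_AC - d_BC)/2 etc.
  eA <- tree$edge.length[tree$edge[, 2] == 1L]
  expect_equal(eA, (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-12)
})

test_that("NJ recovers additive matrices exactly (topology + path lengths)", {
  for (seed in 1:30) {
    n <- 4L + seed %% 3L
    case <- random_additive_case(n, seed)
    tree <- neighbor_joining(case$D)
    expect_equal(tree_path_distances(tree)[case$leaves, case$leaves],
                 case$D, tolerance = 1e-8)
    expect_identical(canon_splits(tree_splits(tree), case$leaves),
                     canon_splits(case$splits, case$leaves))
  }
})

test_that("NJ topology matches the ape oracle on empirical-style matrices", {
  skip_if_not_installed("ape")
  aln <- generate_alignment(shaped_spec(seed = 4))$alignment
  dm <- build_distance_matrix(aln, "k2p")
  ours <- neighbor_joining(dm)
  theirs <- ape::nj(stats::as.dist(dm$d))
  expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(theirs))[1], 0)
})

test_that("NJ is deterministic and demands >= 3 taxa", {
  aln <- related_alignment(n_records = 8L, len = 120L, seed = 6L)
  dm <- build_distance_matrix(aln)
  expect_identical(write_newick(neighbor_joining(dm)),
                   write_newick(neighbor_joining(dm)))
  expect_error(neighbor_joining(matrix(0, 2, 2)), class = "aspcr_size_error")
})

test_that("bootstrap: strong splits, {0,1} supports at one replicate, determinism", {
  aln <- two_clade_alignment()
  tree <- bootstrap_support(aln, replicates = 200L, seed = 7L)
  expect_true(all(tree$support >= 0 & tree$support <= 1))
  # the clade split has >= 10 fixed differences: support ~ 1
  # canonical bipartition keys exclude the side holding the first tip, so
  # the clade split is keyed by the CladeB leaf set
  clade_b <- aln$id[aln$species == "CladeB"]
  keys <- aspcr:::bipartition_keys(tree)
  split_key <- paste(sort(clade_b), collapse = "\x1f")
  scored <- tree$support[match(split_key, keys)]
  expect_gte(scored, 0.99)

  one <- bootstrap_support(aln, replicates = 1L, seed = 3L)
  expect_true(all(one$support %in% c(0, 1)))

  t1 <- bootstrap_support(aln, replicates = 50L, seed = 11L)
  t2 <- bootstrap_support(aln, replicates = 50L, seed = 11L)
  expect_identical(t1$support, t2$support)
  expect_error(bootstrap_support(aln, replicates = 0L),
               class = "aspcr_config_error")
})

test_that("monophyly detection on planted clades and trivial subsets", {
  aln <- two_clade_alignment()
  tree <- neighbor_joining(build_distance_matrix(aln))
  expect_true(is_monophyletic(tree, aln$id))                       # all leaves
  expect_true(is_monophyletic(tree, aln$id[1]))                    # pendant
  expect_true(is_monophyletic(tree, aln$id[aln$species == "CladeA"]))
  expect_true(is_monophyletic(tree, aln$id[aln$species == "CladeB"]))
  mixed <- c(aln$id[aln$species == "CladeA"][1:2],
             aln$id[aln$species == "CladeB"][1])
  expect_false(is_monophyletic(tree, mixed))
  expect_error(is_monophyletic(tree, "not_a_leaf"),
               class = "aspcr_label_error")
})

test_that("Newick output is well-formed and round-trips through ape", {
  D <- matrix(c(0, 0.2, 0.4, 0.2, 0, 0.4, 0.4, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tri <- neighbor_joining(D)
  nwk <- write_newick(tri)
  expect_match(nwk, "^\\([A-C]:[0-9.eE+-]+,[A-C]:[0-9.eE+-]+,[A-C]:[0-9.eE+-]+\\);$")

  skip_if_not_installed("ape")
  aln <- two_clade_alignment(n_per_clade = 3L)
  tree <- bootstrap_support(aln, replicates = 20L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, tree$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tree))[1], 0)
  # supports come back as integer-percent internal labels
  expect_true(any(grepl("^[0-9]+$", back$node.label)))

  plain <- neighbor_joining(build_distance_matrix(aln))
  expect_false(grepl(")[0-9]", write_newick(plain)))
})
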