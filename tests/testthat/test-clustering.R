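test_that("variant-gene selection keeps the top variances in input order", {
  vars <- c(0.5, 0.1, 3, 0.01, 2, 0.2, 1, 0.05, 0.8, 0.02)
  # deterministic rows with exact variances: alternate +/- around 0
  vals <- t(sapply(vars, function(v) sqrt(v) * scale(c(-1, 1, -1, 1, -1, 1))[, 1]))
  dimnames(vals) <- list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6))
  m <- expression_matrix(vals + 5, level = "gene")

  expect_identical(rownames(select_variant_genes(m, 1)), rownames(m))
  top3 <- select_variant_genes(m, 0.30)
  expect_identical(rownames(top3), c("g03", "g05", "g07"))  # vars 3, 2, 1

  # constant genes rank last and drop out whenever top_frac < 1
  m2 <- rbind(m, const = rep(4, 6))
  m2 <- expression_matrix(m2)
  expect_false("const" %in% rownames(select_variant_genes(m2, 0.5)))
  expect_error(select_variant_genes(m, 0), "top_frac")
})

test_that("Spearman distance matches hand-ranked correlations", {
  m <- expression_matrix(matrix(c(1, 2, 3, 4,
                                  1, 3, 2, 4,
                                  4, 3, 2, 1), ncol = 3,
                                dimnames = list(sprintf("g%d", 1:4),
                                                c("a", "b", "rev"))))
  d <- spearman_distance(m)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d["a", "b"], 1 - 0.8)          # hand Spearman on 4 ranks
  expect_equal(d["a", "rev"], 2)              # exact rank reversal
  expect_equal(d, t(d))

  # rank invariance: strictly increasing transform of a profile
  m2 <- m
  m2[, "b"] <- exp(m2[, "b"])
  expect_equal(spearman_distance(expression_matrix(m2)), d)

  mc <- m; mc[, "b"] <- 3
  expect_error(spearman_distance(expression_matrix(mc)),
               "constant sample profile.*b")
})

test_that("complete linkage merges by smallest maximum distance", {
  d <- matrix(c(0, 1, 4,
                1, 0, 5,
                4, 5, 0), 3, dimnames = list(c("A", "B", "C"),
                                             c("A", "B", "C")))
  tr <- complete_linkage(d)
  expect_equal(tr$height, c(1, 5))
  expect_identical(tr$merge[1, ], c(-2L, -1L))
  expect_equal(tree_to_newick(tr), "((A:1,B:1):4,C:5);")

  d2 <- d[1:2, 1:2]
  tr2 <- complete_linkage(d2)
  expect_equal(tr2$height, 1)
  expect_equal(tree_to_newick(tr2), "(A:1,B:1);")

  expect_error(complete_linkage(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(complete_linkage(-d), "negative")
})

test_that("linkage agrees with brute force and hclust on random instances", {
  set.seed(12)
  for (i in 1:20) {
    d <- random_distance_matrix(6)
    ours <- complete_linkage(d)
    ref <- brute_complete_linkage(d)
    expect_equal(ours$height, ref$height)
    expect_equal(as.matrix(stats::cophenetic(ours)),
                 as.matrix(stats::cophenetic(ref)))
    # independent library implementation as a second oracle
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    expect_equal(sort(ours$height), sort(hc$height))
    expect_equal(as.matrix(stats::cophenetic(ours))[rownames(d), rownames(d)],
                 as.matrix(stats::cophenetic(hc))[rownames(d), rownames(d)])
    # complete-linkage property: cophenetic dominates the input distance
    cop <- as.matrix(stats::cophenetic(ours))[rownames(d), rownames(d)]
    expect_true(all(cop - d >= -1e-12))
    expect_true(all(diff(ours$height) >= 0))
  }
})

test_that("Newick export round-trips through an independent parser", {
  set.seed(3)
  d <- random_distance_matrix(7)
  tr <- complete_linkage(d)
  ph <- ape::read.tree(text = tree_to_newick(tr))
  expect_setequal(ph$tip.label, rownames(d))
  # leaf-to-leaf path lengths in the parsed tree = 2 * cophenetic height
  cop_ape <- ape::cophenetic.phylo(ph)[rownames(d), rownames(d)]
  cop_ours <- as.matrix(stats::cophenetic(tr))[rownames(d), rownames(d)]
  expect_equal(cop_ape, 2 * cop_ours, tolerance = 1e-9)

  # re-export of the worked 3-leaf example is stable
  d3 <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nw <- tree_to_newick(complete_linkage(d3))
  ph3 <- ape::read.tree(text = nw)
  expect_equal(sort(ph3$edge.length), sort(c(1, 1, 4, 5)))
})

test_that("samples with well-separated group structure cluster by group", {
  cfg <- synth_config(seed = 5, n_genes = 800, n_signature = 30,
                      n_decoy = 5 * 15, decoy_effect_range = log2(c(8, 64)),
                      probesets_per_gene = 1L, n_unmapped = 0L,
                      reference_sizes = c(A = 8L, B = 8L, C = 8L,
                                          D = 8L, E = 8L))
  co <- generate_cohort(cfg)
  g <- suppressMessages(collapse_probesets(co$expr, co$probeset_map))
  tree <- complete_linkage(spearman_distance(select_variant_genes(g, 0.30)))
  k <- length(unique(co$samples$group))
  cl <- cut_clusters(tree, k)
  truth <- co$samples$group[match(names(cl), co$samples$sample_id)]
  expect_gte(mclust::adjustedRandIndex(cl, truth), 0.9)
})
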