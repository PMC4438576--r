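test_that("two-group summaries match hand-computed pooled statistics", {
  m <- toy_matrix(c(1, 1, 1, 1,
                    2, 4, 1, 1),
                  c("g0", "g1"), c("a1", "a2", "b1", "b2"))
  st <- gene_stats(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(st$delta, c(0, 2))
  expect_equal(st$s2, c(0, 1))        # SSA = 2, SSB = 0, pooled over df 2
  expect_equal(st$df, c(2L, 2L))

  # permutation within groups changes nothing
  st2 <- gene_stats(m, c("a2", "a1"), c("b2", "b1"))
  expect_equal(st2$delta, st$delta)
  expect_equal(st2$s2, st$s2)

  expect_error(gene_stats(m, c("a1", "a2"), c("a2", "b1")), "overlap")
  expect_error(gene_stats(m, "a1", c("b1", "b2")), "at least 2")
})

test_that("variance prior estimation recovers known hyperparameters", {
  # equal variances: infinite prior df, bias-corrected common scale
  pr <- estimate_prior(rep(0.25, 100), df = 10)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, exp(log(0.25) - digamma(5) + log(5)))

  # scale equivariance: doubling s2 doubles s0_sq, d0 unchanged
  set.seed(11)
  s2 <- 0.05 * (rchisq(2000, 13) / 13) / (rchisq(2000, 4) / 4)
  a <- estimate_prior(s2, 13)
  b <- estimate_prior(2 * s2, 13)
  expect_equal(b$d0, a$d0, tolerance = 1e-8)
  expect_equal(b$s0_sq, 2 * a$s0_sq, tolerance = 1e-8)

  # moment-matching recovery at M = 5000, d = 13 from the true sampling model
  set.seed(4)
  s2 <- 0.05 * (rchisq(5000, 13) / 13) / (rchisq(5000, 4) / 4)
  pr <- estimate_prior(s2, 13)
  expect_lt(abs(pr$d0 - 4) / 4, 0.25)
  expect_lt(abs(pr$s0_sq - 0.05) / 0.05, 0.10)

  expect_error(estimate_prior(rep(0, 100), 10), "all sample variances")
  expect_error(estimate_prior(c(0.1, 0.2), 10), ">= 50 genes")
})

test_that("moderated t matches its closed form and both df limits", {
  # worked example: delta 2, s2 1, d 2, d0 2, s0 1, n 2+2
  mt <- moderated_t(2, 1, 2, list(d0 = 2, s0_sq = 1), 2, 2)
  expect_equal(mt$t_mod, 2)
  expect_equal(mt$df_total, 4)
  # two-sided t tail via the independent incomplete-beta identity
  expect_equal(mt$p, pbeta(4 / (4 + 2^2), 4 / 2, 1 / 2), tolerance = 1e-12)
  expect_equal(mt$p, 0.1161165, tolerance = 1e-6)

  expect_equal(moderated_t(0, 1, 4, list(d0 = 3, s0_sq = 2), 3, 3)$p, 1)

  # d0 -> 0: classical pooled two-sample t, exactly
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(4 + i %% 3)
    y <- rnorm(5) + 0.5
    st <- gene_stats(toy_matrix(c(x, y), "g",
                                c(sprintf("x%d", seq_along(x)),
                                  sprintf("y%d", seq_along(y)))),
                     sprintf("x%d", seq_along(x)),
                     sprintf("y%d", seq_along(y)))
    mt0 <- moderated_t(st$delta, st$s2, st$df, list(d0 = 0, s0_sq = 1),
                       length(x), length(y))
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mt0$t_mod, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mt0$p, ref$p.value, tolerance = 1e-12)
  }

  # d0 -> Inf: delta / sqrt(s0_sq * (1/nA + 1/nB)), normal reference
  mtI <- moderated_t(1.2, 5, 8, list(d0 = Inf, s0_sq = 0.09), 4, 6)
  expect_equal(mtI$t_mod, 1.2 / sqrt(0.09 * (1 / 4 + 1 / 6)))
  expect_equal(mtI$p, 2 * pnorm(-abs(mtI$t_mod)))

  # degenerate rows
  dg <- moderated_t(c(0, 1), c(0, 0), 2, list(d0 = 0, s0_sq = 0), 2, 2)
  expect_equal(dg$p, c(1, 0))
  expect_identical(dg$degenerate, c(FALSE, TRUE))
})

test_that("pooled BH adjustment matches the hand step-up and is stable", {
  expect_equal(global_fdr(0.03), 0.03)
  expect_equal(global_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.02, 0.5, 0.04, 0.9)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(global_fdr(p)[perm], global_fdr(p[perm]))
  expect_error(global_fdr(c(0.5, 0)), "must lie in")
  expect_error(global_fdr(c(0.5, 1.2)), "must lie in")
})

test_that("per-comparison statistics agree with an independent limma fit", {
  set.seed(31)
  n_a <- 6L; n_b <- 8L
  sig2 <- 0.1 * (4 / rchisq(300, 4))
  vals <- matrix(rnorm(300 * (n_a + n_b), sd = sqrt(sig2)), 300)
  vals[1:30, 1:n_a] <- vals[1:30, 1:n_a] + 1
  dimnames(vals) <- list(sprintf("g%03d", 1:300),
                         c(sprintf("a%d", 1:n_a), sprintf("b%d", 1:n_b)))
  m <- expression_matrix(vals + 8)

  st <- gene_stats(m, sprintf("a%d", 1:n_a), sprintf("b%d", 1:n_b))
  pr <- estimate_prior(st$s2, st$df[1])
  mt <- moderated_t(st$delta, st$s2, st$df[1], pr, n_a, n_b)

  design <- cbind(1, rep(c(1, 0), c(n_a, n_b)))
  fit <- limma::eBayes(limma::lmFit(vals, design))
  expect_equal(pr$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(pr$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(mt$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(mt$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("the consensus rule demands fold, FDR and direction in EVERY comparison", {
  mk_table <- function(deltas, fdrs) {
    genes <- rownames(deltas)
    do.call(rbind, lapply(colnames(deltas), function(g) {
      data.frame(gene = genes, group = g, delta = deltas[, g],
                 fold = 2^deltas[, g], t_mod = 1, df_total = 10,
                 p = fdrs[, g], fdr = fdrs[, g], row.names = NULL)
    }))
  }
  lf <- log2(c(1.6, 1.4, 2.0))
  deltas <- rbind(up_all = log2(c(2, 2, 2)),
                  mixed = log2(c(2, 2, 0.5)),
                  fold_fail = lf,
                  down_all = -log2(c(2, 3, 2)))
  colnames(deltas) <- c("r1", "r2", "r3")
  fdrs <- matrix(0.01, 4, 3, dimnames = dimnames(deltas))

  sig <- consensus_signature(mk_table(deltas, fdrs))
  expect_identical(sort(sig$gene), c("down_all", "up_all"))
  expect_identical(sig$direction[match(c("up_all", "down_all"), sig$gene)],
                   c("up", "down"))

  up <- consensus_signature(mk_table(deltas, fdrs), direction = "up_only")
  expect_identical(up$gene, "up_all")

  # one failing FDR excludes
  fdrs2 <- fdrs; fdrs2["up_all", "r2"] <- 0.2
  expect_false("up_all" %in% consensus_signature(mk_table(deltas, fdrs2))$gene)

  # incomplete table is an error
  tab <- mk_table(deltas, fdrs)
  expect_error(consensus_signature(tab[-1, ]), "incomplete")

  # brute-force re-check of every reported gene on a synthetic table
  co <- small_cohort()
  g <- suppressMessages(collapse_probesets(co$expr, co$probeset_map))
  tab <- diffexp_table(g, co$samples)
  sig <- consensus_signature(tab, fdr_max = 0.1, fold_min = 1.5)
  for (gene in sig$gene) {
    rows <- tab[tab$gene == gene, ]
    expect_true(all(rows$fdr <= 0.1))
    expect_true(all(pmax(rows$fold, 1 / rows$fold) >= 1.5))
    expect_true(all(rows$delta > 0) || all(rows$delta < 0))
  }
  # and no gene failing the brute-force rule was reported
  pass <- vapply(unique(tab$gene), function(gene) {
    rows <- tab[tab$gene == gene, ]
    all(rows$fdr <= 0.1) && all(pmax(rows$fold, 1 / rows$fold) >= 1.5) &&
      (all(rows$delta > 0) || all(rows$delta < 0))
  }, TRUE)
  expect_setequal(sig$gene, unique(tab$gene)[pass])
})

test_that("fold versus pooled rest is exact on constructed inputs", {
  m <- toy_matrix(c(5, 5, 4, 4,
                    6, 6, 5, 5),
                  c("flat", "up1"), c("t1", "t2", "r1", "r2"))
  f <- fold_vs_rest(m, c("t1", "t2"))
  expect_equal(unname(f["flat"]), 2^1)
  expect_equal(unname(f["up1"]), 2.0)
  m2 <- toy_matrix(rep(3, 4), "g", c("t1", "t2", "r1", "r2"))
  expect_equal(unname(fold_vs_rest(m2, c("t1", "t2"))["g"]), 1.0)
  expect_error(fold_vs_rest(m, colnames(m)), "no non-target")

  # planted log2(96.9) effect at zero noise reproduces the fold exactly
  co <- small_cohort(zero_noise = TRUE, effect_range = log2(c(96.9, 96.9)),
                     n_drug_targets = 0L)
  g <- suppressMessages(collapse_probesets(co$expr, co$probeset_map))
  tgt <- co$samples$sample_id[co$samples$is_target]
  folds <- fold_vs_rest(g, tgt)[co$truth$signature$gene]
  expect_equal(unname(folds), rep(96.9, 20), tolerance = 1e-9)
})
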