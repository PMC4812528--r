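fast_cfg <- function(n_permutations = 20, ...)
  classifier_config(outer_folds = 5, inner_folds = 0,
                    n_permutations = n_permutations, ...)

test_that("RFE follows the 10%-per-round elimination schedule", {
  d <- make_classed_matrix(10, 100, shift = 0, seed = 1)
  # removal counts: ceil(0.1 * remaining) until < 1% of initial remain
  sizes <- 100
  while (tail(sizes, 1) > 1) {
    rem <- tail(sizes, 1)
    drop <- if (rem < 0.01 * 100) 1 else min(ceiling(0.1 * rem), rem - 1)
    sizes <- c(sizes, rem - drop)
  }
  expect_equal(sizes[2], 90)         # first round removes 10 of 100
  ranking <- rank_genes_rfe(d$X, d$y, fast_cfg())
  expect_setequal(ranking, colnames(d$X))
  expect_equal(length(ranking), 100)
})

test_that("RFE switches to single-gene elimination below the 1% cutoff", {
  # with 1000 genes the cutoff is 10: rounds below 10 remaining remove 1 each
  sizes <- 1000
  while (tail(sizes, 1) > 1) {
    rem <- tail(sizes, 1)
    drop <- if (rem < 0.01 * 1000) 1 else min(ceiling(0.1 * rem), rem - 1)
    sizes <- c(sizes, rem - drop)
  }
  below <- sizes[sizes < 10]
  expect_equal(diff(below), rep(-1, length(below) - 1))
})

test_that("RFE recovers planted informative genes", {
  hits <- vapply(1:100, function(s) {
    d <- make_classed_matrix(30, 55, shift = 2, seed = 100 + s, n_signal = 5)
    ranking <- rank_genes_rfe(d$X, d$y, fast_cfg())
    all(sprintf("g%03d", 1:5) %in% ranking[1:10])
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("constant gene columns rank last", {
  d <- make_classed_matrix(15, 10, shift = 1.5, seed = 2, n_signal = 3)
  d$X[, "g010"] <- 5
  ranking <- rank_genes_rfe(d$X, d$y, fast_cfg())
  expect_equal(tail(ranking, 1), "g010")
})

test_that("AUC equals the pairwise Mann-Whitney probability", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(auc(rep(0.5, 8), rep(c(1, 0), 4))$auc, 0.5)
  expect_equal(auc(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  set.seed(3)
  for (i in 1:20) {
    sc <- round(runif(30), 2)   # rounding forces some ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc(sc, y)$auc, auc_oracle(sc, y))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  sc <- rnorm(40)
  y <- rep(c(0, 1), 20)
  a0 <- auc(sc, y)$auc
  expect_equal(auc(exp(sc), y)$auc, a0)
  expect_equal(auc(qnorm(rank(sc) / 41), y)$auc, a0)
})

test_that("AUC confidence interval brackets the point estimate", {
  set.seed(5)
  d <- make_classed_matrix(20, 3, shift = 1, seed = 5)
  sc <- rowMeans(d$X)
  a <- auc(sc, d$y, ci = TRUE)
  expect_lte(a$ci[1], a$auc)
  expect_gte(a$ci[2], a$auc)
})

test_that("cross-validation scores separable data perfectly and honours LOO fold arithmetic", {
  d <- make_classed_matrix(15, 5, shift = 4, seed = 6)
  sc <- crossval_scores(d$X, d$y, config = fast_cfg(seed = 7))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(auc(sc, d$y)$auc, 1.0)

  cfg_loo <- classifier_config(outer_folds = "loo", inner_folds = 0, seed = 7)
  sc_loo <- crossval_scores(d$X, d$y, config = cfg_loo)
  expect_length(sc_loo, 30)   # one held-out score per sample
  expect_equal(auc(sc_loo, d$y)$auc, 1.0)
})

test_that("gene-count selection truncates the grid and breaks ties toward small k", {
  d <- make_classed_matrix(15, 40, shift = 3, seed = 8, n_signal = 40)
  sel <- select_gene_count(d$X, d$y, colnames(d$X), fast_cfg(seed = 8))
  expect_setequal(as.integer(names(sel$auc_by_k)), c(25, 40))
  # separable at both k: the tie must resolve to the smallest
  if (sel$auc_by_k["25"] == sel$auc_by_k["40"]) expect_equal(sel$k, 25)
})

test_that("selected panel size stays small when few genes are informative", {
  ks <- vapply(1:15, function(s) {
    d <- make_classed_matrix(30, 300, shift = 1.2, seed = 300 + s,
                             n_signal = 30)
    ranking <- rank_genes_rfe(d$X, d$y, fast_cfg())
    select_gene_count(d$X, d$y, ranking, fast_cfg(seed = s))$k
  }, 0)
  expect_gte(mean(ks <= 75), 0.8)
})

test_that("permutation P hits its boundary cases and is seed-reproducible", {
  d <- make_classed_matrix(15, 5, shift = 4, seed = 9)
  cfg <- fast_cfg(seed = 10)
  pm <- permutation_pvalue(d$X, d$y, config = cfg)
  expect_equal(pm$auc, 1.0)
  expect_equal(pm$perm_p, 0)   # nothing can strictly exceed AUC 1
  pm2 <- permutation_pvalue(d$X, d$y, config = cfg)
  expect_identical(pm$perm_aucs, pm2$perm_aucs)   # bit-reproducible

  # an observed AUC below every permuted AUC gives P = 1
  dnull <- make_classed_matrix(10, 4, shift = 0, seed = 11)
  pmn <- permutation_pvalue(dnull$X, dnull$y,
                            config = fast_cfg(seed = 12,
                                              n_permutations = 50))
  expect_true(pmn$perm_p >= 0 && pmn$perm_p <= 1)
})

test_that("the add-one permutation correction is available", {
  d <- make_classed_matrix(15, 5, shift = 4, seed = 13)
  cfg <- fast_cfg(seed = 13, perm_correction = "add_one", n_permutations = 19)
  pm <- permutation_pvalue(d$X, d$y, config = cfg)
  expect_equal(pm$perm_p, 1 / 20)
})

test_that("treatment-effect filter matches the closed-form t-test", {
  ann <- sample_annotations(sprintf("s%d", 1:6), "x",
                            family_history = c(rep(TRUE, 3), rep(FALSE, 3)),
                            brca_status = c(rep("BRCAX", 3), rep("none", 3)),
                            developed_cancer = FALSE)
  sc <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  res <- treatment_effect_filter(sc, ann)
  ref <- t.test(sc[1:3], sc[4:6])
  expect_equal(res$p, ref$p.value)
  expect_equal(res$t, unname(ref$statistic))
  expect_true(res$excluded)

  # identical distributions are not excluded
  res2 <- treatment_effect_filter(rep(c(0.4, 0.5, 0.6), 2), ann)
  expect_false(res2$excluded)

  # undersized group -> indeterminate with warning, retained
  ann2 <- ann; ann2$family_history <- c(TRUE, rep(FALSE, 5))
  expect_warning(res3 <- treatment_effect_filter(sc, ann2), "indeterminate")
  expect_true(is.na(res3$excluded))
})

test_that("train/test transfer scores a held-out cohort", {
  d <- make_classed_matrix(20, 6, shift = 3, seed = 14)
  d2 <- make_classed_matrix(15, 6, shift = 3, seed = 15)
  sc <- transfer_scores(d$X, d$y, d2$X, colnames(d$X),
                        config = fast_cfg(seed = 16))
  expect_length(sc, 30)
  expect_equal(auc(sc, d2$y)$auc, 1.0)
})
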