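test_that("rank-consistency P centres at 0.5 and reduces to the percentile at m = 1", {
  # a pathway exactly in the middle of every data set
  pm <- matrix(rep(seq(0.01, 0.99, length.out = 99), 4), 99, 4)
  rownames(pm) <- sprintf("P%02d", 1:99)
  rc <- rank_consistency_p(pm)
  expect_equal(rc$rank_p[50], 0.5)

  # single data set: P equals the scaled rank
  pm1 <- matrix(c(0.001, 0.5, 0.9), 3, 1)
  rc1 <- rank_consistency_p(pm1)
  expect_equal(rc1$rank_p, (rank(pm1[, 1]) - 0.5) / 3)
})

test_that("rank-consistency is invariant to monotone transforms of per-dataset P", {
  set.seed(41)
  pm <- matrix(runif(200), 50, 4)
  r1 <- rank_consistency_p(pm)$rank_p
  r2 <- rank_consistency_p(pm^3)$rank_p        # strictly monotone
  r3 <- rank_consistency_p(1 - exp(-pm))$rank_p
  expect_equal(r1, r2)
  expect_equal(r1, r3)
})

test_that("the exact tail agrees with a Monte-Carlo oracle where the normal approximation fails", {
  # top-ranked in all 5 of 100 data sets: mean scaled rank = 0.005
  thr <- 0.005
  p_exact <- pathrisk:::irwin_hall_cdf(5 * thr, 5)
  p_mc <- uniform_mean_tail_mc(thr, 5, n_draws = 1e6)
  se <- sqrt(max(p_exact, 1e-12) * (1 - p_exact) / 1e6)
  expect_lte(abs(p_mc - p_exact), 3 * se + 1e-12)
  # and at a moderate quantile both the MC and the exact agree
  thr2 <- 0.35
  p2 <- pathrisk:::irwin_hall_cdf(5 * thr2, 5)
  p2_mc <- uniform_mean_tail_mc(thr2, 5)
  expect_lte(abs(p2 - p2_mc), 3 * sqrt(p2 * (1 - p2) / 1e6))
  # the normal approximation is close in the body but not in the deep tail
  rc_norm <- stats::pnorm(thr2, 0.5, sqrt(1 / 60))
  expect_lt(abs(rc_norm - p2), 0.01)
})

test_that("P-value combination closed forms are exact and reduce to identity at m = 1", {
  expect_equal(combine_p(c(0.5, 0.5), "fisher"), 0.5966, tolerance = 1e-4)
  expect_equal(combine_p(c(0.01, 0.8, 0.9), "wilkinson_min"), 0.0297,
               tolerance = 1e-4)
  for (m in c("fisher", "wilkinson_min", "sum_p"))
    expect_equal(combine_p(0.37, m), 0.37)
  # sum_p at an easy closed form: P(U1 + U2 <= 1) = 0.5
  expect_equal(combine_p(c(0.5, 0.5), "sum_p"), 0.5)
  expect_warning(combine_p(c(0, 0.5), "fisher"), "clamped")
})

test_that("Storey q-values are monotone, bounded by BH, with a sane null pi0", {
  set.seed(42)
  ps <- runif(1000)
  res <- storey_qvalues(ps)
  expect_gte(res$pi0, 0.85)
  expect_lte(res$pi0, 1.0)
  o <- order(ps)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  bh <- p.adjust(ps, "BH")
  expect_true(all(res$q <= bh + 1e-12))
  # degenerate identical Ps
  resd <- suppressWarnings(storey_qvalues(rep(0.2, 20)))
  expect_equal(resd$pi0, 1)
})

test_that("candidate selection funnel is monotone and respects flags", {
  ev <- data.frame(pathway = sprintf("P%d", 1:5),
                   rank_p = c(0.04, 0.04, 0.2, 0.001, NA),
                   treatment_effect = c(FALSE, TRUE, FALSE, FALSE, FALSE),
                   brca_subgroup = c(FALSE, FALSE, FALSE, TRUE, NA))
  sel <- select_candidate_pathways(ev, alpha = 0.05)
  expect_equal(sel$candidates$pathway, "P1")
  expect_equal(unname(sel$funnel), c(5L, 3L, 2L, 1L))
  expect_true(all(diff(sel$funnel) <= 0))
  empty <- select_candidate_pathways(ev[0, ], alpha = 0.05)
  expect_equal(unname(empty$funnel), rep(0L, 4))
})

test_that("mutation-expression concordance matches direct Spearman and skips constants", {
  sm <- sprintf("s%02d", 1:10)
  expr <- matrix(rnorm(20), 10, 2, dimnames = list(sm, c("G1", "G2")))
  expr[1:3, "G1"] <- expr[1:3, "G1"] + 10   # mutated samples are the top 3
  gm <- matrix(0L, 10, 2, dimnames = list(sm, c("G1", "G2")))
  gm[1:3, "G1"] <- 1L
  gm <- structure(gm, level = "gene", class = c("mutation_matrix", class(gm)))
  res <- mutation_expression_concordance(expr, gm)
  direct <- cor(gm[, "G1"], expr[, "G1"], method = "spearman")
  expect_equal(res$results$rho[res$results$gene == "G1"], direct)
  expect_false("G2" %in% res$results$gene)   # constant mutation vector
  expect_equal(res$n_skipped_constant, 1)
})

test_that("concordance selection is rare under a fully null simulation", {
  set.seed(43)
  n <- 40; G <- 2000
  sm <- sprintf("s%03d", 1:n)
  expr <- matrix(rnorm(n * G), n, dimnames = list(sm, sprintf("g%04d", 1:G)))
  gm <- matrix(rbinom(n * G, 1, 0.15), n,
               dimnames = list(sm, sprintf("g%04d", 1:G)))
  gm <- structure(gm, level = "gene", class = c("mutation_matrix", class(gm)))
  res <- mutation_expression_concordance(expr, gm, fdr_cutoff = 0.2)
  expect_lt(mean(res$results$selected), 0.01)
})
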