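small_sim <- function(...) simulation_config(n_pathways = 10,
                                             pathway_size_range = c(6, 10),
                                             n_causal_pathways = 2,
                                             n_cases = 12, n_controls_fh = 12,
                                             n_controls_nofh = 6, ...)

test_that("expression generator is deterministic and seed-sensitive", {
  cfg <- small_sim()
  a <- simulate_expression_cohort(cfg, "c", seed = 5)
  b <- simulate_expression_cohort(cfg, "c", seed = 5)
  expect_identical(a$expr, b$expr)
  c_ <- simulate_expression_cohort(cfg, "c", seed = 6)
  expect_false(identical(a$expr, c_$expr))
})

test_that("strata counts follow the configured design deterministically", {
  cfg <- small_sim()
  a <- simulate_expression_cohort(cfg, "c", seed = 5)
  ann <- a$annotations
  expect_equal(sum(ann$family_history & ann$developed_cancer), 12)
  expect_equal(sum(ann$family_history & !ann$developed_cancer), 12)
  expect_equal(sum(!ann$family_history), 6)
  expect_equal(sum(!ann$family_history & ann$developed_cancer), 3)
  expect_equal(sum(ann$brca_status == "carrier"),
               2 * round(0.4 * 12))
  # repeated generation gives identical strata (allocation, not sampling)
  b <- simulate_expression_cohort(cfg, "c", seed = 99)
  expect_identical(a$annotations[, -1], b$annotations[, -1])
})

test_that("planted expression signal drives causal-pathway separability", {
  cfg <- small_sim(effect_size = 2, causal_gene_fraction = 0.5)
  a <- simulate_expression_cohort(cfg, "c", seed = 7)
  fh <- a$annotations$family_history
  y <- as.integer(a$annotations$developed_cancer[fh])
  ccfg <- classifier_config(outer_folds = 5, inner_folds = 0, seed = 7)
  pw_causal <- a$truth$causal_pathways[1]
  pw_null <- setdiff(names(a$collection), a$truth$causal_pathways)[1]
  auc_c <- auc(crossval_scores(a$expr[fh, a$collection$sets[[pw_causal]]],
                               y, config = ccfg, calibrate = FALSE), y)$auc
  auc_n <- auc(crossval_scores(a$expr[fh, a$collection$sets[[pw_null]]],
                               y, config = ccfg, calibrate = FALSE), y)$auc
  expect_gt(auc_c, 0.85)
  expect_lt(auc_n, 0.85)
})

test_that("a zero effect size leaves pathway AUCs at chance level", {
  cfg <- simulation_config(n_pathways = 30, pathway_size_range = c(6, 10),
                           n_causal_pathways = 0, effect_size = 0,
                           n_cases = 20, n_controls_fh = 20,
                           n_controls_nofh = 4)
  a <- simulate_expression_cohort(cfg, "c", seed = 8)
  fh <- a$annotations$family_history
  y <- as.integer(a$annotations$developed_cancer[fh])
  ccfg <- classifier_config(outer_folds = 2, inner_folds = 0, seed = 8)
  aucs <- vapply(names(a$collection), function(pw)
    auc(crossval_scores(a$expr[fh, a$collection$sets[[pw]]], y,
                        config = ccfg, calibrate = FALSE), y)$auc, 0)
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
})

test_that("variant generator plants case enrichment and cascade decoys", {
  cfg <- small_sim(mutation_rate_causal_cases = 0.6,
                   mutation_rate_causal_controls = 0.05)
  vt <- simulate_variant_table(cfg, seed = 9)
  expect_s3_class(vt$variants, "annotated_variants")
  res <- filter_variants(vt$variants, length(vt$sample_ids))
  # every decoy rule sees its configured number of failures
  expect_true(all(res$exclusions >= cfg$n_decoys_per_rule))
  # ground truth is sufficient to score recovery
  expect_named(vt$truth, c("causal_pathways", "pathway_carrier", "is_case",
                           "frequent_genes", "expected_threshold"))
  gm <- collapse_to_genes(res$retained, vt$sample_ids)
  pm <- collapse_to_pathways(gm, vt$collection)
  rate_case <- mean(pm[vt$truth$is_case, vt$truth$causal_pathways])
  rate_ctrl <- mean(pm[!vt$truth$is_case, vt$truth$causal_pathways])
  expect_gt(rate_case, rate_ctrl)
})

test_that("threshold selection recovers the constructed frequency breakpoint", {
  vt <- simulate_variant_table(small_sim(), seed = 10)
  sel <- select_frequency_threshold(vt$background_gene_freqs)
  expect_equal(sel$threshold, vt$truth$expected_threshold)
})

test_that("fluorescence generator is deterministic with coherent ground truth", {
  cfg <- simulation_config()
  a <- simulate_fluorescence_field(cfg, "clustered_small", seed = 11)
  b <- simulate_fluorescence_field(cfg, "clustered_small", seed = 11)
  expect_identical(a$field$nuclei, b$field$nuclei)
  expect_equal(nrow(a$truth$centers), a$truth$n_nuclei)
  expect_true(a$truth$cell_area_fraction > 0 &&
                a$truth$cell_area_fraction < 1)
  d <- simulate_fluorescence_field(cfg, "dispersed_large", seed = 11)
  # dispersed centers are farther apart than clustered ones
  expect_gt(mean(nearest_nucleus_distances(d$truth$centers)),
            mean(nearest_nucleus_distances(a$truth$centers)))
})
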