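#' Pipeline configuration
#'
#' Bundles every stage configuration and the study-wide thresholds: the
#' rank-consistency significance level, the exclusion-filter level
#' (treatment-effect and BRCA-subgroup t-tests / exact tests), the
#' covariate-confounding screen level, and the concordance local-FDR cutoff.
#' Threshold defaults are the published values.
#'
#' @param sim A [simulation_config()] describing the synthetic cohorts.
#' @param classifier A [classifier_config()].
#' @param variant A [variant_filter_config()].
#' @param alpha_rank Rank-consistency candidate threshold (0.05).
#' @param alpha_filter Exclusion-filter threshold (0.05).
#' @param alpha_ancova Covariate-confounding screen threshold (0.01).
#' @param fdr_cutoff Mutation-expression concordance local-FDR cutoff (0.2).
#' @param seed Master seed; fans out to per-stage child seeds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            classifier = classifier_config(),
                            variant = variant_filter_config(),
                            alpha_rank = 0.05, alpha_filter = 0.05,
                            alpha_ancova = 0.01, fdr_cutoff = 0.2,
                            seed = 1L) {
  stopifnot(alpha_rank > 0, alpha_rank <= 1, alpha_filter > 0,
            alpha_filter < 1, alpha_ancova > 0, alpha_ancova < 1)
  structure(list(sim = sim, classifier = classifier, variant = variant,
                 alpha_rank = alpha_rank, alpha_filter = alpha_filter,
                 alpha_ancova = alpha_ancova, fdr_cutoff = fdr_cutoff,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Compare evidence between BRCA1/2 carriers and BRCAX women per pathway.
# The exclusion flag comes from the unconditional exact test applied once in
# each direction on pathway mutation status (flagged when either direction
# attains P < alpha); a two-sided t-test on expression-based pathway scores
# is reported alongside for inspection but does not flag by default.
brca_subgroup_flag <- function(scores, annotations, pathway_matrix,
                               seq_annotations, alpha = 0.05) {
  fh <- annotations$family_history
  carrier <- annotations$brca_status == "carrier"
  pw <- colnames(scores)
  expr_p <- vapply(pw, function(p) {
    x <- scores[fh & carrier, p]
    y <- scores[fh & !carrier, p]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
  }, 0)
  mut_p <- rep(NA_real_, length(pw))
  names(mut_p) <- pw
  if (!is.null(pathway_matrix)) {
    lab <- factor(ifelse(seq_annotations$brca_status == "carrier",
                         "carrier", "BRCAX"), levels = c("BRCAX", "carrier"))
    shared <- intersect(pw, colnames(pathway_matrix))
    if (length(shared) > 0 && nlevels(droplevels(lab)) == 2) {
      assoc <- pathway_mutation_association(
        pathway_matrix[, shared, drop = FALSE], lab, mode = "each-direction")
      mut_p[shared] <- pmin(assoc$p, assoc$p_reverse)
    }
  }
  flagged <- !is.na(mut_p) & mut_p < alpha
  data.frame(pathway = pw, expr_subgroup_p = expr_p, mut_subgroup_p = mut_p,
             brca_subgroup = flagged, stringsAsFactors = FALSE)
}

#' Run the integrative pathway susceptibility pipeline end-to-end
#'
#' Executes the full design on synthetic cohorts generated from the
#' configuration: (1) simulate two expression cohorts and a germline variant
#' table with shared pathway structure; (2) screen out covariate-confounded
#' genes; (3) restrict pathways to the surviving expression universe;
#' (4) per-pathway SVM classification with permutation P in each cohort,
#' with the treatment-effect filter computed from family-history controls
#' versus non-family-history women; (5) the variant filtering cascade,
#' frequent-gene threshold selection and exclusion, pathway collapsing, and
#' one-sided unconditional exact tests; (6) BRCA-subgroup exclusion flags;
#' (7) rank-consistency combination across the per-dataset P-values plus the
#' alternative combiners and Storey q-values; (8) the candidate funnel; and
#' (9) mutation-expression concordance.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, [write_report()] is called.
#' @return A list of class `pipeline_result`: `evidence` (per-pathway table),
#'   `candidates`, `funnel`, `screens` (per-cohort classification tables),
#'   `mutation` (association table), `concordance`, `exclusions`
#'   (cascade counts), `threshold` (selected frequent-gene threshold),
#'   `ancova_blacklist`, `truth` (generator ground truth), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  simc <- config$sim
  simc$seed <- config$seed

  cohA <- simulate_expression_cohort(simc, "cohortA",
                                     seed = child_seed(config$seed, "cohA"))
  cohB <- simulate_expression_cohort(simc, "cohortB",
                                     seed = child_seed(config$seed, "cohB"))
  vt <- simulate_variant_table(simc, annotations = cohA$annotations,
                               seed = child_seed(config$seed, "seq"))

  # covariate-confounding screen on cohort A's surveyed subset
  anc <- exclude_confounded_genes(cohA$expr, cohA$covariates,
                                  alpha = config$alpha_ancova)
  universe <- setdiff(colnames(cohA$expr), anc$blacklist)
  collection <- restrict_to_universe(cohA$collection, universe,
                                     min_size = 5)

  screen_cohort <- function(coh, label) {
    fh <- coh$annotations$family_history
    labels <- factor(as.integer(coh$annotations$developed_cancer[fh]),
                     levels = c(0, 1))
    cc <- config$classifier
    cc$seed <- child_seed(config$seed, label)
    scr <- classify_pathways(coh$expr[fh, universe, drop = FALSE], labels,
                             collection, cc)
    # per-sample scores for all women: cross-validated for the
    # family-history samples, transferred for the rest
    panels <- attr(scr, "panels")
    nofh <- !fh
    all_scores <- matrix(NA_real_, nrow(coh$expr), nrow(scr),
                         dimnames = list(coh$annotations$sample_id,
                                         scr$pathway))
    all_scores[fh, ] <- attr(scr, "scores")
    for (p in scr$pathway)
      all_scores[nofh, p] <- transfer_scores(
        coh$expr[fh, universe, drop = FALSE], labels,
        coh$expr[nofh, universe, drop = FALSE], panels[[p]], config = cc)
    attr(scr, "all_scores") <- all_scores
    scr
  }
  scrA <- screen_cohort(cohA, "screenA")
  scrB <- screen_cohort(cohB, "screenB")

  # treatment-effect filter: one test per pathway, with every sample scored
  # by the SAME model (trained on cohort A's family-history women) so the
  # two comparison groups are calibrated identically: test-cohort
  # family-history women without cancer vs all women without a family
  # history
  fhA <- cohA$annotations$family_history
  labelsA <- factor(as.integer(cohA$annotations$developed_cancer[fhA]),
                    levels = c(0, 1))
  ccA <- config$classifier
  ccA$seed <- child_seed(config$seed, "screenA")
  panelsA <- attr(scrA, "panels")
  held_out <- rbind(cohB$annotations,
                    cohA$annotations[!fhA, , drop = FALSE])
  held_expr <- rbind(cohB$expr[, universe, drop = FALSE],
                     cohA$expr[!fhA, universe, drop = FALSE])
  for (p in scrA$pathway) {
    sc <- transfer_scores(cohA$expr[fhA, universe, drop = FALSE], labelsA,
                          held_expr, panelsA[[p]], config = ccA)
    tf <- treatment_effect_filter(sc, held_out,
                                  alpha = config$alpha_filter)
    scrA[scrA$pathway == p, "treatment_p"] <- tf$p
    scrA[scrA$pathway == p, "excluded_by_treatment_filter"] <- tf$excluded
  }

  # variant cascade and pathway mutation association
  filt <- filter_variants(vt$variants, length(vt$sample_ids), config$variant)
  gm <- collapse_to_genes(filt$retained, vt$sample_ids)
  thr <- select_frequency_threshold(vt$background_gene_freqs,
                                    grid = config$variant$freq_gene_grid,
                                    n_points = config$variant$freq_gene_grid_points)
  gm2 <- exclude_frequent_genes(gm, vt$background_gene_freqs, thr$threshold,
                                config$variant$always_keep_genes)
  pm <- collapse_to_pathways(gm2, collection)
  mut_lab <- factor(as.integer(vt$truth$is_case), levels = c(0, 1))
  assoc <- pathway_mutation_association(pm, mut_lab)

  # BRCA subgroup flags from cohort A scores and the mutation matrix
  subgroup <- brca_subgroup_flag(attr(scrA, "all_scores"), cohA$annotations,
                                 pm, vt$annotations,
                                 alpha = config$alpha_filter)

  # combine evidence across the three data sets
  pwn <- scrA$pathway
  p_matrix <- cbind(cohortA = scrA$perm_p,
                    cohortB = scrB$perm_p[match(pwn, scrB$pathway)],
                    mutation = assoc$p[match(pwn, assoc$pathway)])
  rownames(p_matrix) <- pwn
  rc <- rank_consistency_p(p_matrix)
  clamp <- function(p) pmax(p, .Machine$double.xmin)
  alt <- t(apply(p_matrix, 1, function(ps) {
    ps <- clamp(ps[!is.na(ps)])
    c(fisher = combine_p(ps, "fisher"),
      wilkinson_min = combine_p(ps, "wilkinson_min"),
      sum_p = combine_p(ps, "sum_p"))
  }))
  qv <- storey_qvalues(rc$rank_p)

  evidence <- data.frame(
    pathway = pwn,
    p_cohortA = p_matrix[, "cohortA"],
    p_cohortB = p_matrix[, "cohortB"],
    p_mutation = p_matrix[, "mutation"],
    rank_p = rc$rank_p,
    fisher_p = alt[, "fisher"],
    wilkinson_p = alt[, "wilkinson_min"],
    sum_p = alt[, "sum_p"],
    q_value = qv$q,
    treatment_effect = scrA$excluded_by_treatment_filter,
    treatment_p = scrA$treatment_p,
    expr_subgroup_p = subgroup$expr_subgroup_p[match(pwn, subgroup$pathway)],
    brca_subgroup = subgroup$brca_subgroup[match(pwn, subgroup$pathway)],
    missing_in_dataset = rowSums(is.na(p_matrix)) > 0,
    stringsAsFactors = FALSE)
  rownames(evidence) <- NULL

  sel <- select_candidate_pathways(evidence, alpha = config$alpha_rank)

  conc <- mutation_expression_concordance(
    cohA$expr[vt$sample_ids, , drop = FALSE], gm2,
    fdr_cutoff = config$fdr_cutoff)

  out <- structure(list(
    evidence = evidence, candidates = sel$candidates, funnel = sel$funnel,
    screens = list(cohortA = scrA, cohortB = scrB), mutation = assoc,
    concordance = conc, exclusions = filt$exclusions,
    threshold = thr$threshold, ancova_blacklist = anc$blacklist,
    truth = list(causal_pathways = cohA$truth$causal_pathways,
                 variant_truth = vt$truth),
    config = config), class = "pipeline_result")
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' Write pipeline artifacts
#'
#' Writes the evidence and candidate tables, the mutation association table,
#' the concordance table (TSV, stable column order, fixed float precision),
#' and a JSON report containing the funnel counts, cascade exclusion counts,
#' the selected frequent-gene threshold, and a provenance block (seed,
#' thresholds, package and R versions).
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(d) {
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], function(x) signif(x, 8))
    d
  }
  write_tsv_table(fmt(result$evidence), file.path(out_dir, "evidence.tsv"))
  write_tsv_table(fmt(result$candidates), file.path(out_dir, "candidates.tsv"))
  write_tsv_table(fmt(result$mutation), file.path(out_dir, "mutation.tsv"))
  if (!is.null(result$concordance$results))
    write_tsv_table(fmt(result$concordance$results),
                    file.path(out_dir, "concordance.tsv"))
  cfg <- result$config
  report <- list(
    schema_version = "1.0",
    funnel = as.list(result$funnel),
    cascade_exclusions = as.list(result$exclusions),
    frequent_gene_threshold = result$threshold,
    n_ancova_blacklisted = length(result$ancova_blacklist),
    provenance = list(
      seed = cfg$seed,
      alpha_rank = cfg$alpha_rank, alpha_filter = cfg$alpha_filter,
      alpha_ancova = cfg$alpha_ancova, fdr_cutoff = cfg$fdr_cutoff,
      package_version = as.character(utils::packageVersion("pathrisk")),
      r_version = R.version.string))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
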