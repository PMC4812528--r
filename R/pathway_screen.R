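#' Screen every pathway with the SVM classifier
#'
#' For each gene set: rank member genes by RFE, select the best panel size on
#' the gene-count grid, compute cross-validated per-sample scores and AUC,
#' and (optionally) a label-permutation empirical P-value and the
#' treatment-effect exclusion flag.
#'
#' @param expr Numeric matrix, samples x genes.
#' @param labels Binary labels for the classification contrast (within the
#'   family-history subgroup: developed cancer vs not).
#' @param collection A [gene_set_collection()], already restricted to the
#'   expression universe.
#' @param config A [classifier_config()].
#' @param annotations Optional [sample_annotations()] aligned with rows of
#'   `expr`; enables the treatment-effect filter (which uses all samples,
#'   scoring non-family-history samples with [transfer_scores()]).
#' @param permutations Compute permutation P-values (default TRUE).
#' @return A data.frame of class `pathway_screen` with one row per pathway:
#'   `pathway`, `size`, `k`, `auc`, `ci_low`, `ci_high`, `perm_p`,
#'   `treatment_p`, `excluded_by_treatment_filter`. The per-sample score
#'   matrix is attached as attribute `"scores"`.
#' @export
classify_pathways <- function(expr, labels, collection,
                              config = classifier_config(),
                              annotations = NULL, permutations = TRUE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  y <- as_binary_factor(labels)
  pw <- names(collection)
  res <- vector("list", length(pw))
  panels <- vector("list", length(pw))
  names(panels) <- pw
  scores <- matrix(NA_real_, nrow = nrow(expr), ncol = length(pw),
                   dimnames = list(rownames(expr), pw))
  for (i in seq_along(pw)) {
    genes <- intersect(collection$sets[[i]], colnames(expr))
    Xp <- expr[, genes, drop = FALSE]
    ranked <- rank_genes_rfe(Xp, y, config)
    sel <- select_gene_count(Xp, y, ranked, config)
    panels[[i]] <- ranked[seq_len(sel$k)]
    sc <- crossval_scores(Xp, y, ranked, sel$k, config, calibrate = TRUE)
    scores[, i] <- sc
    a <- auc(sc, y, ci = TRUE)
    pp <- NA_real_
    if (permutations) {
      pm <- permutation_pvalue(Xp, y, ranked, sel$k, config)
      pp <- pm$perm_p
    }
    tf <- list(excluded = NA, p = NA_real_)
    if (!is.null(annotations))
      tf <- treatment_effect_filter(sc, annotations)
    res[[i]] <- data.frame(pathway = pw[i], size = length(genes), k = sel$k,
                           auc = a$auc, ci_low = a$ci[1], ci_high = a$ci[2],
                           perm_p = pp, treatment_p = tf$p,
                           excluded_by_treatment_filter = tf$excluded,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "scores") <- scores
  attr(out, "panels") <- panels
  class(out) <- c("pathway_screen", "data.frame")
  out
}

#' Score held-out samples with a model trained on another cohort
#'
#' Train/test transfer: fits the RBF SVM on the full training cohort (genes
#' z-scored by training statistics, cost tuned by inner CV on the training
#' cohort) and scores the test samples.
#'
#' @param expr_train,labels_train Training cohort matrix and labels.
#' @param expr_test Test cohort matrix (same gene columns available).
#' @param genes Ordered gene ranking from the training cohort.
#' @param k Panel size (selected on the training cohort).
#' @param config A [classifier_config()].
#' @param calibrate Return Platt-calibrated probabilities (default TRUE).
#' @return Numeric scores for the test samples.
#' @export
transfer_scores <- function(expr_train, labels_train, expr_test,
                            genes, k = length(genes),
                            config = classifier_config(), calibrate = TRUE) {
  y <- as_binary_factor(labels_train)
  panel <- genes[seq_len(k)]
  sc <- scale_by_train(expr_train[, panel, drop = FALSE],
                       expr_test[, panel, drop = FALSE])
  gamma <- median_heuristic_gamma(sc$train)
  cost <- tune_cost(sc$train, y, gamma, config,
                    child_seed(config$seed, "transfer"))
  if (calibrate) svm_probability(sc$train, y, sc$test, cost, gamma)
  else svm_decision(sc$train, y, sc$test, cost, gamma)
}
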