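#' Classifier configuration
#'
#' Bundles every tunable of the per-pathway classification stage: an RBF-kernel
#' SVM whose cost parameter is tuned by nested cross-validation, applied to the
#' top-k genes ranked by linear-SVM recursive feature elimination (RFE), with
#' an AUC permutation null.
#'
#' @param c_grid Candidate SVM cost values for nested tuning.
#' @param outer_folds Number of outer CV folds (10), or `"loo"` for
#'   leave-one-out.
#' @param inner_folds Inner folds for cost tuning (5). Set to 0 to skip tuning
#'   and use `c_fixed`.
#' @param c_fixed Cost used when tuning is disabled.
#' @param gene_count_grid Gene-panel sizes evaluated when selecting k
#'   (25, 50, ..., 300).
#' @param rfe_fraction Fraction of remaining genes removed per RFE round (0.10).
#' @param rfe_single_gene_cutoff When fewer than this fraction of the initial
#'   genes remain, RFE removes exactly one gene per round (0.01).
#' @param n_permutations Label permutations for the empirical P (1000).
#' @param perm_refit Re-run RFE and k-selection inside each permutation
#'   (default FALSE: the observed gene panel is reused).
#' @param perm_correction `"none"` reports the plain fraction of permuted AUCs
#'   exceeding the observed (can be 0); `"add_one"` reports (r+1)/(B+1).
#' @param perm_scheme `"within_fold"` (default) permutes labels within each
#'   cross-validation fold, preserving the stratified design exactly — an
#'   exact conditional permutation test that also permits fold-level
#'   precomputation; `"global"` reshuffles all labels and re-stratifies the
#'   folds per permutation.
#' @param seed Integer seed controlling fold assignment and permutations.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(c_grid = c(0.01, 0.1, 1, 10, 100),
                              outer_folds = 10,
                              inner_folds = 5,
                              c_fixed = 1,
                              gene_count_grid = seq(25, 300, by = 25),
                              rfe_fraction = 0.10,
                              rfe_single_gene_cutoff = 0.01,
                              n_permutations = 1000,
                              perm_refit = FALSE,
                              perm_correction = c("none", "add_one"),
                              perm_scheme = c("within_fold", "global"),
                              seed = 1L) {
  stopifnot(all(c_grid > 0),
            rfe_fraction > 0, rfe_fraction < 1,
            rfe_single_gene_cutoff > 0, rfe_single_gene_cutoff < 1,
            n_permutations >= 1,
            all(diff(gene_count_grid) > 0))
  structure(list(c_grid = c_grid, outer_folds = outer_folds,
                 inner_folds = inner_folds, c_fixed = c_fixed,
                 gene_count_grid = gene_count_grid,
                 rfe_fraction = rfe_fraction,
                 rfe_single_gene_cutoff = rfe_single_gene_cutoff,
                 n_permutations = n_permutations,
                 perm_refit = perm_refit,
                 perm_correction = match.arg(perm_correction),
                 perm_scheme = match.arg(perm_scheme),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# Coerce labels to a 0/1 factor; the positive class (scored high) is the
# second level.
as_binary_factor <- function(labels) {
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must contain exactly two classes")
  y
}

# z-score columns by training statistics; zero-variance columns become zero.
scale_by_train <- function(Xtr, Xte = NULL) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       test = if (is.null(Xte)) NULL
              else sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
}

# RBF bandwidth by the median heuristic: gamma = 1 / median squared pairwise
# Euclidean distance of the (scaled) training rows.
median_heuristic_gamma <- function(X) {
  d2 <- stats::dist(X)^2
  med <- stats::median(d2)
  if (!is.finite(med) || med <= 0) return(1 / max(1, ncol(X)))
  1 / med
}

# Fit an RBF SVM on (Xtr, ytr) and return decision values for Xte oriented so
# that larger values favour the positive (second) class.
svm_decision <- function(Xtr, ytr, Xte, cost, gamma) {
  m <- e1071::svm(Xtr, ytr, kernel = "radial", cost = cost, gamma = gamma,
                  scale = FALSE, fitted = FALSE)
  pr <- stats::predict(m, Xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pos <- levels(ytr)[2]
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (identical(first, pos)) as.numeric(dv) else -as.numeric(dv)
}

# Platt-style calibrated probability of the positive class: a sigmoid
# (logistic regression) mapping decision values to [0,1], fitted on the
# training fold only. Monotone, so AUC is unchanged relative to raw decision
# values; complete separation simply saturates the sigmoid.
svm_probability <- function(Xtr, ytr, Xte, cost, gamma) {
  m <- e1071::svm(Xtr, ytr, kernel = "radial", cost = cost, gamma = gamma,
                  scale = FALSE, fitted = FALSE)
  orient <- function(pr) {
    dv <- attr(pr, "decision.values")
    first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    if (identical(first, levels(ytr)[2])) as.numeric(dv) else -as.numeric(dv)
  }
  dv_tr <- orient(stats::predict(m, Xtr, decision.values = TRUE))
  dv_te <- orient(stats::predict(m, Xte, decision.values = TRUE))
  y01 <- as.integer(ytr == levels(ytr)[2])
  fit <- suppressWarnings(
    stats::glm(y01 ~ dv, family = stats::binomial(),
               data = data.frame(y01 = y01, dv = dv_tr)))
  as.numeric(suppressWarnings(
    stats::predict(fit, data.frame(dv = dv_te), type = "response")))
}

# Pick the SVM cost by inner stratified cross-validation on the training fold,
# maximizing inner CV AUC of decision values. Ties go to the smaller cost.
tune_cost <- function(Xtr, ytr, gamma, config, seed) {
  if (config$inner_folds < 2 || length(config$c_grid) == 1)
    return(config$c_fixed)
  k <- min(config$inner_folds, min(table(ytr)))
  if (k < 2) return(config$c_fixed)
  fold <- stratified_folds(ytr, k, seed)
  aucs <- vapply(config$c_grid, function(cc) {
    sc <- numeric(length(ytr))
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(ytr[tr])) < 2) return(NA_real_)
      sc[!tr] <- svm_decision(Xtr[tr, , drop = FALSE], droplevels(ytr[tr]),
                              Xtr[!tr, , drop = FALSE], cc, gamma)
    }
    auc(sc, ytr)$auc
  }, 0)
  if (all(is.na(aucs))) return(config$c_fixed)
  config$c_grid[which.max(aucs)]
}

#' Rank pathway genes by SVM recursive feature elimination
#'
#' Repeatedly fits a linear max-margin model on the remaining genes, scores
#' each gene by its squared weight, and removes the lowest-scoring
#' `ceil(rfe_fraction * remaining)` genes; once fewer than
#' `rfe_single_gene_cutoff` of the initial genes remain, exactly one gene is
#' removed per round. The reversed elimination order is the ranking. Gene
#' ranking is linear even though final classification uses the RBF kernel,
#' which has no per-gene weight.
#'
#' @param X Numeric matrix, samples x genes (colnames = gene symbols).
#' @param labels Binary class labels.
#' @param config A [classifier_config()].
#' @return Character vector of gene names, most informative first.
#' @export
rank_genes_rfe <- function(X, labels, config = classifier_config()) {
  y <- as_binary_factor(labels)
  if (ncol(X) < 2) stop("RFE needs at least 2 genes")
  if (min(table(y)) < 2) stop("RFE needs at least 2 samples per class")
  X <- scale_by_train(X)$train
  n_init <- ncol(X)
  remaining <- colnames(X)
  removed <- character(0)
  while (length(remaining) > 1) {
    m <- e1071::svm(X[, remaining, drop = FALSE], y, kernel = "linear",
                    cost = config$c_fixed, scale = FALSE, fitted = FALSE)
    w <- as.numeric(crossprod(m$coefs, m$SV))
    score <- w^2
    n_rem <- length(remaining)
    n_drop <- if (n_rem < config$rfe_single_gene_cutoff * n_init) 1L
              else min(ceiling(config$rfe_fraction * n_rem), n_rem - 1L)
    # worst first; ties broken toward removing later columns first
    ord <- order(score, -seq_along(score))
    drop_idx <- ord[seq_len(n_drop)]
    removed <- c(removed, remaining[drop_idx])
    remaining <- remaining[-drop_idx]
  }
  c(remaining, rev(removed))
}

#' Area under the ROC curve with confidence interval
#'
#' The AUC is the Mann-Whitney probability: across all case/control pairs, the
#' fraction in which the case scores higher, counting ties as 1/2. It is the
#' frequency with which the model would order two randomly chosen patients
#' correctly. The 95% CI uses the DeLong variance (via pROC).
#'
#' @param scores Numeric score vector (higher = more case-like).
#' @param labels Binary labels; the second factor level is the case class.
#' @param ci Compute the DeLong 95% CI (default FALSE; adds cost).
#' @return List with `auc` and `ci` (length-2 vector or NULL).
#' @export
auc <- function(scores, labels, ci = FALSE) {
  y <- as_binary_factor(labels)
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  a <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ci_v <- NULL
  if (ci) {
    ci_v <- tryCatch({
      ro <- pROC::roc(response = y, predictor = scores,
                      levels = levels(y), direction = "<", quiet = TRUE)
      as.numeric(pROC::ci.auc(ro, method = "delong"))[c(1, 3)]
    }, error = function(e) c(NA_real_, NA_real_))
  }
  list(auc = a, ci = ci_v)
}

# Cross-validated decision scores for a fixed gene panel. Internal engine
# shared by the user-facing crossval_scores and the permutation null.
cv_engine <- function(X, y, folds, config, calibrate = FALSE,
                      fixed_cost = NULL) {
  n <- length(y)
  scores <- numeric(n)
  chosen_c <- numeric(max(folds))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2)
      stop("a training fold contains a single class; reduce folds")
    sc <- scale_by_train(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
    gamma <- median_heuristic_gamma(sc$train)
    cost <- if (!is.null(fixed_cost)) fixed_cost
            else tune_cost(sc$train, y[tr], gamma, config,
                           child_seed(config$seed, paste0("inner", f)))
    chosen_c[f] <- cost
    scores[!tr] <- if (calibrate)
      svm_probability(sc$train, y[tr], sc$test, cost, gamma)
    else
      svm_decision(sc$train, y[tr], sc$test, cost, gamma)
  }
  list(scores = scores, chosen_c = chosen_c)
}

#' Cross-validated per-sample class scores
#'
#' Every sample is scored by a model never trained on it: stratified k-fold
#' (or leave-one-out) cross-validation, with the SVM cost tuned by inner
#' cross-validation within each training fold and genes z-scored using
#' training-fold statistics only. Scores are Platt-calibrated probabilities
#' in [0,1]; set `calibrate = FALSE` for raw decision values (the AUC is
#' identical since calibration is monotone).
#'
#' @param X Numeric matrix, samples x genes.
#' @param labels Binary labels.
#' @param genes Ordered gene ranking (e.g. from [rank_genes_rfe()]).
#' @param k Number of top-ranked genes to use (defaults to all).
#' @param config A [classifier_config()]; `outer_folds` may be `"loo"`.
#' @param calibrate Return calibrated probabilities (default TRUE).
#' @return Numeric vector of per-sample scores, in input sample order.
#' @export
crossval_scores <- function(X, labels, genes = colnames(X), k = length(genes),
                            config = classifier_config(), calibrate = TRUE) {
  y <- as_binary_factor(labels)
  stopifnot(k >= 1, k <= length(genes))
  panel <- genes[seq_len(k)]
  Xp <- X[, panel, drop = FALSE]
  folds <- make_outer_folds(y, config)
  cv_engine(Xp, y, folds, config, calibrate = calibrate)$scores
}

make_outer_folds <- function(y, config) {
  if (identical(config$outer_folds, "loo")) return(seq_along(y))
  k <- min(config$outer_folds, min(table(y)) * 2)
  if (k < 2) stop("class counts too small for cross-validation")
  stratified_folds(y, k, child_seed(config$seed, "outer"))
}

#' Select the best-performing gene-panel size
#'
#' Evaluates the cross-validated AUC for each panel size on the grid that does
#' not exceed the pathway size; if the pathway is smaller than the largest
#' grid point, the full gene set is also a candidate. Ties favour the smallest
#' k (parsimony). The same fold assignment is reused across the grid so panel
#' sizes are compared on identical splits.
#'
#' @inheritParams crossval_scores
#' @return List with `k` (selected size), `auc` (its CV AUC), and
#'   `auc_by_k` (named vector over candidates).
#' @export
select_gene_count <- function(X, labels, genes = colnames(X),
                              config = classifier_config()) {
  y <- as_binary_factor(labels)
  p <- length(genes)
  ks <- config$gene_count_grid[config$gene_count_grid <= p]
  if (p < max(config$gene_count_grid) && !(p %in% ks)) ks <- c(ks, p)
  if (length(ks) == 0) ks <- p
  folds <- make_outer_folds(y, config)
  aucs <- vapply(ks, function(k) {
    sc <- cv_engine(X[, genes[seq_len(k)], drop = FALSE], y, folds, config)
    auc(sc$scores, y)$auc
  }, 0)
  names(aucs) <- ks
  best <- which.max(aucs)   # first maximum = smallest k on ties
  list(k = ks[best], auc = aucs[best], auc_by_k = aucs)
}

#' Permutation-based empirical P-value for a pathway AUC
#'
#' Compares the observed cross-validated AUC against AUCs obtained after
#' randomly shuffling the class labels; the reported P is the fraction of
#' permuted AUCs strictly greater than the observed one (so it can be 0; see
#' `perm_correction` in [classifier_config()] for the (r+1)/(B+1) variant).
#' By default the observed gene panel and the cost chosen on observed labels
#' are reused inside permutations; `perm_refit = TRUE` re-runs ranking and
#' panel-size selection per permutation.
#'
#' @inheritParams crossval_scores
#' @param k Panel size.
#' @return List with `auc` (observed), `perm_p`, `perm_aucs`.
#' @export
permutation_pvalue <- function(X, labels, genes = colnames(X),
                               k = length(genes),
                               config = classifier_config()) {
  y <- as_binary_factor(labels)
  panel <- genes[seq_len(k)]
  folds <- make_outer_folds(y, config)
  obs <- cv_engine(X[, panel, drop = FALSE], y, folds, config)
  obs_auc <- auc(obs$scores, y)$auc
  perm_cost <- stats::median(obs$chosen_c)
  B <- config$n_permutations
  rs <- set_local_seed(child_seed(config$seed, "perm"))
  on.exit(restore_seed(rs))
  perm_aucs <- numeric(B)
  if (config$perm_refit) {
    for (b in seq_len(B)) {
      yp <- y[sample.int(length(y))]
      fp <- stratified_folds(yp, max(folds), child_seed(config$seed,
                                                        paste0("permfold", b)))
      rk <- rank_genes_rfe(X, yp, config)
      sel <- select_gene_count(X, yp, rk, config)
      sc <- cv_engine(X[, rk[seq_len(sel$k)], drop = FALSE], yp, fp, config,
                      fixed_cost = perm_cost)
      perm_aucs[b] <- auc(sc$scores, yp)$auc
    }
  } else {
    # the gene panel and the cost chosen on observed labels are reused;
    # only labels are reshuffled and the SVM refitted
    Xp <- X[, panel, drop = FALSE]
    nf <- max(folds)
    n <- length(y)
    pos_lab <- levels(y)[2]
    n1 <- sum(y == pos_lab); n0 <- n - n1
    rank_auc <- function(scores, yy) {
      r <- rank(scores)
      (sum(r[yy == pos_lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    if (config$perm_scheme == "within_fold") {
      # permuting labels within folds preserves the stratified design, so
      # fold assignment, per-fold scaling and the label-free bandwidth can
      # be precomputed once
      pre <- lapply(seq_len(nf), function(f) {
        tr <- folds != f
        sc <- scale_by_train(Xp[tr, , drop = FALSE], Xp[!tr, , drop = FALSE])
        list(tr = tr, train = sc$train, test = sc$test,
             gamma = median_heuristic_gamma(sc$train))
      })
      fold_members <- split(seq_len(n), folds)
      for (b in seq_len(B)) {
        yp <- y
        for (mem in fold_members)
          yp[mem] <- yp[mem][sample.int(length(mem))]
        scores <- numeric(n)
        for (f in seq_len(nf)) {
          pf <- pre[[f]]
          scores[!pf$tr] <- svm_decision(pf$train, yp[pf$tr], pf$test,
                                         perm_cost, pf$gamma)
        }
        perm_aucs[b] <- rank_auc(scores, yp)
      }
    } else {
      for (b in seq_len(B)) {
        yp <- y[sample.int(n)]
        fp <- stratified_folds(yp, nf,
                               child_seed(config$seed, paste0("permfold", b)))
        scores <- numeric(n)
        for (f in seq_len(nf)) {
          tr <- fp != f
          sc <- scale_by_train(Xp[tr, , drop = FALSE],
                               Xp[!tr, , drop = FALSE])
          scores[!tr] <- svm_decision(sc$train, yp[tr], sc$test, perm_cost,
                                      median_heuristic_gamma(sc$train))
        }
        perm_aucs[b] <- rank_auc(scores, yp)
      }
    }
  }
  r <- sum(perm_aucs > obs_auc + 1e-12)
  p <- if (config$perm_correction == "add_one") (r + 1) / (B + 1) else r / B
  list(auc = obs_auc, perm_p = p, perm_aucs = perm_aucs)
}

#' Treatment-effect exclusion filter
#'
#' Pathway-level predictions should separate familial cases from familial
#' controls because of inherited susceptibility, not because cases underwent
#' cancer therapy. A pathway is flagged when its per-sample scores differ
#' (two-sided two-sample t-test, P < `alpha`) between (i) women with a family
#' history who did not develop cancer and (ii) women without a family history
#' (regardless of cancer status).
#'
#' @param scores Per-sample classifier scores.
#' @param annotations A [sample_annotations()] data.frame aligned with
#'   `scores`.
#' @param alpha Exclusion threshold (default 0.05).
#' @return List with `excluded` (logical, NA when indeterminate), `p`,
#'   `t`, and group sizes.
#' @export
treatment_effect_filter <- function(scores, annotations, alpha = 0.05) {
  g1 <- annotations$family_history & !annotations$developed_cancer
  g2 <- !annotations$family_history
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) {
    warning("treatment-effect filter indeterminate: a comparison group has ",
            "fewer than 2 samples; pathway retained")
    return(list(excluded = NA, p = NA_real_, t = NA_real_, n1 = n1, n2 = n2))
  }
  tt <- tryCatch(stats::t.test(scores[g1], scores[g2]),
                 error = function(e) NULL)
  if (is.null(tt))
    return(list(excluded = FALSE, p = 1, t = 0, n1 = n1, n2 = n2))
  list(excluded = tt$p.value < alpha, p = tt$p.value,
       t = unname(tt$statistic), n1 = n1, n2 = n2)
}
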