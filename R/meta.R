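#' Rank-consistency combined P-value across data sets
#'
#' Within each data set, pathways are ranked by ascending P-value and ranks
#' scaled to (0,1) as (rank - 0.5)/N (average ranks for ties). For each
#' pathway, the mean scaled rank over its m observed data sets is referred to
#' the null in which scaled ranks are i.i.d. Uniform(0,1): a one-sided P for
#' consistently low ranking. The combination depends only on within-dataset
#' rank order, so it is invariant to monotone transforms of the per-dataset
#' P-values. The default null uses the exact Irwin-Hall distribution of the
#' sum of m uniforms; `approx = "normal"` uses the N(0.5, 1/(12m))
#' approximation, which is accurate in the body but badly underestimates
#' extreme tails.
#'
#' @param p_matrix Numeric matrix, pathways x data sets, of P-values; NAs mark
#'   pathways missing from a data set.
#' @param approx `"irwin_hall"` (exact, default) or `"normal"`.
#' @return A data.frame with `pathway`, `mean_scaled_rank`, `m` (observed
#'   data sets), `rank_p`.
#' @export
rank_consistency_p <- function(p_matrix, approx = c("irwin_hall", "normal")) {
  approx <- match.arg(approx)
  stopifnot(is.matrix(p_matrix), ncol(p_matrix) >= 1)
  scaled <- apply(p_matrix, 2, function(p) {
    obs <- !is.na(p)
    N <- sum(obs)
    out <- rep(NA_real_, length(p))
    if (N == 0) return(out)
    if (length(unique(p[obs])) == 1 && N > 1)
      warning("a data set has all-equal P-values; its ranks are uninformative")
    out[obs] <- (rank(p[obs], ties.method = "average") - 0.5) / N
    out
  })
  scaled <- matrix(scaled, nrow = nrow(p_matrix),
                   dimnames = dimnames(p_matrix))
  m <- rowSums(!is.na(scaled))
  mean_rank <- rowMeans(scaled, na.rm = TRUE)
  rank_p <- vapply(seq_len(nrow(scaled)), function(i) {
    if (m[i] == 0) return(NA_real_)
    if (approx == "normal")
      stats::pnorm(mean_rank[i], mean = 0.5, sd = sqrt(1 / (12 * m[i])))
    else
      irwin_hall_cdf(mean_rank[i] * m[i], m[i])
  }, 0)
  data.frame(pathway = rownames(p_matrix) %||% seq_len(nrow(p_matrix)),
             mean_scaled_rank = mean_rank, m = m, rank_p = rank_p,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine independent P-values
#'
#' Classical combination methods: Fisher's combined probability test
#' (-2 sum log p against chi-square with 2m df), Wilkinson's minimum-P method
#' at k = 1 (Beta(1, m) tail of the smallest P), and Edgington's "sum p"
#' method (Irwin-Hall tail of the sum). All methods reduce to the identity at
#' m = 1. Zeros are clamped to the smallest positive double with a warning.
#'
#' @param ps Numeric vector of P-values in (0, 1].
#' @param method `"fisher"`, `"wilkinson_min"`, or `"sum_p"`.
#' @return The combined P-value.
#' @export
combine_p <- function(ps, method = c("fisher", "wilkinson_min", "sum_p")) {
  method <- match.arg(method)
  stopifnot(length(ps) >= 1, all(ps >= 0), all(ps <= 1))
  if (any(ps == 0)) {
    warning("P-value of 0 clamped to smallest positive value")
    ps[ps == 0] <- .Machine$double.xmin
  }
  m <- length(ps)
  switch(method,
         fisher = stats::pchisq(-2 * sum(log(ps)), df = 2 * m,
                                lower.tail = FALSE),
         wilkinson_min = 1 - (1 - min(ps))^m,
         sum_p = irwin_hall_cdf(sum(ps), m))
}

#' Storey q-values
#'
#' Estimates the proportion of true nulls pi0 from the P-value distribution on
#' a lambda grid (0.05 to 0.95 by 0.05) with a cubic smoothing spline
#' evaluated at lambda = 0.95, then converts P-values to q-values:
#' q(i) = min over j >= i of pi0 * m * p(j) / j on the sorted P-values.
#'
#' @param ps Numeric vector of P-values.
#' @return List with `q` (same order as `ps`) and `pi0`.
#' @export
storey_qvalues <- function(ps) {
  stopifnot(all(ps >= 0 & ps <= 1))
  m <- length(ps)
  if (m < 10) warning("fewer than 10 P-values; pi0 estimate is unstable")
  lambda <- seq(0.05, 0.95, by = 0.05)
  if (length(unique(ps)) < 2 || max(ps) <= min(lambda)) {
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(ps > l) / (1 - l), 0)
    pi0 <- tryCatch({
      sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(sp, x = 0.95)$y
    }, error = function(e) utils::tail(pi0_l, 1))
    pi0 <- min(1, max(pi0, 1e-8))
  }
  o <- order(ps)
  q_sorted <- pi0 * m * ps[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(1, q_sorted)
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, pi0 = pi0)
}

#' Select candidate pathways with a step-by-step funnel
#'
#' Retains pathways whose rank-consistency P-value falls below `alpha`, then
#' drops pathways flagged by the treatment-effect filter or by the BRCA
#' subgroup comparison. Returns the surviving pathways ordered by rank P and
#' the per-step funnel counts (non-increasing by construction).
#'
#' @param evidence A data.frame with columns `pathway`, `rank_p`, and logical
#'   flag columns `treatment_effect` and `brca_subgroup` (NA treated as
#'   not flagged).
#' @param alpha Rank-P threshold (default 0.05).
#' @return List with `candidates` (data.frame ordered by `rank_p`) and
#'   `funnel` (named integer vector of counts after each step).
#' @export
select_candidate_pathways <- function(evidence, alpha = 0.05) {
  if (nrow(evidence) == 0)
    return(list(candidates = evidence,
                funnel = c(input = 0L, rank_significant = 0L,
                           after_treatment_filter = 0L,
                           after_brca_filter = 0L)))
  flag <- function(x) !is.na(x) & x
  sig <- !is.na(evidence$rank_p) & evidence$rank_p < alpha
  s1 <- evidence[sig, , drop = FALSE]
  s2 <- s1[!flag(s1$treatment_effect), , drop = FALSE]
  s3 <- s2[!flag(s2$brca_subgroup), , drop = FALSE]
  s3 <- s3[order(s3$rank_p), , drop = FALSE]
  list(candidates = s3,
       funnel = c(input = nrow(evidence),
                  rank_significant = nrow(s1),
                  after_treatment_filter = nrow(s2),
                  after_brca_filter = nrow(s3)))
}

#' Mutation-expression concordance with local FDR selection
#'
#' For each gene present in both the expression matrix and the gene-level
#' mutation matrix, computes Spearman's rank correlation between binary
#' mutation status and expression over the shared samples. Correlations are
#' Fisher-transformed to z-scores (scaled by sqrt(n - 3)); the null z
#' distribution is estimated empirically by central matching (median and
#' IQR-based sigma), and each gene's local false discovery rate is
#' pi0 * f0(z) / f(z) with f estimated by kernel density. Genes with constant
#' mutation vectors have undefined correlation and are skipped.
#'
#' @param expr Numeric matrix, samples x genes.
#' @param gene_matrix A gene-level `mutation_matrix`.
#' @param fdr_cutoff Local FDR selection cutoff (default 0.2).
#' @return List with `results` (data.frame: `gene`, `rho`, `z`, `local_fdr`,
#'   `selected`), `n_skipped_constant`, and `null_fit` (mu, sigma, pi0).
#' @export
mutation_expression_concordance <- function(expr, gene_matrix,
                                            fdr_cutoff = 0.2) {
  samples <- intersect(rownames(expr), rownames(gene_matrix))
  if (length(samples) < 5) stop("fewer than 5 shared samples")
  genes <- intersect(colnames(expr), colnames(gene_matrix))
  n <- length(samples)
  rho <- vapply(genes, function(g) {
    mv <- gene_matrix[samples, g]
    if (length(unique(mv)) < 2) return(NA_real_)
    stats::cor(mv, expr[samples, g], method = "spearman")
  }, 0)
  skipped <- sum(is.na(rho))
  genes <- genes[!is.na(rho)]
  rho <- rho[!is.na(rho)]
  if (length(rho) == 0)
    return(list(results = data.frame(gene = character(0), rho = numeric(0),
                                     z = numeric(0), local_fdr = numeric(0),
                                     selected = logical(0)),
                n_skipped_constant = skipped, null_fit = NULL))
  z <- atanh(pmin(0.9999, pmax(-0.9999, rho))) * sqrt(n - 3)
  # empirical null by central matching
  mu0 <- stats::median(z)
  sigma0 <- max(stats::IQR(z) / 1.349, 1e-6)
  # pi0 from two-sided P-values under the fitted null
  p0 <- 2 * stats::pnorm(-abs(z - mu0) / sigma0)
  if (length(z) >= 10) {
    pi0 <- storey_qvalues(p0)$pi0
    f <- stats::density(z, n = 1024)
    fz <- stats::approx(f$x, f$y, xout = z, rule = 2)$y
    f0z <- stats::dnorm(z, mu0, sigma0)
    lfdr <- pmin(1, pi0 * f0z / pmax(fz, 1e-12))
  } else {
    # too few genes for density estimation: conservative fallback using the
    # two-sided null P as the local fdr proxy
    pi0 <- 1
    lfdr <- pmin(1, p0)
  }
  res <- data.frame(gene = genes, rho = rho, z = z, local_fdr = lfdr,
                    selected = lfdr <= fdr_cutoff, stringsAsFactors = FALSE)
  list(results = res, n_skipped_constant = skipped,
       null_fit = list(mu = mu0, sigma = sigma0, pi0 = pi0))
}
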