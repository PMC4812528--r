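# Pooled-variance score statistic for a 2x2 table of independent binomials:
# positive when the case rate exceeds the control rate. Defined as 0 when the
# pooled rate is 0 or 1 (no evidence either way).
score_statistic <- function(a, n1, b, n2) {
  p1 <- a / n1
  p2 <- b / n2
  pp <- (a + b) / (n1 + n2)
  den <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  t <- (p1 - p2) / den
  t[!is.finite(t)] <- 0
  t
}

#' Barnard's unconditional exact test for a 2x2 table
#'
#' One-sided unconditional exact test comparing two binomial proportions
#' (mutated cases out of `n1` vs mutated controls out of `n2`). Unlike
#' Fisher's conditional test, the margin is not fixed: the P-value is the
#' supremum, over the common nuisance success probability pi, of the total
#' probability of tables whose pooled-variance score statistic is at least as
#' extreme as the observed one. The supremum is located on a fine grid over
#' pi in (0,1) and sharpened by local optimization; the open-interval
#' boundary limits are handled analytically (an observed statistic of zero or
#' below yields P = 1).
#'
#' @param a Mutated cases.
#' @param n1 Total cases.
#' @param b Mutated controls.
#' @param n2 Total controls.
#' @param direction `"greater"`: alternative is that cases are more mutated;
#'   `"less"`: cases less mutated.
#' @param grid_step Spacing of the nuisance-parameter grid (default 0.001).
#' @return List with `p`, `statistic`, and `pi_hat` (arg-max of the nuisance
#'   search).
#' @export
barnard_test <- function(a, n1, b, n2, direction = c("greater", "less"),
                         grid_step = 0.001) {
  direction <- match.arg(direction)
  stopifnot(a >= 0, a <= n1, b >= 0, b <= n2, n1 >= 1, n2 >= 1)
  if (direction == "less")
    return(barnard_test(n1 - a, n1, n2 - b, n2, "greater", grid_step))

  t_obs <- score_statistic(a, n1, b, n2)
  if (t_obs <= 0)   # region includes the all-zero table: sup_pi P -> 1
    return(list(p = 1, statistic = t_obs, pi_hat = NA_real_))

  aa <- 0:n1
  bb <- 0:n2
  Tmat <- outer(aa, bb, function(x, y) score_statistic(x, n1, y, n2))
  region <- Tmat >= t_obs - 1e-12

  region_prob <- function(pi) {
    pa <- stats::dbinom(aa, n1, pi)
    pb <- stats::dbinom(bb, n2, pi)
    sum((pa %o% pb)[region])
  }
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  vals <- vapply(grid, region_prob, 0)
  i <- which.max(vals)
  lo <- if (i == 1) 1e-8 else grid[i - 1]
  hi <- if (i == length(grid)) 1 - 1e-8 else grid[i + 1]
  opt <- stats::optimize(region_prob, c(lo, hi), maximum = TRUE,
                         tol = 1e-10)
  p <- max(vals[i], opt$objective)
  list(p = min(1, p), statistic = t_obs,
       pi_hat = if (opt$objective >= vals[i]) opt$maximum else grid[i])
}

#' Pathway-level mutation-rate association
#'
#' Applies [barnard_test()] to every pathway column of a binary mutation
#' matrix, comparing carrier rates between the two label groups. In
#' `"each-direction"` mode both one-sided P-values are returned (used when
#' asking whether mutation rates differ between BRCA1/2 carriers and BRCAX
#' women in either direction).
#'
#' @param pathway_matrix A pathway-level `mutation_matrix`
#'   (see [collapse_to_pathways()]).
#' @param labels Binary labels aligned with matrix rows; the second factor
#'   level is the case group.
#' @param mode `"one-direction"` (cases more mutated) or `"each-direction"`.
#' @return A data.frame with `pathway`, `mutated_cases`, `n_cases`,
#'   `mutated_controls`, `n_controls`, `p` (and `p_reverse` in
#'   each-direction mode). All-zero pathways get P = 1.
#' @export
pathway_mutation_association <- function(pathway_matrix, labels,
                                         mode = c("one-direction",
                                                  "each-direction")) {
  mode <- match.arg(mode)
  y <- as_binary_factor(labels)
  stopifnot(length(y) == nrow(pathway_matrix))
  case <- y == levels(y)[2]
  n1 <- sum(case); n2 <- sum(!case)
  res <- lapply(colnames(pathway_matrix), function(pw) {
    a <- sum(pathway_matrix[case, pw])
    b <- sum(pathway_matrix[!case, pw])
    p <- barnard_test(a, n1, b, n2, "greater")$p
    row <- data.frame(pathway = pw, mutated_cases = a, n_cases = n1,
                      mutated_controls = b, n_controls = n2, p = p,
                      stringsAsFactors = FALSE)
    if (mode == "each-direction")
      row$p_reverse <- barnard_test(a, n1, b, n2, "less")$p
    row
  })
  do.call(rbind, res)
}
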