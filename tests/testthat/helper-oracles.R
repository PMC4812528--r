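# Independent oracles used to freeze expected values. These deliberately use
# different algorithmic routes than the package implementation.

# Brute-force unconditional exact test: enumerate all (a', b') tables,
# compute the pooled score statistic directly, and maximize the region
# probability over a dense fixed grid of the nuisance probability (no local
# refinement). Grid points are packed near the boundaries so the open
# interval's limits are represented.
barnard_oracle <- function(a, n1, b, n2, n_grid = 20001) {
  stat <- function(x, y) {
    pp <- (x + y) / (n1 + n2)
    t <- (x / n1 - y / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    ifelse(is.finite(t), t, 0)
  }
  t_obs <- stat(a, b)
  tables <- expand.grid(aa = 0:n1, bb = 0:n2)
  region <- tables[stat(tables$aa, tables$bb) >= t_obs - 1e-12, ]
  pis <- c(10^seq(-9, -3.01, length.out = 200),
           seq(1e-3, 1 - 1e-3, length.out = n_grid),
           1 - 10^seq(-9, -3.01, length.out = 200))
  PA <- outer(0:n1, pis, function(x, p) dbinom(x, n1, p))
  PB <- outer(0:n2, pis, function(x, p) dbinom(x, n2, p))
  vals <- colSums(PA[region$aa + 1, , drop = FALSE] *
                    PB[region$bb + 1, , drop = FALSE])
  min(1, max(vals))
}

# Pairwise-enumeration AUC: mean over all case/control pairs of
# win + half-tie.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels != 1]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Monte-Carlo tail probability for the mean of m iid Uniform(0,1).
uniform_mean_tail_mc <- function(threshold, m, n_draws = 1e6, seed = 42) {
  rs <- pathrisk:::set_local_seed(seed)
  on.exit(pathrisk:::restore_seed(rs))
  x <- matrix(stats::runif(n_draws * m), ncol = m)
  mean(rowMeans(x) <= threshold)
}

# Small separable or null expression matrices for classifier tests.
make_classed_matrix <- function(n_per_class, n_genes, shift, seed,
                                n_signal = n_genes) {
  rs <- pathrisk:::set_local_seed(seed)
  on.exit(pathrisk:::restore_seed(rs))
  X <- matrix(stats::rnorm(2 * n_per_class * n_genes), 2 * n_per_class)
  colnames(X) <- sprintf("g%03d", seq_len(n_genes))
  y <- rep(c(1, 0), each = n_per_class)
  X[y == 1, seq_len(n_signal)] <- X[y == 1, seq_len(n_signal)] + shift
  list(X = X, y = y)
}

# The six-variant hand-trace table exercising every cascade rule.
toy_variant_table <- function() {
  annotated_variants(
    chrom = rep("1", 6), pos = 101:106, ref = rep("A", 6),
    alt = c("G", "AG", "G", "AT", "G", "G"),
    gene = c("GENE1", "GENE2", "GENE3", "GENE4", "GENE5", "GENE6"),
    variant_class = c("SNV", "InDel", "SNV", "InDel", "SNV", "SNV"),
    severity = c("HIGH", "HIGH", "MODERATE", "MODERATE", "HIGH", "HIGH"),
    is_missense = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    pop_af_max = c(0.02, 0.001, 0.001, 0.001, 0.001, 0.001),
    background_af = c(0, 0, 0, 0, 0, 0),
    deleterious_call = c(NA, NA, "neutral", NA, NA, NA),
    in_exon_pad2 = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    carriers = list("s1", "s1", "s2", c("s2", "s3"), "s4",
                    paste0("s", 1:4)))
}
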