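#' Read a tab-separated table
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used by all
#' package I/O: header row, no factor coercion, no name mangling.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a tab-separated table
#'
#' @param x A data.frame or matrix.
#' @param path File path.
#' @param rownames Column name under which to store row names, or NULL to drop.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path, rownames = NULL) {
  if (!is.null(rownames)) {
    x <- data.frame(rn = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
    names(x)[1] <- rownames
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Derive a reproducible child seed from a master seed and a stage label.
# Counter-based so stages can be rerun in isolation; kept below 2^31.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(h %% 1000003L)) %% 2147483647L
}

# Stratified fold assignment: per class, samples are dealt round-robin into
# folds in a seeded random order. Guarantees both classes in every training
# set whenever class counts allow it.
stratified_folds <- function(labels, k, seed) {
  stopifnot(k >= 2)
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  rs <- set_local_seed(seed)
  on.exit(restore_seed(rs))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Save/restore .Random.seed so seeded internals do not clobber the caller's
# RNG stream.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Cumulative distribution of the sum of m independent Uniform(0,1) variables
# (Irwin-Hall), evaluated at s in [0, m]. Used both for Edgington's sum-p
# combination and for the exact rank-consistency null. Alternating-sign series
# is numerically safe for the m used here; the upper half is computed by
# reflection to avoid cancellation.
irwin_hall_cdf <- function(s, m) {
  stopifnot(m >= 1)
  if (s <= 0) return(0)
  if (s >= m) return(1)
  if (s > m / 2) return(1 - irwin_hall_cdf(m - s, m))
  j <- 0:floor(s)
  terms <- (-1)^j * exp(lchoose(m, j) + m * log(s - j) - lfactorial(m))
  max(0, min(1, sum(terms)))
}
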