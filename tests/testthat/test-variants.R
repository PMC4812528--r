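test_that("the filtering cascade hand-trace retains exactly the rare exonic HIGH/InDel variants", {
  res <- filter_variants(toy_variant_table(), n_samples = 20)
  expect_equal(nrow(res$retained), 2)
  expect_setequal(res$retained$gene, c("GENE2", "GENE4"))
  expect_equal(unname(res$exclusions),
               c(1L, 0L, 1L, 1L, 1L, 0L))
  expect_equal(names(res$exclusions),
               c("pop_af", "background_af", "internal_freq", "off_exon",
                 "effect", "missing_call"))
  # conservation: input = retained + sum of exclusions
  expect_equal(nrow(res$retained) + sum(res$exclusions),
               nrow(toy_variant_table()))
})

test_that("empty carrier sets never trip the internal-frequency rule", {
  v <- toy_variant_table()[2, , drop = FALSE]
  v$carriers <- list(character(0))
  res <- filter_variants(v, n_samples = 5)
  expect_equal(nrow(res$retained), 1)
})

test_that("missense SNVs without a deleteriousness call follow the configured policy", {
  v <- toy_variant_table()[3, , drop = FALSE]
  v$deleterious_call <- NA_character_
  drop <- filter_variants(v, 20)
  expect_equal(unname(drop$exclusions["missing_call"]), 1L)
  keep <- filter_variants(v, 20,
                          variant_filter_config(drop_missing_call = FALSE))
  expect_equal(nrow(keep$retained), 1)
})

test_that("variant tables round-trip through TSV", {
  v <- toy_variant_table()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_variant_tsv(v, tf)
  v2 <- read_variant_tsv(tf)
  expect_equal(v2$gene, v$gene)
  expect_equal(v2$pop_af_max, v$pop_af_max)
  expect_equal(v2$carriers, v$carriers)
})

test_that("gene collapsing binarizes carriage", {
  v <- annotated_variants(
    chrom = c("1", "1", "2"), pos = c(10, 20, 30), ref = "A", alt = "G",
    gene = c("G1", "G1", "G2"), variant_class = "SNV", severity = "HIGH",
    is_missense = FALSE, pop_af_max = 0, background_af = 0,
    deleterious_call = NA, in_exon_pad2 = TRUE,
    carriers = list(c("s1", "s2"), "s1", "s3"))
  M <- collapse_to_genes(v, c("s1", "s2", "s3", "s4"))
  expect_equal(M["s1", "G1"], 1L)   # two variants, still one
  expect_equal(M["s2", "G1"], 1L)   # shared variant expands to both carriers
  expect_equal(M["s3", "G2"], 1L)
  expect_equal(sum(M["s4", ]), 0L)
  expect_true(all(M %in% 0:1))

  # no retained variants -> all-zero matrix
  M0 <- collapse_to_genes(v[0, , drop = FALSE], c("s1", "s2"))
  expect_equal(ncol(M0), 0)
})

test_that("threshold selection finds the constructed breakpoint", {
  freqs <- c(stats::setNames(rep(0.001, 50), sprintf("L%02d", 1:50)),
             stats::setNames(rep(0.05, 10), sprintf("H%02d", 1:10)))
  # brute-force count curve on the same grid
  cand <- seq(0.002, 0.10, length.out = 50)
  counts <- vapply(cand, function(t) sum(freqs > t), 1L)
  drop_at <- which.max(-diff(counts))
  expect_equal(cand[drop_at], 0.048)   # last candidate below the 5% block
  sel <- select_frequency_threshold(freqs)
  expect_equal(sel$threshold, 0.048)
  expect_equal(sel$curve$n_excluded, counts)

  # uniformly spread frequencies: every adjacent drop equals one, so the
  # tie-break returns the smallest candidate
  flat <- stats::setNames(cand[-1] - 1e-4, sprintf("F%02d", seq_along(cand[-1])))
  expect_equal(select_frequency_threshold(flat)$threshold, 0.002)

  # everything below the grid -> warning, grid minimum
  low <- stats::setNames(rep(0.0001, 5), sprintf("X%d", 1:5))
  expect_warning(sel_low <- select_frequency_threshold(low), "grid minimum")
  expect_equal(sel_low$threshold, 0.002)
})

test_that("frequent-gene exclusion respects the keep-list and boundary semantics", {
  M <- matrix(1L, 2, 4, dimnames = list(c("s1", "s2"),
                                        c("BRCA1", "FREQ", "EDGE", "NOVEL")))
  M <- structure(M, level = "gene", class = c("mutation_matrix", class(M)))
  bg <- c(BRCA1 = 0.05, FREQ = 0.05, EDGE = 0.018)
  out <- exclude_frequent_genes(M, bg, threshold = 0.018)
  expect_setequal(colnames(out), c("BRCA1", "EDGE", "NOVEL"))
})

test_that("pathway collapsing is an exact column-OR of member genes", {
  gm <- matrix(c(0L, 1L, 0L, 0L, 1L, 0L), 3, 2,
               dimnames = list(c("s1", "s2", "s3"), c("G1", "G2")))
  gm <- structure(gm, level = "gene", class = c("mutation_matrix", class(gm)))
  gc <- gene_set_collection(list(PWA = c("G1", "G2"), PWB = "G2",
                                 PWC = "G9"))
  expect_message(pm <- collapse_to_pathways(gm, gc), "no genes")
  expect_equal(unname(pm[, "PWA"]),
               as.integer(gm[, "G1"] | gm[, "G2"]))
  expect_equal(unname(pm[, "PWB"]), unname(gm[, "G2"]))
  expect_equal(sum(pm[, "PWC"]), 0L)
  # dominance property on random matrices
  set.seed(21)
  for (i in 1:5) {
    G <- matrix(rbinom(60, 1, 0.3), 6, 10,
                dimnames = list(sprintf("s%d", 1:6), sprintf("G%d", 1:10)))
    G <- structure(G, level = "gene", class = c("mutation_matrix", class(G)))
    sets <- list(P1 = sprintf("G%d", 1:4), P2 = sprintf("G%d", 3:10))
    P <- collapse_to_pathways(G, gene_set_collection(sets))
    for (pw in names(sets))
      expect_equal(unname(P[, pw]),
                   as.integer(rowSums(G[, sets[[pw]], drop = FALSE]) > 0))
  }
})

test_that("VCF input yields the same table as the flat TSV carrier", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=SEV,Number=1,Type=String,Description=\"Severity\">",
    "##INFO=<ID=MISSENSE,Number=1,Type=Integer,Description=\"Missense\">",
    "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Population AF\">",
    "##INFO=<ID=BGAF,Number=1,Type=Float,Description=\"Background AF\">",
    "##INFO=<ID=DELCALL,Number=1,Type=String,Description=\"Call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "150", ".", "A", "G", ".", ".",
          "GENE=TP53;SEV=HIGH;MISSENSE=0;POPAF=0.001;BGAF=0.0;DELCALL=.",
          "GT", "0/1", "0/0", "1/1", sep = "\t"),
    paste("1", "500", ".", "AT", "A", ".", ".",
          "GENE=ATM;SEV=MODERATE;MISSENSE=0;POPAF=0.002;BGAF=0.01;DELCALL=.",
          "GT", "0/0", "0/1", "0/0", sep = "\t"),
    paste("2", "90", ".", "C", "T", ".", ".",
          "GENE=CHEK2;SEV=MODERATE;MISSENSE=1;POPAF=0.0;BGAF=0.0;DELCALL=deleterious",
          "GT", "0/0", "0/0", "0/1", sep = "\t"))
  vf <- withr::local_tempfile(lines = vcf, fileext = ".vcf")
  bed <- withr::local_tempfile(
    lines = c("1\t100\t200", "1\t480\t520", "2\t200\t300"),
    fileext = ".bed")
  v <- read_variants_vcf(vf, exon_bed = bed)
  expect_equal(v$gene, c("TP53", "ATM", "CHEK2"))
  expect_equal(v$variant_class, c("SNV", "InDel", "SNV"))
  expect_equal(v$carriers, list(c("s1", "s3"), "s2", "s3"))
  # exon +/- 2bp: positions 150 and 500 inside padded exons; 90 outside
  expect_equal(v$in_exon_pad2, c(TRUE, TRUE, FALSE))
  res <- filter_variants(v, n_samples = 20)
  expect_setequal(res$retained$gene, c("TP53", "ATM"))
})
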