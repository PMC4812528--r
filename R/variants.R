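#' Variant filter configuration
#'
#' Thresholds of the germline variant filtering cascade. Defaults follow the
#' published cascade: drop variants with reference-population minor allele
#' frequency above 1%, background-cohort frequency above 3%, or carried by
#' more than 15% of study samples; keep only exonic (+/- 2 bp) variants of
#' adequate predicted severity. Genes mutated in more than
#' `freq_gene_threshold` of background germline samples are excluded from
#' pathway collapsing (BRCA1/2 always kept).
#'
#' @param maf_pop Reference-population MAF cutoff (0.01).
#' @param maf_background Background-cohort MAF cutoff (0.03).
#' @param internal_freq_max Maximum carrier fraction within the study (0.15).
#' @param freq_gene_threshold Background gene mutation frequency above which a
#'   gene is excluded (0.018).
#' @param freq_gene_grid Range searched by [select_frequency_threshold()]
#'   (0.002 to 0.10).
#' @param freq_gene_grid_points Number of evenly spaced candidates (50).
#' @param always_keep_genes Genes exempt from the frequent-gene exclusion.
#' @param drop_missing_call Drop missense SNVs lacking a deleteriousness call
#'   (default TRUE).
#' @return A list of class `variant_filter_config`.
#' @export
variant_filter_config <- function(maf_pop = 0.01, maf_background = 0.03,
                                  internal_freq_max = 0.15,
                                  freq_gene_threshold = 0.018,
                                  freq_gene_grid = c(0.002, 0.10),
                                  freq_gene_grid_points = 50,
                                  always_keep_genes = c("BRCA1", "BRCA2"),
                                  drop_missing_call = TRUE) {
  stopifnot(maf_pop > 0, maf_pop < 1, maf_background > 0, maf_background < 1,
            internal_freq_max > 0, internal_freq_max < 1,
            freq_gene_threshold > 0, freq_gene_threshold < 1,
            freq_gene_grid[1] < freq_gene_grid[2])
  structure(list(maf_pop = maf_pop, maf_background = maf_background,
                 internal_freq_max = internal_freq_max,
                 freq_gene_threshold = freq_gene_threshold,
                 freq_gene_grid = freq_gene_grid,
                 freq_gene_grid_points = freq_gene_grid_points,
                 always_keep_genes = toupper(always_keep_genes),
                 drop_missing_call = drop_missing_call),
            class = "variant_filter_config")
}

#' Construct an annotated variant table
#'
#' One row per variant with the annotation columns the cascade consumes.
#' `carriers` is a list-column of sample-id character vectors (heterozygous
#' and homozygous carriage are treated identically).
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles (pos is 1-based).
#' @param gene Gene symbol.
#' @param variant_class `"SNV"` or `"InDel"`.
#' @param severity `"HIGH"`, `"MODERATE"`, `"LOW"`, or `"MODIFIER"`.
#' @param is_missense Logical.
#' @param pop_af_max Maximum MAF across reference populations.
#' @param background_af Frequency in the background germline cohort.
#' @param deleterious_call `"deleterious"`, `"neutral"`, or NA.
#' @param in_exon_pad2 Logical: within primary-transcript exons +/- 2 bases.
#' @param carriers List of character vectors of carrier sample ids.
#' @return A data.frame of class `annotated_variants`.
#' @export
annotated_variants <- function(chrom, pos, ref, alt, gene, variant_class,
                               severity, is_missense, pop_af_max,
                               background_af, deleterious_call, in_exon_pad2,
                               carriers) {
  stopifnot(all(pos >= 1),
            all(pop_af_max >= 0 & pop_af_max <= 1),
            all(background_af >= 0 & background_af <= 1),
            all(variant_class %in% c("SNV", "InDel")),
            all(severity %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")),
            all(is.na(deleterious_call) |
                  deleterious_call %in% c("deleterious", "neutral")))
  if (!is.list(carriers)) carriers <- as.list(carriers)
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = as.character(ref), alt = as.character(alt),
                  gene = toupper(as.character(gene)),
                  variant_class = variant_class, severity = severity,
                  is_missense = as.logical(is_missense),
                  pop_af_max = pop_af_max, background_af = background_af,
                  deleterious_call = as.character(deleterious_call),
                  in_exon_pad2 = as.logical(in_exon_pad2),
                  stringsAsFactors = FALSE)
  v$carriers <- carriers
  class(v) <- c("annotated_variants", "data.frame")
  v
}

#' Read an annotated variant table from TSV
#'
#' Flat-file carrier of [annotated_variants()]: same columns, with `carriers`
#' as a comma-separated sample-id string.
#'
#' @param path TSV path.
#' @return An [annotated_variants()] data.frame.
#' @export
read_variant_tsv <- function(path) {
  d <- read_tsv_table(path)
  carriers <- strsplit(ifelse(is.na(d$carriers) | d$carriers == "",
                              NA_character_, d$carriers), ",", fixed = TRUE)
  carriers <- lapply(carriers, function(x) if (all(is.na(x))) character(0) else x)
  annotated_variants(d$chrom, d$pos, d$ref, d$alt, d$gene, d$variant_class,
                     d$severity, as.logical(d$is_missense), d$pop_af_max,
                     d$background_af, d$deleterious_call,
                     as.logical(d$in_exon_pad2), carriers)
}

#' Read an annotated variant table from a VCF file
#'
#' VCF carrier of [annotated_variants()]: annotations are read from the INFO
#' fields `GENE`, `SEV`, `MISSENSE` (0/1), `POPAF`, `BGAF`, `DELCALL`, and
#' per-sample genotype columns define carriage (any non-missing,
#' non-homozygous-reference genotype; heterozygous and homozygous carriage
#' are equivalent). Exon membership comes from the INFO field `EXONPAD2` if
#' present, otherwise from `exon_bed`, a BED file of primary-transcript
#' exons (0-based half-open intervals, padded by 2 bases on each side
#' internally to admit splice-site variants).
#'
#' @param path VCF path (requires the vcfR package).
#' @param exon_bed Optional BED path for exon intervals.
#' @return An [annotated_variants()] data.frame.
#' @export
read_variants_vcf <- function(path, exon_bed = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_variants_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  info_field <- function(el) {
    x <- vcfR::extract.info(v, element = el)
    x[x == "."] <- NA_character_
    x
  }
  gene <- info_field("GENE")
  sev <- info_field("SEV")
  missense <- info_field("MISSENSE") %in% c("1", "TRUE", "true")
  popaf <- as.numeric(info_field("POPAF"))
  bgaf <- as.numeric(info_field("BGAF"))
  delcall <- info_field("DELCALL")
  popaf[is.na(popaf)] <- 0
  bgaf[is.na(bgaf)] <- 0

  gt <- vcfR::extract.gt(v)
  carriers <- lapply(seq_len(nrow(gt)), function(i) {
    g <- gt[i, ]
    colnames(gt)[!is.na(g) & !(g %in% c("0/0", "0|0"))]
  })

  pos <- as.integer(fix[, "POS"])
  chrom <- fix[, "CHROM"]
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  cls <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV", "InDel")

  exonpad <- info_field("EXONPAD2")
  if (!all(is.na(exonpad))) {
    in_exon <- exonpad %in% c("1", "TRUE", "true")
  } else if (!is.null(exon_bed)) {
    bed <- utils::read.table(exon_bed, sep = "\t", stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end")[1:3])
    in_exon <- vapply(seq_along(pos), function(i) {
      b <- bed[bed$chrom == chrom[i], , drop = FALSE]
      # BED is 0-based half-open: interval covers (start+1)..end 1-based;
      # pad by 2 on each side
      any(pos[i] >= b$start - 1 & pos[i] <= b$end + 2)
    }, TRUE)
  } else {
    stop("exon membership unavailable: supply exon_bed or an EXONPAD2 ",
         "INFO field")
  }

  annotated_variants(chrom, pos, ref, alt, gene, cls, sev, missense,
                     popaf, bgaf, delcall, in_exon, carriers)
}

#' Write an annotated variant table to TSV
#'
#' @param variants An [annotated_variants()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(variants, path) {
  d <- as.data.frame(variants)
  d$carriers <- vapply(variants$carriers, paste, "", collapse = ",")
  write_tsv_table(d, path)
}

#' Apply the variant filtering cascade
#'
#' Rules are applied in order, each variant attributed to the first rule it
#' fails: (1) reference-population MAF above `maf_pop`; (2) background-cohort
#' frequency above `maf_background`; (3) carried by more than
#' `internal_freq_max` of the study samples; (4) outside primary-transcript
#' exons +/- 2 bp; (5) effect rules — severity LOW/MODIFIER dropped, HIGH
#' retained, MODERATE InDels retained, missense SNVs retained only when called
#' deleterious, other MODERATE SNVs dropped; (6) missense SNVs with a missing
#' deleteriousness call (dropped when `drop_missing_call`). Survivors are the
#' "potentially pathogenic" set.
#'
#' @param variants An [annotated_variants()] data.frame.
#' @param n_samples Number of samples in the study cohort.
#' @param config A [variant_filter_config()].
#' @return List with `retained` (filtered [annotated_variants()]) and
#'   `exclusions` (named integer vector: `pop_af`, `background_af`,
#'   `internal_freq`, `off_exon`, `effect`, `missing_call`).
#' @export
filter_variants <- function(variants, n_samples,
                            config = variant_filter_config()) {
  stopifnot(nrow(variants) > 0, n_samples >= 1)
  n_carriers <- vapply(variants$carriers, function(x) length(unique(x)), 1L)
  reason <- rep(NA_character_, nrow(variants))

  fail1 <- variants$pop_af_max > config$maf_pop
  fail2 <- variants$background_af > config$maf_background
  fail3 <- n_carriers / n_samples > config$internal_freq_max
  fail4 <- !variants$in_exon_pad2
  missing_call <- variants$is_missense & variants$variant_class == "SNV" &
    variants$severity == "MODERATE" & is.na(variants$deleterious_call)
  retained_by_effect <- with(variants,
    severity == "HIGH" |
      (severity == "MODERATE" & variant_class == "InDel") |
      (severity == "MODERATE" & variant_class == "SNV" & is_missense &
         !is.na(deleterious_call) & deleterious_call == "deleterious"))
  fail6 <- missing_call & config$drop_missing_call
  fail5 <- !retained_by_effect & !missing_call

  reason[fail6] <- "missing_call"
  reason[fail5] <- "effect"
  reason[fail4] <- "off_exon"
  reason[fail3] <- "internal_freq"
  reason[fail2] <- "background_af"
  reason[fail1] <- "pop_af"

  rule_names <- c("pop_af", "background_af", "internal_freq", "off_exon",
                  "effect", "missing_call")
  exclusions <- vapply(rule_names, function(r) sum(reason == r, na.rm = TRUE),
                       1L)
  keep <- is.na(reason)
  if (sum(!retained_by_effect & missing_call & !config$drop_missing_call) > 0)
    message(sum(missing_call & !config$drop_missing_call),
            " missense SNV(s) with missing deleteriousness call retained")
  retained <- variants[keep, , drop = FALSE]
  class(retained) <- class(variants)
  list(retained = retained, exclusions = exclusions)
}

#' Collapse retained variants to a binary gene-level mutation matrix
#'
#' A sample/gene cell is 1 when the sample carries at least one retained
#' variant in that gene; multiplicity is discarded (carriers of a variant in
#' a gene held an average of about one variant in it in the source data).
#'
#' @param variants Retained [annotated_variants()].
#' @param sample_ids Ordered character vector of all sample ids.
#' @return A binary matrix, samples x genes, of class `mutation_matrix` with
#'   attribute `level = "gene"`.
#' @export
collapse_to_genes <- function(variants, sample_ids) {
  genes <- sort(unique(variants$gene))
  M <- matrix(0L, nrow = length(sample_ids), ncol = length(genes),
              dimnames = list(sample_ids, genes))
  for (i in seq_len(nrow(variants))) {
    carr <- intersect(variants$carriers[[i]], sample_ids)
    if (length(carr) > 0) M[carr, variants$gene[i]] <- 1L
  }
  structure(M, level = "gene", class = c("mutation_matrix", class(M)))
}

#' Select the frequent-gene exclusion threshold
#'
#' For each candidate threshold t on an evenly spaced grid, counts the genes
#' whose background mutation frequency exceeds t, and returns the candidate at
#' the lower endpoint of the largest drop in that count between adjacent
#' candidates — the last threshold that still excludes the block of
#' frequently mutated genes responsible for the drop. Ties favour the
#' smallest candidate.
#'
#' @param background_gene_freqs Named numeric vector, gene -> background
#'   mutation frequency.
#' @param grid Length-2 range (default 0.002 to 0.10).
#' @param n_points Number of evenly spaced candidates (default 50).
#' @return List with `threshold`, and `curve` (data.frame of candidate
#'   thresholds and excluded-gene counts, for auditing).
#' @export
select_frequency_threshold <- function(background_gene_freqs,
                                       grid = c(0.002, 0.10), n_points = 50) {
  stopifnot(n_points >= 2, grid[1] > 0, grid[2] < 1, grid[1] < grid[2])
  cand <- seq(grid[1], grid[2], length.out = n_points)
  n_excl <- vapply(cand, function(t) sum(background_gene_freqs > t), 1L)
  if (n_excl[1] == 0) {
    warning("all background frequencies at or below the grid minimum")
    return(list(threshold = cand[1],
                curve = data.frame(threshold = cand, n_excluded = n_excl)))
  }
  drops <- -diff(n_excl)
  best <- which.max(drops)   # first maximum = smallest threshold on ties
  list(threshold = cand[best],
       curve = data.frame(threshold = cand, n_excluded = n_excl))
}

#' Exclude frequently mutated genes from a mutation matrix
#'
#' Genes mutated in more than `threshold` of background germline samples are
#' unlikely to drive susceptibility (selective pressure argument) and add
#' noise at the pathway level; their columns are removed, except genes in
#' `always_keep` (BRCA1/2 by default). Genes absent from the background table
#' are treated as unobserved (frequency 0) and kept.
#'
#' @param gene_matrix A gene-level `mutation_matrix`.
#' @param background_gene_freqs Named numeric vector, gene -> frequency.
#' @param threshold Exclusion threshold (strictly greater than).
#' @param always_keep Genes never excluded.
#' @return The pruned `mutation_matrix`.
#' @export
exclude_frequent_genes <- function(gene_matrix, background_gene_freqs,
                                   threshold = 0.018,
                                   always_keep = c("BRCA1", "BRCA2")) {
  stopifnot(threshold > 0, threshold < 1)
  freqs <- background_gene_freqs[match(colnames(gene_matrix),
                                       names(background_gene_freqs))]
  freqs[is.na(freqs)] <- 0
  drop <- freqs > threshold & !(colnames(gene_matrix) %in% toupper(always_keep))
  out <- gene_matrix[, !drop, drop = FALSE]
  structure(out, level = "gene", class = c("mutation_matrix", class(out)))
}

#' Collapse a gene-level mutation matrix to pathways
#'
#' A sample/pathway cell is 1 when any member gene of the pathway is mutated
#' in that sample (OR semantics; overlapping pathways may share mutated
#' genes). Pathways with no genes in the matrix yield all-zero columns.
#'
#' @param gene_matrix A gene-level `mutation_matrix`.
#' @param collection A [gene_set_collection()].
#' @return A binary samples x pathways `mutation_matrix`
#'   (attribute `level = "pathway"`).
#' @export
collapse_to_pathways <- function(gene_matrix, collection) {
  stopifnot(identical(attr(gene_matrix, "level"), "gene"),
            inherits(collection, "gene_set_collection"))
  pw <- names(collection)
  M <- matrix(0L, nrow = nrow(gene_matrix), ncol = length(pw),
              dimnames = list(rownames(gene_matrix), pw))
  empty <- character(0)
  for (i in seq_along(pw)) {
    genes <- intersect(collection$sets[[i]], colnames(gene_matrix))
    if (length(genes) == 0) { empty <- c(empty, pw[i]); next }
    M[, i] <- as.integer(rowSums(gene_matrix[, genes, drop = FALSE]) > 0)
  }
  if (length(empty) > 0)
    message(length(empty), " pathway(s) have no genes in the mutation matrix")
  structure(M, level = "pathway", class = c("mutation_matrix", class(M)))
}
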