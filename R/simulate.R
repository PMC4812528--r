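#' Simulation configuration
#'
#' Defines the synthetic study conditions used for validation: cohort strata
#' sizes mirroring the discovery cohorts' design (family-history cases,
#' family-history controls, no-family-history controls), pathway structure,
#' planted expression effects, mutation enrichment, covariate links, and
#' microscopy field geometry.
#'
#' @param n_pathways Number of pathways (100).
#' @param pathway_size_range Min/max genes per pathway (c(10, 30)).
#' @param n_causal_pathways Pathways carrying planted signal (5).
#' @param causal_gene_fraction Fraction of member genes carrying signal (0.3).
#' @param effect_size Standardized mean shift added to signal genes in cases,
#'   in SD units (1.0).
#' @param n_cases Family-history women who developed cancer (40).
#' @param n_controls_fh Family-history women who did not (40).
#' @param n_controls_nofh Women without family history (20; half developed
#'   sporadic cancer, deterministically).
#' @param carrier_fraction_fh Fraction of family-history women carrying a
#'   BRCA1/2 mutation (0.4, as in the discovery tables).
#' @param noise_correlation Within-pathway exchangeable gene correlation
#'   (0.2).
#' @param mutation_rate_null Per-gene background carrier probability (0.01).
#' @param mutation_rate_causal_cases Per-pathway carrier probability for
#'   cases in causal pathways (0.35).
#' @param mutation_rate_causal_controls Same for controls (0.05).
#' @param n_frequent_genes Genes in the high-background-frequency block (10).
#' @param frequent_gene_freq Their background mutation frequency (0.05).
#' @param covariate_link_fraction Fraction of genes linked to a clinical
#'   covariate (0.05).
#' @param n_decoys_per_rule Decoy variants failing each cascade rule (2).
#' @param image_dim Field edge length in pixels (192).
#' @param nuclei_range Min/max nuclei per field (c(8, 14)).
#' @param nucleus_radius Nucleus disk radius in pixels (6).
#' @param image_noise_sd Gaussian intensity noise SD (0.05).
#' @param seed Integer master seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_pathways = 100,
                              pathway_size_range = c(10, 30),
                              n_causal_pathways = 5,
                              causal_gene_fraction = 0.3,
                              effect_size = 1.0,
                              n_cases = 40, n_controls_fh = 40,
                              n_controls_nofh = 20,
                              carrier_fraction_fh = 0.4,
                              noise_correlation = 0.2,
                              mutation_rate_null = 0.01,
                              mutation_rate_causal_cases = 0.35,
                              mutation_rate_causal_controls = 0.05,
                              n_frequent_genes = 10,
                              frequent_gene_freq = 0.05,
                              covariate_link_fraction = 0.05,
                              n_decoys_per_rule = 2,
                              image_dim = 192,
                              nuclei_range = c(8, 14),
                              nucleus_radius = 6,
                              image_noise_sd = 0.05,
                              seed = 1L) {
  stopifnot(n_causal_pathways <= n_pathways,
            causal_gene_fraction >= 0, causal_gene_fraction <= 1,
            noise_correlation >= 0, noise_correlation < 1,
            mutation_rate_null >= 0, mutation_rate_null <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

# Deterministic pathway membership: sizes cycle through the size range,
# genes are disjoint across pathways. No RNG involved.
make_pathway_collection <- function(config) {
  sizes <- rep(seq(config$pathway_size_range[1], config$pathway_size_range[2]),
               length.out = config$n_pathways)
  nm <- sprintf("PW%03d", seq_len(config$n_pathways))
  sets <- lapply(seq_len(config$n_pathways), function(i)
    sprintf("%s_G%03d", nm[i], seq_len(sizes[i])))
  names(sets) <- nm
  gene_set_collection(sets, descriptions = rep("synthetic pathway",
                                               config$n_pathways))
}

# Deterministic strata allocation for one synthetic cohort.
make_cohort_annotations <- function(config, cohort_label) {
  n_ca <- config$n_cases; n_fh <- config$n_controls_fh
  n_no <- config$n_controls_nofh
  fh <- c(rep(TRUE, n_ca + n_fh), rep(FALSE, n_no))
  cancer <- c(rep(TRUE, n_ca), rep(FALSE, n_fh),
              rep(c(TRUE, FALSE), length.out = n_no))
  carrier <- logical(n_ca + n_fh + n_no)
  carrier[seq_len(round(config$carrier_fraction_fh * n_ca))] <- TRUE
  carrier[n_ca + seq_len(round(config$carrier_fraction_fh * n_fh))] <- TRUE
  sample_annotations(
    sample_id = sprintf("%s_S%03d", cohort_label, seq_along(fh)),
    cohort = cohort_label, family_history = fh,
    brca_status = ifelse(carrier, "carrier", ifelse(fh, "BRCAX", "none")),
    developed_cancer = cancer)
}

#' Simulate an expression cohort with planted pathway signal
#'
#' Generates normalized expression for all pathway genes: correlated Gaussian
#' noise (exchangeable correlation within each pathway block) plus a mean
#' shift of `effect_size` SD added, in family-history cases only, to a fixed
#' fraction of the member genes of each causal pathway. Clinical covariates
#' are generated for a subset of samples, with a minority of genes linearly
#' linked to the first covariate. Strata counts are allocated
#' deterministically; the generator is bit-reproducible given
#' (config, seed).
#'
#' @param config A [simulation_config()].
#' @param cohort_label Label for sample ids and annotations.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list: `expr` (samples x genes), `annotations`, `covariates`
#'   (data.frame with partial coverage), `collection`
#'   (the [gene_set_collection()]), and `truth` (causal pathway names, signal
#'   genes, covariate-linked genes).
#' @export
simulate_expression_cohort <- function(config = simulation_config(),
                                       cohort_label = "cohortA",
                                       seed = config$seed) {
  rs <- set_local_seed(seed)
  on.exit(restore_seed(rs))
  collection <- make_pathway_collection(config)
  ann <- make_cohort_annotations(config, cohort_label)
  n <- nrow(ann)
  genes <- unlist(collection$sets, use.names = FALSE)
  expr <- matrix(NA_real_, n, length(genes),
                 dimnames = list(ann$sample_id, genes))
  rho <- config$noise_correlation
  for (i in seq_along(collection$sets)) {
    g <- collection$sets[[i]]
    shared <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * length(g)), n, length(g))
    expr[, g] <- sqrt(rho) * shared + sqrt(1 - rho) * eps
  }
  causal <- names(collection$sets)[seq_len(config$n_causal_pathways)]
  signal_genes <- unlist(lapply(causal, function(pw) {
    g <- collection$sets[[pw]]
    g[seq_len(max(1, round(config$causal_gene_fraction * length(g))))]
  }))
  is_case <- ann$family_history & ann$developed_cancer
  expr[is_case, signal_genes] <- expr[is_case, signal_genes] +
    config$effect_size
  # clinical covariates on a subset of samples; a minority of genes linked
  n_cov <- max(5, round(0.8 * n))
  cov_samples <- ann$sample_id[seq_len(n_cov)]
  covariates <- data.frame(
    sample_id = cov_samples,
    lymphocyte_count = stats::rnorm(n_cov, 1000, 200),
    age_menarche = stats::rnorm(n_cov, 13, 1.5),
    stringsAsFactors = FALSE)
  n_linked <- round(config$covariate_link_fraction * length(genes))
  linked <- if (n_linked > 0) sample(genes, n_linked) else character(0)
  if (n_linked > 0) {
    z <- scale(covariates$lymphocyte_count)[, 1]
    expr[cov_samples, linked] <- expr[cov_samples, linked] + 0.8 * z
  }
  list(expr = expr, annotations = ann, covariates = covariates,
       collection = collection,
       truth = list(causal_pathways = causal, signal_genes = signal_genes,
                    covariate_linked_genes = linked))
}

#' Simulate an annotated germline variant table
#'
#' Per-gene, per-sample carrier indicators are Bernoulli with the background
#' rate; in causal pathways, each family-history case is additionally a
#' pathway-level carrier with elevated probability (controls at a lower
#' rate), realized in one randomly chosen member gene. Every carried variant
#' is decorated with annotations that pass the filtering cascade; a
#' configured number of decoy variants failing each cascade rule is appended.
#' Background gene frequencies include a block of frequently mutated genes so
#' the threshold-selection procedure has a constructed breakpoint.
#'
#' @param config A [simulation_config()].
#' @param annotations Optional [sample_annotations()]; defaults to a cohort
#'   generated from `config`.
#' @param seed Integer seed.
#' @return A list: `variants` ([annotated_variants()]), `sample_ids`,
#'   `annotations`, `background_gene_freqs`, `collection`, and `truth`
#'   (causal pathways, per-sample pathway carriage, frequent genes, expected
#'   threshold-selection breakpoint).
#' @export
simulate_variant_table <- function(config = simulation_config(),
                                   annotations = NULL,
                                   seed = config$seed) {
  rs <- set_local_seed(child_seed(seed, "variants"))
  on.exit(restore_seed(rs))
  collection <- make_pathway_collection(config)
  if (is.null(annotations))
    annotations <- make_cohort_annotations(config, "seqcohort")
  ann <- annotations[annotations$family_history, , drop = FALSE]
  sample_ids <- ann$sample_id
  is_case <- ann$developed_cancer
  genes <- unlist(collection$sets, use.names = FALSE)
  causal <- names(collection$sets)[seq_len(config$n_causal_pathways)]

  carrier <- matrix(stats::rbinom(length(sample_ids) * length(genes), 1,
                                  config$mutation_rate_null),
                    nrow = length(sample_ids),
                    dimnames = list(sample_ids, genes))
  pathway_carrier <- matrix(0L, length(sample_ids), length(causal),
                            dimnames = list(sample_ids, causal))
  for (pw in causal) {
    rate <- ifelse(is_case, config$mutation_rate_causal_cases,
                   config$mutation_rate_causal_controls)
    hit <- stats::rbinom(length(sample_ids), 1, rate)
    pathway_carrier[, pw] <- hit
    g <- collection$sets[[pw]]
    for (s in which(hit == 1))
      carrier[s, sample(g, 1)] <- 1L
  }

  mutated_genes <- colnames(carrier)[colSums(carrier) > 0]
  severities <- c("HIGH", "MODERATE")
  mk_real <- function(i, g) {
    sev <- severities[1 + (i %% 2)]
    cls <- if (sev == "MODERATE" && i %% 4 == 1) "InDel" else "SNV"
    missense <- sev == "MODERATE" && cls == "SNV"
    data.frame(chrom = as.character(1 + (i %% 22)), pos = 1000L + i,
               ref = "A", alt = if (cls == "SNV") "G" else "AG",
               gene = g, variant_class = cls, severity = sev,
               is_missense = missense,
               pop_af_max = stats::runif(1, 0, 0.005),
               background_af = stats::runif(1, 0, 0.02),
               deleterious_call = if (missense) "deleterious" else NA_character_,
               in_exon_pad2 = TRUE, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_along(mutated_genes),
                 function(i) mk_real(i, mutated_genes[i]))
  carriers <- lapply(mutated_genes,
                     function(g) sample_ids[carrier[, g] == 1])

  # decoys: each fails exactly one cascade rule, with random carriers
  decoy_template <- function(i, fail) {
    d <- mk_real(10000 + i, sample(genes, 1))
    d$severity <- "HIGH"; d$is_missense <- FALSE
    d$deleterious_call <- NA_character_
    switch(fail,
           pop_af = { d$pop_af_max <- stats::runif(1, 0.02, 0.2) },
           background_af = { d$background_af <- stats::runif(1, 0.05, 0.2) },
           internal_freq = { },   # handled via carriers below
           off_exon = { d$in_exon_pad2 <- FALSE },
           effect = { d$severity <- sample(c("LOW", "MODIFIER"), 1) },
           missing_call = { d$severity <- "MODERATE"; d$is_missense <- TRUE
                            d$variant_class <- "SNV"; d$alt <- "G" })
    d
  }
  rules <- c("pop_af", "background_af", "internal_freq", "off_exon",
             "effect", "missing_call")
  for (r in rules) {
    for (j in seq_len(config$n_decoys_per_rule)) {
      d <- decoy_template(length(rows) + j, r)
      rows <- c(rows, list(d))
      carriers <- c(carriers, list(
        if (r == "internal_freq")
          sample_ids[seq_len(ceiling(0.2 * length(sample_ids)))]
        else sample(sample_ids, min(2, length(sample_ids)))))
    }
  }
  tab <- do.call(rbind, rows)
  variants <- annotated_variants(tab$chrom, tab$pos, tab$ref, tab$alt,
                                 tab$gene, tab$variant_class, tab$severity,
                                 tab$is_missense, tab$pop_af_max,
                                 tab$background_af, tab$deleterious_call,
                                 tab$in_exon_pad2, carriers)

  freq_block <- sample(genes, config$n_frequent_genes)
  bg <- stats::setNames(stats::runif(length(genes), 0, 0.0015), genes)
  bg[freq_block] <- config$frequent_gene_freq
  cand <- seq(0.002, 0.10, length.out = 50)
  expected_threshold <- max(cand[cand < config$frequent_gene_freq])

  list(variants = variants, sample_ids = sample_ids, annotations = ann,
       background_gene_freqs = bg, collection = collection,
       truth = list(causal_pathways = causal,
                    pathway_carrier = pathway_carrier,
                    is_case = is_case,
                    frequent_genes = freq_block,
                    expected_threshold = expected_threshold))
}

# Paint a filled disk into a matrix (1-based pixel coordinates).
paint_disk <- function(img, cx, cy, r, value = 1) {
  nx <- nrow(img); ny <- ncol(img)
  xs <- max(1, floor(cx - r)):min(nx, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(ny, ceiling(cy + r))
  for (x in xs) for (y in ys)
    if ((x - cx)^2 + (y - cy)^2 <= r^2) img[x, y] <- value
  img
}

#' Simulate a fluorescence microscopy field
#'
#' Emulates the two observed morphological phenotypes: control-like compact
#' clusters of tightly bunched small cells (`"clustered_small"`) versus
#' high-risk-like dispersed large cells (`"dispersed_large"`, which also
#' carry higher F-actin and focal-adhesion coverage). Nuclei are disks at
#' clustered or dispersed centers; the cell region is the union of larger
#' disks around the nuclei; stain channels are painted on a known fraction of
#' the cell region (pixels nearest the nuclei), and Gaussian noise is added.
#'
#' @param config A [simulation_config()].
#' @param phenotype `"clustered_small"` or `"dispersed_large"`.
#' @param seed Integer seed.
#' @param noise_sd Overrides `config$image_noise_sd` (set 0 for noiseless
#'   ground-truth checks).
#' @return A list: `field` ([fluorescence_field()]) and `truth`
#'   (`n_nuclei`, `centers`, `cell_area_fraction`, `actin_fraction`,
#'   `adhesion_fraction`).
#' @export
simulate_fluorescence_field <- function(config = simulation_config(),
                                        phenotype = c("clustered_small",
                                                      "dispersed_large"),
                                        seed = config$seed,
                                        noise_sd = config$image_noise_sd) {
  phenotype <- match.arg(phenotype)
  rs <- set_local_seed(child_seed(seed, paste0("field_", phenotype)))
  on.exit(restore_seed(rs))
  dimn <- config$image_dim
  r_nuc <- config$nucleus_radius
  n_nuc <- sample(seq(config$nuclei_range[1], config$nuclei_range[2]), 1)
  min_sep <- 2.4 * r_nuc
  margin <- 4 * r_nuc

  sample_centers <- function(propose) {
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(centers) < n_nuc && tries < 5000) {
      p <- propose()
      tries <- tries + 1
      if (p[1] < margin || p[1] > dimn - margin ||
          p[2] < margin || p[2] > dimn - margin) next
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, p)^2))) >= min_sep)
        centers <- rbind(centers, p)
    }
    centers
  }
  if (phenotype == "clustered_small") {
    r_cell <- 2.0 * r_nuc
    actin_target <- 0.35; adhesion_target <- 0.20
    propose_set <- function() {
      cl <- c(stats::runif(1, 0.35 * dimn, 0.65 * dimn),
              stats::runif(1, 0.35 * dimn, 0.65 * dimn))
      sample_centers(function() cl + stats::rnorm(2, 0, 3.2 * r_nuc))
    }
  } else {
    r_cell <- 3.2 * r_nuc
    actin_target <- 0.65; adhesion_target <- 0.40
    propose_set <- function() sample_centers(function()
      stats::runif(2, 0, dimn))
  }
  # the cell region must be simply connected (no background pockets fully
  # enclosed by cells): "area covered by cells" is otherwise ill-defined
  # for the hole-filling segmentation the ground truth is scored against
  for (attempt in 1:50) {
    centers <- propose_set()
    n_nuc <- nrow(centers)
    nuclei <- matrix(0, dimn, dimn)
    cellm <- matrix(0, dimn, dimn)
    for (i in seq_len(n_nuc)) {
      nuclei <- paint_disk(nuclei, centers[i, 1], centers[i, 2], r_nuc)
      cellm <- paint_disk(cellm, centers[i, 1], centers[i, 2], r_cell)
    }
    # pockets are checked after a closing at the analysis scale, since
    # closing can seal a nearly-closed ring of cells
    cl <- EBImage::closing(EBImage::Image(cellm),
                           EBImage::makeBrush(5, "disc"))
    if (sum(EBImage::fillHull(cl) > 0) == sum(cl > 0)) break
  }
  # stains are cortical: the fraction of cell pixels farthest from any
  # nucleus center (peripheral F-actin and cell-ECM focal adhesions); the
  # stained shell encloses the cell interior, so hole filling in the
  # segmentation recovers the full cell region
  cell_idx <- which(cellm == 1, arr.ind = TRUE)
  dmin <- apply(cell_idx, 1, function(p)
    min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)))
  paint_frac <- function(target) {
    k <- round(target * nrow(cell_idx))
    m <- matrix(0, dimn, dimn)
    if (k > 0) {
      sel <- cell_idx[order(dmin, decreasing = TRUE)[seq_len(k)], ,
                      drop = FALSE]
      m[sel] <- 1
    }
    m
  }
  actin <- paint_frac(actin_target)
  adhesion <- paint_frac(adhesion_target)

  addnoise <- function(m) {
    if (noise_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m))
    pmax(m, 0)
  }
  # stains ride on a diffuse cytoplasmic base covering the whole cell body
  field <- fluorescence_field(addnoise(0.45 * cellm + 0.55 * actin),
                              addnoise(0.45 * cellm + 0.55 * adhesion),
                              addnoise(nuclei),
                              group = if (phenotype == "clustered_small")
                                "control" else "high_risk")
  list(field = field,
       truth = list(n_nuclei = n_nuc, centers = centers,
                    cell_area_fraction = mean(cellm),
                    actin_fraction = mean(actin[cellm == 1]),
                    adhesion_fraction = mean(adhesion[cellm == 1])))
}
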