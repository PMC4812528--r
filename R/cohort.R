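#' Construct per-sample annotations
#'
#' Validates the annotation invariants used throughout the pipeline. BRCA
#' status `"BRCAX"` denotes a family-history participant without a known
#' pathogenic BRCA1/2 mutation, so both `"carrier"` and `"BRCAX"` require
#' `family_history = TRUE`.
#'
#' @param sample_id Unique sample identifiers.
#' @param cohort Cohort label per sample (e.g. "utah", "ontario").
#' @param family_history Logical; at least two first-degree relatives with
#'   cancer.
#' @param brca_status One of "carrier", "BRCAX", "none" per sample.
#' @param developed_cancer Logical per sample.
#' @param batch Optional batch label.
#' @param age_at_draw Optional age in years at blood draw.
#' @return A data.frame of class `sample_annotations`.
#' @export
sample_annotations <- function(sample_id, cohort, family_history, brca_status,
                               developed_cancer, batch = NA_character_,
                               age_at_draw = NA_real_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample_id values must be unique")
  brca_status <- match.arg(brca_status, c("carrier", "BRCAX", "none"),
                           several.ok = TRUE)
  n <- length(sample_id)
  ann <- data.frame(sample_id = sample_id,
                    cohort = rep_len(as.character(cohort), n),
                    family_history = rep_len(as.logical(family_history), n),
                    brca_status = rep_len(brca_status, n),
                    developed_cancer = rep_len(as.logical(developed_cancer), n),
                    batch = rep_len(as.character(batch), n),
                    age_at_draw = rep_len(as.numeric(age_at_draw), n),
                    stringsAsFactors = FALSE)
  bad <- ann$brca_status %in% c("carrier", "BRCAX") & !ann$family_history
  if (any(bad))
    stop("carrier/BRCAX status requires family_history = TRUE (sample ",
         ann$sample_id[bad][1], ")")
  class(ann) <- c("sample_annotations", "data.frame")
  ann
}

#' Published cohort composition tables
#'
#' Stratum counts for the two PBMC discovery cohorts (Utah, USA and Ontario,
#' Canada), by family history, BRCA1/2 mutation carriage, and breast cancer
#' status. These printed counts are inputs to [summarize_cohort()] arithmetic
#' and to the deterministic strata allocation of the synthetic generator.
#'
#' @return A data.frame with columns `family_history`, `brca_carrier`,
#'   `developed_cancer`, `n` (and `median_age` for Utah).
#' @export
cohort_table_utah <- function() {
  data.frame(
    family_history = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    brca_carrier = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    developed_cancer = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    n = c(16L, 23L, 18L, 26L, 22L, 19L),
    median_age = c(59, 59, 60, 63, 66, 58))
}

#' @rdname cohort_table_utah
#' @export
cohort_table_ontario <- function() {
  data.frame(
    family_history = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    brca_carrier = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    developed_cancer = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    n = c(11L, 17L, 14L, 18L, 8L, 5L))
}

#' Expand a stratum-count table into per-sample annotations
#'
#' @param counts A table as returned by [cohort_table_utah()].
#' @param cohort Cohort label for all samples.
#' @param prefix Sample-id prefix.
#' @return A [sample_annotations()] data.frame with one row per patient.
#' @export
expand_cohort_table <- function(counts, cohort, prefix = cohort) {
  idx <- rep(seq_len(nrow(counts)), counts$n)
  fh <- counts$family_history[idx]
  carrier <- counts$brca_carrier[idx]
  brca <- ifelse(carrier, "carrier", ifelse(fh, "BRCAX", "none"))
  sample_annotations(
    sample_id = sprintf("%s_%03d", prefix, seq_along(idx)),
    cohort = cohort,
    family_history = fh,
    brca_status = brca,
    developed_cancer = counts$developed_cancer[idx])
}

#' Summarize cohort composition
#'
#' Counts samples by family history, BRCA status, and cancer status, and
#' derives the headline fractions (percent carriers, percent who developed
#' cancer, family-history subgroup size). Counts partition the cohort, so
#' they always sum to the number of annotations.
#'
#' @param annotations A [sample_annotations()] data.frame (or several row-bound
#'   together).
#' @return A list with elements `strata` (count table), `total`,
#'   `n_family_history`, `n_carrier`, `n_developed_cancer`, `pct_carrier`,
#'   `pct_developed_cancer` (rounded percent).
#' @export
summarize_cohort <- function(annotations) {
  stopifnot(nrow(annotations) > 0)
  strata <- stats::aggregate(
    list(n = annotations$sample_id),
    by = list(family_history = annotations$family_history,
              brca_status = annotations$brca_status,
              developed_cancer = annotations$developed_cancer),
    FUN = length)
  total <- nrow(annotations)
  n_carrier <- sum(annotations$brca_status == "carrier")
  n_cancer <- sum(annotations$developed_cancer)
  list(strata = strata,
       total = total,
       n_family_history = sum(annotations$family_history),
       n_carrier = n_carrier,
       n_developed_cancer = n_cancer,
       pct_carrier = round(100 * n_carrier / total),
       pct_developed_cancer = round(100 * n_cancer / total))
}

#' Screen out covariate-confounded genes
#'
#' Multifactor ANCOVA-style screen: for each gene, expression is regressed
#' jointly on the supplied covariates and each factor receives a joint F-test
#' (via single-term deletion, so term order does not matter; categorical
#' covariates are tested as whole factors). A gene is blacklisted when any
#' factor's P falls below `alpha`. Covariates may cover only a subset of the
#' samples; factors sharing a missingness pattern are fitted jointly on their
#' complete cases.
#'
#' @param expr Numeric matrix, samples x genes, rownames = sample ids.
#' @param covariates Data.frame of covariates, rownames (or a `sample_id`
#'   column) identifying samples; numeric or factor/character columns; NAs
#'   mark missing values.
#' @param alpha Per-factor significance cutoff (default 0.01). No multiplicity
#'   correction is applied; this is a deliberately permissive exclusion screen.
#' @return A list: `blacklist` (gene symbols), `min_p` (named per-gene minimum
#'   factor P), `factor_p` (genes x factors matrix of P-values).
#' @export
exclude_confounded_genes <- function(expr, covariates, alpha = 0.01) {
  stopifnot(is.matrix(expr), alpha > 0, alpha < 1)
  if ("sample_id" %in% names(covariates)) {
    rownames(covariates) <- covariates$sample_id
    covariates$sample_id <- NULL
  }
  if (ncol(covariates) == 0 || nrow(covariates) == 0) {
    return(list(blacklist = character(0),
                min_p = stats::setNames(rep(NA_real_, ncol(expr)),
                                        colnames(expr)),
                factor_p = matrix(NA_real_, ncol(expr), 0,
                                  dimnames = list(colnames(expr), NULL))))
  }
  shared <- intersect(rownames(expr), rownames(covariates))
  if (length(shared) == 0) stop("no shared samples between expr and covariates")
  covariates <- covariates[shared, , drop = FALSE]
  # drop zero-variance covariates
  keep <- vapply(covariates, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) > 1
  }, TRUE)
  if (any(!keep))
    warning("dropping zero-variance covariate(s): ",
            paste(names(covariates)[!keep], collapse = ", "))
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0)
    return(exclude_confounded_genes(expr, covariates[, 0, drop = FALSE], alpha))
  for (j in seq_along(covariates))
    if (is.character(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]])

  # group covariates by identical missingness pattern; fit jointly per group
  pat <- vapply(covariates, function(v) paste(as.integer(is.na(v)),
                                              collapse = ""), "")
  groups <- split(names(covariates), pat)
  factor_p <- matrix(NA_real_, nrow = ncol(expr), ncol = ncol(covariates),
                     dimnames = list(colnames(expr), names(covariates)))
  for (grp in groups) {
    cc <- stats::complete.cases(covariates[, grp, drop = FALSE])
    samp <- shared[cc]
    X <- covariates[cc, grp, drop = FALSE]
    df_model <- sum(vapply(X, function(v)
      if (is.factor(v)) nlevels(droplevels(v)) - 1L else 1L, 1L))
    if (length(samp) <= df_model + 1)
      stop("fewer complete samples (", length(samp),
           ") than model degrees of freedom for covariates: ",
           paste(grp, collapse = ", "), "; reduce covariates")
    for (g in colnames(expr)) {
      dat <- data.frame(.y = expr[samp, g], X, check.names = FALSE)
      fit <- stats::lm(.y ~ ., data = dat)
      # perfect fits (exactly confounded genes) trigger a harmless warning
      dr <- suppressWarnings(stats::drop1(fit, test = "F"))
      pv <- dr[["Pr(>F)"]][-1]
      factor_p[g, grp] <- pv
    }
  }
  min_p <- apply(factor_p, 1, function(p)
    if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE))
  blacklist <- names(min_p)[!is.na(min_p) & min_p < alpha]
  list(blacklist = blacklist, min_p = min_p, factor_p = factor_p)
}
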