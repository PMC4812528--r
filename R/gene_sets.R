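#' Construct a gene set collection
#'
#' A `gene_set_collection` is an ordered list of named pathways, each mapping
#' to a set of uppercase gene symbols. It is the unit every downstream stage
#' (classification, mutation collapsing) iterates over.
#'
#' @param sets Named list; each element a character vector of gene symbols.
#' @param descriptions Optional character vector of per-set descriptions.
#' @param source_tags Optional character vector of provenance labels
#'   (e.g. "KEGG", "MSigDB", "article").
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, source_tags = NULL) {
  stopifnot(is.list(sets))
  nm <- names(sets)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("every gene set must be named")
  if (anyDuplicated(nm))
    stop("duplicate gene set name: ", nm[duplicated(nm)][1])
  sets <- lapply(sets, function(g) {
    g <- unique(toupper(as.character(g)))
    g <- g[!is.na(g) & g != ""]
    if (length(g) == 0) stop("gene set with no genes after cleaning")
    g
  })
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (is.null(source_tags)) source_tags <- rep(NA_character_, length(sets))
  structure(list(sets = sets, descriptions = descriptions,
                 source_tags = source_tags),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat("gene_set_collection:", length(x$sets), "sets, gene counts",
      min(sz), "-", max(sz), "\n")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene symbols are
#' uppercased and deduplicated; empty gene fields are dropped.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("GMT file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0)
    stop("malformed GMT line ", bad[1], ": fewer than 3 tab-separated fields")
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm))
    stop("duplicate gene set name in GMT: ", nm[duplicated(nm)][1])
  desc <- vapply(parts, `[[`, "", 2)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, descriptions = desc)
}

#' Write gene sets to a GMT file
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i], collection$descriptions[i],
            collection$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Restrict gene sets to a measured gene universe
#'
#' Intersects every set with the genes actually present in the expression
#' matrix (or other measured universe) and drops sets left with fewer than
#' `min_size` genes. Pathway genes absent from the platform cannot inform a
#' classifier, so they are removed up front and the loss is reported.
#'
#' @param collection A [gene_set_collection()].
#' @param universe Character vector of measured gene symbols.
#' @param min_size Minimum surviving set size (default 5).
#' @return A restricted [gene_set_collection()]; attribute `"dropped"` lists
#'   the names of sets removed for falling below `min_size`.
#' @export
restrict_to_universe <- function(collection, universe, min_size = 5) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(universe) == 0) stop("universe is empty")
  universe <- unique(toupper(universe))
  kept <- lapply(collection$sets, function(g) g[g %in% universe])
  ok <- lengths(kept) >= min_size
  dropped <- names(collection$sets)[!ok]
  if (!any(ok)) {
    warning("no gene sets survive restriction to the universe")
    out <- structure(list(sets = list(), descriptions = character(0),
                          source_tags = character(0)),
                     class = "gene_set_collection")
    attr(out, "dropped") <- dropped
    return(out)
  }
  out <- structure(list(sets = kept[ok],
                        descriptions = collection$descriptions[ok],
                        source_tags = collection$source_tags[ok]),
                   class = "gene_set_collection")
  attr(out, "dropped") <- dropped
  out
}
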