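# Rescale an intensity image to [0,1] (8-bit style contrast stretch).
# A constant image maps to all zeros.
stretch01 <- function(img) {
  rng <- range(img)
  if (!is.finite(rng[1]) || rng[2] <= rng[1])
    return(array(0, dim = dim(img)))
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Construct a fluorescence field
#'
#' Three aligned single-channel intensity images for one microscopy field:
#' F-actin (phalloidin), focal adhesions (vinculin), and nuclei (DAPI).
#'
#' @param actin,adhesion,nuclei Numeric matrices of identical dimensions,
#'   non-negative intensities.
#' @param pixel_size Microns per pixel (optional).
#' @param sample_id,group Identifiers; `group` is `"control"` or
#'   `"high_risk"`.
#' @return A list of class `fluorescence_field`.
#' @export
fluorescence_field <- function(actin, adhesion, nuclei, pixel_size = NA_real_,
                               sample_id = NA_character_,
                               group = NA_character_) {
  stopifnot(identical(dim(actin), dim(adhesion)),
            identical(dim(actin), dim(nuclei)),
            all(actin >= 0), all(adhesion >= 0), all(nuclei >= 0))
  structure(list(actin = actin, adhesion = adhesion, nuclei = nuclei,
                 pixel_size = pixel_size, sample_id = sample_id,
                 group = group),
            class = "fluorescence_field")
}

#' Read a fluorescence field from image files
#'
#' Loads the three channels from TIFF/PNG files (one file per channel) via
#' EBImage; multi-channel images are collapsed to their first frame.
#'
#' @param actin_path,adhesion_path,nuclei_path Image file paths.
#' @inheritParams fluorescence_field
#' @return A [fluorescence_field()].
#' @export
read_fluorescence_field <- function(actin_path, adhesion_path, nuclei_path,
                                    pixel_size = NA_real_,
                                    sample_id = NA_character_,
                                    group = NA_character_) {
  load1 <- function(p) {
    img <- EBImage::imageData(EBImage::readImage(p))
    if (length(dim(img)) > 2) img <- img[, , 1]
    as.matrix(img)
  }
  fluorescence_field(load1(actin_path), load1(adhesion_path),
                     load1(nuclei_path), pixel_size = pixel_size,
                     sample_id = sample_id, group = group)
}

#' Segment the cell-covered area of a field
#'
#' Contrast-stretches the combined channels (or a single channel), applies a
#' global Otsu threshold, then morphological closing and hole filling. The
#' cell-area fraction is the masked proportion of the field.
#'
#' @param field A [fluorescence_field()], or a single intensity matrix.
#' @param brush_size Diameter of the disc brush used for closing (default 5).
#' @return List with `mask` (binary matrix) and `cell_area_fraction`.
#' @export
segment_cell_area <- function(field, brush_size = 5) {
  img <- if (inherits(field, "fluorescence_field"))
    pmax(field$actin, field$adhesion, field$nuclei) else field
  img <- stretch01(img)
  if (max(img) == 0)
    return(list(mask = matrix(0L, nrow(img), ncol(img)),
                cell_area_fraction = 0))
  th <- EBImage::otsu(EBImage::Image(img))
  mask <- EBImage::Image(img > th)
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  mask <- EBImage::fillHull(EBImage::closing(mask, brush))
  mask <- matrix(as.integer(mask > 0), nrow(img), ncol(img))
  list(mask = mask, cell_area_fraction = mean(mask))
}

#' Count nuclei and locate their centers
#'
#' Binarizes the nuclei (DAPI) channel by Otsu threshold, fills holes, splits
#' touching nuclei by watershed on the distance map (the edge-guided
#' splitting role), and keeps particles of at least `min_area` pixels.
#'
#' @param nuclei_channel Intensity matrix (DAPI).
#' @param min_area Minimum particle area in pixels (default 30).
#' @return List with `count` and `centers` (matrix with columns x, y; one row
#'   per nucleus).
#' @export
count_nuclei <- function(nuclei_channel, min_area = 30) {
  img <- stretch01(nuclei_channel)
  if (max(img) == 0)
    return(list(count = 0L, centers = matrix(numeric(0), 0, 2,
                                             dimnames = list(NULL, c("x", "y")))))
  th <- EBImage::otsu(EBImage::Image(img))
  mask <- EBImage::fillHull(EBImage::Image(img > th))
  labels <- EBImage::watershed(EBImage::distmap(mask))
  areas <- table(labels[labels > 0])
  keep <- as.integer(names(areas)[areas >= min_area])
  if (length(keep) == 0)
    return(list(count = 0L, centers = matrix(numeric(0), 0, 2,
                                             dimnames = list(NULL, c("x", "y")))))
  mom <- EBImage::computeFeatures.moment(labels)
  centers <- mom[keep, c("m.cx", "m.cy"), drop = FALSE]
  colnames(centers) <- c("x", "y")
  rownames(centers) <- NULL
  list(count = length(keep), centers = centers)
}

#' Cell-size metric
#'
#' Percent of field area covered by cells divided by the number of nuclei in
#' the field: an average projected cell size in percent-per-nucleus. Fewer
#' nuclei at fixed coverage means larger cells.
#'
#' @param cell_area_fraction Proportion of the field covered by cells.
#' @param n_nuclei Nuclei count (must be >= 1; fields with no nuclei are
#'   excluded upstream).
#' @return The metric (100 * fraction / count).
#' @export
cell_size_metric <- function(cell_area_fraction, n_nuclei) {
  stopifnot(cell_area_fraction >= 0, cell_area_fraction <= 1)
  if (n_nuclei < 1) {
    warning("field with no nuclei: cell-size metric undefined")
    return(NA_real_)
  }
  100 * cell_area_fraction / n_nuclei
}

#' Three shortest inter-nucleus distances
#'
#' Computes all pairwise Euclidean distances between nucleus centers and
#' returns the three smallest, sorted ascending (fewer if fewer pairs exist).
#' A compactness measure: tightly clustered cells yield small values.
#'
#' @param centers Matrix with columns x, y.
#' @return Sorted numeric vector of length min(3, n_pairs); empty (with a
#'   warning) when fewer than 2 centers.
#' @export
nearest_nucleus_distances <- function(centers) {
  if (is.null(centers) || nrow(centers) < 2) {
    warning("fewer than 2 nucleus centers: no distances")
    return(numeric(0))
  }
  d <- sort(as.numeric(stats::dist(centers)))
  d[seq_len(min(3, length(d)))]
}

#' Fraction of cell area covered by a stain
#'
#' Subtracts the background level (estimated as the median intensity outside
#' the cell mask), contrast-stretches, and binarizes the stain channel by an
#' Otsu threshold computed over the cell region (bright stain against
#' diffuse cytoplasmic signal); reports the stained proportion of the cell
#' mask. A cell region of near-uniform positive intensity counts as fully
#' stained.
#'
#' @param stain_channel Intensity matrix (phalloidin or vinculin).
#' @param cell_mask Binary matrix from [segment_cell_area()].
#' @return Proportion in [0,1]; NA (with a warning) for an empty mask.
#' @export
stain_fraction <- function(stain_channel, cell_mask) {
  if (sum(cell_mask) == 0) {
    warning("empty cell mask: stain fraction undefined")
    return(NA_real_)
  }
  bg <- if (any(cell_mask == 0)) stats::median(stain_channel[cell_mask == 0])
        else 0
  img <- stretch01(pmax(stain_channel - bg, 0))
  inside <- img[cell_mask == 1]
  if (max(inside) == 0) return(0)
  if (diff(range(inside)) < 1e-3)   # uniform positive signal: fully stained
    return(1)
  th <- EBImage::otsu(EBImage::Image(matrix(inside, nrow = 1)))
  sum(inside > th) / sum(cell_mask)
}

#' Quantify one fluorescence field
#'
#' Runs the full morphometry pipeline on a field: cell-area segmentation,
#' nuclei counting, cell-size metric, three shortest inter-nucleus distances,
#' and actin/adhesion stain fractions.
#'
#' @param field A [fluorescence_field()].
#' @param min_area Minimum nucleus particle area (pixels).
#' @return A one-row data.frame of metrics (`shortest3` summarized by its
#'   mean as `mean_shortest3`, with the full vector as attribute
#'   `"shortest3"`).
#' @export
quantify_field <- function(field, min_area = 30) {
  seg <- segment_cell_area(field)
  nuc <- count_nuclei(field$nuclei, min_area = min_area)
  csm <- if (nuc$count >= 1)
    cell_size_metric(seg$cell_area_fraction, nuc$count) else NA_real_
  s3 <- if (nuc$count >= 2) nearest_nucleus_distances(nuc$centers)
        else numeric(0)
  out <- data.frame(sample_id = field$sample_id, group = field$group,
                    cell_area_fraction = seg$cell_area_fraction,
                    n_nuclei = nuc$count, cell_size_metric = csm,
                    mean_shortest3 = if (length(s3)) mean(s3) else NA_real_,
                    actin_fraction = stain_fraction(field$actin, seg$mask),
                    adhesion_fraction = stain_fraction(field$adhesion,
                                                       seg$mask),
                    stringsAsFactors = FALSE)
  attr(out, "shortest3") <- s3
  out
}

#' Compare per-field metrics between groups
#'
#' Welch two-sided t-tests per metric, with fields (not patients) as the
#' statistical unit. Metrics constant in both groups give P = 1 when the
#' means agree.
#'
#' @param metrics Data.frame of per-field metrics (rows = fields) including a
#'   `group` column.
#' @param metric_cols Metric columns to test (default: all numeric columns).
#' @return Data.frame with `metric`, `mean_group1`, `mean_group2`, `t`, `p`.
#' @export
compare_groups <- function(metrics, metric_cols = NULL) {
  g <- factor(metrics$group)
  stopifnot(nlevels(g) == 2)
  if (is.null(metric_cols))
    metric_cols <- names(metrics)[vapply(metrics, is.numeric, TRUE)]
  res <- lapply(metric_cols, function(mc) {
    x <- metrics[[mc]][g == levels(g)[1]]
    y <- metrics[[mc]][g == levels(g)[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2)
      return(data.frame(metric = mc, mean_group1 = mean(x),
                        mean_group2 = mean(y), t = NA_real_, p = NA_real_))
    tt <- tryCatch(stats::t.test(x, y),
                   error = function(e) NULL)   # constant data
    if (is.null(tt))
      return(data.frame(metric = mc, mean_group1 = mean(x),
                        mean_group2 = mean(y), t = 0,
                        p = if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0))
    data.frame(metric = mc, mean_group1 = mean(x), mean_group2 = mean(y),
               t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, res)
}
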