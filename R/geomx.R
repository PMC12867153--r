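#' Segment-level count matrix with negative probes
#'
#' Container for compartment-level spatial-transcriptomics counts: a
#' genes-by-segments nonnegative matrix, the subset of rows that are
#' negative (no-target) probes, and an optional compartment label per
#' segment (e.g. `"PanCK+"`, `"CD45+"`).
#'
#' @param counts Numeric matrix, genes in rows, segments in columns, with
#'   dimnames.
#' @param negative_probes Character vector of row names; must be a
#'   nonempty strict subset of the genes.
#' @param segment_labels Optional named character vector over segments.
#' @return An object of class `"count_matrix"`.
#' @export
count_matrix <- function(counts, negative_probes, segment_labels = NULL) {
  stopifnot(is.matrix(counts), is.numeric(counts),
            !is.null(rownames(counts)), !is.null(colnames(counts)),
            all(counts >= 0, na.rm = TRUE))  # NA marks flagged segments
  if (length(negative_probes) == 0L ||
      !all(negative_probes %in% rownames(counts)) ||
      length(negative_probes) >= nrow(counts)) {
    stop("negative_probes must be a nonempty strict subset of the gene rows")
  }
  if (!is.null(segment_labels)) {
    stopifnot(all(colnames(counts) %in% names(segment_labels)))
    segment_labels <- segment_labels[colnames(counts)]
  }
  structure(list(counts = counts,
                 negative_probes = as.character(negative_probes),
                 segment_labels = segment_labels),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix: %d genes (%d negative probes) x %d segments\n",
              nrow(x$counts), length(x$negative_probes), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# population (n-denominator) standard deviation; the two-point worked
# example of the geometric LOQ (probes 1 and 100 -> LOQ 1000) pins this
# convention down
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-segment limit of quantification from negative probes
#'
#' The LOQ of a segment is the geometric mean of its negative-probe
#' counts plus two standard deviations. In the default `"geometric"`
#' mode both moments are geometric: `LOQ = geoMean * geoSD^2`, i.e.
#' `exp(mean(log n) + 2 sd(log n))`. The `"arithmetic"` mode is the
#' literal mixed reading, `mean(n) + 2 sd(n)`. Standard deviations use
#' the population (n) denominator; zeros get a pseudocount of 0.5 before
#' any log. A segment whose negative probes are all zero is flagged
#' unquantifiable (`NA` LOQ).
#'
#' @param matrix A [count_matrix()] with at least two negative probes.
#' @param mode `"geometric"` (default) or `"arithmetic"`.
#' @return A `data.frame` with `segment_id`, `loq`, `quantifiable`.
#' @export
compute_loq <- function(matrix, mode = c("geometric", "arithmetic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "count_matrix"),
            length(matrix$negative_probes) >= 2L)
  neg <- matrix$counts[matrix$negative_probes, , drop = FALSE]
  loq <- apply(neg, 2, function(n) {
    if (all(n == 0)) return(NA_real_)
    n[n == 0] <- 0.5
    if (mode == "geometric") exp(mean(log(n)) + 2 * sd_pop(log(n)))
    else mean(n) + 2 * sd_pop(n)
  })
  data.frame(segment_id = colnames(neg), loq = unname(loq),
             quantifiable = !is.na(loq), stringsAsFactors = FALSE)
}

#' Filter genes (and segments) by the limit of quantification
#'
#' A gene is retained iff its count exceeds the segment LOQ in at least
#' `min_segment_fraction` of the quantifiable segments (the `>=` rule, so
#' a gene above LOQ in exactly the threshold fraction is kept). Negative
#' probes are never retained. Unquantifiable segments are masked out.
#'
#' @param matrix A [count_matrix()].
#' @param loq A [compute_loq()] result (computed if omitted).
#' @param min_segment_fraction Proportion in `[0, 1]`, default 0.1.
#' @return List of class `"loq_masks"`: `genes` and `segments`, named
#'   logical vectors.
#' @export
filter_by_loq <- function(matrix, loq = compute_loq(matrix),
                          min_segment_fraction = 0.1) {
  stopifnot(inherits(matrix, "count_matrix"),
            min_segment_fraction >= 0, min_segment_fraction <= 1)
  seg_ok <- stats::setNames(loq$quantifiable, loq$segment_id)
  seg_ok <- seg_ok[colnames(matrix$counts)]
  if (!any(seg_ok)) stop("no quantifiable segment")
  cc <- matrix$counts[, seg_ok, drop = FALSE]
  ll <- loq$loq[match(colnames(cc), loq$segment_id)]
  above <- sweep(cc, 2, ll, `>`)
  frac <- rowMeans(above)
  genes <- frac >= min_segment_fraction
  genes[rownames(matrix$counts) %in% matrix$negative_probes] <- FALSE
  if (!any(genes)) stop("all genes fall below the LOQ filter")
  structure(list(genes = genes,
                 segments = stats::setNames(seg_ok, colnames(matrix$counts))),
            class = "loq_masks")
}

#' Q3 (upper-quartile) normalization of a count matrix
#'
#' Each retained segment is scaled by
#' `factor = Q3_segment / target`, where `Q3_segment` is the segment's
#' 75th percentile over retained genes and `target` is by default the
#' geometric mean of those percentiles over retained segments (the
#' platform convention, which keeps normalized values on the count
#' scale). Afterward every retained segment's Q3 over retained genes
#' equals the common target. Passing a fixed numeric `target` instead
#' makes normalization exactly invariant to rescaling any single
#' segment. A segment with zero Q3 is flagged and excluded from the
#' geometric-mean target. Normalizing an already-normalized matrix is a
#' no-op (all factors 1).
#'
#' @param matrix A [count_matrix()] (or the `matrix` element of a
#'   previous normalization).
#' @param masks A [filter_by_loq()] result; default retains every
#'   non-negative-probe gene and all segments.
#' @param target `"geomean"` (default) or a positive number.
#' @return Object of class `"normalized_matrix"`: the scaled
#'   [count_matrix()], per-segment `q3` and `factor`, the masks and the
#'   common `target`.
#' @export
q3_normalize <- function(matrix, masks = NULL, target = "geomean") {
  if (inherits(matrix, "normalized_matrix")) matrix <- matrix$matrix
  stopifnot(inherits(matrix, "count_matrix"))
  if (is.null(masks)) {
    masks <- structure(list(
      genes = stats::setNames(!(rownames(matrix$counts) %in% matrix$negative_probes),
                              rownames(matrix$counts)),
      segments = stats::setNames(rep(TRUE, ncol(matrix$counts)),
                                 colnames(matrix$counts))), class = "loq_masks")
  }
  g <- masks$genes[rownames(matrix$counts)]
  s <- masks$segments[colnames(matrix$counts)]
  if (!any(g) || !any(s)) stop("need at least one retained gene and segment")
  q3 <- apply(matrix$counts[g, , drop = FALSE], 2,
              stats::quantile, probs = 0.75, names = FALSE, type = 7)
  good <- s & q3 > 0
  if (!any(good)) stop("every retained segment has zero Q3")
  tgt <- if (identical(target, "geomean")) exp(mean(log(q3[good])))
         else { stopifnot(is.numeric(target), target > 0); target }
  factor <- ifelse(good, q3 / tgt, NA_real_)
  norm <- matrix$counts
  norm[, good] <- sweep(matrix$counts[, good, drop = FALSE], 2,
                        factor[good], `/`)
  norm[, !good] <- NA_real_
  out <- list(matrix = count_matrix(norm, matrix$negative_probes,
                                    matrix$segment_labels),
              q3 = stats::setNames(q3, colnames(matrix$counts)),
              factor = stats::setNames(factor, colnames(matrix$counts)),
              masks = masks, target = tgt,
              flagged_segments = colnames(matrix$counts)[s & !good])
  class(out) <- "normalized_matrix"
  out
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("Q3-normalized matrix: %d x %d, target Q3 = %g\n",
              nrow(x$matrix$counts), ncol(x$matrix$counts), x$target))
  if (length(x$flagged_segments)) {
    cat("  flagged (zero-Q3) segments:",
        paste(x$flagged_segments, collapse = ", "), "\n")
  }
  invisible(x)
}
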