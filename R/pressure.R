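#' Radius neighbor search over cell centroids
#'
#' Grid-bucketed fixed-radius search: cells are binned into squares of
#' side `radius`, so each query inspects at most its 3 x 3 neighborhood of
#' buckets. Boundary cells at distance exactly `radius` are included; the
#' query cell itself is excluded.
#'
#' @param x,y Coordinate vectors.
#' @param radius Positive search radius.
#' @param query Integer indices of the cells to query (default: all).
#' @return List (one element per query) of integer index vectors, sorted.
#' @keywords internal
radius_search <- function(x, y, radius, query = seq_along(x)) {
  stopifnot(radius > 0, length(x) == length(y))
  gx <- as.integer(floor(x / radius))
  gy <- as.integer(floor(y / radius))
  key <- paste(gx, gy, sep = ",")
  buckets <- split(seq_along(x), key)
  r2 <- radius * radius
  lapply(query, function(q) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- buckets[[paste(gx[q] + dx, gy[q] + dy, sep = ",")]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != q]
    d2 <- (x[cand] - x[q])^2 + (y[cand] - y[q])^2
    sort(cand[d2 <= r2])
  })
}

#' Cells within a radius of an index cell
#'
#' All cells of any class whose centroid lies within Euclidean distance
#' `radius` of the index cell's centroid (boundary included), excluding
#' the index cell itself.
#'
#' @param table A single-sample cell table.
#' @param index_cell `cell_id` of the index cell (must be present).
#' @param radius Positive radius in coordinate units.
#' @return The subset of `table` forming the neighborhood (possibly zero
#'   rows).
#' @export
neighborhood <- function(table, index_cell, radius) {
  validate_cell_table(table, allow_negative = TRUE)
  stopifnot(radius > 0)
  if (length(unique(table$sample_id)) > 1L) {
    stop("neighborhood() expects a single-sample table")
  }
  i <- which(table$cell_id == index_cell)
  if (length(i) != 1L) stop("index cell '", index_cell, "' not found")
  nb <- radius_search(table$x, table$y, radius, query = i)[[1L]]
  table[nb, , drop = FALSE]
}

# single-probability quantile, linear interpolation between order
# statistics (identical arithmetic to stats::quantile type 7, without its
# per-call overhead; pressure evaluates this tens of thousands of times)
q_type7 <- function(v, p) {
  n <- length(v)
  if (n == 1L) return(v[1L])
  h <- (n - 1) * p
  lo <- floor(h)
  s <- sort.int(v, method = "quick")
  s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
}

resolve_cancer_labels <- function(table, cancer_labels) {
  if (inherits(cancer_labels, "gating_result")) {
    lab <- cancer_labels$is_cancer
  } else if (is.logical(cancer_labels)) {
    lab <- cancer_labels
  } else if (is.null(cancer_labels) && "cell_class" %in% names(table)) {
    lab <- table$cell_class == "cancer"
  } else {
    stop("cancer_labels must be a gating_result, a logical vector, or NULL ",
         "with a ground-truth cell_class column present")
  }
  if (length(lab) != nrow(table)) stop("cancer labels do not match the table")
  lab
}

#' Estimate the typical cancer-cell diameter
#'
#' If cell areas are available the diameter is the median over cancer
#' cells of the area-equivalent circular diameter `2 * sqrt(area / pi)`;
#' without areas it falls back to the median nearest-neighbor distance
#' among cancer cells (which needs at least two of them).
#'
#' @param table A cell table (typically one sample).
#' @param cancer_labels A [gate_cancer_cells()] result, a logical vector,
#'   or `NULL` to use the ground-truth `cell_class` column.
#' @return A single positive length.
#' @export
estimate_cell_diameter <- function(table, cancer_labels = NULL) {
  validate_cell_table(table, allow_negative = TRUE)
  lab <- resolve_cancer_labels(table, cancer_labels)
  idx <- which(lab)
  if (length(idx) == 0L) stop("no cancer cells; diameter is not estimable")
  if ("area" %in% names(table) && any(is.finite(table$area[idx]))) {
    a <- table$area[idx]
    a <- a[is.finite(a)]
    if (any(a <= 0)) stop("cancer-cell areas must be positive")
    return(stats::median(2 * sqrt(a / pi)))
  }
  if (length(idx) < 2L) {
    stop("a single cancer cell without an area gives no diameter estimate; ",
         "sample unusable")
  }
  cx <- table$x[idx]; cy <- table$y[idx]
  nn <- vapply(seq_along(idx), function(i) {
    sqrt(min((cx[-i] - cx[i])^2 + (cy[-i] - cy[i])^2))
  }, numeric(1))
  d <- stats::median(nn)
  if (d <= 0) stop("degenerate cancer-cell geometry: zero median spacing")
  d
}

#' Proximal pressure of markers on cancer cells
#'
#' For every cancer cell the proximal pressure of a marker is the 90th
#' percentile (linear interpolation between order statistics) of that
#' marker's expression over all cells — of any class — within the
#' proximity constraint: centroid distance at most
#' `radius_in_diameters` times the estimated cancer-cell diameter
#' (boundary included, index cell excluded). Cells whose neighborhood is
#' empty get a missing pressure and are counted, never zero-filled.
#' Per sample and marker the summary is the median over non-missing
#' pressures; across samples each marker's summaries are z-scored with
#' the population (n) denominator, so with two or more samples the
#' z-scores have mean 0 and variance 1.
#'
#' The default two-diameter radius reads "the region within a 1-cell
#' diameter around" a cell of diameter `d` as centroid distance
#' `<= 2 d` (own radius plus one diameter), which coincides with the
#' two-cell-radius description of the pressure area; pass
#' `radius_in_diameters = 1` for the strict centroid reading.
#'
#' @param table A cell table, one or more samples. Pressure operates on
#'   whatever intensity scale the table carries; pass it through
#'   [normalize_markers()] first for z-scored expression.
#' @param markers Marker names to profile (default: all markers).
#' @param radius_in_diameters Proximity constraint in units of the
#'   estimated cell diameter (default 2).
#' @param cancer_labels See [estimate_cell_diameter()].
#' @param prob Percentile defining the pressure (default 0.9).
#' @return An object of class `"pressure_profile"`: `cells` (long
#'   `data.frame` of per-cancer-cell pressures), `samples` (per sample and
#'   marker: cells, empty neighborhoods, median pressure, cohort z-score),
#'   `diameters` (per-sample diameter and radius), and the call
#'   parameters. Samples with no cancer cells are listed in
#'   `empty_samples` with missing summaries.
#' @seealso [compare_pressure()] for the group comparison;
#'   [summary.pressure_profile()].
#' @export
proximal_pressure <- function(table, markers = NULL, radius_in_diameters = 2,
                              cancer_labels = NULL, prob = 0.9) {
  validate_cell_table(table, allow_negative = TRUE)
  stopifnot(radius_in_diameters > 0, prob > 0, prob < 1)
  if (is.null(markers)) markers <- cell_markers(table)
  missing <- setdiff(markers, names(table))
  if (length(missing)) stop("markers absent: ", paste(missing, collapse = ", "))
  lab <- resolve_cancer_labels(table, cancer_labels)

  sids <- unique(table$sample_id)
  cell_rows <- list(); samp_rows <- list(); diam_rows <- list()
  empty_samples <- character(0)
  for (sid in sids) {
    rows <- which(table$sample_id == sid)
    sub <- table[rows, , drop = FALSE]
    sl <- lab[rows]
    cidx <- which(sl)
    if (length(cidx) == 0L) {
      empty_samples <- c(empty_samples, sid)
      diam_rows[[sid]] <- data.frame(sample_id = sid, diameter = NA_real_,
                                     radius = NA_real_, n_cancer = 0L)
      samp_rows[[sid]] <- data.frame(sample_id = sid, marker = markers,
                                     n_cancer = 0L, n_empty = 0L,
                                     median_pressure = NA_real_,
                                     stringsAsFactors = FALSE)
      next
    }
    diam <- estimate_cell_diameter(sub, sl)
    radius <- radius_in_diameters * diam
    nbs <- radius_search(sub$x, sub$y, radius, query = cidx)
    n_empty <- sum(lengths(nbs) == 0L)
    diam_rows[[sid]] <- data.frame(sample_id = sid, diameter = diam,
                                   radius = radius, n_cancer = length(cidx))
    for (m in markers) {
      vals <- sub[[m]]
      pr <- vapply(nbs, function(nb) {
        if (length(nb) == 0L) NA_real_ else q_type7(vals[nb], prob)
      }, numeric(1))
      cell_rows[[paste(sid, m)]] <-
        data.frame(sample_id = sid, cell_id = sub$cell_id[cidx], marker = m,
                   n_neighbors = lengths(nbs), pressure = pr,
                   stringsAsFactors = FALSE)
      samp_rows[[paste(sid, m)]] <-
        data.frame(sample_id = sid, marker = m, n_cancer = length(cidx),
                   n_empty = n_empty,
                   median_pressure = if (all(is.na(pr))) NA_real_
                                     else stats::median(pr, na.rm = TRUE),
                   stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, c(samp_rows, list(make.row.names = FALSE)))
  samples$z <- NA_real_
  for (m in markers) {
    i <- which(samples$marker == m & !is.na(samples$median_pressure))
    if (length(i) >= 2L) {
      v <- samples$median_pressure[i]
      sd_pop <- sqrt(mean((v - mean(v))^2))
      samples$z[i] <- if (sd_pop > 0) (v - mean(v)) / sd_pop else 0
    }
  }
  out <- list(cells = if (length(cell_rows))
                do.call(rbind, c(cell_rows, list(make.row.names = FALSE)))
              else NULL,
              samples = samples,
              diameters = do.call(rbind, c(diam_rows, list(make.row.names = FALSE))),
              empty_samples = empty_samples,
              params = list(markers = markers,
                            radius_in_diameters = radius_in_diameters,
                            prob = prob))
  class(out) <- "pressure_profile"
  out
}

#' @export
print.pressure_profile <- function(x, ...) {
  ns <- length(unique(x$samples$sample_id))
  cat(sprintf("Proximal pressure profile: %d sample(s), %d marker(s), radius = %g cell diameters, percentile = %g\n",
              ns, length(x$params$markers), x$params$radius_in_diameters,
              100 * x$params$prob))
  if (length(x$empty_samples)) {
    cat("  samples without cancer cells:",
        paste(x$empty_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize a pressure profile
#'
#' @param object A [proximal_pressure()] result.
#' @param ... Unused.
#' @return The per-sample, per-marker summary `data.frame` (median
#'   pressure and cohort z-score), invisibly also printed as a
#'   samples-by-markers median table.
#' @export
summary.pressure_profile <- function(object, ...) {
  s <- object$samples
  wide <- stats::reshape(s[, c("sample_id", "marker", "median_pressure")],
                         direction = "wide", idvar = "sample_id",
                         timevar = "marker")
  names(wide) <- sub("^median_pressure\\.", "", names(wide))
  cat("Per-sample median proximal pressure:\n")
  print(wide, row.names = FALSE, digits = 3)
  invisible(s)
}

#' @export
as.data.frame.pressure_profile <- function(x, ...) x$samples

#' Plot per-cell proximal pressures
#'
#' Box plots of per-cancer-cell pressures by sample for one marker.
#'
#' @param x A [proximal_pressure()] result.
#' @param marker Marker to plot (default: first profiled marker).
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.pressure_profile <- function(x, marker = x$params$markers[1], ...) {
  if (is.null(x$cells)) stop("profile has no per-cell pressures")
  d <- x$cells[x$cells$marker == marker & !is.na(x$cells$pressure), ]
  graphics::boxplot(pressure ~ sample_id, data = d,
                    ylab = sprintf("%s proximal pressure", marker),
                    xlab = "sample", las = 2, ...)
  invisible(x)
}

#' Collapse per-sample pressure summaries to one value per patient
#'
#' When patients contribute several cores or samples, cohort z-scores can
#' be computed across samples or across patients; both readings are
#' defensible, so the package scores across samples by default and offers
#' this collapse. Per patient and marker the collapsed summary is the
#' median of the per-sample median pressures; z-scores are recomputed
#' across patients with the population denominator.
#'
#' @param profile A [proximal_pressure()] result.
#' @param meta Per-sample `data.frame` with `sample_id` and `patient_id`.
#' @return A `data.frame` with one row per (patient, marker):
#'   `patient_id`, `marker`, `median_pressure`, `z`.
#' @export
collapse_by_patient <- function(profile, meta) {
  stopifnot(inherits(profile, "pressure_profile"),
            all(c("sample_id", "patient_id") %in% names(meta)))
  s <- merge(profile$samples, meta[, c("sample_id", "patient_id")],
             by = "sample_id")
  agg <- stats::aggregate(median_pressure ~ patient_id + marker, data = s,
                          FUN = stats::median, na.rm = TRUE)
  agg <- agg[order(agg$marker, agg$patient_id), ]
  agg$z <- NA_real_
  for (m in unique(agg$marker)) {
    i <- which(agg$marker == m & is.finite(agg$median_pressure))
    if (length(i) >= 2L) {
      v <- agg$median_pressure[i]
      sd_pop <- sqrt(mean((v - mean(v))^2))
      agg$z[i] <- if (sd_pop > 0) (v - mean(v)) / sd_pop else 0
    }
  }
  rownames(agg) <- NULL
  agg
}

#' Compare proximal pressure between response groups
#'
#' Per marker, the per-sample median pressures of "resistant" samples are
#' compared with those of "sensitive" samples by a two-sided Wilcoxon
#' rank-sum test; p-values are adjusted across markers with
#' Benjamini-Hochberg. The effect direction is the sign of
#' (resistant median - sensitive median). A marker whose summaries are
#' entirely missing in one group is reported untestable rather than
#' silently dropped.
#'
#' @param profile A [proximal_pressure()] result.
#' @param meta Per-sample `data.frame` with `sample_id` and `response`
#'   (`"sensitive"` / `"resistant"`; other labels are ignored).
#' @param markers Markers to compare (default: all profiled).
#' @return Object of class `"pressure_comparison"`: a `data.frame` with
#'   one row per marker (group sizes, rank-sum statistic, p, BH-adjusted
#'   p, direction, untestable flag).
#' @export
compare_pressure <- function(profile, meta, markers = NULL) {
  stopifnot(inherits(profile, "pressure_profile"),
            all(c("sample_id", "response") %in% names(meta)))
  if (is.null(markers)) markers <- profile$params$markers
  s <- merge(profile$samples, meta[, c("sample_id", "response")],
             by = "sample_id")
  rows <- lapply(markers, function(m) {
    sm <- s[s$marker == m, ]
    a <- sm$median_pressure[sm$response == "sensitive"]
    b <- sm$median_pressure[sm$response == "resistant"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0L || length(b) == 0L) {
      return(data.frame(marker = m, n_sensitive = length(a),
                        n_resistant = length(b), statistic = NA_real_,
                        p_value = NA_real_, direction = 0L, untestable = TRUE,
                        stringsAsFactors = FALSE))
    }
    ts <- rank_sum_test(b, a)
    data.frame(marker = m, n_sensitive = length(a), n_resistant = length(b),
               statistic = ts$statistic, p_value = ts$p_value,
               direction = sign(stats::median(b) - stats::median(a)),
               untestable = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  testable <- !out$untestable
  if (any(testable)) out$fdr[testable] <- bh_fdr(out$p_value[testable])
  class(out) <- c("pressure_comparison", "data.frame")
  out
}

#' @export
print.pressure_comparison <- function(x, ...) {
  cat("Group comparison of per-sample median proximal pressure",
      "(resistant vs sensitive)\n")
  df <- as.data.frame(x)
  df$direction <- c("down", "none", "up")[df$direction + 2L]
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
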