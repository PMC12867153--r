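#' Describe one immune population for the tissue simulator
#'
#' @param class_name Cell-class label; also the name of the population's
#'   defining marker (e.g. `"CD8"`).
#' @param count Number of cells of this class per sample.
#' @param attraction Attraction strength `lambda >= 0` toward cancer cells.
#'   `lambda = 0` places the population uniformly; the mixing weight of the
#'   attracted component is `lambda / (1 + lambda)`.
#' @param marker_mean_log,marker_sd_log Lognormal parameters (natural-log
#'   scale) of the defining marker's intensity on cells of this class.
#' @return A list with the five population fields.
#' @export
immune_population <- function(class_name, count, attraction,
                              marker_mean_log = 6, marker_sd_log = 0.5) {
  stopifnot(is.character(class_name), length(class_name) == 1L,
            count >= 1, attraction >= 0, marker_sd_log >= 0)
  list(class_name = class_name, count = as.integer(count),
       attraction = attraction,
       marker_mean_log = marker_mean_log, marker_sd_log = marker_sd_log)
}

#' Simulation configuration for a synthetic tumor cohort
#'
#' Parameterizes a cohort of synthetic tissue samples: cancer cells placed
#' in clustered nests, immune populations with tunable attraction toward
#' cancer cells, lognormal marker intensities with class-specific means,
#' and a planted group difference ("resistant" samples multiply selected
#' populations' attraction by `group_effect`).
#'
#' Coordinates and lengths share one arbitrary unit (think micrometres);
#' areas are in squared units. The attraction kernel is exponential decay
#' in the distance to the nearest cancer cell with scale equal to one
#' synthetic cell diameter, `2 * sqrt(cell_area_mean / pi)`.
#'
#' @param n_samples_per_group Samples per response group (two groups).
#' @param field_size Two positive extents `c(width, height)` of the field.
#' @param n_nests Number of cancer-cell nests (cluster centers).
#' @param nest_spread Standard deviation of cancer-cell displacement
#'   around its nest center.
#' @param n_cancer_cells Cancer cells per sample.
#' @param immune_populations List of [immune_population()] descriptions.
#' @param epithelial_markers Marker names expressed by cancer cells.
#' @param cancer_marker_mean_log,cancer_marker_sd_log Lognormal parameters
#'   of epithelial-marker intensity on cancer cells.
#' @param background_marker_mean_log,background_marker_sd_log Lognormal
#'   parameters of every marker on cells that do not express it.
#' @param cell_area_mean,cell_area_sd Truncated-normal cell-area
#'   parameters (areas floored at 1 so a diameter is always estimable).
#' @param group_effect Named numeric vector: multiplier applied to the
#'   named populations' attraction in "resistant" samples. The default
#'   plants a five-fold CD8 attraction increase, the cohort-level signal
#'   every downstream stage is checked against.
#' @param seed Integer root seed; identical configurations and seeds give
#'   bit-identical cohorts.
#' @return A validated list of class `"sim_config"`.
#' @seealso [generate_tissue()], [generate_cohort()]
#' @export
sim_config <- function(n_samples_per_group = 20,
                       field_size = c(1000, 1000),
                       n_nests = 5,
                       nest_spread = 60,
                       n_cancer_cells = 150,
                       immune_populations = list(
                         immune_population("CD8", 60, 1),
                         immune_population("CD20", 40, 1),
                         immune_population("CD68", 40, 1),
                         immune_population("FOXP3", 25, 1),
                         immune_population("CD4", 50, 1)
                       ),
                       epithelial_markers = c("PanCK", "Ecad"),
                       cancer_marker_mean_log = 6,
                       cancer_marker_sd_log = 0.5,
                       background_marker_mean_log = 3,
                       background_marker_sd_log = 0.5,
                       cell_area_mean = 200,
                       cell_area_sd = 40,
                       group_effect = c(CD8 = 5),
                       seed = 1L) {
  cfg <- list(n_samples_per_group = as.integer(n_samples_per_group),
              field_size = as.numeric(field_size),
              n_nests = as.integer(n_nests),
              nest_spread = as.numeric(nest_spread),
              n_cancer_cells = as.integer(n_cancer_cells),
              immune_populations = immune_populations,
              epithelial_markers = as.character(epithelial_markers),
              cancer_marker_mean_log = cancer_marker_mean_log,
              cancer_marker_sd_log = cancer_marker_sd_log,
              background_marker_mean_log = background_marker_mean_log,
              background_marker_sd_log = background_marker_sd_log,
              cell_area_mean = cell_area_mean,
              cell_area_sd = cell_area_sd,
              group_effect = group_effect,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config Object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    stopifnot(n_samples_per_group >= 1,
              length(field_size) == 2L, all(field_size > 0),
              n_nests >= 1, nest_spread >= 0,
              n_cancer_cells >= 1,
              length(immune_populations) >= 1,
              length(epithelial_markers) >= 1,
              cancer_marker_sd_log >= 0, background_marker_sd_log >= 0,
              cell_area_mean > 0, cell_area_sd >= 0,
              all(group_effect >= 0))
  })
  cls <- vapply(config$immune_populations, `[[`, "", "class_name")
  if (anyDuplicated(cls)) stop("immune population class names must be unique")
  if (any(cls %in% config$epithelial_markers)) {
    stop("immune class names must not collide with epithelial markers")
  }
  invisible(config)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic tissue configuration\n")
  cat(sprintf("  %d samples/group, field %g x %g, %d cancer cells in %d nests (spread %g)\n",
              x$n_samples_per_group, x$field_size[1], x$field_size[2],
              x$n_cancer_cells, x$n_nests, x$nest_spread))
  for (p in x$immune_populations) {
    cat(sprintf("  %-6s n = %3d  lambda = %g\n", p$class_name, p$count,
                p$attraction))
  }
  cat("  resistant-group effect:",
      paste(names(x$group_effect), x$group_effect, sep = " x ", collapse = ", "),
      "\n")
  invisible(x)
}

# Squared-distance of each (px, py) to its nearest (cx, cy); plain loops
# over the smaller set keep memory flat for large proposal batches.
nearest_cancer_dist <- function(px, py, cx, cy) {
  best <- rep(Inf, length(px))
  for (j in seq_along(cx)) {
    d2 <- (px - cx[j])^2 + (py - cy[j])^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Rejection sampler for the attracted component: uniform proposals over the
# field accepted with probability exp(-d_nearest_cancer / scale). Exact for
# that density and deterministic under the caller's RNG state.
sample_attracted <- function(n, field, cx, cy, scale) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  out_x <- numeric(0); out_y <- numeric(0)
  tries <- 0L
  while (length(out_x) < n && tries < 1000L) {
    b <- max(2000L, 40L * (n - length(out_x)))
    px <- stats::runif(b, 0, field[1])
    py <- stats::runif(b, 0, field[2])
    keep <- stats::runif(b) < exp(-nearest_cancer_dist(px, py, cx, cy) / scale)
    out_x <- c(out_x, px[keep]); out_y <- c(out_y, py[keep])
    tries <- tries + 1L
  }
  if (length(out_x) < n) stop("attraction sampler failed to place cells")
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

rtrunc_norm <- function(n, mean, sd, floor = 1) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < floor)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate one synthetic tissue sample
#'
#' Places cancer cells by a Thomas-like cluster process (nest centers
#' uniform over the field, offspring displaced by a Gaussian of scale
#' `nest_spread`, clamped to the field) and each immune population by a
#' two-component mixture: a uniform component and an attracted component
#' whose density decays exponentially with the distance to the nearest
#' cancer cell. The mixing weight of the attracted component is
#' `lambda_eff / (1 + lambda_eff)` with
#' `lambda_eff = attraction * group multiplier` for "resistant" samples.
#' Marker intensities are lognormal with the class mean for each class's
#' defining marker(s) and the background mean elsewhere; ground-truth
#' `cell_class` is recorded. Coincident coordinates are permitted.
#'
#' @param config A [sim_config()].
#' @param sample_id Sample identifier for the output rows.
#' @param group `"sensitive"` or `"resistant"`; selects whether
#'   `group_effect` multipliers apply.
#' @param seed_offset Integer added to `config$seed` so each sample draws
#'   from its own reproducible stream.
#' @return A cell table `data.frame` (see [cell_markers()]) with columns
#'   `sample_id, cell_id, x, y, area`, one column per marker, and
#'   `cell_class`.
#' @export
generate_tissue <- function(config, sample_id, group = "sensitive",
                            seed_offset = 0L) {
  validate_sim_config(config)
  stopifnot(group %in% c("sensitive", "resistant"))
  set.seed((config$seed + as.integer(seed_offset)) %% 2147483647L)
  fld <- config$field_size
  diam <- 2 * sqrt(config$cell_area_mean / pi)

  # cancer nests
  ncc <- config$n_cancer_cells
  centers <- cbind(stats::runif(config$n_nests, 0, fld[1]),
                   stats::runif(config$n_nests, 0, fld[2]))
  nest <- sample.int(config$n_nests, ncc, replace = TRUE)
  cx <- pmin(pmax(centers[nest, 1] + stats::rnorm(ncc, 0, config$nest_spread), 0), fld[1])
  cy <- pmin(pmax(centers[nest, 2] + stats::rnorm(ncc, 0, config$nest_spread), 0), fld[2])

  xs <- cx; ys <- cy
  classes <- rep("cancer", ncc)
  for (p in config$immune_populations) {
    lam <- p$attraction
    if (group == "resistant" && p$class_name %in% names(config$group_effect)) {
      lam <- lam * config$group_effect[[p$class_name]]
    }
    w <- lam / (1 + lam)
    n_attr <- stats::rbinom(1L, p$count, w)
    att <- sample_attracted(n_attr, fld, cx, cy, diam)
    n_unif <- p$count - n_attr
    xs <- c(xs, att[, 1], stats::runif(n_unif, 0, fld[1]))
    ys <- c(ys, att[, 2], stats::runif(n_unif, 0, fld[2]))
    classes <- c(classes, rep(p$class_name, p$count))
  }

  n <- length(xs)
  markers <- c(config$epithelial_markers,
               vapply(config$immune_populations, `[[`, "", "class_name"))
  mean_log <- matrix(config$background_marker_mean_log, n, length(markers),
                     dimnames = list(NULL, markers))
  sd_log <- matrix(config$background_marker_sd_log, n, length(markers))
  mean_log[classes == "cancer", config$epithelial_markers] <- config$cancer_marker_mean_log
  sd_log[classes == "cancer",
         match(config$epithelial_markers, markers)] <- config$cancer_marker_sd_log
  for (p in config$immune_populations) {
    rows <- classes == p$class_name
    mean_log[rows, p$class_name] <- p$marker_mean_log
    sd_log[rows, match(p$class_name, markers)] <- p$marker_sd_log
  }
  intens <- matrix(stats::rlnorm(n * length(markers), as.vector(mean_log),
                                 as.vector(sd_log)),
                   n, length(markers), dimnames = list(NULL, markers))

  out <- data.frame(sample_id = sample_id,
                    cell_id = sprintf("c%05d", seq_len(n)),
                    x = xs, y = ys,
                    area = rtrunc_norm(n, config$cell_area_mean, config$cell_area_sd),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(intens))
  out$cell_class <- classes
  validate_cell_table(out)
  out
}

#' Generate a full synthetic cohort with planted ground truth
#'
#' Builds `2 * n_samples_per_group` samples in two response groups.
#' "Resistant" samples apply the configuration's `group_effect` attraction
#' multipliers. On-treatment Ki67 percentages are drawn uniformly from
#' `[0.5, 2.7]` (sensitive) and `[7.4, 25]` (resistant) so that every
#' sample falls unambiguously inside the printed classification bands;
#' [classify_response()] recovers the group label exactly.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_cohort"` with elements `cells` (one cell
#'   table stacking all samples) and `meta` (per-sample `data.frame`:
#'   `sample_id`, `patient_id`, `timepoint`, `ki67_percent`, `aqua_score`,
#'   `response`).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_samples_per_group
  set.seed(config$seed %% 2147483647L)
  ki67 <- c(stats::runif(n, 0.5, 2.7), stats::runif(n, 7.4, 25))
  ids <- c(sprintf("sens%02d", seq_len(n)), sprintf("res%02d", seq_len(n)))
  groups <- rep(c("sensitive", "resistant"), each = n)
  meta <- data.frame(sample_id = ids,
                     patient_id = sub("^(sens|res)", "pt_\\1", ids),
                     timepoint = "onTx",
                     ki67_percent = ki67,
                     aqua_score = NA_real_,
                     response = classify_response(ki67),
                     stringsAsFactors = FALSE)
  tables <- vector("list", 2L * n)
  for (i in seq_along(ids)) {
    tables[[i]] <- generate_tissue(config, ids[i], groups[i], seed_offset = i)
  }
  out <- list(cells = do.call(rbind, tables), meta = meta, config = config)
  class(out) <- "sim_cohort"
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples (%d/group), %d cells, markers: %s\n",
              nrow(x$meta), x$config$n_samples_per_group, nrow(x$cells),
              paste(cell_markers(x$cells), collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic segment-level count matrix with negative probes
#'
#' Emulates compartment-level spatial-transcriptomics counts: gene counts
#' are lognormal around gene-specific means multiplied by segment-specific
#' scale factors (so the 75th percentile differs across segments before
#' normalization), and negative probes are drawn from a low-mean
#' distribution near the unexpressed-gene level. A planted
#' expressed/unexpressed split is recorded so LOQ filtering can be scored
#' against ground truth.
#'
#' @param n_segments,n_genes Number of segments and (non-probe) genes.
#' @param n_neg_probes Number of negative probes (`>= 2`).
#' @param seed Integer seed; fixed seed gives an identical matrix.
#' @param frac_expressed Fraction of genes planted as expressed (counts
#'   well above the negative-probe level).
#' @param segment_scale Optional numeric vector of per-segment scale
#'   factors; default lognormal with sdlog 0.4. Pass `rep(1, n_segments)`
#'   to remove segment-level scale differences.
#' @param neg_constant Degenerate mode: if non-`NULL`, every negative
#'   probe count is set to this constant (zero log-variance, so the
#'   geometric LOQ equals the constant).
#' @return A [count_matrix()] whose `"expressed"` attribute is the named
#'   logical ground-truth vector over genes.
#' @export
generate_counts <- function(n_segments, n_genes, n_neg_probes, seed,
                            frac_expressed = 0.6, segment_scale = NULL,
                            neg_constant = NULL) {
  stopifnot(n_segments >= 1, n_genes >= 1, n_neg_probes >= 2)
  set.seed(as.integer(seed) %% 2147483647L)
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  neg_ids <- sprintf("NEGPRB%02d", seq_len(n_neg_probes))
  expressed <- stats::setNames(rep(FALSE, n_genes), gene_ids)
  expressed[sample.int(n_genes, round(frac_expressed * n_genes))] <- TRUE
  # unexpressed genes sit slightly below the probe mean so the planted
  # split is separable by a negative-probe LOQ at realistic probe counts
  mean_log <- ifelse(expressed, stats::runif(n_genes, 3.5, 6), 0.4)
  mean_log <- c(mean_log, rep(0.8, n_neg_probes))
  if (is.null(segment_scale)) {
    segment_scale <- stats::rlnorm(n_segments, 0, 0.4)
  }
  stopifnot(length(segment_scale) == n_segments, all(segment_scale > 0))
  nr <- n_genes + n_neg_probes
  mu <- outer(mean_log, log(segment_scale), `+`)
  counts <- matrix(stats::rlnorm(nr * n_segments, as.vector(mu), 0.3),
                   nr, n_segments,
                   dimnames = list(c(gene_ids, neg_ids),
                                   sprintf("seg%03d", seq_len(n_segments))))
  if (!is.null(neg_constant)) {
    stopifnot(neg_constant > 0)
    counts[neg_ids, ] <- neg_constant
  }
  labels <- stats::setNames(rep(c("PanCK+", "CD45+"), length.out = n_segments),
                            colnames(counts))
  cm <- count_matrix(counts, neg_ids, labels)
  attr(cm, "expressed") <- expressed
  cm
}
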