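#' Normalize marker intensities per sample
#'
#' In `"zscore"` mode each marker is `log1p`-transformed and then centered
#' and scaled to zero mean and unit variance within each sample; `"raw"`
#' returns the table unchanged. Markers that are constant within a sample
#' cannot be scaled: they are centered only and flagged. The transform
#' parameters are attached as the `"norm_report"` attribute
#' (`data.frame`: sample, marker, mean, sd, constant flag) for audit.
#'
#' @param table A cell table (nonnegative intensities).
#' @param mode `"zscore"` (default) or `"raw"`.
#' @return The table with transformed marker columns (which may be
#'   negative after z-scoring) and a `"norm_report"` attribute.
#' @export
normalize_markers <- function(table, mode = c("zscore", "raw")) {
  mode <- match.arg(mode)
  validate_cell_table(table)
  if (mode == "raw") {
    attr(table, "norm_report") <- data.frame(sample_id = character(0),
                                             marker = character(0),
                                             mean = numeric(0), sd = numeric(0),
                                             constant = logical(0))
    return(table)
  }
  markers <- cell_markers(table)
  rep_rows <- list()
  for (sid in unique(table$sample_id)) {
    rows <- table$sample_id == sid
    for (m in markers) {
      y <- log1p(table[[m]][rows])
      mu <- mean(y)
      s <- stats::sd(y)
      constant <- !is.finite(s) || s == 0
      table[[m]][rows] <- if (constant) y - mu else (y - mu) / s
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(sample_id = sid, marker = m, mean = mu,
                   sd = if (constant) NA_real_ else s, constant = constant,
                   stringsAsFactors = FALSE)
    }
  }
  attr(table, "norm_report") <- do.call(rbind, rep_rows)
  table
}

# Two-component 1-D Gaussian mixture by EM, seeded at the 25th/75th
# percentiles so the fit is deterministic and shift-equivariant (gating
# thresholds then transform covariantly under rescaling of intensities).
fit_gmm2 <- function(x, max_iter = 300, tol = 1e-9) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  mu <- q
  sg <- rep(max(stats::sd(x) / 2, 1e-6), 2)
  pi1 <- 0.5
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(x, mu[1], sg[1])
    d2 <- (1 - pi1) * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    if (any(tot == 0) || anyNA(tot)) return(NULL)
    g <- d2 / tot
    ll <- sum(log(tot))
    n2 <- sum(g); n1 <- length(x) - n2
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
    mu <- c(sum((1 - g) * x) / n1, sum(g * x) / n2)
    sg <- sqrt(c(sum((1 - g) * (x - mu[1])^2) / n1,
                 sum(g * (x - mu[2])^2) / n2))
    sg <- pmax(sg, 1e-8)
    pi1 <- n1 / length(x)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (mu[1] > mu[2]) {  # keep component 2 the high (positive) one
    mu <- rev(mu); sg <- rev(sg); pi1 <- 1 - pi1
  }
  list(mu = mu, sg = sg, pi1 = pi1)
}

# Equal-posterior crossing between the two component means; NULL when the
# fit is degenerate (collapsed means or vanishing separation).
gmm_threshold <- function(fit) {
  if (is.null(fit)) return(NULL)
  if (diff(fit$mu) < 1e-6 * max(1, abs(fit$mu[2]))) return(NULL)
  f <- function(t) {
    log(fit$pi1) + stats::dnorm(t, fit$mu[1], fit$sg[1], log = TRUE) -
      log(1 - fit$pi1) - stats::dnorm(t, fit$mu[2], fit$sg[2], log = TRUE)
  }
  lo <- fit$mu[1]; hi <- fit$mu[2]
  if (f(lo) <= 0 || f(hi) >= 0) return(NULL)
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Gate cancer cells from epithelial-marker intensities
#'
#' Fits, per sample and per epithelial marker, a positivity threshold on
#' the log of the strictly positive intensities via a two-component
#' Gaussian mixture (threshold at the equal-posterior point between the
#' component means; ties broken toward non-cancer). A cell is labeled
#' cancer if it is positive for at least one marker (`policy = "any"`,
#' matching "and/or") or for all markers (`policy = "all"`). Zero
#' intensities are below any threshold. Degenerate mixture fits (collapsed
#' components, too few positive cells) fall back to the 75th-percentile
#' log-intensity threshold and are flagged.
#'
#' @param table A cell table with raw (un-normalized) intensities.
#' @param epithelial_markers Marker names used to identify cancer cells.
#' @param policy `"any"` (default) or `"all"`.
#' @return An object of class `"gating_result"`: list with `is_cancer`
#'   (logical per row of `table`), `thresholds` (`data.frame` of
#'   per-sample per-marker thresholds on the intensity scale, method and
#'   fallback flag), `policy` and `markers`.
#' @export
gate_cancer_cells <- function(table,
                              epithelial_markers = c("PanCK", "Ecad"),
                              policy = c("any", "all")) {
  policy <- match.arg(policy)
  validate_cell_table(table)
  missing <- setdiff(epithelial_markers, cell_markers(table))
  if (length(missing) > 0L) {
    stop("markers not in table: ", paste(missing, collapse = ", "))
  }
  pos_mat <- matrix(FALSE, nrow(table), length(epithelial_markers))
  thr_rows <- list()
  for (sid in unique(table$sample_id)) {
    rows <- which(table$sample_id == sid)
    for (k in seq_along(epithelial_markers)) {
      m <- epithelial_markers[k]
      v <- table[[m]][rows]
      lx <- log(v[v > 0])
      thr_log <- NULL
      method <- "gmm"
      if (length(lx) >= 20L && stats::sd(lx) > 0) {
        thr_log <- gmm_threshold(fit_gmm2(lx))
      }
      if (is.null(thr_log)) {
        method <- "quantile75"
        thr_log <- stats::quantile(if (length(lx)) lx else log(pmax(v, 1e-12)),
                                   0.75, names = FALSE, type = 7)
      }
      # strictly greater: a cell exactly at threshold is non-cancer
      pos_mat[rows, k] <- v > exp(thr_log)
      thr_rows[[length(thr_rows) + 1L]] <-
        data.frame(sample_id = sid, marker = m, threshold = exp(thr_log),
                   method = method, fallback = method != "gmm",
                   stringsAsFactors = FALSE)
    }
  }
  is_cancer <- if (policy == "any") rowSums(pos_mat) >= 1L
               else rowSums(pos_mat) == length(epithelial_markers)
  out <- list(is_cancer = is_cancer,
              positivity = stats::setNames(as.data.frame(pos_mat),
                                           epithelial_markers),
              thresholds = do.call(rbind, thr_rows),
              policy = policy, markers = epithelial_markers)
  class(out) <- "gating_result"
  out
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("Cancer-cell gating (%s of %s): %d / %d cells labeled cancer\n",
              x$policy, paste(x$markers, collapse = ", "),
              sum(x$is_cancer), length(x$is_cancer)))
  nfall <- sum(x$thresholds$fallback)
  if (nfall > 0L) cat(sprintf("  %d threshold(s) used the quantile fallback\n", nfall))
  invisible(x)
}
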