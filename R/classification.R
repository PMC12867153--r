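#' Ki67 labeling index from an AQUA score
#'
#' The labeling index is `ln(AQUA score + 0.01)`; the small offset keeps
#' zero scores finite. Strictly increasing, and inverted exactly by
#' `exp(index) - 0.01`.
#'
#' @param aqua_score Nonnegative AQUA (automated quantitative analysis)
#'   score(s).
#' @return Numeric vector of labeling indices.
#' @examples
#' ki67_index(0)        # ln(0.01)
#' ki67_index(0.99)     # 0
#' @export
ki67_index <- function(aqua_score) {
  if (!is.numeric(aqua_score) || anyNA(aqua_score) || any(aqua_score < 0)) {
    stop("aqua_score must be nonnegative")
  }
  log(aqua_score + 0.01)
}

#' Classify endocrine-therapy response from on-treatment Ki67
#'
#' Tumors with on-treatment Ki67 at or below 2.7% of tumor cells are
#' classed endocrine-deprivation sensitive, at or above 7.4% resistant,
#' and strictly between the two intermediate (excluded from group
#' comparisons). Boundaries are closed on the sensitive and resistant
#' sides, matching the printed `<=` / `>=` criteria.
#'
#' @param ki67_percent Ki67-positive percentage(s) in `[0, 100]`.
#' @return Character vector with values `"sensitive"`, `"intermediate"`,
#'   or `"resistant"`.
#' @examples
#' classify_response(c(2.7, 5, 7.4))
#' @export
classify_response <- function(ki67_percent) {
  if (!is.numeric(ki67_percent) || anyNA(ki67_percent) ||
      any(ki67_percent < 0 | ki67_percent > 100)) {
    stop("ki67_percent must lie in [0, 100]")
  }
  ifelse(ki67_percent <= 2.7, "sensitive",
         ifelse(ki67_percent >= 7.4, "resistant", "intermediate"))
}

#' Default cytolytic-activity gene set
#'
#' Granzyme A and perforin, the canonical two-gene cytolytic-activity
#' signature; the set is fully configurable in [signature_score()]
#' because signature definitions vary across studies.
#'
#' @return Character vector of gene symbols.
#' @export
cytolytic_genes <- function() c("GZMA", "PRF1")

#' Score a gene signature per sample
#'
#' Method `"geomean"` computes, per sample, the geometric mean of
#' `expression + pseudocount` over the genes of the set present in the
#' data (pseudocount 0.01 by default; set it to 0 for the pure geometric
#' mean). Method `"meanz"` computes per-gene z-scores across the cohort
#' and averages them per sample, so cohort scores are centered at zero;
#' it requires at least two samples.
#'
#' @param expr Named nonnegative expression vector (one sample) or a
#'   genes-by-samples numeric matrix.
#' @param gene_set Character vector of gene identifiers; genes absent from
#'   `expr` are dropped (an error if none remain).
#' @param method `"geomean"` or `"meanz"`.
#' @param pseudocount Offset added before the log in `"geomean"`.
#' @return A `data.frame` with columns `sample_id`, `score`, `method`, and
#'   the genes used in the `"genes"` attribute.
#' @examples
#' signature_score(c(GZMA = 4, PRF1 = 9), pseudocount = 0)$score  # 6
#' @export
signature_score <- function(expr, gene_set = cytolytic_genes(),
                            method = c("geomean", "meanz"),
                            pseudocount = 0.01) {
  method <- match.arg(method)
  stopifnot(length(gene_set) >= 1, pseudocount >= 0)
  if (is.vector(expr)) expr <- matrix(expr, ncol = 1,
                                      dimnames = list(names(expr), "sample1"))
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), all(expr >= 0))
  genes <- intersect(gene_set, rownames(expr))
  if (length(genes) == 0L) {
    stop("no gene of the set is present; missing: ",
         paste(gene_set, collapse = ", "))
  }
  sub <- expr[genes, , drop = FALSE]
  if (method == "geomean") {
    score <- exp(colMeans(log(sub + pseudocount)))
  } else {
    if (ncol(sub) < 2L) stop("'meanz' needs a cohort of >= 2 samples")
    sds <- apply(sub, 1, stats::sd)
    z <- (sub - rowMeans(sub)) / ifelse(sds > 0, sds, 1)
    score <- colMeans(z)
  }
  out <- data.frame(sample_id = colnames(expr), score = unname(score),
                    method = method, stringsAsFactors = FALSE)
  attr(out, "genes") <- genes
  out
}
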