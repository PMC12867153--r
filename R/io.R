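#' Read and write cell tables as delimited text
#'
#' Tab-separated UTF-8 with a header row: `sample_id, cell_id, x, y,
#' area`, one column per marker, and optionally `cell_class`.
#'
#' @param table A cell table.
#' @param path File path.
#' @return `read_cell_table()` returns a validated cell table;
#'   `write_cell_table()` returns `path` invisibly.
#' @export
write_cell_table <- function(table, path) {
  validate_cell_table(table, allow_negative = TRUE)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8")
  validate_cell_table(tab, allow_negative = TRUE)
  tab
}

#' Read and write count matrices as delimited text
#'
#' Genes-by-segments tab-separated text with a `gene_id` column and a
#' boolean `negative_probe` column ahead of the per-segment counts.
#' Segment compartment labels, when present, go to a companion
#' two-column file.
#'
#' @param matrix A [count_matrix()].
#' @param path Counts file path.
#' @param segments_path Optional path for the `segment_id, label` table.
#' @return `read_count_matrix()` returns a [count_matrix()];
#'   `write_count_matrix()` returns `path` invisibly.
#' @export
write_count_matrix <- function(matrix, path, segments_path = NULL) {
  stopifnot(inherits(matrix, "count_matrix"))
  df <- data.frame(gene_id = rownames(matrix$counts),
                   negative_probe = rownames(matrix$counts) %in%
                     matrix$negative_probes,
                   matrix$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(segments_path) && !is.null(matrix$segment_labels)) {
    utils::write.table(
      data.frame(segment_id = names(matrix$segment_labels),
                 label = unname(matrix$segment_labels)),
      segments_path, sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, segments_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  counts <- as.matrix(df[, setdiff(names(df), c("gene_id", "negative_probe")),
                         drop = FALSE])
  rownames(counts) <- df$gene_id
  labels <- NULL
  if (!is.null(segments_path)) {
    seg <- utils::read.delim(segments_path, stringsAsFactors = FALSE)
    labels <- stats::setNames(seg$label, seg$segment_id)
  }
  count_matrix(counts, df$gene_id[df$negative_probe], labels)
}

#' Read and write a simulation configuration as JSON
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `read_sim_config()` returns a validated [sim_config()];
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  jsonlite::write_json(sim_config_as_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# JSON-safe plain-list form: group_effect as a named list so a singleton
# keeps its name under auto_unbox
sim_config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$group_effect <- as.list(cfg$group_effect)
  cfg
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  as_sim_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Rebuild a simulation configuration from a plain list
#'
#' Accepts the parsed form of a configuration JSON (or of the
#' `sim_config` entry of a pipeline manifest) and revalidates it, so a
#' manifest alone suffices to reproduce a run.
#'
#' @param raw A named list with the [sim_config()] fields.
#' @return A validated [sim_config()].
#' @export
as_sim_config <- function(raw) {
  pops <- raw$immune_populations
  if (is.data.frame(pops)) {
    pops <- lapply(seq_len(nrow(pops)), function(i) as.list(pops[i, ]))
  }
  do.call(sim_config, c(
    raw[setdiff(names(raw), c("immune_populations", "group_effect"))],
    list(immune_populations = lapply(pops, function(p)
           do.call(immune_population, p[c("class_name", "count", "attraction",
                                          "marker_mean_log", "marker_sd_log")])),
         group_effect = unlist(raw$group_effect))))
}
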