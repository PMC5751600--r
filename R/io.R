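# TSV readers/writers for every pipeline artifact. All writers accept an
# optional run_config whose settings (seed included) are embedded as "# "
# comment lines; all readers skip such lines, so reader/writer pairs are
# bijections on valid files.

write_tsv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- config_header(config)
  if (length(hdr)) writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  if (!file.exists(path)) stop("missing input file: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = colClasses,
                    check.names = FALSE)
}

#' Read an expression matrix and its sample metadata
#'
#' @param matrix_path TSV with first column `gene` and one column per sample.
#' @param metadata_path TSV with columns `sample`, `tissue`, `status`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  tab <- read_tsv(matrix_path)
  if (names(tab)[1] != "gene")
    stop("expression matrix must start with a 'gene' column")
  genes <- as.character(tab$gene)
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- is.na(v) & !is.na(vals[[j]])
    if (any(bad))
      stop("unparsable expression value(s) for gene(s): ",
           paste(genes[bad], collapse = ", "),
           " in sample ", names(vals)[j])
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  meta <- read_tsv(metadata_path, colClasses = "character")
  expression_matrix(m, meta)
}

#' Write an expression matrix and its sample metadata
#'
#' @param em an [expression_matrix()].
#' @param matrix_path,metadata_path output TSV paths.
#' @param config optional [run_config()] embedded as a comment header.
#' @export
write_expression <- function(em, matrix_path, metadata_path, config = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, matrix_path, config)
  write_tsv(em$metadata, metadata_path, config)
  invisible(matrix_path)
}

#' Read a probe-to-gene map
#'
#' @param path TSV with columns `probe`, `gene`.
#' @return A [probe_map()].
#' @export
read_probe_map <- function(path) {
  tab <- read_tsv(path, colClasses = "character")
  if (!all(c("probe", "gene") %in% names(tab)))
    stop("probe map must have columns probe, gene")
  probe_map(tab$probe, tab$gene)
}

#' @rdname read_probe_map
#' @param pm a [probe_map()].
#' @param config optional [run_config()].
#' @export
write_probe_map <- function(pm, path, config = NULL) {
  write_tsv(as.data.frame(pm), path, config)
}

#' Read/write a directed regulatory edge list
#'
#' TSV with columns `src`, `dst`, `sign` (`sign` in `{+1, -1, NA}`).
#'
#' @param path TSV path.
#' @return A [regulatory_network()].
#' @export
read_regulatory <- function(path) {
  tab <- read_tsv(path)
  if (!all(c("src", "dst") %in% names(tab)))
    stop("regulatory edge list must have columns src, dst")
  if (!is.null(tab$sign)) {
    s <- as.character(tab$sign)
    ok <- is.na(s) | s %in% c("NA", "+1", "-1", "1")
    if (!all(ok))
      stop("malformed sign token(s): ",
           paste(unique(s[!ok]), collapse = ", "))
    tab$sign <- suppressWarnings(as.numeric(s))
  }
  regulatory_network(tab)
}

#' @rdname read_regulatory
#' @param net a [regulatory_network()].
#' @param config optional [run_config()].
#' @export
write_regulatory <- function(net, path, config = NULL) {
  stopifnot(inherits(net, "regulatory_network"))
  write_tsv(net$edges, path, config)
}

#' Read/write an undirected PPI edge list with confidences
#'
#' TSV with columns `p`, `q`, `conf`; confidences outside `[0, 1]` are an
#' error.
#'
#' @param path TSV path.
#' @return A [ppi_network()].
#' @export
read_ppi <- function(path) {
  tab <- read_tsv(path)
  if (!all(c("p", "q", "conf") %in% names(tab)))
    stop("PPI edge list must have columns p, q, conf")
  ppi_network(tab)
}

#' @rdname read_ppi
#' @param net a [ppi_network()].
#' @param config optional [run_config()].
#' @export
write_ppi <- function(net, path, config = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  write_tsv(net$edges, path, config)
}

#' Read/write a drug-target evidence table
#'
#' TSV with one row per evidence item: `drug_id`, `drug_name`, `target`,
#' `prob`, `sign`, `evidence_type`.
#'
#' @param path TSV path.
#' @return A [drug_evidence()] table.
#' @export
read_drug_evidence <- function(path) {
  tab <- read_tsv(path)
  s <- as.character(tab$sign)
  ok <- s %in% c("+1", "-1", "1")
  if (!all(ok))
    stop("malformed sign token(s): ", paste(unique(s[!ok]), collapse = ", "))
  tab$sign <- as.numeric(s)
  drug_evidence(tab)
}

#' @rdname read_drug_evidence
#' @param ev a [drug_evidence()] table.
#' @param config optional [run_config()].
#' @export
write_drug_evidence <- function(ev, path, config = NULL) {
  stopifnot(inherits(ev, "drug_evidence"))
  write_tsv(as.data.frame(ev), path, config)
}

#' Read/write a seed gene list (one symbol per line)
#'
#' @param path text file path.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  x <- trimws(readLines(path))
  x <- x[x != "" & !startsWith(x, "#")]
  if (anyDuplicated(x)) x <- unique(x)
  x
}

#' @rdname read_gene_list
#' @param genes character vector.
#' @param config optional [run_config()].
#' @export
write_gene_list <- function(genes, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- config_header(config)
  if (length(hdr)) writeLines(hdr, con)
  writeLines(genes, con)
  invisible(path)
}

#' Export a network as node and edge tables (and optionally GraphML)
#'
#' @param nodes data.frame of node attributes (first column: node id).
#' @param edges data.frame of edge attributes (first two columns: endpoints).
#' @param prefix path prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv` and, if `graphml = TRUE`, `<prefix>.graphml`.
#' @param config optional [run_config()].
#' @param graphml also write GraphML via igraph.
#' @export
write_network_export <- function(nodes, edges, prefix, config = NULL,
                                 graphml = FALSE) {
  write_tsv(nodes, paste0(prefix, "_nodes.tsv"), config)
  write_tsv(edges, paste0(prefix, "_edges.tsv"), config)
  if (graphml) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  }
  invisible(prefix)
}
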