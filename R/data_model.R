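#' Expression matrix with sample metadata
#'
#' Gene-by-sample matrix of log-scale intensities together with a metadata
#' table assigning each sample a tissue region and a case/control status.
#'
#' @param values numeric matrix; rownames are gene symbols, colnames sample ids.
#' @param metadata data.frame with columns `sample`, `tissue`, `status`
#'   (`status` in `"case"`/`"control"`); one row per column of `values`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `metadata` (the data.frame, ordered as the columns).
#' @export
expression_matrix <- function(values, metadata) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  genes <- trimws(rownames(values))
  if (anyDuplicated(genes))
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (any(genes == "")) stop("empty gene symbol in expression matrix")
  rownames(values) <- genes
  stopifnot(is.data.frame(metadata))
  need <- c("sample", "tissue", "status")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  metadata$sample <- trimws(as.character(metadata$sample))
  metadata$tissue <- as.character(metadata$tissue)
  metadata$status <- as.character(metadata$status)
  if (anyDuplicated(metadata$sample))
    stop("duplicate sample id in metadata: ",
         paste(unique(metadata$sample[duplicated(metadata$sample)]), collapse = ", "))
  bad <- setdiff(unique(metadata$status), c("case", "control"))
  if (length(bad))
    stop("unknown status label: ", paste(bad, collapse = ", "))
  missing <- setdiff(colnames(values), metadata$sample)
  if (length(missing))
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
  metadata <- metadata[match(colnames(values), metadata$sample),
                       need, drop = FALSE]
  rownames(metadata) <- NULL
  if (anyNA(values)) stop("expression matrix contains missing values")
  structure(list(values = values, metadata = metadata), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$metadata$tissue, x$metadata$status)
  print(tab)
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Subset an expr_matrix by gene and/or sample, keeping metadata aligned.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  v <- x$values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  expression_matrix(v, x$metadata[match(colnames(v), x$metadata$sample), ,
                                  drop = FALSE])
}

#' Probe-to-gene map
#'
#' Many-to-one mapping from array probe ids to gene symbols.
#'
#' @param probe character vector of probe ids.
#' @param gene character vector of gene symbols (same length).
#' @return data.frame of class `probe_map` with columns `probe`, `gene`.
#' @export
probe_map <- function(probe, gene) {
  probe <- trimws(as.character(probe))
  gene <- trimws(as.character(gene))
  stopifnot(length(probe) == length(gene))
  if (any(gene == "" | is.na(gene)))
    stop("probe map contains empty gene symbols")
  if (anyDuplicated(probe))
    stop("duplicate probe id in probe map: ",
         paste(unique(probe[duplicated(probe)]), collapse = ", "))
  structure(data.frame(probe = probe, gene = gene,
                       stringsAsFactors = FALSE),
            class = c("probe_map", "data.frame"))
}

#' Directed gene-gene regulatory network
#'
#' @param edges data.frame with columns `src`, `dst` and optionally `sign`
#'   (`+1`, `-1`, or `NA` for relationships of unknown direction of effect;
#'   the sign is carried but unused by seed expansion).
#' @return list of class `regulatory_network` with `edges` and `nodes`.
#' @export
regulatory_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("src", "dst") %in% names(edges)))
  edges$src <- trimws(as.character(edges$src))
  edges$dst <- trimws(as.character(edges$dst))
  if (is.null(edges$sign)) edges$sign <- NA_real_
  edges$sign <- as.numeric(edges$sign)
  bad <- !(is.na(edges$sign) | edges$sign %in% c(-1, 1))
  if (any(bad))
    stop("regulatory edge sign must be +1, -1 or NA; offending rows: ",
         paste(which(bad), collapse = ", "))
  loops <- edges$src == edges$dst
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop regulatory edge(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  key <- paste(edges$src, edges$dst, sep = "\t")
  if (anyDuplicated(key)) {
    message("dropping ", sum(duplicated(key)),
            " duplicate regulatory edge(s)")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(edges = edges[, c("src", "dst", "sign")],
                 nodes = sort(unique(c(edges$src, edges$dst)))),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d nodes, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Undirected protein-protein interaction network with confidences
#'
#' Endpoints are stored lexicographically ordered so duplicate undirected
#' edges are detectable; confidences outside `[0, 1]` are an error, not a
#' silent clamp.
#'
#' @param edges data.frame with columns `p`, `q`, `conf`.
#' @return list of class `ppi_network` with `edges` and `nodes`.
#' @export
ppi_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("p", "q", "conf") %in% names(edges)))
  p <- trimws(as.character(edges$p))
  q <- trimws(as.character(edges$q))
  conf <- as.numeric(edges$conf)
  if (anyNA(conf)) stop("non-numeric PPI confidence")
  out <- conf < 0 | conf > 1
  if (any(out))
    stop("PPI confidence outside [0,1] at row(s): ",
         paste(which(out), collapse = ", "))
  loops <- p == q
  if (any(loops)) {
    message("dropping ", sum(loops), " PPI self-loop(s)")
    p <- p[!loops]; q <- q[!loops]; conf <- conf[!loops]
  }
  swap <- p > q
  tmp <- p[swap]; p[swap] <- q[swap]; q[swap] <- tmp
  key <- paste(p, q, sep = "\t")
  if (anyDuplicated(key))
    stop("duplicate PPI edge(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  edges <- data.frame(p = p, q = q, conf = conf, stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = sort(unique(c(p, q)))),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d undirected edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Drug-target evidence table
#'
#' One row per evidence item supporting a drug-target interaction, with an
#' evidence probability in `[0, 1]` and a sign (`+1` activation, `-1`
#' inhibition).
#'
#' @param evidence data.frame with columns `drug_id`, `drug_name`, `target`,
#'   `prob`, `sign`, and optionally `evidence_type`.
#' @return data.frame of class `drug_evidence`.
#' @export
drug_evidence <- function(evidence) {
  stopifnot(is.data.frame(evidence),
            all(c("drug_id", "drug_name", "target", "prob", "sign") %in%
                  names(evidence)))
  evidence$drug_id <- trimws(as.character(evidence$drug_id))
  evidence$drug_name <- as.character(evidence$drug_name)
  evidence$target <- trimws(as.character(evidence$target))
  evidence$prob <- as.numeric(evidence$prob)
  evidence$sign <- as.numeric(evidence$sign)
  if (is.null(evidence$evidence_type)) evidence$evidence_type <- "unknown"
  if (anyNA(evidence$prob) || any(evidence$prob < 0 | evidence$prob > 1))
    stop("evidence probability outside [0,1]")
  if (anyNA(evidence$sign) || !all(evidence$sign %in% c(-1, 1)))
    stop("malformed evidence sign (must be +1 or -1)")
  rownames(evidence) <- NULL
  cols <- c("drug_id", "drug_name", "target", "prob", "sign", "evidence_type")
  structure(evidence[, cols], class = c("drug_evidence", "data.frame"))
}
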