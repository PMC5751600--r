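# Disease-specific module selection: one-layer expansion of GWAS seed genes
# through the regulatory edge list, signed log-hypergeometric enrichment of
# co-expression modules against the expanded gene set, and construction of
# high-confidence PPI networks for the selected modules.

#' One-layer seed expansion of a regulatory network
#'
#' The expanded node set is the seeds plus every gene sharing a directed
#' regulatory edge with a seed (either direction); the edge set is the
#' induced subgraph of the full edge list on that node set. Edge signs are
#' carried but not used. Seeds absent from the edge list remain as isolated
#' nodes (logged).
#'
#' @param seeds non-empty character vector of seed gene symbols.
#' @param regnet a [regulatory_network()].
#' @return A [regulatory_network()] restricted to the expanded node set,
#'   with attributes `seeds` and `isolated_seeds`.
#' @export
expand_seed_network <- function(seeds, regnet) {
  stopifnot(length(seeds) >= 1, inherits(regnet, "regulatory_network"))
  seeds <- unique(trimws(seeds))
  e <- regnet$edges
  touch <- e$src %in% seeds | e$dst %in% seeds
  neighbors <- unique(c(e$src[touch], e$dst[touch]))
  nodes <- sort(unique(c(seeds, neighbors)))
  keep <- e$src %in% nodes & e$dst %in% nodes
  sub <- e[keep, , drop = FALSE]
  rownames(sub) <- NULL
  isolated <- setdiff(seeds, unique(c(e$src, e$dst)))
  if (length(isolated))
    message(length(isolated), " seed(s) have no regulatory edges: ",
            paste(isolated, collapse = ", "))
  out <- structure(list(edges = sub, nodes = nodes),
                   class = "regulatory_network")
  attr(out, "seeds") <- seeds
  attr(out, "isolated_seeds") <- isolated
  out
}

#' Signed log-hypergeometric module enrichment score
#'
#' Given a universe of `N` genes of which `K` are candidates, a module of
#' `n` genes containing `k` candidates scores
#' `sign(K/N - k/n) * log_base(P(X = k))` where `X` is hypergeometric
#' `(N, K, n)`. Because the point probability is below 1, its log is
#' negative and the score is positive exactly when the module is
#' over-represented (`k/n > K/N`); `sign(0)` yields a score of 0.
#'
#' @param N total genes across all co-expression modules.
#' @param K candidates (expanded-network genes) among the `N`.
#' @param n module size.
#' @param k candidates inside the module.
#' @param log_base logarithm base (default 10).
#' @return Numeric score (vectorized over the count arguments).
#' @export
f_pts <- function(N, K, n, k, log_base = 10) {
  if (any(N < 0 | K < 0 | n < 0 | k < 0))
    stop("counts must be non-negative")
  if (any(K > N) || any(n > N)) stop("K and n must not exceed N")
  if (any(k > pmin(K, n))) stop("k must not exceed min(K, n)")
  if (any(k < pmax(0, n - (N - K)))) stop("k below the hypergeometric support")
  s <- sign(K / N - k / n)
  lp <- stats::dhyper(k, K, N - K, n, log = TRUE) / log(log_base)
  s * lp
}

#' Rank co-expression modules by enrichment in a candidate gene set
#'
#' Computes the overlap counts of every non-grey module with the expanded
#' regulatory-network genes, scores each with [f_pts()], and ranks modules
#' by decreasing score; a module is selected when its score is positive
#' (over-represented). The universe `N` is every gene that entered
#' clustering (grey/unassigned genes included) and `K` the candidates among
#' them, mirroring published count tables whose `N` slightly exceeds the
#' sum of the module sizes.
#'
#' @param partition a [detect_modules()] partition.
#' @param network_genes character vector of expanded-network gene symbols.
#' @param log_base logarithm base for [f_pts()].
#' @return data.frame of class `enrichment_result`: `module`, `N`, `K`,
#'   `n`, `k`, `f_pts`, `rank`, `selected`.
#' @export
rank_modules <- function(partition, network_genes, log_base = 10) {
  stopifnot(inherits(partition, "coexpr_partition"))
  mods <- module_labels(partition)
  if (!length(mods)) stop("partition has no non-grey modules")
  lab <- partition$labels
  genes <- names(lab)
  N <- length(genes)
  hits <- genes %in% network_genes
  K <- sum(hits)
  if (K == 0)
    warning("no module gene overlaps the expanded network; ",
            "all scores are driven by the sign convention")
  df <- data.frame(module = mods, N = N, K = K,
                   n = vapply(mods, function(m) sum(lab == m), integer(1)),
                   k = vapply(mods, function(m) sum(hits[lab == m]),
                              integer(1)),
                   stringsAsFactors = FALSE)
  score_enrichment_counts(df, log_base = log_base)
}

#' Score and rank modules from explicit overlap counts
#'
#' Computes `f_pts`, ranks and selection flags from a table of counts, so
#' enrichment can be reproduced from published count tables without the
#' expression data.
#'
#' @param counts data.frame with columns `module`, `N`, `K`, `n`, `k`.
#' @param log_base logarithm base.
#' @return data.frame of class `enrichment_result`, sorted by decreasing
#'   `f_pts` (ties broken by module name).
#' @export
score_enrichment_counts <- function(counts, log_base = 10) {
  stopifnot(all(c("module", "N", "K", "n", "k") %in% names(counts)))
  counts$f_pts <- f_pts(counts$N, counts$K, counts$n, counts$k,
                        log_base = log_base)
  ord <- order(-counts$f_pts, counts$module)
  counts <- counts[ord, , drop = FALSE]
  counts$rank <- seq_len(nrow(counts))
  counts$selected <- counts$f_pts > 0
  rownames(counts) <- NULL
  structure(counts, class = c("enrichment_result", "data.frame"))
}

#' Read/write an enrichment table
#'
#' @param enr an `enrichment_result`.
#' @param path TSV path (`module, N, K, n, k, f_pts, rank, selected`).
#' @param config optional [run_config()].
#' @export
write_enrichment <- function(enr, path, config = NULL) {
  stopifnot(inherits(enr, "enrichment_result"))
  write_tsv(as.data.frame(enr), path, config)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  tab <- read_tsv(path)
  tab$selected <- as.logical(tab$selected)
  structure(tab, class = c("enrichment_result", "data.frame"))
}

#' Build a disease-module PPI network
#'
#' Keeps PPI edges with both endpoints in the module and confidence at or
#' above the threshold, then drops genes left without any edge. Each
#' retained gene is annotated with its dysregulation direction and
#' accumulated change from the differential-expression result, a priority
#' (1 for GWAS seeds, 1/2 for other expanded-network genes, 1/4 otherwise),
#' and its RP-score (relevant-protein importance on this module network):
#' `exp(k * ln(S_p) - ln(deg_p))` with `S_p` the summed confidence of the
#' gene's module edges and `deg_p` their count.
#'
#' @param module_genes character vector of the module's gene symbols.
#' @param ppi a [ppi_network()].
#' @param conf_threshold minimum edge confidence in `[0, 1]`.
#' @param de a `de_result` from [moderated_test()].
#' @param seed_set GWAS seed genes.
#' @param expanded_set expanded-network genes (seeds included).
#' @param k_const the empirical constant of the RP-score (default 2).
#' @param label module label used in messages and exports.
#' @return An object of class `module_network`: list with `label`, `nodes`
#'   (data.frame `gene, direction, delta, priority, rp_score`) and `edges`
#'   (data.frame `p, q, conf`).
#' @export
build_module_network <- function(module_genes, ppi, conf_threshold, de,
                                 seed_set, expanded_set, k_const = 2,
                                 label = "module") {
  stopifnot(inherits(ppi, "ppi_network"),
            conf_threshold >= 0, conf_threshold <= 1)
  e <- ppi$edges
  keep <- e$p %in% module_genes & e$q %in% module_genes &
    e$conf >= conf_threshold
  e <- e[keep, , drop = FALSE]
  if (!nrow(e))
    stop("module ", label, ": no PPI edge survives the confidence threshold")
  genes <- sort(unique(c(e$p, e$q)))
  strength <- vapply(genes, function(g)
    sum(e$conf[e$p == g | e$q == g]), numeric(1))
  degree <- vapply(genes, function(g)
    sum(e$p == g | e$q == g), numeric(1))
  rp <- exp(k_const * log(strength) - log(degree))
  i <- match(genes, de$gene)
  direction <- ifelse(is.na(i), 0, de$direction[i])
  delta <- ifelse(is.na(i), NA_real_, de$delta[i])
  priority <- ifelse(genes %in% seed_set, 1,
                     ifelse(genes %in% expanded_set, 0.5, 0.25))
  rownames(e) <- NULL
  structure(list(label = label,
                 nodes = data.frame(gene = genes, direction = direction,
                                    delta = delta, priority = priority,
                                    rp_score = rp, row.names = NULL,
                                    stringsAsFactors = FALSE),
                 edges = e),
            class = "module_network")
}

#' @export
print.module_network <- function(x, ...) {
  cat(sprintf("module_network '%s': %d genes, %d edges\n",
              x$label, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
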