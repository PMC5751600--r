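# Drug scoring: signed evidence-weighted drug-target confidence, PPI node
# weights, pharmacology P-scores, module-level drug effect scores (DES) and
# their enrichment-weighted sum across disease modules (DESS), ranking, and
# the extended drug-target network export.

#' Signed drug-target confidence
#'
#' The net action of a drug on a target is the probability-weighted sum of
#' its evidence items, `sum_i prob_i * sign_i`; positive means net
#' activation, negative net inhibition. An empty evidence list scores 0.
#'
#' @param prob numeric vector of evidence probabilities in `[0, 1]`.
#' @param sign numeric vector of evidence signs (`+1`/`-1`).
#' @return Numeric scalar.
#' @export
conf_dp <- function(prob, sign) {
  if (length(prob) == 0) return(0)
  stopifnot(length(prob) == length(sign),
            all(prob >= 0 & prob <= 1), all(sign %in% c(-1, 1)))
  sum(prob * sign)
}

#' Per-pair drug-target confidence table
#'
#' Collapses a [drug_evidence()] table to one row per (drug, target) with
#' the [conf_dp()] confidence.
#'
#' @param ev a [drug_evidence()] table.
#' @return data.frame `drug_id`, `drug_name`, `target`, `conf`,
#'   `n_evidence`.
#' @export
conf_table <- function(ev) {
  stopifnot(inherits(ev, "drug_evidence"))
  key <- paste(ev$drug_id, ev$target, sep = "\t")
  agg <- rowsum(ev$prob * ev$sign, group = key)
  cnt <- as.vector(table(key)[rownames(agg)])
  parts <- do.call(rbind, strsplit(rownames(agg), "\t", fixed = TRUE))
  name <- ev$drug_name[match(parts[, 1], ev$drug_id)]
  out <- data.frame(drug_id = parts[, 1], drug_name = name,
                    target = parts[, 2], conf = as.vector(agg),
                    n_evidence = cnt, stringsAsFactors = FALSE)
  out[order(out$drug_id, out$target), , drop = FALSE]
}

#' PPI node weight
#'
#' Log-scale importance of a protein in an interaction network:
#' `k * ln(S_p) - ln(deg_p)`, where `S_p` is the summed confidence of the
#' protein's incident edges and `deg_p` their number. Undefined for
#' proteins with no incident edge (the caller must skip those).
#'
#' @param ppi a [ppi_network()] (or any list with an `edges` data.frame
#'   `p, q, conf`).
#' @param protein gene/protein symbol.
#' @param k_const empirical constant (default 2).
#' @return Numeric scalar.
#' @export
weight_p <- function(ppi, protein, k_const = 2) {
  e <- ppi$edges
  inc <- e$p == protein | e$q == protein
  deg <- sum(inc)
  if (deg == 0) stop("protein ", protein, " has degree 0; weight undefined")
  k_const * log(sum(e$conf[inc])) - log(deg)
}

#' Vectorized PPI node weights
#'
#' @param ppi a [ppi_network()].
#' @param proteins character vector; proteins absent from the network get
#'   `NA` (their weight is undefined).
#' @param k_const empirical constant.
#' @return Named numeric vector.
#' @export
weight_table <- function(ppi, proteins, k_const = 2) {
  e <- ppi$edges
  ends <- c(e$p, e$q)
  confs <- c(e$conf, e$conf)
  strength <- rowsum(confs, group = ends)
  degree <- table(ends)
  w <- stats::setNames(rep(NA_real_, length(proteins)), proteins)
  hit <- proteins %in% rownames(strength)
  w[hit] <- k_const * log(strength[proteins[hit], 1]) -
    log(as.vector(degree[proteins[hit]]))
  w
}

#' Drug-protein pharmacology score
#'
#' `P-score(d, p) = conf(d, p) * weight(p)`: the drug's net signed action
#' on the protein scaled by the protein's network importance.
#'
#' @param conf signed drug-target confidence from [conf_dp()].
#' @param weight node weight from [weight_p()].
#' @return Numeric (vectorized).
#' @export
p_score <- function(conf, weight) conf * weight

#' RP-score of a protein in a disease-module network
#'
#' `exp(k * ln(S_p) - ln(deg_p))` over the module network's edges incident
#' to the protein; with `k = 2` this is `S_p^2 / deg_p`. Equals the
#' exponential of [weight_p()] computed on the module network.
#'
#' @param modnet a `module_network` from [build_module_network()].
#' @param protein gene symbol; must be in the module network.
#' @param k_const empirical constant.
#' @return Numeric scalar (non-negative).
#' @export
rp_score <- function(modnet, protein, k_const = 2) {
  stopifnot(inherits(modnet, "module_network"))
  e <- modnet$edges
  inc <- e$p == protein | e$q == protein
  if (!sum(inc)) stop("protein ", protein, " absent from module network")
  exp(k_const * log(sum(e$conf[inc])) - log(sum(inc)))
}

# log2 floored at 0 so that the sign of a DES term is carried solely by the
# reversal alignment, never by a sub-unit score magnitude.
l2pos <- function(x) pmax(log2(x), 0)

#' Module-level drug effect score (DES)
#'
#' Sums, over the drug's targets inside the module network with nonzero
#' confidence and nonzero dysregulation, the reversal-aligned product
#' `sign_di * max(log2 |P-score|, 0) * max(log2 RP-score, 0) * priority`,
#' where `sign_di = -sign(conf(d,i)) * g_i` is `+1` when the drug's net
#' action opposes the gene's dysregulation direction `g_i` and `-1` when it
#' reinforces it. No eligible target gives a score of 0.
#'
#' @param target_conf named numeric vector: the drug's signed confidence per
#'   target gene.
#' @param target_pscore named numeric vector: P-score per target gene
#'   (aligned with `target_conf`).
#' @param modnet a `module_network`.
#' @return Numeric scalar.
#' @export
des_score <- function(target_conf, target_pscore, modnet) {
  stopifnot(inherits(modnet, "module_network"))
  nodes <- modnet$nodes
  tg <- names(target_conf)
  i <- match(tg, nodes$gene)
  ok <- !is.na(i) & target_conf != 0 & !is.na(target_pscore) &
    nodes$direction[i] != 0
  if (!any(ok)) return(0)
  i <- i[ok]
  conf <- target_conf[ok]
  ps <- target_pscore[ok]
  sign_di <- -sign(conf) * nodes$direction[i]
  sum(sign_di * l2pos(abs(ps)) * l2pos(nodes$rp_score[i]) *
        nodes$priority[i])
}

#' Drug effect sum score (DESS)
#'
#' Integrates a drug's module-level effects over the selected
#' (positively enriched) disease modules: `sum_m DES(d, m) * f_m(pts)`.
#'
#' @param des_by_module named numeric vector of DES values, one per module.
#' @param f_by_module named numeric vector of enrichment scores; only
#'   modules present in both vectors and with positive score contribute.
#' @return Numeric scalar.
#' @export
dess_score <- function(des_by_module, f_by_module) {
  mods <- intersect(names(des_by_module), names(f_by_module))
  mods <- mods[f_by_module[mods] > 0]
  if (!length(mods)) return(0)
  sum(des_by_module[mods] * f_by_module[mods])
}

#' Score and rank all drugs against the selected disease modules
#'
#' For every drug: per-target signed confidences ([conf_table()]), P-scores
#' against the full PPI network, DES per selected module and the
#' enrichment-weighted DESS; drugs are then ranked by decreasing DESS (ties
#' broken lexicographically by drug id) and the top fraction flagged.
#'
#' @param ev a [drug_evidence()] table.
#' @param modnets named list of `module_network`s (names = module labels).
#' @param enrichment an `enrichment_result`; only its selected modules are
#'   scored.
#' @param ppi the full [ppi_network()] used for target weights.
#' @param k_const empirical constant of the weight/RP formulas.
#' @param top_fraction fraction of drugs flagged as candidates.
#' @return data.frame of class `drug_score_table`: `drug_id`, `drug_name`,
#'   `dess`, one `des_<module>` and `n_targets_<module>` column per selected
#'   module, `rank`, `top`.
#' @export
score_drugs <- function(ev, modnets, enrichment, ppi, k_const = 2,
                        top_fraction = 0.01) {
  stopifnot(inherits(enrichment, "enrichment_result"))
  sel <- enrichment$module[enrichment$selected]
  sel <- intersect(sel, names(modnets))
  fvals <- stats::setNames(enrichment$f_pts, enrichment$module)
  ct <- conf_table(ev)
  ct$weight <- weight_table(ppi, ct$target, k_const = k_const)
  ct$p_score <- p_score(ct$conf, ct$weight)
  drugs <- sort(unique(ct$drug_id))
  des_mat <- matrix(0, length(drugs), length(sel),
                    dimnames = list(drugs, sel))
  ntg_mat <- matrix(0L, length(drugs), length(sel),
                    dimnames = list(drugs, sel))
  by_drug <- split(ct, ct$drug_id)
  for (d in drugs) {
    sub <- by_drug[[d]]
    conf_v <- stats::setNames(sub$conf, sub$target)
    ps_v <- stats::setNames(sub$p_score, sub$target)
    for (m in sel) {
      des_mat[d, m] <- des_score(conf_v, ps_v, modnets[[m]])
      nodes <- modnets[[m]]$nodes
      i <- match(sub$target, nodes$gene)
      dir_i <- rep(0, length(i))
      dir_i[!is.na(i)] <- nodes$direction[i[!is.na(i)]]
      ntg_mat[d, m] <- sum(!is.na(i) & sub$conf != 0 & dir_i != 0)
    }
  }
  dess <- vapply(drugs, function(d)
    dess_score(stats::setNames(des_mat[d, ], colnames(des_mat)), fvals),
    numeric(1))
  out <- data.frame(drug_id = drugs,
                    drug_name = ct$drug_name[match(drugs, ct$drug_id)],
                    dess = unname(dess), stringsAsFactors = FALSE)
  for (m in sel) {
    out[[paste0("des_", m)]] <- des_mat[, m]
    out[[paste0("n_targets_", m)]] <- ntg_mat[, m]
  }
  rank_and_select(out, top_fraction)
}

#' Rank drugs and flag the top fraction
#'
#' Orders a drug score table by decreasing DESS with lexicographic drug-id
#' tie-breaking, assigns ranks 1..n, and flags the top
#' `max(1, floor(fraction * n))` drugs.
#'
#' @param scores data.frame with at least `drug_id` and `dess`.
#' @param top_fraction fraction in (0, 1].
#' @return The table sorted with `rank` and `top` columns, class
#'   `drug_score_table`.
#' @export
rank_and_select <- function(scores, top_fraction = 0.01) {
  stopifnot(nrow(scores) >= 1, top_fraction > 0, top_fraction <= 1)
  ord <- order(-scores$dess, scores$drug_id)
  scores <- scores[ord, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  n_top <- max(1L, floor(top_fraction * nrow(scores)))
  scores$top <- scores$rank <= n_top
  rownames(scores) <- NULL
  structure(scores, class = c("drug_score_table", "data.frame"))
}

#' Extended drug-target network for the selected drugs
#'
#' Nodes are the selected drugs, their targets inside the disease modules,
#' and a one-layer extension to the drugs' remaining targets; edges are
#' typed `stimulation` (net activating action), `inhibition` (net
#' inhibiting action) or `ppi` (module-gene interactions at or above the
#' confidence threshold). Gene nodes carry their dysregulation direction and
#' RP-score (NA outside the module networks).
#'
#' @param drug_ids selected drug ids (non-empty).
#' @param modnets named list of `module_network`s.
#' @param ev a [drug_evidence()] table.
#' @param ppi the full [ppi_network()].
#' @param conf_threshold PPI confidence threshold for included interactions.
#' @return list with `nodes` (`id, type, direction, rp_score`) and `edges`
#'   (`from, to, type, value`).
#' @export
build_extended_drug_network <- function(drug_ids, modnets, ev, ppi,
                                        conf_threshold = 0.75) {
  stopifnot(length(drug_ids) >= 1)
  ct <- conf_table(ev)
  ct <- ct[ct$drug_id %in% drug_ids & ct$conf != 0, , drop = FALSE]
  mod_nodes <- do.call(rbind, lapply(modnets, function(m) m$nodes))
  module_genes <- unique(mod_nodes$gene)
  in_module <- ct$target %in% module_genes
  genes <- unique(ct$target)  # module targets plus one-layer extensions
  drug_edges <- data.frame(
    from = ct$drug_id, to = ct$target,
    type = ifelse(ct$conf > 0, "stimulation", "inhibition"),
    value = ct$conf, stringsAsFactors = FALSE)
  pe <- ppi$edges
  keep <- pe$p %in% genes & pe$q %in% genes & pe$conf >= conf_threshold
  ppi_edges <- data.frame(from = pe$p[keep], to = pe$q[keep],
                          type = rep("ppi", sum(keep)),
                          value = pe$conf[keep], stringsAsFactors = FALSE)
  gi <- match(genes, mod_nodes$gene)
  nodes <- rbind(
    data.frame(id = sort(unique(ct$drug_id)), type = "drug",
               direction = NA_real_, rp_score = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(id = genes, type = ifelse(genes %in% module_genes,
                                         "module_gene", "extension_gene"),
               direction = mod_nodes$direction[gi],
               rp_score = mod_nodes$rp_score[gi],
               stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  edges <- rbind(drug_edges, ppi_edges)
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
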