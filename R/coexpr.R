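# Weighted co-expression module detection: soft-thresholded unsigned
# adjacency, topological overlap, average-linkage clustering with a static
# cut, and module eigengene / trait correlation summaries.

# Standard color palette used to label modules in decreasing size order.
module_palette <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
            "darkgrey", "orange", "darkorange", "white", "skyblue")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("module", seq_len(n - length(base))))
}

#' Trim outlier samples by hierarchical clustering
#'
#' Builds an average-linkage tree on pairwise Euclidean distances between
#' samples and cuts it at `cut_height`; samples outside the largest resulting
#' cluster are removed (and logged).
#'
#' @param em an [expression_matrix()] with >= 3 samples.
#' @param cut_height static cut height on the sample tree.
#' @return The retained [expression_matrix()]; removed sample ids are in
#'   attribute `removed`.
#' @export
trim_outlier_samples <- function(em, cut_height = 100) {
  stopifnot(inherits(em, "expr_matrix"), ncol(em$values) >= 3)
  d <- stats::dist(t(em$values))
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep_cl <- as.integer(names(sizes)[which.max(sizes)])
  keep <- names(cl)[cl == keep_cl]
  removed <- setdiff(colnames(em$values), keep)
  if (length(removed) == ncol(em$values))
    stop("sample trimming removed all samples")
  if (length(removed))
    message("trimmed ", length(removed), " outlier sample(s): ",
            paste(removed, collapse = ", "))
  out <- em[, keep]
  attr(out, "removed") <- removed
  out
}

# Unsigned soft-thresholded adjacency |cor|^beta with zero-variance guard.
soft_adjacency <- function(em, beta) {
  v <- apply(em$values, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(em$values)[v == 0], collapse = ", "))
  abs(stats::cor(t(em$values)))^beta
}

#' Choose a soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the unsigned adjacency is formed, connectivities
#' are binned, and the fit index is the squared correlation of
#' `log10(frequency)` against `log10(bin center)`. The chosen power is the
#' smallest one reaching `rsq_target` among powers whose network remains
#' usable — mean connectivity at least `min_mean_connectivity` (powers that
#' thin the network further always look spuriously scale-free while carrying
#' no clustering signal). When no usable candidate reaches the target
#' (typical when the correlation structure is block-like rather than
#' scale-free), the candidate power closest to `fallback_power` — the
#' field-standard default for unsigned networks — is used rather than the
#' argmax of an uninformative fit.
#'
#' @param em an [expression_matrix()].
#' @param powers candidate powers (>= 2 unless a single power is forced).
#' @param rsq_target fit target in (0, 1].
#' @param n_bins number of connectivity bins.
#' @param fallback_power power used when no eligible candidate reaches the
#'   target.
#' @param min_mean_connectivity eligibility floor for the mean connectivity;
#'   default `max(2, 0.01 * n_genes)`.
#' @return list with `beta` (chosen power) and `fit` (data.frame
#'   `power`, `rsq`, `mean_connectivity`, `eligible`).
#' @export
pick_soft_threshold <- function(em, powers = 1:20, rsq_target = 0.8,
                                n_bins = 10, fallback_power = 6,
                                min_mean_connectivity = NULL) {
  stopifnot(length(powers) >= 1)
  if (length(powers) == 1)
    return(list(beta = powers,
                fit = data.frame(power = powers, rsq = NA_real_,
                                 mean_connectivity = NA_real_)))
  acor <- abs(stats::cor(t(em$values)))
  diag(acor) <- 0
  fit <- data.frame(power = powers, rsq = NA_real_,
                    mean_connectivity = NA_real_)
  for (i in seq_along(powers)) {
    a <- acor^powers[i]
    k <- rowSums(a)
    fit$mean_connectivity[i] <- mean(k)
    brk <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    freq <- as.vector(table(bin))
    ctr <- (brk[-1] + brk[-length(brk)]) / 2
    keep <- freq > 0 & ctr > 0
    if (sum(keep) < 3)
      stop("fewer than 3 populated connectivity bins at power ", powers[i])
    fit$rsq[i] <- stats::cor(log10(freq[keep]), log10(ctr[keep]))^2
  }
  if (is.null(min_mean_connectivity))
    min_mean_connectivity <- max(2, 0.01 * nrow(em$values))
  fit$eligible <- fit$mean_connectivity >= min_mean_connectivity
  hit <- which(fit$rsq >= rsq_target & fit$eligible)
  beta <- if (length(hit)) powers[min(hit)]
    else powers[which.min(abs(powers - fallback_power))]
  list(beta = beta, fit = fit)
}

#' Topological overlap dissimilarity
#'
#' Unsigned adjacency `a_ij = |cor|^beta`; the topological overlap between
#' genes i and j combines their direct adjacency with the adjacency they
#' share through third genes:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivity `k_i = sum_{u != i} a_iu`. The returned matrix is
#' `1 - TOM` with zero diagonal.
#'
#' @param em an [expression_matrix()] with >= 2 genes.
#' @param beta soft-thresholding power.
#' @return Symmetric dissimilarity matrix in `[0, 1]` with attribute `beta`.
#' @export
compute_tom <- function(em, beta) {
  stopifnot(inherits(em, "expr_matrix"), nrow(em$values) >= 2)
  a <- soft_adjacency(em, beta)
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a            # sum over u != i,j since diag(a) = 0
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  diss <- 1 - tom
  diss <- (diss + t(diss)) / 2 # symmetrize away float asymmetry
  attr(diss, "beta") <- beta
  diss
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage dendrogram with a static cut at `cut_height`; clusters
#' below `min_size` are relabelled `"grey"` (unassigned). Surviving modules
#' are named from a fixed palette in decreasing size order, largest first
#' (`"turquoise"`, `"blue"`, `"brown"`, `"yellow"`, `"green"`, ...); size
#' ties are broken by the lexicographically smallest member gene so labels
#' do not depend on input gene order.
#'
#' @param diss square symmetric dissimilarity matrix (from [compute_tom()]).
#' @param min_size minimum module size.
#' @param cut_height static cut height.
#' @return An object of class `coexpr_partition`: list with `labels` (named
#'   character vector over genes), `sizes`, `beta`, `min_size`, `cut_height`.
#' @export
detect_modules <- function(diss, min_size = 30, cut_height = 0.97) {
  stopifnot(is.matrix(diss), nrow(diss) == ncol(diss))
  if (all(diss == 0)) stop("degenerate all-zero dissimilarity")
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_size]
  labels <- rep("grey", length(cl))
  names(labels) <- names(cl)
  if (length(big)) {
    first_gene <- vapply(big, function(b) min(names(cl)[cl == as.integer(b)]),
                         character(1))
    ord <- big[order(-sizes[big], first_gene)]
    pal <- module_palette(length(ord))
    for (i in seq_along(ord)) labels[cl == as.integer(ord[i])] <- pal[i]
  }
  msizes <- table(labels)
  structure(list(labels = labels,
                 sizes = msizes[order(-msizes)],
                 beta = attr(diss, "beta"),
                 min_size = min_size, cut_height = cut_height),
            class = "coexpr_partition")
}

#' @export
print.coexpr_partition <- function(x, ...) {
  cat(sprintf("coexpr_partition: %d genes, %d modules (+grey)\n",
              length(x$labels), sum(names(x$sizes) != "grey")))
  print(x$sizes)
  invisible(x)
}

# Non-grey module labels in decreasing size order.
module_labels <- function(partition) {
  nm <- names(partition$sizes)
  nm[nm != "grey"]
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized gene x sample submatrix, oriented so that it correlates
#' positively with the module's mean standardized expression profile.
#'
#' @param em an [expression_matrix()].
#' @param partition a [detect_modules()] partition covering the matrix genes.
#' @return list with `eigengenes` (module x sample matrix), `loadings`
#'   (per-module named gene-loading vectors) and `var_explained`.
#' @export
module_eigengenes <- function(em, partition) {
  stopifnot(inherits(em, "expr_matrix"),
            inherits(partition, "coexpr_partition"))
  mods <- module_labels(partition)
  if (!all(names(partition$labels) %in% rownames(em$values)))
    stop("partition covers genes absent from the expression matrix")
  eg <- matrix(NA_real_, length(mods), ncol(em$values),
               dimnames = list(mods, colnames(em$values)))
  loadings <- list()
  ve <- numeric(length(mods)); names(ve) <- mods
  for (m in mods) {
    genes <- names(partition$labels)[partition$labels == m]
    if (length(genes) < 2) stop("module ", m, " has fewer than 2 genes")
    sub <- t(scale(t(em$values[genes, , drop = FALSE])))
    sv <- svd(sub)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(sub)) < 0) {
      e <- -e
      sv$u[, 1] <- -sv$u[, 1]
    }
    eg[m, ] <- e
    loadings[[m]] <- stats::setNames(sv$u[, 1], genes)
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, loadings = loadings, var_explained = ve)
}

#' Module-trait correlation summaries
#'
#' Two complementary views of how well each module separates cases from
#' controls: (i) per (module, sample), the Pearson correlation of the
#' sample's standardized module-gene expression with the module's gene
#' loadings, plus an asymptotic p-value; (ii) per (module, tissue), a
#' two-sample t-test of the eigengene values, case versus control.
#'
#' @param em an [expression_matrix()].
#' @param partition a [detect_modules()] partition.
#' @return list with `eigengenes` (module x sample), `sample_cor`
#'   (data.frame `module`, `sample`, `tissue`, `status`, `r`, `p`) and
#'   `tissue_tests` (data.frame `module`, `tissue`, `t`, `p`).
#' @export
module_trait_correlation <- function(em, partition) {
  me <- module_eigengenes(em, partition)
  md <- em$metadata
  mods <- rownames(me$eigengenes)
  rows <- list()
  for (m in mods) {
    genes <- names(me$loadings[[m]])
    sub <- t(scale(t(em$values[genes, , drop = FALSE])))
    ld <- me$loadings[[m]]
    ng <- length(genes)
    for (s in colnames(sub)) {
      r <- stats::cor(sub[, s], ld)
      p <- if (abs(r) >= 1) 0 else {
        tt <- r * sqrt((ng - 2) / (1 - r^2))
        2 * stats::pt(-abs(tt), df = ng - 2)
      }
      i <- match(s, md$sample)
      rows[[length(rows) + 1]] <-
        data.frame(module = m, sample = s, tissue = md$tissue[i],
                   status = md$status[i], r = r, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  sample_cor <- do.call(rbind, rows)
  tt_rows <- list()
  for (m in mods) {
    for (ti in sort(unique(md$tissue))) {
      e_case <- me$eigengenes[m, md$tissue == ti & md$status == "case"]
      e_ctrl <- me$eigengenes[m, md$tissue == ti & md$status == "control"]
      if (length(e_case) >= 2 && length(e_ctrl) >= 2) {
        tst <- stats::t.test(e_case, e_ctrl)
        tt_rows[[length(tt_rows) + 1]] <-
          data.frame(module = m, tissue = ti, t = unname(tst$statistic),
                     p = tst$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  list(eigengenes = me$eigengenes, sample_cor = sample_cor,
       tissue_tests = do.call(rbind, tt_rows))
}

#' Read/write a module assignment table
#'
#' @param partition a `coexpr_partition`.
#' @param path TSV path (`gene`, `module`).
#' @param config optional [run_config()].
#' @export
write_partition <- function(partition, path, config = NULL) {
  stopifnot(inherits(partition, "coexpr_partition"))
  df <- data.frame(gene = names(partition$labels),
                   module = unname(partition$labels),
                   stringsAsFactors = FALSE)
  write_tsv(df, path, config)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  tab <- read_tsv(path, colClasses = "character")
  labels <- stats::setNames(tab$module, tab$gene)
  msizes <- table(labels)
  structure(list(labels = labels, sizes = msizes[order(-msizes)],
                 beta = NA_real_, min_size = NA_integer_,
                 cut_height = NA_real_),
            class = "coexpr_partition")
}
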