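test_that("sample trimming removes exactly the distant outlier", {
  fx <- make_block_em(20, rho = 0.5, n_case = 5, n_ctrl = 5, seed = 13)
  em <- fx$em
  # all samples close together: nothing removed at a generous height
  kept <- trim_outlier_samples(em, cut_height = 1e6)
  expect_equal(colnames(kept$values), colnames(em$values))

  v <- em$values
  v[, 3] <- v[, 3] + 50  # Euclidean distance ~ 50*sqrt(20) from the rest
  em2 <- expression_matrix(v, em$metadata)
  # distance oracle: the outlier's nearest neighbour is far beyond the cut
  d <- as.matrix(dist(t(v)))
  expect_gt(min(d[3, -3]), 100)
  expect_message(kept2 <- trim_outlier_samples(em2, cut_height = 100),
                 "trimmed 1")
  expect_identical(attr(kept2, "removed"), colnames(v)[3])
})

test_that("soft-threshold selection: contract cases", {
  fx <- make_block_em(c(40, 40), rho = 0.7, n_case = 10, n_ctrl = 10,
                      seed = 17)
  expect_equal(pick_soft_threshold(fx$em, powers = 1)$beta, 1)
  pk <- pick_soft_threshold(fx$em, powers = 1:10)
  expect_true(all(pk$fit$rsq >= 0 & pk$fit$rsq <= 1))
  expect_true(pk$beta %in% 1:10)
  # block-structured data never reaches the scale-free target, so the
  # fallback (nearest candidate to the unsigned default) is chosen
  expect_equal(pick_soft_threshold(fx$em, powers = c(2, 4, 8),
                                   rsq_target = 0.999)$beta, 4)
})

test_that("TOM equals the brute-force triple-loop oracle", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:15, 1)
    V <- matrix(rnorm(n * 12), n, 12,
                dimnames = list(sprintf("g%02d", 1:n), sprintf("s%02d", 1:12)))
    md <- data.frame(sample = colnames(V), tissue = "T1",
                     status = rep(c("case", "control"), 6))
    em <- expression_matrix(V, md)
    beta <- sample(1:6, 1)
    diss <- compute_tom(em, beta)
    expect_equal(unname(diss), tom_brute(V, beta), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(diss >= -1e-12 & diss <= 1 + 1e-12))
    expect_equal(diss, t(diss))
    expect_equal(unname(diag(diss)), rep(0, n))
  }
})

test_that("TOM degenerate cases", {
  md <- data.frame(sample = paste0("s", 1:4), tissue = "T1",
                   status = rep(c("case", "control"), 2))
  # two perfectly correlated genes and no third: dissimilarity 0
  V <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  colnames(V) <- paste0("s", 1:4)
  diss <- compute_tom(expression_matrix(V, md), beta = 3)
  expect_equal(diss[1, 2], 0)
  # constant gene is named in the error
  V2 <- rbind(V, g3 = c(5, 5, 5, 5))
  expect_error(compute_tom(expression_matrix(V2, md), 3), "g3")
})

test_that("module detection recovers planted blocks and labels by size", {
  fx <- make_block_em(c(40, 30), rho = 0.9, n_case = 10, n_ctrl = 10,
                      seed = 23)
  diss <- compute_tom(fx$em, 6)
  part <- detect_modules(diss, min_size = 10, cut_height = 0.97)
  mods <- names(part$sizes)[names(part$sizes) != "grey"]
  expect_length(mods, 2)
  expect_gte(ari(part$labels, fx$block), 0.9)
  # largest module takes the first palette name
  expect_equal(unname(part$sizes["turquoise"]),
               max(part$sizes[mods]))
  expect_equal(mods[order(-part$sizes[mods])][1:2], c("turquoise", "blue"))

  # min size above n: everything grey
  part_all_grey <- detect_modules(diss, min_size = 1000, cut_height = 0.97)
  expect_true(all(part_all_grey$labels == "grey"))

  # label assignment is invariant to input gene order
  perm <- sample(nrow(fx$em$values))
  diss_p <- compute_tom(fx$em[perm, ], 6)
  part_p <- detect_modules(diss_p, min_size = 10, cut_height = 0.97)
  expect_identical(part_p$labels[names(part$labels)], part$labels)

  expect_error(detect_modules(matrix(0, 4, 4), 2, 0.97), "degenerate")
})

test_that("eigengenes summarize modules and separate planted case shifts", {
  fx <- make_block_em(c(25, 25), rho = 0.8, n_case = 12, n_ctrl = 12,
                      tissues = c("T1", "T2"), shift = 1.5, seed = 29)
  diss <- compute_tom(fx$em, 6)
  part <- detect_modules(diss, min_size = 10, cut_height = 0.97)
  mt <- module_trait_correlation(fx$em, part)
  expect_true(all(abs(mt$sample_cor$r) <= 1 + 1e-12))
  expect_true(all(mt$sample_cor$p >= 0 & mt$sample_cor$p <= 1))

  # module of identical profiles: the eigengene is the common profile
  md <- fx$em$metadata
  prof <- rnorm(ncol(fx$em$values))
  V <- matrix(rep(prof, 5), 5, byrow = TRUE,
              dimnames = list(sprintf("h%d", 1:5), colnames(fx$em$values)))
  V <- V + matrix(rnorm(length(V), sd = 1e-6), nrow(V))
  em_id <- expression_matrix(V, md)
  part_id <- structure(list(labels = setNames(rep("turquoise", 5),
                                              rownames(V)),
                            sizes = table(rep("turquoise", 5)),
                            beta = 1, min_size = 1, cut_height = 1),
                       class = "coexpr_partition")
  me_id <- module_eigengenes(em_id, part_id)
  expect_gt(abs(cor(me_id$eigengenes["turquoise", ], prof)), 0.999)

  # the shifted module's eigengene separates case from control
  shifted_mod <- unname(part$labels[rownames(fx$em$values)[1]])
  tp <- mt$tissue_tests$p[mt$tissue_tests$module == shifted_mod]
  expect_true(all(tp < 0.01))

  # eigengene orientation: positive correlation with the mean profile
  me <- module_eigengenes(fx$em, part)
  for (m in rownames(me$eigengenes)) {
    genes <- names(part$labels)[part$labels == m]
    prof <- colMeans(t(scale(t(fx$em$values[genes, ]))))
    expect_gt(cor(me$eigengenes[m, ], prof), 0)
  }

  expect_error(module_eigengenes(
    fx$em, structure(list(labels = setNames("x", rownames(fx$em$values)[1]),
                          sizes = table("x"), beta = 1, min_size = 1,
                          cut_height = 1), class = "coexpr_partition")),
    "fewer than 2")
})
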