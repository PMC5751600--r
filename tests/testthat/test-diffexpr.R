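test_that("probe aggregation equals group-by-mean oracle", {
  md <- data.frame(sample = paste0("s", 1:4), tissue = "T1",
                   status = rep(c("case", "control"), 2))
  vals <- matrix(c(1, 3, 5, 7, 2, 4, 6, 8), 2, 4, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), paste0("s", 1:4)))
  pem <- expression_matrix(vals, md)
  pm <- probe_map(c("p1", "p2"), c("G", "G"))
  out <- aggregate_probes(pem, pm)
  expect_equal(as.vector(out$values["G", ]), c(1.5, 3.5, 5.5, 7.5))

  # single-probe gene passes through unchanged
  pm2 <- probe_map(c("p1", "p2"), c("G1", "G2"))
  out2 <- aggregate_probes(pem, pm2)
  expect_equal(out2$values["G1", ], pem$values["p1", ])

  # random fixture vs brute-force oracle
  set.seed(3)
  n_probe <- 50
  probes <- sprintf("p%02d", 1:n_probe)
  genes <- sample(sprintf("g%02d", 1:20), n_probe, replace = TRUE)
  V <- matrix(rnorm(n_probe * 4), n_probe, 4,
              dimnames = list(probes, paste0("s", 1:4)))
  out3 <- aggregate_probes(expression_matrix(V, md), probe_map(probes, genes))
  brute <- t(sapply(sort(unique(genes)), function(g)
    colMeans(V[genes == g, , drop = FALSE])))
  expect_equal(out3$values, brute)

  # unmapped probes dropped with a log, empty intersection errors
  expect_message(aggregate_probes(pem, probe_map("p1", "G")), "1 unmapped")
  expect_error(aggregate_probes(pem, probe_map("zz", "G")), "no probe")
})

test_that("sample dispersion report flags shifted samples (z oracle)", {
  set.seed(5)
  V <- matrix(rnorm(100 * 20), 100, 20,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:20)))
  md <- data.frame(sample = colnames(V), tissue = "T1",
                   status = rep(c("case", "control"), 10))
  em <- expression_matrix(V, md)
  rep0 <- check_sample_dispersion(em)
  expect_length(rep0$flagged, 0)

  V2 <- V; V2[, 7] <- V2[, 7] + 10
  rep1 <- check_sample_dispersion(expression_matrix(V2, md))
  expect_identical(rep1$flagged, "s07")
  # z agrees with a direct standardization of the sample means
  m <- colMeans(V2)
  expect_equal(unname(rep1$z), unname((m - mean(m)) / sd(m)))

  # identical samples: zero dispersion, nothing flagged
  V3 <- matrix(rep(rnorm(10), 4), 10, 4,
               dimnames = list(sprintf("g%02d", 1:10), md$sample[1:4]))
  rep2 <- check_sample_dispersion(expression_matrix(V3, md[1:4, ]))
  expect_equal(rep2$sd, 0)
  expect_length(rep2$flagged, 0)
})

test_that("moderated test: null gene, prior-df limits, monotonicity", {
  fx <- make_block_em(c(30, 30), rho = 0, n_case = 5, n_ctrl = 5,
                      tissues = c("T1", "T2"), seed = 8)
  em <- fx$em
  # force one gene to identical case/control group means in both tissues
  md <- em$metadata
  v <- em$values
  for (ti in c("T1", "T2")) for (st in c("case", "control")) {
    idx <- md$tissue == ti & md$status == st
    v["G001", idx] <- v["G001", idx] - mean(v["G001", idx])
  }
  em <- expression_matrix(v, md)
  de <- moderated_test(em)
  expect_equal(de$stat[de$gene == "G001"], 0)
  expect_equal(de$p[de$gene == "G001"], 1)
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_equal(de$candidate, de$p <= 0.05)
  expect_equal(de$direction, sign(de$delta))
  # delta is the sum of per-tissue log-fold-changes
  expect_equal(de$delta, de$lfc_T1 + de$lfc_T2)

  # prior_df = 0 recovers the ordinary (unmoderated) F statistic
  de0 <- moderated_test(em, prior_df = 0)
  grp <- interaction(md$tissue, md$status)
  ordinary <- apply(em$values, 1, function(x) {
    fit <- lm(x ~ 0 + grp)
    s2 <- sum(resid(fit)^2) / fit$df.residual
    lfc1 <- mean(x[grp == "T1.case"]) - mean(x[grp == "T1.control"])
    lfc2 <- mean(x[grp == "T2.case"]) - mean(x[grp == "T2.control"])
    mean(c(lfc1^2, lfc2^2) / (s2 * (1 / 5 + 1 / 5)))
  })
  expect_equal(de0$stat, unname(ordinary), tolerance = 1e-10)

  # prior_df = Inf: statistic is the pooled z against the prior variance s0
  deI <- moderated_test(em, prior_df = Inf)
  s02 <- attr(deI, "s02")
  z2 <- (de$lfc_T1^2 + de$lfc_T2^2) / 2 / (s02 * (1 / 5 + 1 / 5))
  expect_equal(deI$stat, z2, tolerance = 1e-10)

  # p monotone decreasing in the statistic at fixed df
  ord <- order(de$stat)
  expect_true(all(diff(de$p[ord]) <= 1e-12))

  # delta invariant under sample permutation
  perm <- sample(ncol(em$values))
  de_p <- moderated_test(em[, perm])
  expect_equal(de_p$delta[match(de$gene, de_p$gene)], de$delta)
})

test_that("moderated test matches the reference empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  fx <- make_block_em(c(40, 40), rho = 0.3, n_case = 6, n_ctrl = 6,
                      tissues = c("T1", "T2", "T3"), shift = 1, seed = 21)
  # heterogeneous gene variances so the prior df is finite and shrinkage real
  set.seed(22)
  v <- fx$em$values * runif(nrow(fx$em$values), 0.5, 2)
  em <- expression_matrix(v, fx$em$metadata)
  de_chk <- moderated_test(em)
  expect_true(is.finite(attr(de_chk, "d0")))
  de <- moderated_test(em)
  mt <- moderated_t(em)
  md <- em$metadata
  grp <- factor(paste(md$tissue, md$status, sep = "."))
  design <- model.matrix(~ 0 + grp)
  colnames(design) <- levels(grp)
  fit <- limma::lmFit(em$values, design)
  ctr <- limma::makeContrasts(T1.case - T1.control, T2.case - T2.control,
                              T3.case - T3.control, levels = design)
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, ctr))
  expect_equal(attr(de, "d0"), fit2$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "s02"), fit2$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mt$t), unname(fit2$t), tolerance = 1e-8)
  expect_equal(unname(de$stat), unname(fit2$F), tolerance = 1e-8)
  expect_equal(de$p, fit2$F.p.value, tolerance = 1e-8)
})

test_that("moderated test enforces the per-arm sample minimum", {
  fx <- make_block_em(10, rho = 0, n_case = 1, n_ctrl = 4, seed = 2)
  expect_error(moderated_test(fx$em), ">= 2 samples per arm")
})
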