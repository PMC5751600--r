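make_toy_modnet <- function() {
  ppi <- ppi_network(data.frame(p = c("p", "p", "a"), q = c("a", "b", "b"),
                                conf = c(0.9, 0.8, 0.85)))
  de <- structure(data.frame(gene = c("p", "a", "b"), stat = 1, p = 0.01,
                             candidate = TRUE, delta = c(3, -2, 1),
                             direction = c(1, -1, 1)),
                  class = c("de_result", "data.frame"))
  build_module_network(c("p", "a", "b"), ppi, 0, de,
                       seed_set = "p", expanded_set = c("p", "a"),
                       label = "toy")
}

test_that("conf_dp is the signed probability-weighted evidence sum", {
  expect_equal(conf_dp(1.0, 1), 1.0)
  expect_equal(conf_dp(c(0.8, 0.5), c(1, -1)), 0.3)
  expect_equal(conf_dp(numeric(0), numeric(0)), 0)
  set.seed(41)
  pr <- runif(10); sg <- sample(c(1, -1), 10, TRUE)
  expect_equal(conf_dp(pr, sg), sum(pr * sg))
  # the per-pair table aggregates evidence rows per (drug, target)
  ev <- drug_evidence(data.frame(drug_id = "D1", drug_name = "d",
                                 target = rep("p", 10), prob = pr, sign = sg))
  expect_equal(conf_table(ev)$conf, sum(pr * sg))
  expect_equal(conf_table(ev)$n_evidence, 10L)
})

test_that("weight_p: formula, zero case, scaling law, degree-0 error", {
  ppi <- ppi_network(data.frame(p = c("p", "p"), q = c("a", "b"),
                                conf = c(0.9, 0.8)))
  expect_equal(weight_p(ppi, "p", k_const = 2), 2 * log(1.7) - log(2),
               tolerance = 1e-12)
  one <- ppi_network(data.frame(p = "p", q = "a", conf = 1.0))
  expect_equal(weight_p(one, "p"), 0)
  # doubling all confidences raises the weight by exactly k*ln(2)
  half <- ppi_network(data.frame(p = c("p", "p"), q = c("a", "b"),
                                 conf = c(0.45, 0.4)))
  expect_equal(weight_p(ppi, "p", 2) - weight_p(half, "p", 2), 2 * log(2),
               tolerance = 1e-12)
  expect_error(weight_p(ppi, "zzz"), "degree 0")
  # vectorized weights agree with the scalar form
  rppi <- make_random_ppi(12, 30, seed = 43)
  w <- weight_table(rppi, rppi$nodes)
  for (nd in rppi$nodes)
    expect_equal(unname(w[nd]), weight_p(rppi, nd), tolerance = 1e-12)
})

test_that("p_score is the product and rp_score the exponential identity", {
  expect_equal(p_score(0, 3.2), 0)
  expect_equal(p_score(1, 0.77), 0.77)
  set.seed(47)
  cf <- runif(20, -1, 1); w <- runif(20, -2, 2)
  expect_equal(p_score(cf, w), cf * w)

  mn <- make_toy_modnet()
  # closed form at k = 2: S^2 / deg
  expect_equal(rp_score(mn, "p"), 1.7^2 / 2, tolerance = 1e-12)
  one <- make_toy_modnet()
  one$edges <- one$edges[1, ]; one$edges$conf <- 1
  expect_equal(rp_score(one, "p"), 1)
  # cross-operation consistency: rp = exp(weight on the module network)
  for (g in mn$nodes$gene)
    expect_equal(rp_score(mn, g), exp(weight_p(mn, g)), tolerance = 1e-12)
  expect_error(rp_score(mn, "zzz"), "absent")
})

test_that("DES: hand-built single-term evaluation and sign flip", {
  mn <- make_toy_modnet()
  # single target p: up-regulated (g=+1), priority 1, rp forced to 8
  mn$nodes$rp_score[mn$nodes$gene == "p"] <- 8
  conf <- c(p = -0.9)                    # inhibiting drug
  ps <- c(p = -4)                        # |P-score| = 4
  # sign_d = -sign(-0.9)*+1 = +1; term = 1 * log2(4) * log2(8) * 1 = 6
  expect_equal(des_score(conf, ps, mn), 6)
  # activating drug reinforces the dysregulation: score flips sign
  expect_equal(des_score(c(p = 0.9), c(p = 4), mn), -6)
  # no eligible target
  expect_equal(des_score(c(zz = 1), c(zz = 2), mn), 0)
  # genes with no measured dysregulation contribute nothing
  mn0 <- mn; mn0$nodes$direction[mn0$nodes$gene == "p"] <- 0
  expect_equal(des_score(conf, ps, mn0), 0)
  # sub-unit magnitudes are floored at log2 = 0, not made negative
  expect_equal(des_score(c(p = -0.9), c(p = -0.5), mn), 0)
})

test_that("DESS: definition, additivity and enrichment weighting", {
  expect_equal(dess_score(c(m1 = 3), c(m1 = 0.5)), 1.5)
  expect_equal(dess_score(numeric(0), numeric(0)), 0)
  # only positively enriched modules count
  expect_equal(dess_score(c(m1 = 3, m2 = 10), c(m1 = 0.5, m2 = -1)), 1.5)
  set.seed(53)
  des <- setNames(rnorm(6), paste0("m", 1:6))
  f <- setNames(runif(6, 0.1, 2), paste0("m", 1:6))
  total <- dess_score(des, f)
  parts <- sapply(paste0("m", 1:6), function(m)
    dess_score(des[m], f[m]))
  expect_equal(total, sum(parts), tolerance = 1e-12)
  expect_equal(total, sum(des * f), tolerance = 1e-12)
})

test_that("ranking: top-fraction count, floor guard, permutation invariance", {
  set.seed(59)
  tab <- data.frame(drug_id = sprintf("D%04d", 1:1246),
                    drug_name = "x", dess = rnorm(1246))
  ranked <- rank_and_select(tab, 0.01)
  expect_equal(sum(ranked$top), 12)
  expect_equal(ranked$rank, 1:1246)
  expect_true(all(diff(ranked$dess) <= 0))
  # single drug: the floor guard still selects one
  expect_equal(sum(rank_and_select(tab[1, ], 0.01)$top), 1)
  # permuting the input leaves the ranking identical
  ranked2 <- rank_and_select(tab[sample(1246), ], 0.01)
  expect_identical(ranked2, ranked)
  # deterministic tie-break by drug id
  ties <- data.frame(drug_id = c("D2", "D1"), drug_name = "x", dess = c(1, 1))
  expect_equal(rank_and_select(ties, 0.5)$drug_id, c("D1", "D2"))
})

test_that("extended drug network: typed edges and attribute oracle", {
  mn <- make_toy_modnet()
  ev <- drug_evidence(data.frame(
    drug_id = c("D1", "D1", "D2"), drug_name = c("one", "one", "two"),
    target = c("p", "x", "a"), prob = c(0.9, 0.7, 0.8),
    sign = c(-1, 1, 1)))
  ppi <- ppi_network(data.frame(p = c("p", "p", "x"), q = c("a", "b", "a"),
                                conf = c(0.9, 0.5, 0.8)))
  net <- build_extended_drug_network(c("D1", "D2"), list(toy = mn), ev, ppi,
                                     conf_threshold = 0.75)
  # drug edge signs equal sign(conf(d, p))
  ct <- conf_table(ev)
  for (i in seq_len(nrow(ct))) {
    e <- net$edges[net$edges$from == ct$drug_id[i] &
                     net$edges$to == ct$target[i], ]
    expect_equal(e$type, ifelse(ct$conf[i] > 0, "stimulation", "inhibition"))
    expect_equal(e$value, ct$conf[i])
  }
  # all PPI edges respect the confidence threshold
  pe <- net$edges[net$edges$type == "ppi", ]
  expect_true(all(pe$value >= 0.75))
  # x is an extension gene, p and a are module genes
  expect_equal(net$nodes$type[net$nodes$id == "x"], "extension_gene")
  expect_true(all(net$nodes$type[net$nodes$id %in% c("p", "a")] ==
                    "module_gene"))
  # minimal case: one drug, one module target
  net1 <- build_extended_drug_network("D2", list(toy = mn), ev, ppi, 0.99)
  expect_setequal(net1$nodes$id, c("a", "D2"))
  expect_equal(nrow(net1$edges), 1)
})

test_that("therapeutic monotonicity: boosting an aligned target helps", {
  mn <- make_toy_modnet()
  w <- c(p = 5, a = 5)  # fixed node weights so |P-score| clears the floor
  f <- c(toy = 1.2)
  dess_at <- function(cp) {
    conf <- c(p = cp, a = 0.5)  # a is down-regulated; activating opposes it
    ps <- p_score(conf, w[names(conf)])
    names(ps) <- names(conf)
    dess_score(c(toy = des_score(conf, ps, mn)), f)
  }
  # p is up-regulated: strengthening the inhibition (conf more negative)
  # never decreases the DESS
  vals <- sapply(seq(-0.1, -1, by = -0.1), dess_at)
  expect_true(all(diff(vals) >= -1e-12))
})
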