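# Independent oracles and tiny fixtures used across the suite.

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(length(a), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# brute-force O(n^3) TOM dissimilarity from an expression matrix
tom_brute <- function(values, beta) {
  a <- abs(stats::cor(t(values)))^beta
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    d[i, j] <- 1 - (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  d
}

# exact-arithmetic hypergeometric pmf via prime factorization of the
# factorial ratio: exponents are exact integers; only the final product of
# small prime powers is floating point.
primes_upto <- function(n) {
  if (n < 2) return(integer(0))
  is_p <- rep(TRUE, n)
  is_p[1] <- FALSE
  for (i in 2:floor(sqrt(n))) if (is_p[i]) is_p[seq(i * i, n, by = i)] <- FALSE
  which(is_p)
}

factorial_exponent <- function(n, p) {
  e <- 0L
  q <- p
  while (q <= n) {
    e <- e + n %/% q
    q <- q * p
  }
  e
}

hyper_pmf_exact <- function(N, K, n, k) {
  ps <- primes_upto(max(N, 2))
  e <- vapply(ps, function(p) {
    factorial_exponent(K, p) + factorial_exponent(N - K, p) +
      factorial_exponent(n, p) + factorial_exponent(N - n, p) -
      factorial_exponent(N, p) - factorial_exponent(k, p) -
      factorial_exponent(K - k, p) - factorial_exponent(n - k, p) -
      factorial_exponent(N - K - n + k, p)
  }, numeric(1))
  prod(ps[e > 0]^e[e > 0]) / prod(ps[e < 0]^(-e[e < 0]))
}

# small block-structured expression fixture with metadata
make_block_em <- function(block_sizes, rho = 0.9, n_case = 6, n_ctrl = 6,
                          tissues = "T1", shift = 0, seed = 1) {
  set.seed(seed)
  n_genes <- sum(block_sizes)
  samples <- unlist(lapply(tissues, function(ti)
    paste0(ti, "_", c(sprintf("case%02d", seq_len(n_case)),
                      sprintf("ctrl%02d", seq_len(n_ctrl))))))
  md <- data.frame(sample = samples,
                   tissue = rep(tissues, each = n_case + n_ctrl),
                   status = rep(rep(c("case", "control"),
                                    c(n_case, n_ctrl)), length(tissues)),
                   stringsAsFactors = FALSE)
  n_s <- length(samples)
  block <- rep(seq_along(block_sizes), block_sizes)
  X <- matrix(0, n_genes, n_s)
  for (b in seq_along(block_sizes)) {
    f <- rnorm(n_s)
    idx <- which(block == b)
    X[idx, ] <- sqrt(rho) * matrix(rep(f, each = length(idx)),
                                   length(idx)) +
      sqrt(1 - rho) * matrix(rnorm(length(idx) * n_s), length(idx))
  }
  if (shift != 0) X[block == 1, md$status == "case"] <-
    X[block == 1, md$status == "case"] + shift
  rownames(X) <- sprintf("G%03d", seq_len(n_genes))
  colnames(X) <- samples
  list(em = expression_matrix(X, md), block = block)
}

# random small PPI fixture
make_random_ppi <- function(n_nodes = 10, n_edges = 20, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  ppi_network(data.frame(p = pairs[pick, 1], q = pairs[pick, 2],
                         conf = round(runif(length(pick)), 3),
                         stringsAsFactors = FALSE))
}
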