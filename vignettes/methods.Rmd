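---
title: "Module-based drug repositioning: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-based drug repositioning: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modrepo)
```

`modrepo` chains four statistical stages — moderated differential
expression, weighted co-expression module detection, hypergeometric module
selection against a GWAS-seeded regulatory network, and reversal-rewarding
drug scoring — into a reproducible file-based pipeline. This vignette
explains each model, the tunable parameters and their defaults, the
numerical choices made where the design was genuinely open, and what the
synthetic benchmark does and does not establish.

## 1. Moderated differential expression

Expression is assumed normalized and log-scale; probe-level matrices are
collapsed to genes by the arithmetic mean of each gene's probes. Samples
carry a tissue label and a case/control status, and every tissue must have
at least two samples per arm.

The test fits one mean per tissue × status cell and pools the residual
variance $s_g^2$ per gene ($d$ residual degrees of freedom). Sample
variances are modelled as $s_g^2 \sim s_0^2 F(d, d_0)$ and the prior
$(d_0, s_0^2)$ is fitted by method of moments on $\log s_g^2$ (the standard
empirical-Bayes construction; when the observed spread of log-variances
does not exceed chi-square sampling noise the prior degrees of freedom are
infinite and $s_0^2$ is the mean variance). Posterior variances
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ give one moderated
case-minus-control $t$ per tissue; because tissues use disjoint samples the
contrasts are orthogonal and the overall moderated $F$ is the mean squared
$t$ with $(n_\text{tissues}, d_0 + d)$ degrees of freedom. The test suite
checks this implementation against `limma::eBayes` as an independent
oracle, and checks the two analytic limits (prior df 0: ordinary $F$;
prior df $\infty$: $z$ against $s_0$).

Parameters: `alpha` (candidate cutoff, default 0.05 on raw p-values;
`use_fdr = TRUE` switches to Benjamini–Hochberg, offered because published
descriptions of this design vary between the two). The accumulated change
$\Delta_i$ is the plain sum of per-tissue log-fold-changes; its sign $g_i$
is the dysregulation direction used by the drug scores, and genes with
$\Delta_i = 0$ are excluded from scoring.

## 2. Co-expression modules

Unsigned weighted analysis: adjacency $a_{ij} = |\mathrm{cor}(x_i,x_j)|^\beta$
(Pearson, not biweight), topological overlap
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$,
and average-linkage clustering of $1-\mathrm{TOM}$.

**Static cut instead of dynamic hybrid cutting.** The tree is cut at a fixed
height (`cut_height`, default 0.97) and clusters below `min_module_size`
(default 30) become "grey". A static cut is fully reproducible and has two
transparent knobs; the defaults were chosen once by inspecting
average-linkage TOM dendrograms of block-correlated data, where between-block
merge heights concentrate above 0.99 and within-block below 0.95, and were
not revisited. Modules are named from the conventional palette (turquoise,
blue, brown, yellow, green, …) in decreasing size order, with size ties
broken by the lexicographically smallest member gene so labels cannot depend
on input row order.

**Soft-threshold selection and its failure mode.** For each candidate power
(default 1–20) connectivities are binned (10 equal-width bins) and the
scale-free fit index is the squared correlation of log-frequency against
log-connectivity. The chosen $\beta$ is the smallest power reaching
`rsq_target` (default 0.8) — but only among powers whose mean connectivity
stays above `max(2, 1%)` of the gene count. This eligibility floor is a
deliberate deviation from the textbook rule: on block-correlated data the
index is pathological in both directions — it never reaches the target at
informative powers, and it *spuriously* reaches it at extreme powers where
the network has essentially no edges left (we measured fit "passes" at
$\beta = 11\text{–}13$ with mean connectivity under 3, where planted-block
recovery collapses from ARI 1.0 to 0.07–0.74). When no eligible power
reaches the target, the fallback is the candidate closest to
`fallback_power = 6`, the field-standard default for unsigned networks —
not the argmax of an uninformative fit. Both knobs are exposed.

**Eigengenes.** A module's eigengene is the first right singular vector of
its row-standardized submatrix, sign-oriented to correlate positively with
the module's mean standardized profile (PCA sign is otherwise arbitrary).
Correlation summaries are reported two ways: per (module, sample), the
Pearson correlation of the sample's standardized module expression with the
module's gene loadings (with the asymptotic t-based p-value at
$n_\text{genes}-2$ df); and per (module, tissue), a two-sample t-test of
eigengene values, case versus control.

## 3. Disease-specific module selection

Seed genes are expanded one layer through the directed regulatory edge list:
nodes are seeds plus any gene sharing an edge with a seed, and the edge set
is the *induced subgraph* on those nodes (published expanded networks carry
more edges than a pure star expansion, so neighbour–neighbour edges are
kept). Edge signs, which curated regulatory databases often omit, are
stored but unused here.

With $N$ clustered genes of which $K$ lie in the expanded network, a module
of $n$ genes containing $k$ scores
$f(\mathrm{pts}) = \mathrm{sign}(K/N - k/n)\,\log_{10} P(X = k)$,
$X \sim \mathrm{Hypergeom}(N, K, n)$. Because the point probability is
below one, the score is positive exactly for over-represented modules.
Three resolved design points:

* **Base 10, point probability.** The published description says only
  "log"; base 10 with the pmf (not a tail sum) reproduces all five printed
  scores from the printed counts (0.94, 0.86, −0.55, −0.65, −0.92), which
  the acceptance suite verifies against an exact-arithmetic
  (prime-factorization) pmf oracle. A tail-based variant is deliberately
  not offered.
* **The universe $N$** is every gene that entered clustering, grey included
  — matching published count tables whose $N$ slightly exceeds the sum of
  module sizes. This also matters statistically: hit rates of the modules
  alone bracket $K/N$, so a universe restricted to module genes could never
  select every disease module.
* **PPI grade threshold.** Star-grade interaction tiers have no public
  numeric mapping; module networks keep edges with confidence ≥
  `ppi_threshold` (default 0.75 on [0,1], configurable). Genes left with
  degree zero are dropped.

Module-network genes carry a priority $p_i$: 1 for GWAS seeds, 1/2 for
other expanded-network genes, 1/4 otherwise.

## 4. Drug scoring

`conf(d,p)` is the signed, probability-weighted sum of evidence items.
The node weight and the RP-score were published as sums "over all pairs in
the network", which would make them protein-independent constants; they are
implemented as per-protein sums over *incident* edges (node strength $S_p$
and degree), the only reading under which they are functions of $p$:
$\mathrm{weight}(p) = k\ln S_p - \ln \deg_p$ on the full PPI network, and
$\mathrm{RP}(p) = \exp(k\ln S_p^{mod} - \ln\deg_p^{mod})$ on the module
network (with $k = 2$, $S^2/\deg$). The pharmacology score printed as
"conf(p,q) × weight(p)" is read as $\mathrm{conf}(d,p) \times
\mathrm{weight}(p)$ — the only type-correct combination.

The per-module effect score multiplies, per eligible target (in the module
network, nonzero confidence, nonzero dysregulation):
reversal alignment $\mathrm{sign}_{di} = -\mathrm{sign}(\mathrm{conf})\cdot g_i$,
$\log_2$ magnitudes of |P-score| and RP-score, and the priority. Two
implementer decisions: the alignment sign follows the stated intent that a
drug should reverse the pathological direction (no formula was published),
and each $\log_2$ factor is floored at zero so that sub-unit magnitudes
cannot flip a term's sign — term signs are carried solely by the alignment.
DESS sums module scores weighted by their (positive) enrichment scores;
ranking is by descending DESS with lexicographic drug-id tie-breaks, and
the top `top_fraction` (default 1%, floor-guarded to at least one drug) is
flagged.

## 5. The synthetic world

The generator emulates a three-region case/control microarray study with
known truth. Defaults describe the benchmark world: 12 blocks × 60 genes,
within-block correlation 0.7 (factor model), 3 tissues × 24 samples (half
case), unit noise; blocks 1–2 dysregulated with a 1.5-SD case shift
(opposite signs) in every tissue; 40 seed genes, 75% drawn from the
dysregulated blocks, each emitting 5 regulatory edges (70% within its own
block); a preferential-attachment PPI backbone (2 edges/gene) plus 120
random within-block edges per block, confidences Beta(8,2) within blocks
and Beta(2,2) elsewhere; 30 random decoy drugs of 10 targets and one
designed therapeutic whose signs oppose the planted shifts, with 2–4
evidence items per target at probabilities 0.7–0.95 (multiple concordant
evidence items place |P-scores| above 1, the regime the log2-based scores
were designed for — single weak-evidence worlds degenerate to all-zero
scores and test nothing).

Non-designated blocks additionally receive small random per-(block, tissue)
case shifts (`background_shift`, SD 0.5 noise units). Real case/control
arrays show exactly this broad low-level differential expression (published
candidate sets are far larger than the null rate of the test), and it is
what makes non-disease candidate modules exist so that module *selection*
is a real discrimination task rather than a two-horse race. Setting it to 0
recovers a strictly null background, which the type-I-error calibration
check uses.

What a green benchmark does establish: probes→genes→moderated test→TOM
modules→enrichment→drug ranking recovers planted structure reliably
(planted-block ARI ≥ 0.8 and therapeutic-over-decoy ranking in ≥ 18/20
seeds). What it does not: the generator has Gaussian noise, exactly
block-diagonal correlation and honest evidence signs — no batch effects,
heavy tails, probe cross-hybridization, correlated evidence errors or
annotation noise. Absolute DESS values depend on the scale of the drug and
PPI databases and are not comparable across worlds; published absolute
scores are therefore outside the reproduction surface, while the printed
enrichment scores, computable from their printed counts, are reproduced
exactly.

## 6. Numerical and degenerate-input policy

Readers reject out-of-range confidences, malformed signs, duplicate genes,
samples or undirected edges, and unparsable values, naming the offender.
Zero-variance genes are an error in correlation stages (named); constant
genes in the moderated test are handled by the shrunken variance. The TOM
matrix is symmetrized after computation to remove float asymmetry;
dissimilarities live in [0,1] with zero diagonal. `sign(0) = 0` makes a
module sitting exactly at the expected overlap score 0 (not selected).
Every artifact embeds the run configuration (seed included) as a comment
header, and the run manifest stores MD5 hashes of all artifacts with no
timestamps, so identical (inputs, config, seed) reruns are byte-identical.

## Known limitations

Static tree cutting will not separate nested or touching modules the way
dynamic hybrid cutting can; module merging by eigengene similarity is not
implemented; blockwise processing for very large gene sets (> 20k) is out
of scope; and the scale-free fit index should be treated as diagnostic
output rather than an autonomous selector whenever the data are strongly
block-structured (see §2).
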