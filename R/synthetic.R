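# Synthetic input generator with planted ground truth. Emulates the
# structure of a three-brain-region case/control microarray study:
# block-correlated gene expression, per-tissue case shifts in dysregulated
# blocks, a scale-free-ish PPI graph with beta-distributed confidences
# (higher within planted blocks), regulatory edges centered on GWAS-like
# seed genes, and a drug roster containing one designed therapeutic whose
# signed target actions reverse the planted dysregulation.

#' Synthetic-generator configuration
#'
#' Defaults describe the stated benchmark world: 12 correlated blocks of 60
#' genes, 2 of them dysregulated with a 1.5-SD case shift in every tissue,
#' 3 tissues with 24 samples each (12 case / 12 control), unit noise SD.
#'
#' @param n_blocks number of planted co-expression blocks.
#' @param block_size genes per block.
#' @param n_dysreg number of dysregulated blocks (alternating shift sign,
#'   first block up).
#' @param shift case-minus-control mean shift, in units of the noise SD,
#'   applied in every tissue.
#' @param background_shift SD (in noise-SD units) of small random
#'   per-(block, tissue) case shifts applied to the non-designated blocks,
#'   emulating the broad low-level differential expression of real
#'   case/control arrays; these blocks can enter the candidate set but are
#'   not seed-enriched. Set 0 for a strictly null background.
#' @param rho_in within-block expression correlation.
#' @param rho_out between-block correlation (shared global factor).
#' @param noise_sd residual SD of each gene.
#' @param tissues tissue labels.
#' @param samples_per_tissue samples per tissue (half case, half control).
#' @param probes_per_gene each gene is measured by 1..`probes_per_gene`
#'   probes (probe value = gene value + N(0, `probe_sd`)).
#' @param probe_sd probe-level measurement SD.
#' @param n_seeds number of GWAS-like seed genes.
#' @param seed_frac_dysreg fraction of seeds drawn from dysregulated blocks.
#' @param reg_out_per_seed regulatory edges attached per seed.
#' @param reg_within_prob probability a seed's regulatory partner comes from
#'   the seed's own block (else uniform over all genes).
#' @param ppi_m preferential-attachment edges per gene in the background PPI.
#' @param ppi_block_edges extra random within-block PPI edges per block.
#' @param conf_in Beta shape pair for within-block edge confidences.
#' @param conf_out Beta shape pair for background edge confidences.
#' @param n_decoys random decoy drugs in the roster.
#' @param targets_per_drug targets per drug.
#' @param ev_per_target range (min, max) of evidence items per drug-target
#'   pair; multiple concordant evidence items give signed confidences with
#'   magnitude above 1, the regime the log2-based effect scores address.
#' @param ev_prob_range range of per-evidence probabilities.
#' @param therapeutic_targets_per_block designed-therapeutic targets drawn
#'   from each dysregulated block.
#' @param soft_power the soft-thresholding power the generated world is
#'   designed around (recorded in the truth sidecar; block-correlated
#'   expression is not scale-free, so threshold selection falls back to it).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_blocks = 12, block_size = 60, n_dysreg = 2,
                         shift = 1.5, background_shift = 0.5,
                         rho_in = 0.7, rho_out = 0,
                         noise_sd = 1, tissues = c("FG", "LS", "MS"),
                         samples_per_tissue = 24, probes_per_gene = 2,
                         probe_sd = 0.1, n_seeds = 40,
                         seed_frac_dysreg = 0.75, reg_out_per_seed = 5,
                         reg_within_prob = 0.7, ppi_m = 2,
                         ppi_block_edges = 120, conf_in = c(8, 2),
                         conf_out = c(2, 2), n_decoys = 30,
                         targets_per_drug = 10,
                         ev_per_target = c(2, 4),
                         ev_prob_range = c(0.7, 0.95),
                         therapeutic_targets_per_block = 5,
                         soft_power = 6) {
  stopifnot(n_blocks >= 1, block_size >= 2, n_dysreg >= 0,
            n_dysreg <= n_blocks, shift >= 0, background_shift >= 0,
            rho_in >= 0, rho_in < 1, rho_out >= 0, rho_out <= rho_in,
            noise_sd > 0, samples_per_tissue >= 4,
            samples_per_tissue %% 2 == 0, probes_per_gene >= 1,
            n_seeds >= 1, n_seeds <= n_blocks * block_size,
            seed_frac_dysreg >= 0, seed_frac_dysreg <= 1,
            ppi_m >= 1, length(conf_in) == 2, length(conf_out) == 2,
            n_decoys >= 0, targets_per_drug >= 1,
            therapeutic_targets_per_block >= 1,
            therapeutic_targets_per_block <= block_size)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a full synthetic input bundle with ground truth
#'
#' All randomness derives from `seed`; the same seed yields a bit-identical
#' bundle.
#'
#' @param cfg a [synth_config()].
#' @param seed integer RNG seed.
#' @return list of class `synth_bundle` with elements `expression`
#'   (gene-level [expression_matrix()]), `probes` (probe-level
#'   [expression_matrix()]), `probe_map`, `seeds` (seed gene symbols),
#'   `regulatory` ([regulatory_network()]), `ppi` ([ppi_network()]),
#'   `evidence` ([drug_evidence()]) and `truth` (list: `block` per gene,
#'   `block_shift` per block, `dysreg_blocks`, `therapeutic_drug`,
#'   `seed` used).
#' @export
generate_bundle <- function(cfg = synth_config(), seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed)
  n_genes <- cfg$n_blocks * cfg$block_size
  genes <- sprintf("G%04d", seq_len(n_genes))
  block <- rep(seq_len(cfg$n_blocks), each = cfg$block_size)
  names(block) <- genes

  samples <- unlist(lapply(cfg$tissues, function(ti)
    paste0(ti, "_", c(sprintf("case%02d", seq_len(cfg$samples_per_tissue / 2)),
                      sprintf("ctrl%02d", seq_len(cfg$samples_per_tissue / 2))))))
  n_s <- length(samples)
  md <- data.frame(sample = samples,
                   tissue = rep(cfg$tissues, each = cfg$samples_per_tissue),
                   status = rep(rep(c("case", "control"),
                                    each = cfg$samples_per_tissue / 2),
                                times = length(cfg$tissues)),
                   stringsAsFactors = FALSE)

  # factor model: X = sqrt(rho_out) g + sqrt(rho_in - rho_out) f_block
  #               + sqrt(1 - rho_in) eps, then scaled to noise_sd
  gshared <- stats::rnorm(n_s)
  X <- matrix(0, n_genes, n_s, dimnames = list(genes, samples))
  for (b in seq_len(cfg$n_blocks)) {
    fb <- stats::rnorm(n_s)
    idx <- which(block == b)
    lat <- sqrt(cfg$rho_out) * gshared + sqrt(cfg$rho_in - cfg$rho_out) * fb
    X[idx, ] <- matrix(rep(lat, each = length(idx)), length(idx)) +
      sqrt(1 - cfg$rho_in) *
      matrix(stats::rnorm(length(idx) * n_s), length(idx))
  }
  X <- X * cfg$noise_sd + 8  # array-like positive log-intensity baseline

  dysreg <- seq_len(cfg$n_dysreg)
  block_shift <- rep(0, cfg$n_blocks)
  if (cfg$n_dysreg > 0)
    block_shift[dysreg] <- cfg$shift * cfg$noise_sd *
      rep(c(1, -1), length.out = cfg$n_dysreg)
  is_case <- md$status == "case"
  for (b in dysreg)
    X[block == b, is_case] <- X[block == b, is_case] + block_shift[b]
  # low-level background perturbation of the remaining blocks
  bg_shift <- matrix(0, cfg$n_blocks, length(cfg$tissues),
                     dimnames = list(NULL, cfg$tissues))
  if (cfg$background_shift > 0 && cfg$n_blocks > cfg$n_dysreg) {
    for (b in setdiff(seq_len(cfg$n_blocks), dysreg)) {
      bg_shift[b, ] <- stats::rnorm(length(cfg$tissues),
                                    sd = cfg$background_shift * cfg$noise_sd)
      for (ti in cfg$tissues) {
        sel_s <- is_case & md$tissue == ti
        X[block == b, sel_s] <- X[block == b, sel_s] + bg_shift[b, ti]
      }
    }
  }
  em <- expression_matrix(X, md)

  # probe layer
  ppg <- sample(seq_len(cfg$probes_per_gene), n_genes, replace = TRUE)
  probe_gene <- rep(genes, ppg)
  probes <- sprintf("P%05d", seq_along(probe_gene))
  P <- X[probe_gene, , drop = FALSE] +
    matrix(stats::rnorm(length(probe_gene) * n_s, sd = cfg$probe_sd),
           length(probe_gene))
  rownames(P) <- probes
  probe_em <- expression_matrix(P, md)
  pm <- probe_map(probes, probe_gene)

  # seed genes: mostly from dysregulated blocks
  n_dys_seed <- round(cfg$n_seeds * cfg$seed_frac_dysreg)
  dys_genes <- genes[block %in% dysreg]
  oth_genes <- genes[!(block %in% dysreg)]
  n_dys_seed <- min(n_dys_seed, length(dys_genes))
  seeds <- sort(c(sample(dys_genes, n_dys_seed),
                  sample(oth_genes, cfg$n_seeds - n_dys_seed)))

  # regulatory edges preferentially within the seed's own block
  reg <- list()
  for (s in seeds) {
    for (j in seq_len(cfg$reg_out_per_seed)) {
      pool <- if (stats::runif(1) < cfg$reg_within_prob)
        setdiff(genes[block == block[[s]]], s) else setdiff(genes, s)
      partner <- sample(pool, 1)
      if (stats::runif(1) < 0.5)
        reg[[length(reg) + 1]] <- c(s, partner)
      else
        reg[[length(reg) + 1]] <- c(partner, s)
    }
  }
  reg <- do.call(rbind, reg)
  sgn <- sample(c(1, -1, NA), nrow(reg), replace = TRUE,
                prob = c(0.4, 0.4, 0.2))
  regnet <- regulatory_network(
    data.frame(src = reg[, 1], dst = reg[, 2], sign = sgn,
               stringsAsFactors = FALSE))

  # PPI: preferential-attachment backbone + dense within-block edges
  g_pa <- igraph::sample_pa(n_genes, m = cfg$ppi_m, directed = FALSE)
  el <- igraph::as_edgelist(g_pa)
  pa_edges <- data.frame(p = genes[el[, 1]], q = genes[el[, 2]],
                         stringsAsFactors = FALSE)
  blk_edges <- list()
  for (b in seq_len(cfg$n_blocks)) {
    bg <- genes[block == b]
    i <- sample(bg, cfg$ppi_block_edges, replace = TRUE)
    j <- sample(bg, cfg$ppi_block_edges, replace = TRUE)
    blk_edges[[b]] <- data.frame(p = i, q = j, stringsAsFactors = FALSE)
  }
  all_e <- rbind(pa_edges, do.call(rbind, blk_edges))
  all_e <- all_e[all_e$p != all_e$q, , drop = FALSE]
  pp <- pmin(all_e$p, all_e$q); qq <- pmax(all_e$p, all_e$q)
  dup <- duplicated(paste(pp, qq, sep = "\t"))
  pp <- pp[!dup]; qq <- qq[!dup]
  within <- block[pp] == block[qq]
  conf <- numeric(length(pp))
  conf[within] <- stats::rbeta(sum(within), cfg$conf_in[1], cfg$conf_in[2])
  conf[!within] <- stats::rbeta(sum(!within), cfg$conf_out[1],
                                cfg$conf_out[2])
  ppi <- ppi_network(data.frame(p = pp, q = qq, conf = conf,
                                stringsAsFactors = FALSE))

  # drug roster: one designed therapeutic + random decoys
  ev_rows <- list()
  add_drug <- function(id, name, targets, signs) {
    for (t in seq_along(targets)) {
      n_ev <- sample(cfg$ev_per_target[1]:cfg$ev_per_target[2], 1)
      probs <- stats::runif(n_ev, cfg$ev_prob_range[1],
                            cfg$ev_prob_range[2])
      ev_rows[[length(ev_rows) + 1]] <<-
        data.frame(drug_id = id, drug_name = name, target = targets[t],
                   prob = probs, sign = rep(signs[t], n_ev),
                   evidence_type = "synthetic", stringsAsFactors = FALSE)
    }
  }
  ther_targets <- unlist(lapply(dysreg, function(b)
    sample(genes[block == b], cfg$therapeutic_targets_per_block)))
  ther_signs <- -sign(block_shift[block[ther_targets]])
  add_drug("D0000", "designed_therapeutic", ther_targets, ther_signs)
  for (d in seq_len(cfg$n_decoys)) {
    tg <- sample(genes, cfg$targets_per_drug)
    add_drug(sprintf("D%04d", d), sprintf("decoy_%04d", d), tg,
             sample(c(1, -1), cfg$targets_per_drug, replace = TRUE))
  }
  ev <- drug_evidence(do.call(rbind, ev_rows))

  structure(list(expression = em, probes = probe_em, probe_map = pm,
                 seeds = seeds, regulatory = regnet, ppi = ppi,
                 evidence = ev,
                 truth = list(block = block, block_shift = block_shift,
                              background_shift = bg_shift,
                              dysreg_blocks = dysreg,
                              therapeutic_drug = "D0000",
                              therapeutic_targets = ther_targets,
                              soft_power = cfg$soft_power,
                              seed = seed)),
            class = "synth_bundle")
}

#' Write a synthetic bundle to a directory
#'
#' Writes every pipeline input in its TSV dialect plus a `truth.tsv`
#' sidecar with the planted block labels.
#'
#' @param bundle a [generate_bundle()] result.
#' @param dir output directory (created if needed).
#' @param config optional [run_config()] embedded in the headers.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, config = NULL) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_expression(bundle$expression, fp("expression.tsv"),
                   fp("metadata.tsv"), config)
  write_expression(bundle$probes, fp("probes.tsv"), fp("metadata.tsv"),
                   config)
  write_probe_map(bundle$probe_map, fp("probe_map.tsv"), config)
  write_gene_list(bundle$seeds, fp("seeds.txt"), config)
  write_regulatory(bundle$regulatory, fp("regulatory.tsv"), config)
  write_ppi(bundle$ppi, fp("ppi.tsv"), config)
  write_drug_evidence(bundle$evidence, fp("drug_evidence.tsv"), config)
  truth <- data.frame(gene = names(bundle$truth$block),
                      block = unname(bundle$truth$block),
                      shift = bundle$truth$block_shift[bundle$truth$block],
                      stringsAsFactors = FALSE)
  write_tsv(truth, fp("truth.tsv"), config)
  invisible(dir)
}
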